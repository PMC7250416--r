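#' Is a DHS bracketed by a convergent CTCF pair?
#'
#' True when the nearest CTCF site upstream of the DHS is forward-oriented
#' and the nearest site downstream is reverse-oriented — the convergent
#' configuration that is the hallmark of architectural chromatin loops.
#' A DHS with no CTCF site on one side is not flanked (returns `FALSE`,
#' not an error). Sites overlapping the DHS itself are ignored.
#'
#' @param dhs A single `GRanges` range.
#' @param ctcf_sites `GRanges` of CTCF sites with `+`/`-` strand.
#' @return Logical scalar.
#' @export
ctcf_flanking <- function(dhs, ctcf_sites) {
  stopifnot(length(dhs) == 1L)
  if (length(ctcf_sites) == 0L) return(FALSE)
  st <- as.character(GenomicRanges::strand(ctcf_sites))
  up <- which(GenomicRanges::end(ctcf_sites) < GenomicRanges::start(dhs))
  down <- which(GenomicRanges::start(ctcf_sites) > GenomicRanges::end(dhs))
  if (length(up) == 0L || length(down) == 0L) return(FALSE)
  nearest_up <- up[which.max(GenomicRanges::end(ctcf_sites)[up])]
  nearest_down <- down[which.min(GenomicRanges::start(ctcf_sites)[down])]
  st[nearest_up] == "+" && st[nearest_down] == "-"
}

#' Integrate evidence into a ranked candidate-enhancer report
#'
#' Combines the reporter-assay activity table with transcription-factor
#' overlap, CTCF flanking and promoter-contact evidence, then ranks
#' candidates lexicographically: (1) activity class (strong > weak >
#' inactive), (2) number of overlapping TF peak sets, descending, (3)
#' promoter-contact value, descending, (4) activity fold-change,
#' descending, with remaining ties broken by genomic position. No numeric
#' weighting is invented: every evidence column is reported so that
#' alternative orderings remain auditable.
#'
#' @param records Activity data frame from [capstarr_activity()] (after
#'   [rank_dhs()]), with `chrom`, `start`, `end` in BED (0-based
#'   half-open) coordinates.
#' @param tf_peak_sets Named list of `GRanges` peak sets.
#' @param ctcf_sites Oriented `GRanges` of CTCF sites.
#' @param contact_profile Optional `GRanges` signal track (e.g. from
#'   [virtual_4c()]) supplying a promoter-contact value at each DHS.
#' @param interactions Optional `GRanges` of called 4C interactions;
#'   overlap is reported (`in_4c_call`) but not used in the ordering.
#' @return `records` with columns `tf_overlap_count`, `tf_overlap_names`,
#'   `ctcf_flanked`, `promoter_contact`, `in_4c_call` and
#'   `priority_rank` (a permutation of `1..N`), sorted by priority.
#' @export
prioritize <- function(records, tf_peak_sets, ctcf_sites,
                       contact_profile = NULL, interactions = NULL) {
  gr <- GenomicRanges::GRanges(
    records$chrom,
    IRanges::IRanges(records$start + 1L, records$end))
  n <- nrow(records)
  ov <- lapply(seq_len(n), function(i) overlap_count(gr[i], tf_peak_sets))
  records$tf_overlap_count <- vapply(ov, as.integer, integer(1))
  records$tf_overlap_names <- vapply(
    ov, function(x) paste(attr(x, "sets"), collapse = ","), character(1))
  records$ctcf_flanked <- vapply(seq_len(n), function(i) {
    ctcf_flanking(gr[i], ctcf_sites)
  }, logical(1))
  records$promoter_contact <- if (is.null(contact_profile)) {
    rep(NA_real_, n)
  } else {
    vapply(seq_len(n), function(i) {
      hit <- GenomicRanges::findOverlaps(gr[i], contact_profile,
                                         ignore.strand = TRUE)
      v <- contact_profile$score[S4Vectors::subjectHits(hit)]
      if (length(v) == 0L || all(is.na(v))) NA_real_
      else mean(v, na.rm = TRUE)
    }, numeric(1))
  }
  records$in_4c_call <- if (is.null(interactions)) {
    rep(NA, n)
  } else {
    GenomicRanges::countOverlaps(gr, interactions,
                                 ignore.strand = TRUE) > 0L
  }
  cls <- as.integer(records$activity_class)       # inactive < weak < strong
  cls[is.na(cls)] <- 0L
  contact <- records$promoter_contact
  contact[is.na(contact)] <- -Inf
  fc <- records$fc
  fc[is.na(fc)] <- -Inf
  ord <- order(-cls, -records$tf_overlap_count, -contact, -fc,
               records$chrom, records$start)
  records$priority_rank <- NA_integer_
  records$priority_rank[ord] <- seq_len(n)
  records[ord, ]
}
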