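#' Construct a synthetic locus model
#'
#' A locus model describes a single synthetic chromosome carrying a
#' lymphoid-gene locus with known regulatory ground truth: the gene with
#' its exons and two alternative first exons, a set of candidate DHSs with
#' true activity fold-changes, named transcription-factor peak sets,
#' oriented CTCF sites, planted TAD boundaries, enhancer-promoter loops,
#' and an optional CRISPR-style deletion. Every simulator in the package
#' consumes this object, so each analysis stage can be tested against the
#' planted truth.
#'
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bases.
#' @param gene `GRanges` of the gene body (one range).
#' @param exons `GRanges` of exons, including the two alternative first
#'   exons named `"E1L"` and `"E1S"`.
#' @param promoter_pos Base position of the main promoter (1-based).
#' @param dhs `GRanges` of candidate DHSs with metadata columns `name`,
#'   `true_fc` (true activity fold-change) and `is_ike120` (logical flag
#'   for the strong, fully-TF-bound enhancer analogue; at most one).
#' @param tf_peak_sets Named list of `GRanges` peak sets, one per factor.
#' @param ctcf_sites `GRanges` of CTCF sites with strand orientation.
#' @param tad_boundaries Integer vector of 1-based bin indices at which a
#'   new TAD starts (given `bin_size`).
#' @param bin_size Hi-C bin size in bases.
#' @param loops Data frame with columns `bin_i`, `bin_j`, `bonus` giving
#'   enhancer-promoter contact multipliers.
#' @param enhancer_truth Character vector of DHS names that are true
#'   enhancers.
#' @param deletion `GRanges` (one range) deleted in the mutant locus, or
#'   `NULL`.
#' @param viewpoint_pos Base position of the 4C viewpoint (bait), normally
#'   just upstream of the promoter.
#' @return An object of class `"locus_model"`.
#' @seealso [default_locus_model()] for the packaged default fixture.
#' @export
locus_model <- function(chrom, chrom_length, gene, exons, promoter_pos,
                        dhs, tf_peak_sets, ctcf_sites, tad_boundaries,
                        bin_size = 10000L, loops = NULL,
                        enhancer_truth = character(),
                        deletion = NULL, viewpoint_pos = promoter_pos) {
  stopifnot(chrom_length > 0, length(gene) == 1L)
  feats <- c(gene, exons, GenomicRanges::granges(dhs),
             GenomicRanges::granges(ctcf_sites))
  if (length(feats) > 0L) {
    stopifnot(all(GenomicRanges::start(feats) >= 1L),
              all(GenomicRanges::end(feats) <= chrom_length))
  }
  stopifnot(!is.null(dhs$true_fc), !is.null(dhs$name))
  if (is.null(dhs$is_ike120)) dhs$is_ike120 <- FALSE
  if (sum(dhs$is_ike120) > 1L) {
    stop("at most one DHS may be flagged as the IkE120 analogue")
  }
  if (sum(dhs$is_ike120) == 1L && length(tf_peak_sets) > 0L) {
    anchor <- dhs[dhs$is_ike120]
    n_ov <- overlap_count(anchor, tf_peak_sets)
    if (n_ov != length(tf_peak_sets)) {
      stop("the flagged IkE120 analogue must overlap every TF peak set")
    }
    if (!ctcf_flanking(anchor, ctcf_sites)) {
      stop("the flagged IkE120 analogue must lie between convergent CTCF sites")
    }
  }
  model <- list(
    chrom = chrom, chrom_length = as.integer(chrom_length),
    gene = gene, exons = exons, promoter_pos = as.integer(promoter_pos),
    dhs = dhs, tf_peak_sets = tf_peak_sets, ctcf_sites = ctcf_sites,
    tad_boundaries = as.integer(tad_boundaries),
    bin_size = as.integer(bin_size),
    loops = loops, enhancer_truth = enhancer_truth,
    deletion = deletion, viewpoint_pos = as.integer(viewpoint_pos)
  )
  class(model) <- "locus_model"
  model
}

#' @export
print.locus_model <- function(x, ...) {
  cat("Synthetic locus model:", x$chrom,
      sprintf("(%.2f Mb)", x$chrom_length / 1e6), "\n")
  cat("  DHSs:", length(x$dhs),
      "| true enhancers:", length(x$enhancer_truth),
      "| TF peak sets:", length(x$tf_peak_sets), "\n")
  cat("  TAD starts at bins:", paste(x$tad_boundaries, collapse = ", "),
      sprintf("(bin size %d bp)", x$bin_size), "\n")
  if (!is.null(x$deletion)) {
    cat(sprintf("  deletion: %d bp at [%d, %d]\n",
                GenomicRanges::width(x$deletion),
                GenomicRanges::start(x$deletion),
                GenomicRanges::end(x$deletion)))
  }
  invisible(x)
}

#' The default synthetic locus fixture
#'
#' A 2 Mb chromosome with 200 Hi-C bins of 10 kb, a gene whose promoter
#' sits at 1.2 Mb, and 13 candidate DHSs of which 6 are active: 2 strong
#' (true fold-change >= 3) and 4 weak (fold-change in 1.5-3), mirroring the
#' census logic the activity module implements. The strong enhancer 120 kb
#' upstream of the promoter is the IkE120 analogue: it is the only DHS
#' overlapped by all six lymphoid transcription-factor peak sets
#' (Ikaros, Runx1, Tcf1, Gata3, Ets1 and E2A), it lies between a convergent
#' CTCF pair bracketing the locus, it receives an enhancer-promoter contact
#' loop in the Hi-C simulator, and it carries the default 305 bp deletion.
#'
#' @return A `"locus_model"` object.
#' @export
default_locus_model <- function() {
  chrom <- "chrSyn"
  len <- 2000000L
  gr <- function(start, end, ...) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), ...)
  }
  gene <- gr(1200001L, 1320000L, strand = "+")
  gene$name <- "GeneA"
  exon_starts <- c(1200001L, 1208001L, 1230001L, 1245001L, 1260001L,
                   1280001L, 1300001L, 1310001L, 1316001L)
  exon_ends <- exon_starts + c(400L, 300L, 150L, 150L, 150L, 150L,
                               150L, 150L, 3999L)
  exons <- gr(exon_starts, exon_ends)
  exons$name <- c("E1L", "E1S", "E2", "E3", "E4", "E5", "E6", "E7", "E8")
  # 13 DHSs; the IkE120 analogue sits 120 kb upstream of the promoter,
  # the IkE180 analogue 180 kb upstream; true fold-changes give
  # 2 strong + 4 weak = 6 active of 13.
  dhs_start <- c(920001L, 960001L, 1020001L, 1060001L, 1080100L,
                 1110001L, 1150001L, 1180001L, 1215001L, 1250001L,
                 1340001L, 1380001L, 1420001L)
  dhs <- gr(dhs_start, dhs_start + 251L)
  dhs$name <- c("DHS-280", "DHS-240", "IkE180", "DHS-140", "IkE120",
                "DHS-90", "DHS-50", "IkE+15up", "IkE+15", "DHS+50",
                "DHS+140", "DHS+180", "DHS+220")
  dhs$true_fc <- c(0.9, 1.1, 3.6, 1.0, 4.5,
                   1.8, 1.0, 2.2, 2.6, 1.6,
                   1.2, 0.8, 1.0)
  dhs$is_ike120 <- dhs$name == "IkE120"
  ike <- dhs[dhs$is_ike120]
  tf_names <- c("Ikaros", "Runx1", "Tcf1", "Gata3", "Ets1", "E2A")
  centre <- (GenomicRanges::start(ike) + GenomicRanges::end(ike)) %/% 2L
  tf_peak_sets <- stats::setNames(lapply(seq_along(tf_names), function(i) {
    # every factor binds the IkE120 analogue; each also binds a couple of
    # other DHSs so no other DHS accumulates all six factors
    other_idx <- c(3L, 9L, 3L, 6L, 9L, 8L)[i]
    other <- dhs[other_idx]
    peaks <- c(
      gr(centre - 60L + 7L * i, centre + 60L + 7L * i),
      gr(GenomicRanges::start(other) + 10L * i,
         GenomicRanges::start(other) + 120L + 10L * i)
    )
    peaks$name <- paste0(tf_names[i], "_peak", seq_along(peaks))
    peaks
  }), tf_names)
  ctcf <- gr(c(1000001L, 1340501L, 1500001L),
             c(1000200L, 1340700L, 1500200L),
             strand = c("+", "-", "-"))
  ctcf$name <- paste0("CTCF_", seq_along(ctcf))
  loops <- data.frame(bin_i = 109L, bin_j = 121L, bonus = 2)
  deletion <- gr(1080073L, 1080377L)  # 305 bp covering the IkE120 DHS core
  locus_model(
    chrom = chrom, chrom_length = len,
    gene = gene, exons = exons, promoter_pos = 1200001L,
    dhs = dhs, tf_peak_sets = tf_peak_sets, ctcf_sites = ctcf,
    tad_boundaries = c(61L, 141L), bin_size = 10000L,
    loops = loops,
    enhancer_truth = c("IkE180", "IkE120", "DHS-90", "IkE+15up",
                       "IkE+15", "DHS+50"),
    deletion = deletion,
    viewpoint_pos = 1198800L  # bait ~1.2 kb upstream of E1L
  )
}

#' Apply the model's deletion, producing the mutant locus
#'
#' Removes the deletion interval from the chromosome: the mutant chromosome
#' is shorter by the deletion width, features fully inside the deletion are
#' removed, features overlapping one edge are truncated, and features
#' downstream of the deletion are shifted left by its width. Deleting a
#' region overlapping the 4C viewpoint or the gene body is refused, as the
#' downstream analyses assume both survive in the mutant.
#'
#' @param model A `"locus_model"` with a non-`NULL` `deletion`.
#' @return The mutant `"locus_model"`; its `deletion` field records the
#'   original (wild-type coordinate) interval for coordinate lifting.
#' @export
apply_deletion <- function(model) {
  del <- model$deletion
  if (is.null(del)) stop("model carries no deletion interval")
  dstart <- GenomicRanges::start(del)
  dend <- GenomicRanges::end(del)
  width <- GenomicRanges::width(del)
  vp <- model$viewpoint_pos
  if (vp >= dstart && vp <= dend) {
    stop("deletion overlaps the 4C viewpoint: unsupported scenario")
  }
  if (dend >= GenomicRanges::start(model$gene) &&
      dstart <= GenomicRanges::end(model$gene)) {
    stop("deletion overlaps the gene body: unsupported scenario")
  }
  shift_gr <- function(gr) {
    if (is.null(gr) || length(gr) == 0L) return(gr)
    s <- GenomicRanges::start(gr)
    e <- GenomicRanges::end(gr)
    inside <- s >= dstart & e <= dend
    gr <- gr[!inside]
    s <- GenomicRanges::start(gr)
    e <- GenomicRanges::end(gr)
    # truncate partial overlaps, then shift anything at/after the deletion
    s_new <- ifelse(s >= dstart & s <= dend, dend + 1L, s)
    e_new <- ifelse(e >= dstart & e <= dend, dstart - 1L, e)
    s_new <- ifelse(s_new > dend, s_new - width, s_new)
    e_new <- ifelse(e_new > dend, e_new - width, e_new)
    GenomicRanges::ranges(gr) <- IRanges::IRanges(s_new, e_new)
    gr
  }
  shift_pos <- function(p) ifelse(p > dend, p - width, p)
  mut <- model
  mut$chrom_length <- model$chrom_length - width
  mut$gene <- shift_gr(model$gene)
  mut$exons <- shift_gr(model$exons)
  mut$promoter_pos <- as.integer(shift_pos(model$promoter_pos))
  mut$viewpoint_pos <- as.integer(shift_pos(model$viewpoint_pos))
  mut$dhs <- shift_gr(model$dhs)
  mut$tf_peak_sets <- lapply(model$tf_peak_sets, shift_gr)
  mut$ctcf_sites <- shift_gr(model$ctcf_sites)
  mut$enhancer_truth <- intersect(model$enhancer_truth, mut$dhs$name)
  mut$is_mutant <- TRUE
  mut
}

#' Lift mutant-coordinate positions back to wild-type coordinates
#'
#' Positions at or beyond the deletion start shift right by the deletion
#' width; positions upstream are unchanged. The inverse of the coordinate
#' shift performed by [apply_deletion()].
#'
#' @param pos Integer vector of 1-based mutant-coordinate positions.
#' @param deletion The deletion `GRanges` in wild-type coordinates.
#' @return Wild-type coordinate positions.
#' @export
lift_to_wt <- function(pos, deletion) {
  dstart <- GenomicRanges::start(deletion)
  width <- GenomicRanges::width(deletion)
  ifelse(pos >= dstart, pos + width, pos)
}
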