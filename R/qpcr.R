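#' Read and write qPCR Ct tables
#'
#' Ct tables are tab-separated with a header and columns `group`,
#' `amplicon`, `replicate`, `ct`.
#'
#' @param path File path.
#' @return `read_ct_table()` returns the table as a data frame after
#'   validation; `write_ct_table()` writes it and returns `path`
#'   invisibly.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validate_ct_table(df)
  df
}

#' @rdname read_ct_table
#' @param table A Ct data frame.
#' @export
write_ct_table <- function(table, path) {
  validate_ct_table(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_ct_table <- function(df) {
  need <- c("group", "amplicon", "replicate", "ct")
  if (!all(need %in% names(df))) {
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(df$ct)) || any(df$ct <= 0)) {
    stop("Ct values must be finite and positive")
  }
  invisible(df)
}

#' Per-replicate delta-Ct values
#'
#' For one sample group, subtracts the housekeeping amplicon's Ct from the
#' target amplicon's Ct within each replicate (pairing by replicate
#' identifier, not row order).
#'
#' @param table Ct data frame (see [read_ct_table()]).
#' @param amplicon Target amplicon name.
#' @param housekeeping Housekeeping amplicon name (e.g. `"Rpl32"`).
#' @param group Sample group name.
#' @return Named numeric vector of delta-Ct values, one per replicate.
#' @export
delta_ct <- function(table, amplicon, housekeeping, group) {
  tgt <- table[table$group == group & table$amplicon == amplicon, ]
  hk <- table[table$group == group & table$amplicon == housekeeping, ]
  if (nrow(tgt) == 0L) stop("no rows for amplicon ", amplicon,
                            " in group ", group)
  missing_hk <- setdiff(tgt$replicate, hk$replicate)
  if (length(missing_hk) > 0L) {
    stop("missing housekeeping Ct for replicate ", missing_hk[1L],
         " in group ", group)
  }
  d <- tgt$ct - hk$ct[match(tgt$replicate, hk$replicate)]
  stats::setNames(d, tgt$replicate)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Computes per-replicate relative expression of `test_group` versus
#' `reference_group` as `efficiency^-(dCt_test - mean dCt_reference)`
#' (fold change over the control), reports the mean and standard deviation
#' over replicates, and tests the group difference with an unpaired
#' two-tailed Student's t-test on the delta-Ct values.
#'
#' @param table Ct data frame.
#' @param amplicon Target amplicon.
#' @param test_group,reference_group Group names; the reference group's
#'   own relative expression is 1 by construction.
#' @param housekeeping Housekeeping amplicon; default `"Rpl32"`.
#' @param efficiency Amplification efficiency; default 2 (a perfect
#'   doubling per cycle).
#' @return A one-row data frame of class `"expression_result"`: `amplicon`,
#'   `relative_expression`, `sd`, `t_statistic`, `p_value`,
#'   `n_replicates`. With a single replicate per group, `sd` and `p_value`
#'   are `NA` with a warning.
#' @examples
#' tab <- data.frame(
#'   group = rep(c("wt", "mut"), each = 2),
#'   amplicon = rep(c("E8", "Rpl32"), 2),
#'   replicate = 1, ct = c(25, 20, 27, 20))
#' relative_expression(tab, "E8", "mut", "wt") # 0.25: four-fold decrease
#' @export
relative_expression <- function(table, amplicon, test_group,
                                reference_group, housekeeping = "Rpl32",
                                efficiency = 2) {
  d_test <- delta_ct(table, amplicon, housekeeping, test_group)
  d_ref <- delta_ct(table, amplicon, housekeeping, reference_group)
  rel <- efficiency^(-(d_test - mean(d_ref)))
  single <- length(d_test) < 2L || length(d_ref) < 2L
  if (single) {
    warning("single replicate: sd and p-value unavailable")
    tt <- list(statistic = NA_real_, p.value = NA_real_)
  } else if (stats::sd(d_test) == 0 && stats::sd(d_ref) == 0) {
    # noiseless groups: a zero shift is no evidence, a non-zero shift is
    # a degenerate (infinite-t) difference
    shift <- mean(d_test) - mean(d_ref)
    tt <- if (shift == 0) list(statistic = 0, p.value = 1)
          else list(statistic = sign(shift) * Inf, p.value = 0)
  } else {
    tt <- stats::t.test(d_test, d_ref, var.equal = FALSE,
                        alternative = "two.sided")
  }
  res <- data.frame(
    amplicon = amplicon,
    relative_expression = mean(rel),
    sd = if (single) NA_real_ else stats::sd(rel),
    t_statistic = unname(tt$statistic),
    p_value = unname(tt$p.value),
    n_replicates = length(d_test),
    stringsAsFactors = FALSE
  )
  class(res) <- c("expression_result", "data.frame")
  res
}

#' Fold induction after stimulation, within a genotype
#'
#' Relative expression of the stimulated versus the unstimulated group of
#' the same genotype — e.g. the fold induction after PMA/ionomycin
#' treatment, computed separately in wild-type and enhancer-deleted cells
#' to test whether the deletion abolishes inducibility.
#'
#' @inheritParams relative_expression
#' @param stim_group,unstim_group Stimulated and unstimulated group names.
#' @return An `"expression_result"` data frame (see
#'   [relative_expression()]).
#' @export
fold_induction <- function(table, amplicon, stim_group, unstim_group,
                           housekeeping = "Rpl32", efficiency = 2) {
  relative_expression(table, amplicon, test_group = stim_group,
                      reference_group = unstim_group,
                      housekeeping = housekeeping, efficiency = efficiency)
}

#' Differential signal track (wild-type minus mutant)
#'
#' Subtracts a mutant coverage track from the wild-type track per base,
#' after lifting the mutant track back to wild-type coordinates through
#' the deletion map: mutant positions at or beyond the deletion start
#' shift right by the deletion width, and the deleted interval itself has
#' no mutant counterpart and is reported as missing (`NA`), so it drops
#' out of the bedGraph on export. Bases covered by neither track are
#' treated as 0 in both.
#'
#' @param wt,mut `GRanges` signal tracks with `score` columns, on the same
#'   chromosome (the mutant track in mutant coordinates when `deletion` is
#'   given).
#' @param deletion Optional deletion `GRanges` in wild-type coordinates.
#' @return A `GRanges` track of `wt - mut` with merged breakpoints.
#' @export
differential_track <- function(wt, mut, deletion = NULL) {
  if (length(wt) > 0L && length(mut) > 0L &&
      as.character(GenomicRanges::seqnames(wt)[1L]) !=
        as.character(GenomicRanges::seqnames(mut)[1L])) {
    stop("tracks are on different chromosomes")
  }
  chrom <- as.character(GenomicRanges::seqnames(wt)[1L])
  if (!is.null(deletion)) {
    s <- lift_to_wt(GenomicRanges::start(mut), deletion)
    e <- lift_to_wt(GenomicRanges::end(mut), deletion)
    mut <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e),
                                  score = mut$score)
  }
  # piecewise-constant subtraction over merged breakpoints
  bp <- sort(unique(c(
    GenomicRanges::start(wt), GenomicRanges::end(wt) + 1L,
    GenomicRanges::start(mut), GenomicRanges::end(mut) + 1L,
    if (!is.null(deletion)) c(GenomicRanges::start(deletion),
                              GenomicRanges::end(deletion) + 1L)
  )))
  if (length(bp) < 2L) return(GenomicRanges::GRanges())
  seg <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(bp[-length(bp)], bp[-1L] - 1L))
  value_at <- function(track, seg) {
    v <- rep(0, length(seg))
    hit <- GenomicRanges::findOverlaps(seg, track, ignore.strand = TRUE)
    v[S4Vectors::queryHits(hit)] <- track$score[S4Vectors::subjectHits(hit)]
    v
  }
  score <- value_at(wt, seg) - value_at(mut, seg)
  if (!is.null(deletion)) {
    inside <- GenomicRanges::countOverlaps(seg, deletion,
                                           ignore.strand = TRUE) > 0L
    score[inside] <- NA_real_
  }
  seg$score <- score
  # merge adjacent segments with identical values
  keep <- c(TRUE, !(score[-1L] == score[-length(score)] |
                      (is.na(score[-1L]) & is.na(score[-length(score)]))))
  keep[is.na(keep)] <- TRUE
  grp <- cumsum(keep)
  starts <- tapply(GenomicRanges::start(seg), grp, min)
  ends <- tapply(GenomicRanges::end(seg), grp, max)
  vals <- score[keep]
  out <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(as.integer(starts), as.integer(ends)))
  out$score <- vals
  out
}
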