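#' Fragments per kilobase per million mapped reads
#'
#' @param count Reads mapped to the fragment.
#' @param fragment_length Fragment length in bases (> 0).
#' @param library_size Total mapped reads in the library (> 0).
#' @return `count / (fragment_length/1000) / (library_size/1e6)`.
#' @examples
#' compute_fpkm(10, 1000, 1e6) # 10
#' @export
compute_fpkm <- function(count, fragment_length, library_size) {
  stopifnot(all(fragment_length > 0))
  if (any(library_size <= 0)) stop("library_size must be positive")
  count / (fragment_length / 1000) / (library_size / 1e6)
}

#' Classify enhancer activity from a fold-change
#'
#' A DHS with screen-over-input fold-change below `weak` is inactive, one
#' with fold-change in `[weak, strong)` is a weak enhancer, and one with
#' fold-change at or above `strong` is a strong enhancer. The inclusive
#' lower bound at `strong` follows the operative rule "equal or higher
#' than" the strong threshold.
#'
#' @param fc Numeric vector of fold-changes (>= 0, finite).
#' @param weak,strong Class thresholds; defaults 1.5 and 3.
#' @return An ordered factor with levels `inactive < weak < strong`.
#' @examples
#' classify_activity(c(1.49, 1.5, 2.99, 3)) # inactive weak weak strong
#' @export
classify_activity <- function(fc, weak = 1.5, strong = 3) {
  if (any(!is.finite(fc)) || any(fc < 0)) {
    stop("fold-changes must be finite and non-negative")
  }
  cls <- ifelse(fc >= strong, "strong", ifelse(fc >= weak, "weak", "inactive"))
  factor(cls, levels = c("inactive", "weak", "strong"), ordered = TRUE)
}

#' Merge replicate fold-changes
#'
#' Default is the arithmetic mean of the replicate fold-changes; pooling
#' the raw counts before forming a single fold-change is available as an
#' alternative through `method = "pool"` (in which case `fc1`/`fc2` are
#' interpreted as the pooled screen and input FPKMs).
#'
#' @param fc1,fc2 Replicate fold-changes (finite).
#' @param method `"mean"` (default) or `"pool"`.
#' @return The merged fold-change.
#' @export
replicate_merge <- function(fc1, fc2, method = c("mean", "pool")) {
  method <- match.arg(method)
  stopifnot(all(is.finite(fc1)), all(is.finite(fc2)))
  if (method == "mean") (fc1 + fc2) / 2 else fc1 / fc2
}

#' Per-DHS activity table from screen/input fragment counts
#'
#' Computes screen and input FPKMs and their ratio (the activity
#' fold-change) for every fragment of a count table, classifies each,
#' and merges replicates by averaging the per-replicate fold-changes.
#' Fragments with zero input FPKM have an undefined fold-change; they are
#' flagged (`fc = NA`) and excluded from ranking rather than set to
#' infinity.
#'
#' @param counts Data frame with columns `fragment_id`, `chrom`, `start`,
#'   `end` (0-based half-open, as in the on-disk table), `screen_count`,
#'   `input_count` and `replicate`.
#' @param weak,strong Classification thresholds passed to
#'   [classify_activity()].
#' @return A data frame with one row per fragment: coordinates, per-
#'   replicate fold-changes, merged `fc`, and `activity_class`.
#' @export
capstarr_activity <- function(counts, weak = 1.5, strong = 3) {
  need <- c("fragment_id", "chrom", "start", "end",
            "screen_count", "input_count", "replicate")
  stopifnot(all(need %in% names(counts)))
  reps <- sort(unique(counts$replicate))
  per_rep <- lapply(reps, function(r) {
    d <- counts[counts$replicate == r, ]
    d <- d[order(d$fragment_id), ]
    len <- d$end - d$start
    fpkm_s <- compute_fpkm(d$screen_count, len, sum(d$screen_count))
    fpkm_i <- compute_fpkm(d$input_count, len, sum(d$input_count))
    fc <- ifelse(fpkm_i > 0, fpkm_s / fpkm_i, NA_real_)
    data.frame(fragment_id = d$fragment_id, chrom = d$chrom,
               start = d$start, end = d$end,
               fpkm_screen = fpkm_s, fpkm_input = fpkm_i, fc = fc,
               stringsAsFactors = FALSE)
  })
  out <- per_rep[[1L]][c("fragment_id", "chrom", "start", "end")]
  fc_mat <- vapply(per_rep, function(d) d$fc, numeric(nrow(out)))
  fc_mat <- matrix(fc_mat, nrow = nrow(out))
  colnames(fc_mat) <- paste0("fc_rep", reps)
  out <- cbind(out, fc_mat)
  out$fpkm_screen <- rowMeans(
    matrix(vapply(per_rep, function(d) d$fpkm_screen, numeric(nrow(out))),
           nrow = nrow(out)))
  out$fpkm_input <- rowMeans(
    matrix(vapply(per_rep, function(d) d$fpkm_input, numeric(nrow(out))),
           nrow = nrow(out)))
  out$fc <- rowMeans(fc_mat)
  out$activity_class <- classify_activity(
    ifelse(is.na(out$fc), 0, out$fc), weak = weak, strong = strong)
  out$activity_class[is.na(out$fc)] <- NA
  out
}

#' Rank DHSs by activity and flag the top fraction
#'
#' Ranks records by descending fold-change (rank 1 = most active) and
#' flags those with rank at most `ceiling(top_fraction * N)` — the "top
#' 5 percent of the most active" cut by default. Ties in fold-change are
#' broken by genomic position (chrom, then start) so the ranking is
#' deterministic and invariant to input row order. Records with missing
#' fold-change are excluded from ranking (`rank = NA`).
#'
#' @param records Data frame with at least `fc`, `chrom`, `start` columns
#'   (e.g. the output of [capstarr_activity()]).
#' @param top_fraction Proportion of ranked records to flag; default 0.05.
#' @return `records` with `rank` and `top_fraction_flag` columns added.
#' @export
rank_dhs <- function(records, top_fraction = 0.05) {
  if (nrow(records) == 0L) {
    records$rank <- integer(0)
    records$top_fraction_flag <- logical(0)
    return(records)
  }
  ok <- !is.na(records$fc)
  ord <- order(-records$fc[ok], records$chrom[ok], records$start[ok])
  rank <- rep(NA_integer_, nrow(records))
  rank[which(ok)[ord]] <- seq_len(sum(ok))
  n_flag <- ceiling(top_fraction * sum(ok))
  records$rank <- rank
  records$top_fraction_flag <- !is.na(rank) & rank <= n_flag
  records
}

#' Census of active enhancers in a record set
#'
#' @param records Data frame with an `activity_class` column.
#' @return Named integer vector `c(n_active, n_total)`; a record counts as
#'   active when its class is weak or strong.
#' @export
count_active <- function(records) {
  stopifnot(nrow(records) > 0L)
  cls <- as.character(records$activity_class)
  c(n_active = sum(cls %in% c("weak", "strong"), na.rm = TRUE),
    n_total = nrow(records))
}
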