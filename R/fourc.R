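#' Running mean over fragments with masking
#'
#' Smooths a per-fragment signal with a centered running mean of odd
#' `window` (default 21 fragments). Masked positions are excluded from both
#' numerator and denominator, and receive `NA` in the output; at the
#' profile edges the window is truncated to the available fragments.
#' Circular padding, which makes the smoother exactly mean-preserving, is
#' available for property checks.
#'
#' @param values Numeric vector of per-fragment values.
#' @param window Odd window size in fragments; default 21.
#' @param mask Integer indices of masked fragments (e.g. the viewpoint and
#'   its neighbours), or `NULL`.
#' @param circular If `TRUE`, wrap the window around the vector ends.
#' @return Smoothed values, `NA` at masked positions.
#' @export
running_mean <- function(values, window = 21L, mask = NULL,
                         circular = FALSE) {
  if (window %% 2L == 0L) stop("window must be odd")
  n <- length(values)
  half <- (window - 1L) %/% 2L
  v <- values
  use <- rep(TRUE, n)
  if (!is.null(mask) && length(mask) > 0L) use[mask] <- FALSE
  use <- use & !is.na(v)
  v[!use] <- 0
  if (circular && n > 0L) {
    idx <- function(i) ((i - 1L) %% n) + 1L
    out <- vapply(seq_len(n), function(i) {
      w <- idx((i - half):(i + half))
      s <- sum(v[w])
      m <- sum(use[w])
      if (m == 0L) NA_real_ else s / m
    }, numeric(1))
  } else {
    cs <- cumsum(c(0, v))
    cn <- cumsum(c(0L, as.integer(use)))
    lo <- pmax(1L, seq_len(n) - half)
    hi <- pmin(n, seq_len(n) + half)
    s <- cs[hi + 1L] - cs[lo]
    m <- cn[hi + 1L] - cn[lo]
    out <- ifelse(m == 0L, NA_real_, s / m)
  }
  if (!is.null(mask) && length(mask) > 0L) out[mask] <- NA_real_
  out
}

#' Quantile normalization across samples
#'
#' Forces every sample to the same empirical distribution: for each rank
#' `r`, each sample's `r`-th order statistic is replaced by the mean of all
#' samples' `r`-th order statistics, so the sorted vectors become identical
#' across samples while within-sample rank order is preserved. Tied input
#' values receive the mean of the target quantiles they span. Positions
#' that are `NA` in every sample (e.g. the shared viewpoint mask) stay
#' `NA`; normalization is computed over the complete positions.
#'
#' @param x Numeric matrix (rows = fragments, columns = samples) or list
#'   of equal-length vectors.
#' @return A matrix of the same shape, quantile-normalized by column.
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantile_normalize <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    len <- unique(lengths(x))
    if (length(len) != 1L) stop("samples must have equal length")
    x <- do.call(cbind, x)
  }
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("quantile normalization needs >= 2 samples")
  shared_na <- rowSums(!is.na(x)) == 0L
  ok <- which(!shared_na)
  if (any(is.na(x[ok, ]))) {
    stop("mask must be shared: found values missing in only some samples")
  }
  sub <- x[ok, , drop = FALSE]
  n <- nrow(sub)
  target <- rowMeans(apply(sub, 2L, sort))
  out_sub <- apply(sub, 2L, function(col) {
    ord <- order(col)
    res <- numeric(n)
    res[ord] <- target
    # tied input values get the mean of the target quantiles they span
    stats::ave(res, match(col, col), FUN = mean)
  })
  res <- x
  res[ok, ] <- out_sub
  res
}

#' Build a 4C fragment profile
#'
#' Attaches raw per-fragment counts to a restriction-fragment map, masks
#' the viewpoint fragment and `mask_flank` fragments on each side (which
#' are dominated by self-ligation and undigested artifacts), and smooths
#' the counts with [running_mean()].
#'
#' @param fragmap Fragment `GRanges` from [digest()].
#' @param counts Numeric vector of raw counts, one per fragment.
#' @param viewpoint Viewpoint as a base position (the fragment containing
#'   it is used) or a fragment index given as `I(index)`.
#' @param window Running-mean window; default 21 fragments.
#' @param mask_flank Fragments masked on each side of the viewpoint;
#'   default 1.
#' @param sample Condition label.
#' @return An object of class `"fourc_profile"` with fields `fragmap`,
#'   `viewpoint` (fragment index), `raw`, `smoothed`, `mask`, `sample`,
#'   and `normalized` (filled by [normalize_profiles()]).
#' @export
fourc_profile <- function(fragmap, counts, viewpoint, window = 21L,
                          mask_flank = 1L, sample = "sample") {
  n <- length(fragmap)
  stopifnot(length(counts) == n)
  if (inherits(viewpoint, "AsIs")) {
    vp <- as.integer(viewpoint)
  } else {
    vp <- which(GenomicRanges::start(fragmap) <= viewpoint &
                  GenomicRanges::end(fragmap) >= viewpoint)
    if (length(vp) != 1L) stop("viewpoint position not inside one fragment")
  }
  mask <- intersect((vp - mask_flank):(vp + mask_flank), seq_len(n))
  smoothed <- running_mean(counts, window = window, mask = mask)
  structure(list(fragmap = fragmap, viewpoint = vp, raw = counts,
                 smoothed = smoothed, normalized = NULL,
                 mask = mask, window = as.integer(window),
                 sample = sample),
            class = "fourc_profile")
}

#' @export
print.fourc_profile <- function(x, ...) {
  cat(sprintf(
    "4C profile '%s': %d fragments, viewpoint fragment %d, window %d%s\n",
    x$sample, length(x$raw), x$viewpoint, x$window,
    if (is.null(x$normalized)) "" else ", quantile-normalized"))
  invisible(x)
}

#' Quantile-normalize a set of 4C profiles jointly
#'
#' All samples are normalized together (joint, not pairwise) on their
#' smoothed values; the shared viewpoint mask stays missing.
#'
#' @param profiles List of `"fourc_profile"` objects over the same
#'   fragment map and viewpoint.
#' @return The list with each profile's `normalized` field filled.
#' @export
normalize_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 2L)
  mat <- vapply(profiles, function(p) p$smoothed,
                numeric(length(profiles[[1L]]$raw)))
  normed <- quantile_normalize(mat)
  for (i in seq_along(profiles)) profiles[[i]]$normalized <- normed[, i]
  profiles
}

#' Call viewpoint interactions from a smoothed 4C profile
#'
#' A deliberately simple, testable interaction caller in the spirit of
#' viewpoint-profile methods: on each side of the viewpoint the background
#' is estimated as a monotone non-increasing fit of the smoothed profile
#' against distance (isotonic regression), residual enrichment is the
#' ratio of smoothed signal to background, and fragments whose enrichment
#' exceeds both the `threshold_quantile` of all residuals and `min_ratio`,
#' in runs of at least `background_window / 3` consecutive fragments, are
#' merged into interaction intervals. The run-length requirement suppresses
#' isolated noise excursions; the ratio floor keeps a flat profile (where
#' every residual is near 1) from producing calls.
#'
#' @param profile A `"fourc_profile"` (normalized values are used when
#'   present, otherwise smoothed).
#' @param background_window Window used for the minimum run length
#'   (`ceiling(background_window / 3)` fragments); default 21.
#' @param threshold_quantile Residual-enrichment quantile above which a
#'   fragment is a peak candidate; default 0.97.
#' @param min_ratio Minimum enrichment over background; default 1.8
#'   (calibrated so that background-only profiles stay below it in runs
#'   long enough to call).
#' @return A `GRanges` of disjoint interaction intervals with a `score`
#'   column (mean enrichment over background within the interval); empty
#'   when nothing exceeds background.
#' @export
call_interactions <- function(profile, background_window = 21L,
                              threshold_quantile = 0.97,
                              min_ratio = 1.8) {
  stopifnot(inherits(profile, "fourc_profile"))
  vals <- if (!is.null(profile$normalized)) profile$normalized
          else profile$smoothed
  n <- length(vals)
  vp <- profile$viewpoint
  if (vp - 1L < background_window && n - vp < background_window) {
    stop("profile shorter than background_window on both sides of viewpoint")
  }
  eps <- 1e-9
  enrich <- rep(NA_real_, n)
  left <- which(seq_len(n) < vp & !is.na(vals))
  right <- which(seq_len(n) > vp & !is.na(vals))
  if (length(left) > 1L) {
    # profile increases towards the viewpoint: isotonic fit left to right
    fit <- stats::isoreg(seq_along(left), vals[left])$yf
    enrich[left] <- vals[left] / pmax(fit, eps)
  }
  if (length(right) > 1L) {
    fit <- -stats::isoreg(seq_along(right), -vals[right])$yf
    enrich[right] <- vals[right] / pmax(fit, eps)
  }
  ok <- which(!is.na(enrich))
  if (length(ok) == 0L) return(empty_calls(profile))
  thr <- max(stats::quantile(enrich[ok], threshold_quantile, names = FALSE),
             min_ratio)
  sig <- !is.na(enrich) & enrich > thr
  min_run <- ceiling(background_window / 3)
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values & runs$lengths >= min_run)
  if (length(keep) == 0L) return(empty_calls(profile))
  gr <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(profile$fragmap))[1L],
    IRanges::IRanges(
      GenomicRanges::start(profile$fragmap)[starts[keep]],
      GenomicRanges::end(profile$fragmap)[ends[keep]]))
  gr$score <- vapply(keep, function(k) {
    mean(enrich[starts[k]:ends[k]])
  }, numeric(1))
  GenomicRanges::sort(gr)
}

empty_calls <- function(profile) {
  gr <- GenomicRanges::GRanges()
  gr$score <- numeric(0)
  gr
}

#' Interactions conserved across call sets
#'
#' Reports the regions supported by every call set: for each group of
#' calls that mutually overlap across all sets, the intersection of the
#' overlapping intervals.
#'
#' @param call_sets List (length >= 2) of interaction-call `GRanges`.
#' @return A `GRanges` of conserved intervals (possibly empty).
#' @export
conserved_calls <- function(call_sets) {
  stopifnot(length(call_sets) >= 1L)
  out <- GenomicRanges::granges(call_sets[[1L]])
  for (s in call_sets[-1L]) {
    if (length(out) == 0L) break
    out <- GenomicRanges::intersect(out, GenomicRanges::granges(s),
                                    ignore.strand = TRUE)
  }
  out
}
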