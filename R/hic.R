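#' Construct a binned contact matrix
#'
#' @param counts Symmetric, non-negative numeric matrix of binned contacts.
#' @param bin_size Bin size in bases (default 10 kb).
#' @param chrom Chromosome name.
#' @return An object of class `"contact_matrix"` with fields `counts`,
#'   `bin_size`, `chrom`, `balanced` and (after balancing) `bias`.
#' @export
contact_matrix <- function(counts, bin_size = 10000L, chrom = "chr") {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(counts))) {
    stop("contact matrix must be symmetric")
  }
  structure(list(counts = counts, bin_size = as.integer(bin_size),
                 chrom = chrom, balanced = FALSE, bias = NULL),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("Contact matrix: %s, %d bins of %d bp, %s\n", x$chrom,
              nrow(x$counts), x$bin_size,
              if (x$balanced) "balanced" else "raw"))
  invisible(x)
}

#' Knight-Ruiz balancing of a symmetric contact matrix
#'
#' Finds a positive diagonal scaling `D = diag(x)` such that every row of
#' `D M D` sums to 1, using the Knight-Ruiz inner-outer Newton iteration
#' (conjugate-gradient inner solves). Bins whose marginal is zero are
#' masked out before balancing and propagate as missing (`NA`) rows and
#' columns in the balanced matrix.
#'
#' @param cm A `"contact_matrix"` (raw counts).
#' @param tol Convergence tolerance on the row-sum dispersion
#'   (`max |rowsum - 1|` over non-masked bins); default `1e-8`.
#' @param max_iter Outer-iteration cap; default 1000.
#' @return The balanced `"contact_matrix"`, with `bias` holding the per-bin
#'   scaling factors (`NA` at masked bins) and `masked` the masked indices.
#' @examples
#' cm <- contact_matrix(matrix(c(2, 1, 1, 2), 2))
#' kr_balance(cm)$counts # rows sum to 1
#' @export
kr_balance <- function(cm, tol = 1e-8, max_iter = 1000L) {
  stopifnot(inherits(cm, "contact_matrix"))
  M <- cm$counts
  n <- nrow(M)
  marg <- rowSums(M)
  masked <- which(marg == 0)
  keep <- setdiff(seq_len(n), masked)
  A <- M[keep, keep, drop = FALSE]
  if (any(rowSums(A) == 0)) {
    stop("matrix has a non-masked zero row after masking; cannot balance")
  }
  x <- kr_vector(A, tol = tol, max_iter = max_iter)
  B <- A * tcrossprod(x)  # diag(x) A diag(x)
  disp <- max(abs(rowSums(B) - 1))
  if (disp > tol * 10) {
    stop(sprintf(
      "KR balancing did not converge: row-sum dispersion %.3g after %d outer iterations",
      disp, max_iter))
  }
  out <- matrix(NA_real_, n, n)
  out[keep, keep] <- B
  bias <- rep(NA_real_, n)
  bias[keep] <- x
  res <- cm
  res$counts <- out
  res$balanced <- TRUE
  res$bias <- bias
  res$masked <- masked
  res
}

# Knight-Ruiz inner-outer Newton iteration for a symmetric non-negative
# matrix A with total support; returns x with rowSums(diag(x) A diag(x)) = 1.
kr_vector <- function(A, tol = 1e-8, max_iter = 1000L,
                      delta = 0.1, Delta = 3) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  g <- 0.9
  etamax <- 0.1
  eta <- etamax
  stop_tol <- tol * 0.5
  rt <- tol^2
  v <- x * as.vector(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1
  rold <- rout
  it <- 0L
  while (rout > rt && it < max_iter) {
    it <- it + 1L
    k <- 0L
    y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1L
      if (k == 1L) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.vector(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
    }
    x <- x * y
    v <- x * as.vector(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    rat <- rout / rold
    rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / max(res_norm, .Machine$double.eps))
  }
  x
}

#' Per-bin insulation scores of a balanced contact matrix
#'
#' The raw insulation of bin `i` is the mean balanced contact over the
#' square window of pairs `(a, b)` with `a` in the `window_bins` bins
#' upstream and `b` in the `window_bins` bins downstream of `i` — contacts
#' crossing the bin, diagonal excluded. Bins within `window_bins` of either
#' chromosome edge are undefined (`NA`). Reported scores are normalized to
#' the chromosome-wide average: `log2(raw / mean(raw over defined bins))`,
#' so a score of 0 means average insulation and local minima mark contact
#' depletion, i.e. candidate TAD boundaries.
#'
#' @param cm A balanced `"contact_matrix"`.
#' @param window_bins Window half-size in bins; default 10 (100 kb at the
#'   default 10 kb bin size).
#' @return An object of class `"insulation_profile"`: a list with `scores`
#'   (per-bin, `NA` where undefined), `window_bins`, `bin_size`, `chrom`.
#' @export
insulation_scores <- function(cm, window_bins = 10L) {
  stopifnot(inherits(cm, "contact_matrix"), window_bins >= 1L)
  if (!cm$balanced) stop("insulation requires a balanced matrix")
  M <- cm$counts
  n <- nrow(M)
  if (n <= 2L * window_bins) {
    stop("matrix too small: no bin is further than window_bins from an edge")
  }
  raw <- rep(NA_real_, n)
  for (i in (window_bins + 1L):(n - window_bins)) {
    block <- M[(i - window_bins):(i - 1L), (i + 1L):(i + window_bins),
               drop = FALSE]
    raw[i] <- mean(block)  # NA if any masked bin falls in the window
  }
  mu <- mean(raw, na.rm = TRUE)
  scores <- log2(raw / mu)
  structure(list(scores = scores, window_bins = as.integer(window_bins),
                 bin_size = cm$bin_size, chrom = cm$chrom),
            class = "insulation_profile")
}

#' Delta vector of an insulation profile
#'
#' `delta[i]` is the mean insulation score over the `flank_bins` bins to
#' the right of `i` minus the mean over the `flank_bins` bins to the left,
#' i.e. the local slope of the insulation landscape; it crosses zero
#' steeply at strong TAD boundaries.
#'
#' @param scores Per-bin insulation scores (`NA` allowed).
#' @param flank_bins Flank size in bins; default 3.
#' @return Per-bin delta values (`NA` where either flank is incomplete).
#' @export
delta_vector <- function(scores, flank_bins = 3L) {
  n <- length(scores)
  delta <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - flank_bins < 1L || i + flank_bins > n) next
    left <- scores[(i - flank_bins):(i - 1L)]
    right <- scores[(i + 1L):(i + flank_bins)]
    if (anyNA(left) || anyNA(right)) next
    delta[i] <- mean(right) - mean(left)
  }
  delta
}

#' Call TAD boundaries from an insulation profile
#'
#' Candidate boundaries are strict local minima of the insulation scores.
#' Each candidate is retained only if its boundary strength — the range
#' (maximum minus minimum) of the delta vector over the `flank_bins` bins
#' on either side of the candidate — is at least `strength_threshold`,
#' filtering shallow dips that do not separate contact blocks.
#'
#' @param profile An `"insulation_profile"`, or a bare numeric vector of
#'   scores.
#' @param flank_bins Flank size for the delta vector; default 3.
#' @param strength_threshold Minimum delta range; default 0.7.
#' @return Sorted integer vector of boundary bin indices (possibly empty),
#'   with per-boundary strengths attached as the `"strength"` attribute.
#' @export
call_boundaries <- function(profile, flank_bins = 3L,
                            strength_threshold = 0.7) {
  scores <- if (inherits(profile, "insulation_profile")) profile$scores
            else as.numeric(profile)
  n <- length(scores)
  delta <- delta_vector(scores, flank_bins)
  out <- integer(0)
  strength <- numeric(0)
  for (i in 2L:(n - 1L)) {
    if (is.na(scores[i]) || is.na(scores[i - 1L]) || is.na(scores[i + 1L]))
      next
    if (!(scores[i] < scores[i - 1L] && scores[i] < scores[i + 1L])) next
    lo <- max(1L, i - flank_bins)
    hi <- min(n, i + flank_bins)
    d <- delta[lo:hi]
    if (all(is.na(d))) next
    s <- max(d, na.rm = TRUE) - min(d, na.rm = TRUE)
    if (s >= strength_threshold) {
      out <- c(out, i)
      strength <- c(strength, s)
    }
  }
  ord <- order(out)
  structure(out[ord], strength = strength[ord])
}

#' Virtual 4C profile: one row of the balanced contact matrix
#'
#' Reads the contacts of every bin with one anchor bin (e.g. the gene
#' promoter or a candidate enhancer) as a viewpoint profile. The anchor's
#' own bin is reported as missing.
#'
#' @param cm A balanced `"contact_matrix"`.
#' @param anchor A single `GRanges` range falling entirely within one bin,
#'   or a 1-based bin index.
#' @return A `GRanges` signal track with one range per bin and a `score`
#'   column (`NA` at the anchor bin and at masked bins).
#' @export
virtual_4c <- function(cm, anchor) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (!cm$balanced) stop("virtual 4C requires a balanced matrix")
  n <- nrow(cm$counts)
  if (inherits(anchor, "GRanges")) {
    stopifnot(length(anchor) == 1L)
    b1 <- (GenomicRanges::start(anchor) - 1L) %/% cm$bin_size + 1L
    b2 <- (GenomicRanges::end(anchor) - 1L) %/% cm$bin_size + 1L
    if (b1 != b2) {
      stop("anchor spans two bins; pick a point anchor within one bin")
    }
    bin <- b1
  } else {
    bin <- as.integer(anchor)
  }
  stopifnot(bin >= 1L, bin <= n)
  vals <- cm$counts[bin, ]
  vals[bin] <- NA_real_
  starts <- (seq_len(n) - 1L) * cm$bin_size + 1L
  gr <- GenomicRanges::GRanges(
    cm$chrom, IRanges::IRanges(starts, starts + cm$bin_size - 1L))
  gr$score <- vals
  gr
}

#' Read/write dense and sparse-triplet contact matrix text formats
#'
#' `write_dense_matrix()`/`read_dense_matrix()` exchange the full N x N
#' tab-separated matrix; `write_triplet_matrix()`/`read_triplet_matrix()`
#' exchange the upper triangle as `bin_i  bin_j  count` rows (1-based).
#'
#' @param cm A `"contact_matrix"`.
#' @param path File path.
#' @param bin_size,chrom Matrix metadata for the readers.
#' @return The readers return a `"contact_matrix"`; the writers return
#'   `path` invisibly.
#' @name contact_matrix_io
NULL

#' @rdname contact_matrix_io
#' @export
write_dense_matrix <- function(cm, path) {
  utils::write.table(cm$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname contact_matrix_io
#' @export
read_dense_matrix <- function(path, bin_size = 10000L, chrom = "chr") {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  contact_matrix(m, bin_size = bin_size, chrom = chrom)
}

#' @rdname contact_matrix_io
#' @export
write_triplet_matrix <- function(cm, path) {
  M <- cm$counts
  idx <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
  df <- data.frame(bin_i = idx[, 1L], bin_j = idx[, 2L],
                   count = M[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname contact_matrix_io
#' @export
read_triplet_matrix <- function(path, n_bins = NULL, bin_size = 10000L,
                                chrom = "chr") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("bin_i", "bin_j", "count"))
  n <- if (is.null(n_bins)) max(df$bin_i, df$bin_j) else n_bins
  M <- matrix(0, n, n)
  M[cbind(df$bin_i, df$bin_j)] <- df$count
  M[cbind(df$bin_j, df$bin_i)] <- df$count
  contact_matrix(M, bin_size = bin_size, chrom = chrom)
}

#' Export an insulation profile as a scored GRanges / bedGraph
#'
#' @param profile An `"insulation_profile"`.
#' @return A `GRanges` with one range per bin and the insulation score
#'   (`NA` at undefined bins; dropped by [write_bedgraph()]).
#' @export
insulation_track <- function(profile) {
  n <- length(profile$scores)
  starts <- (seq_len(n) - 1L) * profile$bin_size + 1L
  gr <- GenomicRanges::GRanges(
    profile$chrom, IRanges::IRanges(starts, starts + profile$bin_size - 1L))
  gr$score <- profile$scores
  gr
}
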