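# Shared fixture builders; everything is generated in code at test time.

fixture_model <- function() default_locus_model()

# small GRanges constructor on the synthetic chromosome
syn_gr <- function(start, end, chrom = "chrSyn", ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), ...)
}

# a quick smoothed 4C profile for one condition of the default locus
quick_fourc <- function(seed, condition = "dp", model = fixture_model(),
                        fragmap = NULL) {
  if (is.null(fragmap)) fragmap <- uniform_fragment_map(model)
  cnts <- simulate_fourc_counts(model, fragmap = fragmap, seed = seed,
                                conditions = condition)
  fourc_profile(fragmap, cnts[[condition]],
                viewpoint = model$viewpoint_pos, sample = condition)
}

# independent Sinkhorn iteration: symmetric scaling to unit row sums
sinkhorn_balance <- function(A, iter = 5000, tol = 1e-12) {
  b <- rep(1, nrow(A))
  for (k in seq_len(iter)) {
    r <- b * as.vector(A %*% b)
    if (max(abs(r - 1)) < tol) break
    b <- b / sqrt(r)
  }
  A * tcrossprod(b)
}

# independent delta-vector evaluation (plain loops) used as an oracle
oracle_delta <- function(scores, flank = 3L) {
  n <- length(scores)
  d <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - flank >= 1 && i + flank <= n) {
      d[i] <- mean(scores[(i + 1):(i + flank)]) -
        mean(scores[(i - flank):(i - 1)])
    }
  }
  d
}

# V-shaped insulation dip of unit depth centred at `at`, on a flat profile
dip_profile <- function(n, at, depth) {
  s <- rep(0, n)
  for (k in -3:3) s[at + k] <- -depth * (1 - abs(k) / 3)
  s
}
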