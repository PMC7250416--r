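test_that("default locus encodes the designed ground truth", {
  m <- fixture_model()
  expect_length(m$dhs, 13L)
  expect_equal(sum(m$dhs$true_fc >= 1.5), 6L)
  expect_equal(sum(m$dhs$is_ike120), 1L)
  expect_length(m$tf_peak_sets, 6L)
  expect_equal(GenomicRanges::width(m$deletion), 305L)
  # the flagged enhancer is validated at construction: all-TF overlap and
  # convergent CTCF flanking
  ike <- m$dhs[m$dhs$is_ike120]
  expect_equal(as.integer(overlap_count(ike, m$tf_peak_sets)), 6L)
  expect_true(ctcf_flanking(ike, m$ctcf_sites))
})

test_that("locus model validation rejects inconsistent truth flags", {
  m <- fixture_model()
  dhs <- m$dhs
  dhs$is_ike120 <- dhs$name == "DHS-280"  # not TF-bound
  expect_error(
    locus_model(m$chrom, m$chrom_length, m$gene, m$exons, m$promoter_pos,
                dhs, m$tf_peak_sets, m$ctcf_sites, m$tad_boundaries),
    "overlap every TF peak set")
})

test_that("simulators are deterministic given a seed", {
  m <- fixture_model()
  expect_identical(simulate_capstarr_counts(m, seed = 3),
                   simulate_capstarr_counts(m, seed = 3))
  expect_identical(simulate_hic_matrix(m, seed = 3)$counts,
                   simulate_hic_matrix(m, seed = 3)$counts)
  fm <- uniform_fragment_map(m)
  expect_identical(simulate_fourc_counts(m, fragmap = fm, seed = 3),
                   simulate_fourc_counts(m, fragmap = fm, seed = 3))
  expect_identical(simulate_qpcr(seed = 3), simulate_qpcr(seed = 3))
  expect_false(identical(simulate_qpcr(seed = 3), simulate_qpcr(seed = 4)))
})

test_that("capstarr simulator is centred on the true fold-changes", {
  m <- fixture_model()
  # null case: all true FCs 1 -> estimates centred at 1
  m0 <- m
  m0$dhs$true_fc <- rep(1, 13)
  m0$dhs$is_ike120 <- FALSE
  fcs <- vapply(1:20, function(s) {
    act <- capstarr_activity(simulate_capstarr_counts(m0, seed = s))
    mean(act$fc[act$fragment_id %in% m0$dhs$name])
  }, numeric(1))
  expect_equal(mean(fcs), 1, tolerance = 0.02)

  # planted FC 4 recovered within [3.5, 4.5] in at least 95% of replicates
  m4 <- m
  m4$dhs$true_fc[m4$dhs$name == "IkE120"] <- 4.0
  hits <- vapply(1:200, function(s) {
    act <- capstarr_activity(simulate_capstarr_counts(m4, seed = s))
    fc <- act$fc[act$fragment_id == "IkE120"]
    fc >= 3.5 && fc <= 4.5
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # degenerate depth
  z <- simulate_capstarr_counts(
    m, simulation_config(capstarr = list(depth = 0)), seed = 1)
  expect_true(all(z$screen_count == 0L))
})

test_that("hic simulator is distance-stationary without TADs and symmetric", {
  m <- fixture_model()
  m$tad_boundaries <- integer(0)
  m$loops <- NULL
  cm <- simulate_hic_matrix(m, noise = FALSE)
  M <- cm$counts
  # depends only on |i - j|
  for (k in c(0, 1, 5, 50)) {
    d <- M[cbind(1:(200 - k), (1 + k):200)]
    expect_equal(max(d) - min(d), 0)
  }
  cmn <- simulate_hic_matrix(m, seed = 9)
  expect_equal(cmn$counts, t(cmn$counts))
})

test_that("hic counts match the generative expectation within 3 standard errors", {
  m <- fixture_model()
  expected <- simulate_hic_matrix(m, noise = FALSE)$counts
  sampled <- simulate_hic_matrix(m, seed = 13)$counts
  up <- upper.tri(expected, diag = TRUE)
  # sum of independent Poissons: var = sum of means
  z <- (sum(sampled[up]) - sum(expected[up])) / sqrt(sum(expected[up]))
  expect_lt(abs(z), 3)
})

test_that("fourc background decays monotonically in expectation", {
  m <- fixture_model()
  m$enhancer_truth <- character(0)  # background only
  fm <- uniform_fragment_map(m)
  cnts <- Reduce(`+`, lapply(1:30, function(s) {
    simulate_fourc_counts(m, fragmap = fm, seed = s,
                          conditions = "dp")$dp
  })) / 30
  vp <- attr(simulate_fourc_counts(m, fragmap = fm, seed = 1,
                                   conditions = "dp"), "viewpoint")
  sm <- running_mean(cnts, 21, mask = (vp - 1):(vp + 1))
  # group distances coarsely so sampling noise cannot mask the decay
  grp_mean <- function(idx) {
    g <- (seq_along(idx) - 1) %/% 500
    unname(tapply(sm[idx], g, mean))
  }
  right <- grp_mean((vp + 2):(length(sm) - 1))
  expect_true(all(diff(right) < 0))
  left <- grp_mean((vp - 2):2)  # walking away from the viewpoint
  expect_true(all(diff(left) < 0))
})

test_that("qpcr simulator encodes exact noiseless log2 arithmetic", {
  cfg <- simulation_config(qpcr = list(ct_sd = 0))
  tab <- simulate_qpcr(cfg, seed = 1)
  wt <- tab[tab$group == "wt_unstim" & tab$amplicon == "E8", "ct"][1]
  mut <- tab[tab$group == "mut_unstim" & tab$amplicon == "E8", "ct"][1]
  expect_equal(mut - wt, 2)  # fold 4 = 2 cycles
  # fold 1 target: delta-delta-Ct is zero
  cfg1 <- simulation_config(qpcr = list(ct_sd = 0, fold_down = c(X = 1)))
  tab1 <- simulate_qpcr(cfg1, seed = 1)
  r <- relative_expression(tab1, "X", "mut_unstim", "wt_unstim")
  expect_equal(r$relative_expression, 1)
})

test_that("deletion geometry shifts, truncates, removes and round-trips", {
  m <- fixture_model()
  mut <- apply_deletion(m)
  expect_equal(m$chrom_length - mut$chrom_length, 305L)
  # the deleted DHS is gone, as are all its TF peaks
  expect_false("IkE120" %in% mut$dhs$name)
  expect_equal(length(mut$dhs), 12L)
  # downstream features shifted left by the width
  expect_equal(GenomicRanges::start(mut$gene),
               GenomicRanges::start(m$gene) - 305L)
  # upstream features untouched
  expect_equal(GenomicRanges::start(mut$dhs[mut$dhs$name == "DHS-280"]),
               GenomicRanges::start(m$dhs[m$dhs$name == "DHS-280"]))
  # round trip: lifting every shifted start recovers the original
  keep <- m$dhs$name %in% mut$dhs$name
  expect_equal(lift_to_wt(GenomicRanges::start(mut$dhs), m$deletion),
               GenomicRanges::start(m$dhs[keep]))

  # generic coordinate arithmetic on a plain interval, in BED coordinates
  m2 <- m
  m2$deletion <- syn_gr(100001, 100305)          # BED [100000, 100305)
  probe <- syn_gr(200001, 200100)                # BED [200000, 200100)
  probe$name <- "probe"
  probe$true_fc <- 1
  probe$is_ike120 <- FALSE
  m2$dhs <- c(m2$dhs, probe)
  mut2 <- apply_deletion(m2)
  probe <- mut2$dhs[mut2$dhs$name == "probe"]
  expect_equal(GenomicRanges::start(probe) - 1L, 199695L)
  expect_equal(GenomicRanges::end(probe), 199795L)

  # feature fully inside the deletion is absent from the mutant
  m3 <- m
  doomed <- syn_gr(1080100, 1080200)
  doomed$name <- "doomed"
  doomed$true_fc <- 1
  doomed$is_ike120 <- FALSE
  m3$dhs <- c(m3$dhs, doomed)
  expect_false("doomed" %in% apply_deletion(m3)$dhs$name)

  # unsupported scenarios are refused
  m4 <- m
  m4$deletion <- syn_gr(m$viewpoint_pos - 10L, m$viewpoint_pos + 10L)
  expect_error(apply_deletion(m4), "viewpoint")
  m5 <- m
  m5$deletion <- syn_gr(1250001, 1250300)
  expect_error(apply_deletion(m5), "gene body")
})
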