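ct_rows <- function(group, amplicon, ct, replicate = seq_along(ct)) {
  data.frame(group = group, amplicon = amplicon,
             replicate = replicate, ct = ct, stringsAsFactors = FALSE)
}

test_that("delta-Ct pairs target and housekeeping within replicates", {
  tab <- rbind(ct_rows("wt", "E8", c(25, 25.2, 24.8)),
               ct_rows("wt", "Rpl32", c(20, 20.1, 19.9)))
  expect_equal(unname(delta_ct(tab, "E8", "Rpl32", "wt")),
               c(5, 5.1, 4.9))
  expect_equal(unname(delta_ct(tab, "Rpl32", "Rpl32", "wt")), c(0, 0, 0))

  # pairing is by replicate id, not row order
  tab_perm <- tab[sample.int(nrow(tab)), ]
  expect_equal(delta_ct(tab_perm, "E8", "Rpl32", "wt")[c("1", "2", "3")],
               delta_ct(tab, "E8", "Rpl32", "wt")[c("1", "2", "3")])

  tab_missing <- tab[-4, ]  # drop housekeeping replicate 1
  expect_error(delta_ct(tab_missing, "E8", "Rpl32", "wt"), "replicate 1")
})

test_that("cycle shifts translate to exact fold-changes when noiseless", {
  tab <- rbind(ct_rows("wt", "E8", c(25, 25, 25)),
               ct_rows("wt", "Rpl32", c(20, 20, 20)),
               ct_rows("mut", "E8", c(27, 27, 27)),
               ct_rows("mut", "Rpl32", c(20, 20, 20)))
  r <- relative_expression(tab, "E8", "mut", "wt")
  expect_equal(r$relative_expression, 0.25)   # 2 cycles -> four-fold down

  tab$ct[tab$group == "mut" & tab$amplicon == "E8"] <- 26
  r <- relative_expression(tab, "E8", "mut", "wt")
  expect_equal(r$relative_expression, 0.5)    # 1 cycle -> two-fold down

  # k-cycle shift gives exactly 2^-k
  for (k in c(0.5, 3, 4.7)) {
    tab$ct[tab$group == "mut" & tab$amplicon == "E8"] <- 25 + k
    expect_equal(relative_expression(tab, "E8", "mut", "wt")$relative_expression,
                 2^-k)
  }
})

test_that("identical groups give unit expression and zero t statistic", {
  tab <- rbind(ct_rows("a", "E8", c(25, 25, 25)),
               ct_rows("a", "Rpl32", c(20, 20, 20)),
               ct_rows("b", "E8", c(25, 25, 25)),
               ct_rows("b", "Rpl32", c(20, 20, 20)))
  r <- relative_expression(tab, "E8", "a", "b")
  expect_equal(r$relative_expression, 1)
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("reciprocal comparisons invert exactly in the noiseless case", {
  tab <- rbind(ct_rows("a", "E8", c(25, 25, 25)),
               ct_rows("a", "Rpl32", c(20, 20, 20)),
               ct_rows("b", "E8", c(26.3, 26.3, 26.3)),
               ct_rows("b", "Rpl32", c(20, 20, 20)))
  ab <- relative_expression(tab, "E8", "a", "b")$relative_expression
  ba <- relative_expression(tab, "E8", "b", "a")$relative_expression
  expect_equal(ab * ba, 1)
})

test_that("the t-test matches the Welch formula to high precision", {
  tab <- rbind(ct_rows("wt", "E8", c(25.05, 24.91, 25.22)),
               ct_rows("wt", "Rpl32", c(20.02, 19.95, 20.11)),
               ct_rows("mut", "E8", c(27.1, 26.8, 27.3)),
               ct_rows("mut", "Rpl32", c(19.9, 20.05, 20.0)))
  r <- relative_expression(tab, "E8", "mut", "wt")
  d_mut <- delta_ct(tab, "E8", "Rpl32", "mut")
  d_wt <- delta_ct(tab, "E8", "Rpl32", "wt")
  # independent Welch computation
  v1 <- stats::var(d_mut) / 3
  v2 <- stats::var(d_wt) / 3
  t_manual <- (mean(d_mut) - mean(d_wt)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / 2 + v2^2 / 2)
  p_manual <- 2 * stats::pt(-abs(t_manual), df)
  expect_equal(r$t_statistic, t_manual, tolerance = 1e-10)
  expect_equal(r$p_value, p_manual, tolerance = 1e-10)
})

test_that("fold induction is computed within genotype from the simulator truth", {
  cfg <- simulation_config(qpcr = list(ct_sd = 0))
  tab <- simulate_qpcr(cfg, seed = 1)
  wt <- fold_induction(tab, "E8", "wt_stim", "wt_unstim")
  mut <- fold_induction(tab, "E8", "mut_stim", "mut_unstim")
  expect_equal(wt$relative_expression, 3)   # planted induction
  expect_equal(mut$relative_expression, 1)  # induction abolished
  expect_equal(
    fold_induction(tab, "E8", "wt_unstim", "wt_unstim")$relative_expression,
    1)
})

test_that("planted fold-changes are recovered under realistic noise", {
  folds <- c(E8 = 4, E3_E4 = 2, NULLAMP = 1)
  cfg <- simulation_config(qpcr = list(fold_down = folds))
  ok <- vapply(1:100, function(s) {
    tab <- simulate_qpcr(cfg, seed = s)
    all(vapply(names(folds), function(a) {
      est <- 1 / relative_expression(tab, a, "mut_unstim",
                                     "wt_unstim")$relative_expression
      abs(est - folds[[a]]) / folds[[a]] <= 0.2
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("Ct tables round-trip and are validated", {
  tab <- simulate_qpcr(seed = 2)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_ct_table(tab, tf)
  back <- read_ct_table(tf)
  expect_equal(back$ct, tab$ct)
  tab$ct[1] <- -1
  expect_error(write_ct_table(tab, tf), "positive")
})

test_that("differential tracks subtract per base with deletion lifting", {
  wt <- syn_gr(c(1, 101), c(100, 200))
  wt$score <- c(2, 2)
  mut <- syn_gr(c(1, 101), c(100, 200))
  mut$score <- c(2, 2)
  d <- differential_track(wt, mut)
  expect_true(all(d$score == 0))

  mut$score <- c(1, 1)
  d <- differential_track(wt, mut)
  expect_true(all(d$score == 1))

  other <- GenomicRanges::GRanges("chrOther", IRanges::IRanges(1, 10),
                                  score = 1)
  expect_error(differential_track(wt, other), "different chromosomes")
})

test_that("the deleted region drops out and the signal loss localizes", {
  m <- fixture_model()
  tr <- simulate_coverage_tracks(m, seed = 4)
  d <- differential_track(tr$wt, tr$mut, deletion = tr$deletion)
  # deleted interval has no mutant counterpart: absent after bedGraph export
  tf <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(d, tf)
  back <- read_bedgraph(tf)
  expect_equal(GenomicRanges::countOverlaps(m$deletion, back), 0L)
  # the largest wild-type excess lies near the deleted enhancer
  peak <- back[which.max(back$score)]
  ike <- m$dhs[m$dhs$name == "IkE120"]
  expect_lt(min(abs(c(GenomicRanges::start(peak), GenomicRanges::end(peak)) -
                      GenomicRanges::start(ike))), 5000)
})
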