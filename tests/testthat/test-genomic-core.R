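test_that("read_bed parses BED lines and rejects malformed ones", {
  tf <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20\tx", tf)
  gr <- read_bed(tf)
  expect_equal(as.character(GenomicRanges::seqnames(gr)), "chr1")
  expect_equal(GenomicRanges::start(gr), 11L)  # 1-based internal
  expect_equal(GenomicRanges::end(gr), 20L)
  expect_equal(gr$name, "x")

  writeLines(character(0), tf)
  expect_length(read_bed(tf), 0L)

  writeLines(c("chr1\t1\t5", "chr1\t20\t10"), tf)
  expect_error(read_bed(tf), "line 2")
  writeLines("chr1\tfoo\t10", tf)
  expect_error(read_bed(tf), "non-integer")
})

test_that("BED and bedGraph round-trips are lossless", {
  tf <- withr::local_tempfile(fileext = ".bed")
  set.seed(42)
  n <- 50
  starts <- sort(sample.int(1e6, n))
  gr <- GenomicRanges::GRanges(
    sample(c("chr1", "chr2"), n, TRUE),
    IRanges::IRanges(starts, starts + sample.int(500, n)),
    strand = sample(c("+", "-", "*"), n, TRUE))
  gr$name <- sprintf("f%02d", seq_len(n))
  gr$score <- round(stats::runif(n, 0, 10), 4)
  write_bed(gr, tf)
  back <- read_bed(tf)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_equal(back$name, gr$name)
  expect_equal(back$score, gr$score)
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(gr)))

  bg <- withr::local_tempfile(fileext = ".bedGraph")
  track <- syn_gr(c(1, 101, 301), c(100, 300, 320))
  track$score <- c(1.25, -2.5, 0.75)
  write_bedgraph(track, bg)
  back <- read_bedgraph(bg)
  expect_equal(back$score, track$score)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(track))
})

test_that("activity BED9 colors are deterministic and monotone in score", {
  tf <- withr::local_tempfile(fileext = ".bed")
  gr <- syn_gr(c(1, 101, 201, 301), c(100, 200, 300, 400))
  scores <- c(0, 5, 5, 10)
  write_bed9_rgb(gr, scores, tf, low = "green", high = "red")
  lines <- strsplit(readLines(tf), "\t")
  expect_true(all(lengths(lines) == 9L))
  rgb <- t(vapply(lines, function(x) {
    as.numeric(strsplit(x[9], ",")[[1]])
  }, numeric(3)))
  # equal scores give equal colors; endpoints hit the ramp ends
  expect_equal(rgb[2, ], rgb[3, ])
  expect_equal(rgb[1, ], c(0, 255, 0))
  expect_equal(rgb[4, ], c(255, 0, 0))
  # red channel (activity intensity) is monotone in score
  expect_true(all(diff(rgb[, 1]) >= 0))
})

test_that("digest places cuts at site starts and tiles the sequence", {
  fr <- digest("AAAAAAAAGATCAAAAAAAA", "GATC", "chrT")
  expect_equal(GenomicRanges::start(fr), c(1L, 9L))   # BED [0,8) [8,20)
  expect_equal(GenomicRanges::end(fr), c(8L, 20L))
  expect_equal(S4Vectors::metadata(fr)$enzyme, "GATC")

  fr <- digest("AAAACCCC", "GATC", "chrT")
  expect_length(fr, 1L)
  expect_equal(GenomicRanges::width(fr), 8L)

  fr <- digest("GATCGATC", "GATC", "chrT")
  expect_equal(GenomicRanges::start(fr), c(1L, 5L))
  expect_equal(GenomicRanges::end(fr), c(4L, 8L))
})

test_that("digest agrees with a brute-force occurrence scan and always tiles", {
  set.seed(7)
  for (trial in 1:20) {
    len <- sample(50:400, 1)
    s <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
    site <- sample(c("GATC", "GTAC", "AA"), 1)
    fr <- digest(s, site, "chrT")
    # oracle: scan every offset for a site occurrence
    k <- nchar(site)
    cuts <- which(vapply(seq_len(len - k + 1), function(i) {
      substr(s, i, i + k - 1) == site
    }, logical(1))) - 1L
    bounds <- sort(unique(c(0L, cuts, len)))
    expect_equal(GenomicRanges::start(fr) - 1L, bounds[-length(bounds)])
    expect_equal(GenomicRanges::end(fr), bounds[-1L])
    expect_equal(sum(GenomicRanges::width(fr)), len)
    expect_true(all(GenomicRanges::start(fr)[-1L] ==
                      GenomicRanges::end(fr)[-length(fr)] + 1L))
  }
})

test_that("mean coverage weights by length and counts gaps as zero", {
  track <- syn_gr(1, 100)
  track$score <- 7
  expect_equal(mean_coverage_in_window(track, syn_gr(10, 59)), 7)

  # half the window at value 2, half uncovered
  track <- syn_gr(1, 50)
  track$score <- 2
  expect_equal(mean_coverage_in_window(track, syn_gr(1, 100)), 1.0)

  expect_error(
    mean_coverage_in_window(track, syn_gr(10, 9)), "zero-length")
})

test_that("mean coverage matches a per-base summation oracle", {
  set.seed(11)
  for (trial in 1:10) {
    bounds <- sort(sample.int(5000, 21))
    starts <- bounds[-21][c(TRUE, FALSE)]
    ends <- bounds[-1][c(TRUE, FALSE)] - 1L
    keep <- starts <= ends
    track <- syn_gr(starts[keep], ends[keep])
    track$score <- stats::rnorm(sum(keep))
    w_start <- sample.int(4000, 1)
    window <- syn_gr(w_start, w_start + sample.int(900, 1))
    base_vals <- rep(0, 5100)
    for (i in seq_along(track)) {
      base_vals[GenomicRanges::start(track)[i]:
                  GenomicRanges::end(track)[i]] <- track$score[i]
    }
    oracle <- mean(base_vals[GenomicRanges::start(window):
                               GenomicRanges::end(window)])
    expect_equal(mean_coverage_in_window(track, window), oracle,
                 tolerance = 1e-9)
  }
})

test_that("overlap_count uses half-open overlap and matches all-pairs oracle", {
  target <- syn_gr(101, 200)  # BED [100, 200)
  sets <- replicate(6, {
    g <- syn_gr(151, 160)
    g
  }, simplify = FALSE)
  names(sets) <- paste0("TF", 1:6)
  expect_equal(as.integer(overlap_count(target, sets)), 6L)

  # abutting peak (BED [200,210)) does not overlap BED [100,200)
  sets$TF7 <- syn_gr(201, 210)
  n <- overlap_count(target, sets)
  expect_equal(as.integer(n), 6L)
  expect_false("TF7" %in% attr(n, "sets"))

  set.seed(5)
  for (trial in 1:10) {
    target <- syn_gr(500, 800)
    sets <- lapply(1:5, function(i) {
      st <- sample.int(1200, 8)
      syn_gr(st, st + sample.int(100, 8))
    })
    names(sets) <- paste0("s", 1:5)
    oracle <- sum(vapply(sets, function(ps) {
      any(vapply(seq_along(ps), function(j) {
        max(500, GenomicRanges::start(ps)[j]) <=
          min(800, GenomicRanges::end(ps)[j])
      }, logical(1)))
    }, logical(1)))
    expect_equal(as.integer(overlap_count(target, sets)), oracle)
  }
})
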