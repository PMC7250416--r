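#' Simulation configuration
#'
#' Collects the tunable parameters of every simulator with defaults that
#' encode the study conditions the analysis modules are designed for:
#' 10 kb Hi-C bins, two CapStarr replicates, three qPCR replicates, and
#' effect sizes matching the deletion phenotype the expression module
#' quantifies (common 3' exon down four-fold, internal junctions down
#' two-fold, stimulation-induced upregulation abolished in the mutant,
#' enhancer RNA strongly reduced).
#'
#' @param capstarr List: `depth` (reads per library), `n_background`
#'   (neutral genome-wide fragments co-cloned with the locus DHSs, true
#'   fold-change 1), `n_replicates`, `fragment_length` for background
#'   fragments.
#' @param hic List: `scale` (expected diagonal counts), `decay` (power-law
#'   distance-decay exponent), `within_tad` / `between_tad` contact
#'   multipliers.
#' @param fourc List: `peak_height` (viewpoint-proximal expected count),
#'   `decay_scale` (bases), `decay_exponent`, `enrichment` (planted peak
#'   fold), `peak_halfwidth` (bases), `conditions` (character vector;
#'   names containing `"es"` get no planted peaks).
#' @param qpcr List: `ct_sd` (cycles), `n_replicates`, `baseline_hk` and
#'   `baseline_target` Ct anchors (only differences matter),
#'   `fold_down` named per-amplicon mutant decrease, `induction_wt` and
#'   `induction_mut` stimulation folds.
#' @param coverage List: `baseline`, `peak_height`, `peak_sd` (bases),
#'   `bin` (track bin width, bases) for the histone-acetylation-like
#'   tracks.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(capstarr = list(), hic = list(),
                              fourc = list(), qpcr = list(),
                              coverage = list()) {
  merge_block <- function(defaults, user) {
    stopifnot(all(names(user) %in% names(defaults)))
    utils::modifyList(defaults, user)
  }
  cfg <- list(
    capstarr = merge_block(list(
      depth = 1e6, n_background = 487L, n_replicates = 2L,
      fragment_length = 400L), capstarr),
    hic = merge_block(list(
      scale = 300, decay = 0.8, within_tad = 3, between_tad = 1), hic),
    fourc = merge_block(list(
      peak_height = 100, decay_scale = 10000, decay_exponent = 1,
      enrichment = 5, peak_halfwidth = 1500,
      conditions = c("dn3", "dp", "es")), fourc),
    qpcr = merge_block(list(
      ct_sd = 0.1, n_replicates = 3L,
      baseline_hk = 20, baseline_target = 25,
      fold_down = c(E8 = 4, E4_E5 = 4, E3_E4 = 2, E6_E7 = 2,
                    E1L = 3, E1S = 2, eRNA_set1 = 8, eRNA_set2 = 8),
      induction_wt = 3, induction_mut = 1), qpcr),
    coverage = merge_block(list(
      baseline = 1, peak_height = 20, peak_sd = 500, bin = 200L),
      coverage)
  )
  stopifnot(cfg$capstarr$depth >= 0, cfg$qpcr$n_replicates >= 2L,
            all(cfg$qpcr$fold_down > 0), cfg$hic$scale > 0)
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a random chromosome sequence
#'
#' Uniform random nucleotides; a 4-base recognition site such as GATC then
#' occurs every ~256 bp on average, giving a realistic restriction-
#' fragment density for 4C profiles.
#'
#' @param length Sequence length in bases.
#' @param seed Random seed.
#' @return A [Biostrings::DNAString].
#' @export
simulate_chromosome_sequence <- function(length, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  Biostrings::DNAString(
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""))
}

# save/restore the global RNG state so simulators are self-seeding without
# disturbing the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate CapStarr-seq screen and input fragment counts
#'
#' The plasmid-library input draws `depth` reads multinomially over all
#' cloned fragments with probability proportional to fragment length; the
#' screen draws `depth` reads with probability proportional to length
#' times the fragment's true activity fold-change. The locus DHSs carry
#' the model's `true_fc`; `n_background` neutral fragments (fold-change 1)
#' emulate the rest of a genome-wide screen, so that FPKM-ratio estimates
#' of the locus fold-changes are centred on the truth.
#'
#' @param model A `"locus_model"`.
#' @param config A `"simulation_config"`.
#' @param seed Random seed.
#' @return A data frame with columns `fragment_id`, `chrom`, `start`,
#'   `end` (BED coordinates), `true_fc`, `is_locus`, `screen_count`,
#'   `input_count`, `replicate` — one block per replicate, suitable for
#'   [capstarr_activity()].
#' @export
simulate_capstarr_counts <- function(model, config = simulation_config(),
                                     seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cc <- config$capstarr
  dhs <- model$dhs
  n_bg <- cc$n_background
  len <- c(GenomicRanges::width(dhs), rep(cc$fragment_length, n_bg))
  fc <- c(dhs$true_fc, rep(1, n_bg))
  frag <- data.frame(
    fragment_id = c(dhs$name, sprintf("bg%04d", seq_len(n_bg))),
    chrom = c(rep(model$chrom, length(dhs)), rep("chrBg", n_bg)),
    start = c(GenomicRanges::start(dhs) - 1L,
              seq_len(n_bg) * (cc$fragment_length + 100L)),
    true_fc = fc, is_locus = c(rep(TRUE, length(dhs)), rep(FALSE, n_bg)),
    stringsAsFactors = FALSE
  )
  frag$end <- frag$start + len
  frag <- frag[c("fragment_id", "chrom", "start", "end",
                 "true_fc", "is_locus")]
  p_input <- len / sum(len)
  p_screen <- len * fc / sum(len * fc)
  do.call(rbind, lapply(seq_len(cc$n_replicates), function(r) {
    d <- frag
    d$screen_count <- if (cc$depth > 0) {
      as.integer(stats::rmultinom(1L, cc$depth, p_screen))
    } else rep(0L, nrow(frag))
    d$input_count <- if (cc$depth > 0) {
      as.integer(stats::rmultinom(1L, cc$depth, p_input))
    } else rep(0L, nrow(frag))
    d$replicate <- r
    d
  }))
}

#' Simulate a Hi-C contact matrix with TAD structure
#'
#' Expected contacts between bins `i` and `j` are a power-law distance
#' decay `scale * (1 + |i-j|)^-decay`, multiplied by `within_tad` when the
#' two bins share a TAD block (blocks are delimited by the model's
#' `tad_boundaries`) and by `between_tad` otherwise, and by the loop
#' `bonus` at configured enhancer-promoter bin pairs. Counts are Poisson
#' samples of the expectation; the matrix is symmetric by construction.
#'
#' @inheritParams simulate_capstarr_counts
#' @param noise If `FALSE`, return the expected (noise-free) matrix.
#' @return A `"contact_matrix"` of raw counts.
#' @export
simulate_hic_matrix <- function(model, config = simulation_config(),
                                seed = 1L, noise = TRUE) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  hc <- config$hic
  n <- ceiling(model$chrom_length / model$bin_size)
  block <- findInterval(seq_len(n), sort(model$tad_boundaries)) + 1L
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  expected <- hc$scale * (1 + d)^(-hc$decay)
  same <- outer(block, block, "==")
  expected <- expected * ifelse(same, hc$within_tad, hc$between_tad)
  if (!is.null(model$loops) && nrow(model$loops) > 0L) {
    for (k in seq_len(nrow(model$loops))) {
      i <- model$loops$bin_i[k]
      j <- model$loops$bin_j[k]
      expected[i, j] <- expected[i, j] * model$loops$bonus[k]
      expected[j, i] <- expected[i, j]
    }
  }
  if (noise) {
    up <- upper.tri(expected, diag = TRUE)
    counts <- matrix(0, n, n)
    counts[up] <- stats::rpois(sum(up), expected[up])
    counts <- counts + t(counts) - diag(diag(counts))
  } else {
    counts <- expected
  }
  contact_matrix(counts, bin_size = model$bin_size, chrom = model$chrom)
}

#' Build a uniform synthetic fragment map
#'
#' A fragment map with near-constant fragment length tiling the model's
#' chromosome, for simulations that do not need a base-level sequence
#' (sequence-derived maps come from [digest()]).
#'
#' @param model A `"locus_model"`.
#' @param fragment_length Mean fragment length in bases; default 250
#'   (the expected spacing of a 4-base recognition site).
#' @return A fragment `GRanges` as returned by [digest()].
#' @export
uniform_fragment_map <- function(model, fragment_length = 250L) {
  bounds <- unique(c(seq(0L, model$chrom_length, by = fragment_length),
                     model$chrom_length))
  gr <- GenomicRanges::GRanges(
    model$chrom,
    IRanges::IRanges(bounds[-length(bounds)] + 1L, bounds[-1L]))
  gr$fragment_id <- seq_along(gr)
  S4Vectors::metadata(gr)$enzyme <- "synthetic"
  S4Vectors::metadata(gr)$chrom_length <- model$chrom_length
  gr
}

#' Simulate 4C-seq fragment counts for several conditions
#'
#' Expected counts decay monotonically with distance from the viewpoint
#' fragment, `peak_height * (1 + d/decay_scale)^-decay_exponent`, and the
#' fragments overlapping each true enhancer's contact region are enriched
#' `enrichment`-fold in thymic-like conditions (condition names containing
#' `"es"` receive background only, emulating a cell type where the locus
#' is inactive). Counts are Poisson samples; the viewpoint fragment and
#' its immediate neighbour on each side are set to 0 (masked later by
#' [fourc_profile()]).
#'
#' @inheritParams simulate_capstarr_counts
#' @param fragmap Fragment `GRanges` (from [digest()] or
#'   [uniform_fragment_map()]).
#' @param conditions Condition labels; defaults from `config`.
#' @return A named list of integer count vectors, one per condition, with
#'   the viewpoint fragment index in attribute `"viewpoint"`.
#' @export
simulate_fourc_counts <- function(model, config = simulation_config(),
                                  fragmap, seed = 1L,
                                  conditions = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fc_cfg <- config$fourc
  if (is.null(conditions)) conditions <- fc_cfg$conditions
  n <- length(fragmap)
  mid <- (GenomicRanges::start(fragmap) + GenomicRanges::end(fragmap)) / 2
  vp <- which(GenomicRanges::start(fragmap) <= model$viewpoint_pos &
                GenomicRanges::end(fragmap) >= model$viewpoint_pos)
  stopifnot(length(vp) == 1L)
  d <- abs(mid - model$viewpoint_pos)
  background <- fc_cfg$peak_height *
    (1 + d / fc_cfg$decay_scale)^(-fc_cfg$decay_exponent)
  enh <- model$dhs[model$dhs$name %in% model$enhancer_truth]
  peak_frac <- rep(1, n)
  if (length(enh) > 0L) {
    centres <- (GenomicRanges::start(enh) + GenomicRanges::end(enh)) / 2
    for (cc in centres) {
      hit <- abs(mid - cc) <= fc_cfg$peak_halfwidth
      peak_frac[hit] <- fc_cfg$enrichment
    }
  }
  out <- lapply(conditions, function(cond) {
    lambda <- if (grepl("es", cond, ignore.case = TRUE)) background
              else background * peak_frac
    cnt <- stats::rpois(n, lambda)
    cnt[intersect((vp - 1L):(vp + 1L), seq_len(n))] <- 0L
    cnt
  })
  names(out) <- conditions
  attr(out, "viewpoint") <- vp
  out
}

#' Simulate a qPCR Ct table
#'
#' Encodes expression as `Ct = baseline - log2(expression) + noise` with
#' the housekeeping amplicon constant in expectation across conditions.
#' Wild-type unstimulated expression is 1 for every target; the mutant is
#' reduced by the per-amplicon `fold_down`; stimulation multiplies
#' wild-type expression by `induction_wt` and mutant expression by
#' `induction_mut` (1 = induction abolished).
#'
#' @inheritParams simulate_capstarr_counts
#' @param groups Group labels; default
#'   `wt_unstim, wt_stim, mut_unstim, mut_stim`.
#' @return A Ct data frame with columns `group`, `amplicon`, `replicate`,
#'   `ct` (see [read_ct_table()]).
#' @export
simulate_qpcr <- function(config = simulation_config(), seed = 1L,
                          groups = c("wt_unstim", "wt_stim",
                                     "mut_unstim", "mut_stim")) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  qc <- config$qpcr
  amplicons <- names(qc$fold_down)
  expr <- function(group, amp) {
    base <- if (grepl("^mut", group)) 1 / qc$fold_down[[amp]] else 1
    ind <- if (grepl("stim$", group) && !grepl("unstim$", group)) {
      if (grepl("^mut", group)) qc$induction_mut else qc$induction_wt
    } else 1
    base * ind
  }
  rows <- expand.grid(group = groups,
                      amplicon = c(amplicons, "Rpl32"),
                      replicate = seq_len(qc$n_replicates),
                      stringsAsFactors = FALSE)
  rows$ct <- vapply(seq_len(nrow(rows)), function(i) {
    g <- rows$group[i]
    a <- rows$amplicon[i]
    mu <- if (a == "Rpl32") qc$baseline_hk
          else qc$baseline_target - log2(expr(g, a))
    mu + stats::rnorm(1L, 0, qc$ct_sd)
  }, numeric(1))
  rows[order(rows$group, rows$amplicon, rows$replicate), ]
}

#' Simulate paired wild-type / mutant coverage tracks
#'
#' Histone-acetylation-like tracks: a flat baseline plus Gaussian-shaped
#' peaks over every active enhancer (height proportional to its true
#' fold-change) and the promoter, binned at `coverage$bin` bases, with
#' Poisson noise. The mutant track is generated from the mutant model
#' (deletion applied), so the peak over the deleted enhancer is absent and
#' downstream coordinates are shifted — exercising the deletion-aware
#' differential-track lifting.
#'
#' @inheritParams simulate_capstarr_counts
#' @param noise If `FALSE`, return expected values.
#' @return A list with `wt` and `mut` scored `GRanges` tracks (the mutant
#'   in mutant coordinates) and the `deletion` interval.
#' @export
simulate_coverage_tracks <- function(model, config = simulation_config(),
                                     seed = 1L, noise = TRUE) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cv <- config$coverage
  build <- function(m) {
    n_bins <- ceiling(m$chrom_length / cv$bin)
    starts <- (seq_len(n_bins) - 1L) * cv$bin + 1L
    mids <- starts + cv$bin / 2
    lambda <- rep(cv$baseline, n_bins)
    enh <- m$dhs[m$dhs$name %in% m$enhancer_truth]
    centres <- c((GenomicRanges::start(enh) + GenomicRanges::end(enh)) / 2,
                 m$promoter_pos)
    heights <- c(cv$peak_height * enh$true_fc / 3, cv$peak_height)
    for (k in seq_along(centres)) {
      lambda <- lambda +
        heights[k] * exp(-(mids - centres[k])^2 / (2 * cv$peak_sd^2))
    }
    score <- if (noise) stats::rpois(n_bins, lambda * 4) / 4 else lambda
    gr <- GenomicRanges::GRanges(
      m$chrom,
      IRanges::IRanges(starts, pmin(starts + cv$bin - 1L, m$chrom_length)))
    gr$score <- score
    gr
  }
  mut_model <- apply_deletion(model)
  list(wt = build(model), mut = build(mut_model),
       deletion = model$deletion)
}
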