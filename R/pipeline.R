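#' Pipeline run configuration
#'
#' Resolves unspecified parameters to the workflow defaults: activity
#' thresholds 1.5 / 3 and top fraction 0.05, 10 kb Hi-C bins with a
#' 10-bin insulation window, 3-bin delta flanks and boundary strength
#' 0.7, and a 21-fragment smoothing window.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Global seed; per-stage seeds are derived from it by hashing
#'   the stage name (see [stage_seed()]).
#' @param weak_threshold,strong_threshold,top_fraction Activity module
#'   parameters.
#' @param window_bins,flank_bins,strength_threshold Insulation / boundary
#'   parameters.
#' @param smoothing_window 4C running-mean and caller window (fragments).
#' @param threshold_quantile 4C caller residual quantile.
#' @param housekeeping Housekeeping amplicon name.
#' @param sim A `"simulation_config"` for the generator stage.
#' @param model A `"locus_model"`; default [default_locus_model()].
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(out_dir = tempfile("enhancerscope_run_"),
                       seed = 1L,
                       weak_threshold = 1.5, strong_threshold = 3,
                       top_fraction = 0.05,
                       window_bins = 10L, flank_bins = 3L,
                       strength_threshold = 0.7,
                       smoothing_window = 21L,
                       threshold_quantile = 0.97,
                       housekeeping = "Rpl32",
                       sim = simulation_config(),
                       model = default_locus_model()) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              weak_threshold = weak_threshold,
              strong_threshold = strong_threshold,
              top_fraction = top_fraction,
              window_bins = as.integer(window_bins),
              flank_bins = as.integer(flank_bins),
              strength_threshold = strength_threshold,
              smoothing_window = as.integer(smoothing_window),
              threshold_quantile = threshold_quantile,
              housekeeping = housekeeping,
              sim = sim, model = model)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys are the scalar arguments of [run_config()]; unknown
#' keys are rejected. The locus model and simulation config stay at their
#' defaults (they are R-level objects).
#'
#' @param path YAML file path.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(run_config)), c("sim", "model"))
  bad <- setdiff(names(vals), allowed)
  if (length(bad) > 0L) stop("unknown config keys: ",
                             paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Derive a stage-specific seed from the global seed
#'
#' Hashes the stage name into an offset so each stage draws from an
#' independent, individually reproducible stream.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 1000 + h) %% .Machine$integer.max)
}

#' Run the full synthetic-locus pipeline
#'
#' Executes simulate -> activity scoring -> Hi-C topology -> 4C profiling
#' -> prioritization -> qPCR expression as one reproducible run. Every
#' stage writes its outputs under `config$out_dir`; a manifest records
#' parameters, per-stage seeds and output checksums, so two runs with the
#' same configuration produce identical files.
#'
#' @param config A `"run_config"`.
#' @return Invisibly, a list with the in-memory stage results
#'   (`activity`, `census`, `insulation`, `boundaries`, `virtual4c`,
#'   `profiles`, `interactions`, `conserved`, `report`, `expression`,
#'   `manifest`); the manifest is also written as a tab-separated
#'   key-value file.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- config$model
  sim <- config$sim
  out <- function(...) file.path(config$out_dir, ...)
  log_msg <- function(stage, what) {
    message(sprintf("[%s] %s", stage, what))
  }

  # --- simulate ---------------------------------------------------------
  log_msg("simulate", "generating synthetic inputs")
  counts <- simulate_capstarr_counts(model, sim,
                                     seed = stage_seed(config$seed, "capstarr"))
  utils::write.table(counts, out("capstarr_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cm_raw <- simulate_hic_matrix(model, sim,
                                seed = stage_seed(config$seed, "hic"))
  write_dense_matrix(cm_raw, out("hic_raw.tsv"))
  fragmap <- uniform_fragment_map(model)
  write_bed(fragmap, out("fragments.bed"))
  fourc_counts <- simulate_fourc_counts(
    model, sim, fragmap, seed = stage_seed(config$seed, "fourc"))
  utils::write.table(
    data.frame(fragment_id = fragmap$fragment_id,
               chrom = as.character(GenomicRanges::seqnames(fragmap)),
               start = GenomicRanges::start(fragmap) - 1L,
               end = GenomicRanges::end(fragmap),
               as.data.frame(fourc_counts[seq_along(fourc_counts)])),
    out("fourc_counts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  ct_table <- simulate_qpcr(sim, seed = stage_seed(config$seed, "qpcr"))
  write_ct_table(ct_table, out("ct_table.tsv"))
  tracks <- simulate_coverage_tracks(
    model, sim, seed = stage_seed(config$seed, "coverage"))
  write_bedgraph(tracks$wt, out("h3k27ac_wt.bedgraph"))
  write_bedgraph(tracks$mut, out("h3k27ac_mut.bedgraph"))
  write_bed(model$dhs, out("dhs.bed"))
  write_bed(model$ctcf_sites, out("ctcf.bed"))

  # --- capstarr activity ------------------------------------------------
  log_msg("capstarr", "scoring enhancer activity")
  activity <- capstarr_activity(counts, weak = config$weak_threshold,
                                strong = config$strong_threshold)
  activity <- rank_dhs(activity, top_fraction = config$top_fraction)
  locus <- activity[activity$fragment_id %in% model$dhs$name, ]
  census <- count_active(locus)
  utils::write.table(activity, out("activity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gr_locus <- GenomicRanges::GRanges(
    locus$chrom, IRanges::IRanges(locus$start + 1L, locus$end),
    name = locus$fragment_id)
  write_bed9_rgb(gr_locus, locus$fc, out("activity_rgb.bed"))

  # --- hic topology -----------------------------------------------------
  log_msg("hic", "balancing matrix and calling TAD boundaries")
  cm <- kr_balance(cm_raw)
  prof <- insulation_scores(cm, window_bins = config$window_bins)
  boundaries <- call_boundaries(prof, flank_bins = config$flank_bins,
                                strength_threshold = config$strength_threshold)
  write_bedgraph(insulation_track(prof), out("insulation.bedgraph"))
  if (length(boundaries) > 0L) {
    bgr <- GenomicRanges::GRanges(
      model$chrom,
      IRanges::IRanges((boundaries - 1L) * model$bin_size + 1L,
                       boundaries * model$bin_size))
    write_bed(bgr, out("tad_boundaries.bed"))
  }
  anchor <- GenomicRanges::GRanges(
    model$chrom, IRanges::IRanges(model$promoter_pos, model$promoter_pos))
  v4c <- virtual_4c(cm, anchor)
  write_bedgraph(v4c, out("virtual4c_promoter.bedgraph"))

  # --- fourc ------------------------------------------------------------
  log_msg("fourc", "smoothing profiles and calling interactions")
  profiles <- lapply(names(fourc_counts), function(cond) {
    fourc_profile(fragmap, fourc_counts[[cond]],
                  viewpoint = model$viewpoint_pos,
                  window = config$smoothing_window, sample = cond)
  })
  names(profiles) <- names(fourc_counts)
  profiles <- normalize_profiles(profiles)
  interactions <- lapply(profiles, call_interactions,
                         background_window = config$smoothing_window,
                         threshold_quantile = config$threshold_quantile)
  thymic <- !grepl("es", names(profiles), ignore.case = TRUE)
  conserved <- conserved_calls(interactions[thymic])
  for (cond in names(profiles)) {
    gr <- GenomicRanges::granges(fragmap)
    gr$score <- profiles[[cond]]$normalized
    write_bedgraph(gr, out(sprintf("fourc_%s_normalized.bedgraph", cond)))
    if (length(interactions[[cond]]) > 0L) {
      write_bed(interactions[[cond]], out(sprintf("fourc_%s_calls.bed", cond)))
    }
  }
  if (length(conserved) > 0L) {
    write_bed(conserved, out("fourc_conserved_calls.bed"))
  }

  # --- prioritization ---------------------------------------------------
  log_msg("prioritize", "integrating evidence")
  report <- prioritize(locus, model$tf_peak_sets, model$ctcf_sites,
                       contact_profile = v4c, interactions = conserved)
  utils::write.table(report, out("candidate_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- qpcr expression --------------------------------------------------
  log_msg("qpcr", "delta-delta-Ct expression analysis")
  amplicons <- setdiff(unique(ct_table$amplicon), config$housekeeping)
  expression <- do.call(rbind, lapply(amplicons, function(a) {
    relative_expression(ct_table, a, "mut_unstim", "wt_unstim",
                        housekeeping = config$housekeeping)
  }))
  induction <- rbind(
    cbind(genotype = "wt",
          fold_induction(ct_table, "E8", "wt_stim", "wt_unstim",
                         housekeeping = config$housekeeping)),
    cbind(genotype = "mut",
          fold_induction(ct_table, "E8", "mut_stim", "mut_unstim",
                         housekeeping = config$housekeeping)))
  utils::write.table(expression, out("expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(induction, out("fold_induction.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  diff_track <- differential_track(tracks$wt, tracks$mut,
                                   deletion = tracks$deletion)
  write_bedgraph(diff_track, out("h3k27ac_differential.bedgraph"))

  # --- manifest ---------------------------------------------------------
  files <- sort(list.files(config$out_dir, full.names = FALSE))
  files <- setdiff(files, "manifest.tsv")
  checksums <- tools::md5sum(file.path(config$out_dir, files))
  manifest <- rbind(
    data.frame(key = c("seed", "weak_threshold", "strong_threshold",
                       "top_fraction", "window_bins", "flank_bins",
                       "strength_threshold", "smoothing_window",
                       "threshold_quantile", "housekeeping"),
               value = c(config$seed, config$weak_threshold,
                         config$strong_threshold, config$top_fraction,
                         config$window_bins, config$flank_bins,
                         config$strength_threshold,
                         config$smoothing_window,
                         config$threshold_quantile, config$housekeeping),
               stringsAsFactors = FALSE),
    data.frame(key = paste0("md5:", files), value = unname(checksums),
               stringsAsFactors = FALSE)
  )
  utils::write.table(manifest, out("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(activity = activity, census = census,
                 insulation = prof, boundaries = boundaries,
                 virtual4c = v4c, profiles = profiles,
                 interactions = interactions, conserved = conserved,
                 report = report, expression = expression,
                 induction = induction, diff_track = diff_track,
                 manifest = manifest, out_dir = config$out_dir))
}
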