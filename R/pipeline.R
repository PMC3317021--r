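# End-to-end wiring: simulate a synthetic fidelity study, normalize every
# hybridization, segment, smooth, call peaks, and assemble the per-group
# concordance report benchmarked against duplicate control runs.

#' Simulate and assess a complete WGA fidelity study
#'
#' Emulates the design of a WGA validation experiment: a set of tumor
#' samples each hybridized twice without amplification (the duplicate
#' control pairs that define the reference values), of which the first
#' `n_test` samples are additionally amplified by each method under
#' assessment and hybridized once per method. All hybridizations are
#' normalized and every method group is assessed against its paired
#' controls and the duplicate-control reference.
#'
#' @param seed integer master seed; every draw derives from it.
#' @param n_clones,n_chrom platform size.
#' @param n_segments genome-wide truth segment target per sample.
#' @param n_test samples amplified per method.
#' @param n_ref_pairs duplicate control pairs (>= n_test).
#' @param presets named list of preset names (see [preset_params()]) or
#'   `artifact_model` objects, one per method group.
#' @param control_artifacts artifact model of non-amplified hybridizations.
#' @param cbs,peaks analysis parameters.
#' @param min_overlap minimum shared clones for Pearson correlations.
#' @param scale_target profile scale target.
#' @param prop_neutral fraction of copy-neutral truth segments.
#' @param base_sdlog log-sd of the reference-channel intensity (0 makes the
#'   reference channel deterministic, so zero-artifact duplicates coincide
#'   exactly).
#' @param subgrid_imbalance_sd per-subgrid channel imbalance injected into
#'   every hybridization (0 disables it).
#' @return List: `map`, `reports` (one `concordance_report` per method),
#'   `profiles` (all normalized profiles), `truths`.
#' @export
simulate_fidelity_study <- function(seed = 1, n_clones = 2200, n_chrom = 22,
                                    n_segments = 40, n_test = 3,
                                    n_ref_pairs = 6,
                                    presets = list(scomp = "scomp_like",
                                                   dop = "dop_like"),
                                    control_artifacts = preset_params("control_like"),
                                    cbs = cbs_params(n_perm = 200, seed = seed),
                                    peaks = peak_params(),
                                    min_overlap = 100, scale_target = 1.0,
                                    prop_neutral = 0.4,
                                    subgrid_imbalance_sd = 0.15,
                                    base_sdlog = 0.25) {
  if (n_ref_pairs < n_test)
    validation_error("n_ref_pairs must be >= n_test")
  platform <- make_platform(n_clones = n_clones, n_chrom = n_chrom,
                            seed = derive_seed(seed, "plat"))
  params <- normalization_params(scale_target = scale_target)
  norm <- function(tab, id, group)
    normalize_hybridization(tab, platform$map, params, sample_id = id,
                            group = group)

  truths <- lapply(seq_len(n_ref_pairs), function(s)
    make_truth(platform$map, n_segments = n_segments,
               prop_neutral = prop_neutral,
               seed = derive_seed(seed, "tru", s)))

  controls1 <- list(); controls2 <- list()
  for (s in seq_len(n_ref_pairs)) {
    controls1[[s]] <- norm(simulate_hybridization(
      truths[[s]], platform, control_artifacts,
      seed = derive_seed(seed, "c1", s),
      subgrid_imbalance_sd = subgrid_imbalance_sd, base_sdlog = base_sdlog),
      sprintf("control_%d_run1", s), "control")
    controls2[[s]] <- norm(simulate_hybridization(
      truths[[s]], platform, control_artifacts,
      seed = derive_seed(seed, "c2", s),
      subgrid_imbalance_sd = subgrid_imbalance_sd, base_sdlog = base_sdlog),
      sprintf("control_%d_run2", s), "control")
  }
  duplicate_pairs <- lapply(seq_len(n_ref_pairs), function(s)
    list(controls1[[s]], controls2[[s]]))

  profiles <- c(controls1, controls2)
  reports <- list()
  for (g in names(presets)) {
    model <- presets[[g]]
    if (is.character(model)) model <- preset_params(model)
    # fresh method-specific structures per study, still shared by replicates
    model$method_seed <- derive_seed(seed, "method", g, model$method_seed)
    tests <- lapply(seq_len(n_test), function(s)
      norm(simulate_hybridization(truths[[s]], platform, model,
                                  seed = derive_seed(seed, g, s),
                                  subgrid_imbalance_sd = subgrid_imbalance_sd,
                                  base_sdlog = base_sdlog),
           sprintf("%s_%d", g, s), g))
    profiles <- c(profiles, tests)
    reports[[g]] <- assess_group(tests, controls1[seq_len(n_test)],
                                 duplicate_pairs, platform$map,
                                 cbs = cbs, peaks = peaks,
                                 min_overlap = min_overlap)
  }
  list(map = platform$map, platform = platform, reports = reports,
       profiles = profiles, truths = truths)
}

#' Run the full pipeline from a configuration
#'
#' Configuration is a YAML file or an equivalent nested list with optional
#' blocks `platform`, `truth`, `study`, `cbs`, `peaks` and a global `seed`.
#' The run is deterministic given the seed: one global seed fans out to
#' per-stage seeds through a fixed derivation. When `out_dir` is given,
#' per-sample profiles, segments, peaks, the sample correlation matrix and
#' the report JSON are written there.
#'
#' @param config path to a YAML file, or a list.
#' @param out_dir optional output directory.
#' @return List with `reports`, `correlation` and the study objects.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1
  study_cfg <- config$study %||% list()
  cbs_cfg <- config$cbs %||% list()
  peaks_cfg <- config$peaks %||% list()
  platform_cfg <- config$platform %||% list()

  cbs <- cbs_params(alpha = cbs_cfg$alpha %||% 0.01,
                    n_perm = cbs_cfg$n_perm %||% 200,
                    min_width = cbs_cfg$min_width %||% 2,
                    call_threshold = cbs_cfg$call_threshold %||% 0,
                    seed = seed)
  peaks <- peak_params(window = peaks_cfg$window %||% 20,
                       threshold_k = peaks_cfg$threshold_k %||% 2.0,
                       min_run = peaks_cfg$min_run %||% 5)
  presets <- study_cfg$presets %||% list(scomp = "scomp_like", dop = "dop_like")

  study <- simulate_fidelity_study(
    seed = seed,
    n_clones = platform_cfg$n_clones %||% 2200,
    n_chrom = platform_cfg$n_chrom %||% 22,
    n_segments = study_cfg$n_segments %||% 40,
    n_test = study_cfg$n_test %||% 3,
    n_ref_pairs = study_cfg$n_ref_pairs %||% 6,
    presets = presets, cbs = cbs, peaks = peaks,
    min_overlap = study_cfg$min_overlap %||% 100)

  corr <- correlation_matrix(study$profiles,
                             min_overlap = study_cfg$min_overlap %||% 100)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_clone_map(study$map, file.path(out_dir, "clone_map.tsv"))
    for (p in study$profiles) {
      id <- attr(p, "sample_id")
      write_profile(p, file.path(out_dir, sprintf("profile_%s.tsv", id)))
      segs <- cbs_segment(p, study$map, cbs)
      write_segments(segs, file.path(out_dir, sprintf("segments_%s.bed", id)))
    }
    utils::write.table(corr$r, file.path(out_dir, "correlation_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    for (g in names(study$reports))
      write_report(study$reports[[g]], file.path(out_dir,
                                                 sprintf("report_%s.json", g)))
  }
  list(reports = study$reports, correlation = corr, study = study,
       params = list(seed = seed, cbs = unclass(cbs), peaks = unclass(peaks)))
}
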