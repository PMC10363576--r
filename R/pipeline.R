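# End-to-end orchestration: synthetic dataset construction and the full
# analysis pipeline (features -> unit decode -> ensemble decode ->
# MRF/LDA/volume -> clustering -> corrected stats).

#' Build a complete synthetic dataset
#'
#' Convenience constructor running the generator end to end: repertoire
#' synthesis, MPS computation and deviations, unit generation, spike
#' simulation, and the per-trial feature table (Z + temporal PCs).
#'
#' @param n_units Number of units.
#' @param n_renditions Renditions per call type.
#' @param n_trials Trials per (unit, stimulus).
#' @param seed Integer master seed (sub-stages use seeds derived from it).
#' @param noise_sd Trial gain SD for every unit.
#' @param purity Template purity passed to [synth_units()].
#' @param gain_range,preferred Passed to [synth_units()].
#' @param n_components Temporal PCs to fit.
#' @param ... Passed to [mps_set()] (spectrogram/MPS parameters).
#' @return List with `stimuli`, `mps`, `deviations`, `units`, `responses`
#'   (spikes/trials/drives), `basis`, `features`.
#' @export
synth_dataset <- function(n_units = 20, n_renditions = 11, n_trials = 10,
                          seed = 1, noise_sd = 1.2, purity = 0.4,
                          gain_range = c(2, 7), preferred = NULL,
                          n_components = 5, ...) {
  stimuli <- synth_repertoire(n_renditions_per_type = n_renditions,
                              seed = seed)
  mps <- mps_set(stimuli, ...)
  deviations <- mps_deviations(mps)
  units <- synth_units(n_units, deviations, stimuli$table,
                       seed = seed + 1, noise_sd = noise_sd, purity = purity,
                       gain_range = gain_range, preferred = preferred)
  responses <- simulate_responses(units, stimuli, n_trials,
                                  seed = seed + 2, deviations = deviations)
  pm <- psth_matrix(responses$spikes, responses$trials,
                    min_trials = min(5, n_trials))
  basis <- fit_temporal_pcs(pm, n_components = n_components)
  features <- trial_features(responses$spikes, responses$trials, basis)
  list(stimuli = stimuli, mps = mps, deviations = deviations,
       units = units, responses = responses, basis = basis,
       features = features)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a dataset (synthetic by default) and returns
#' the stage outputs; when `out_dir` is given, stage artifacts are
#' written as plain-text tables along with a JSON manifest of the
#' configuration and seeds.
#'
#' @param config Named list of settings; recognized entries (with
#'   defaults): `n_units` (20), `n_renditions` (11), `n_trials` (10),
#'   `seed` (1), `noise_sd` (1.2), `purity` (0.4), `ensemble_size` (10),
#'   `n_ensembles` (50), `feature_mode` ("zt"), `n_folds` (1),
#'   `unit_pcc_threshold` (12), `lda_dims` (3).
#' @param out_dir Optional output directory.
#' @param dataset Optional precomputed [synth_dataset()] output (skips
#'   generation).
#' @return List with `dataset`, `unit_results`, `good_units`,
#'   `ensembles`, `ensemble_results`, `lda`, `mrfs`, `summaries`,
#'   `regression`, `clustering`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, dataset = NULL) {
  cfg <- utils::modifyList(list(
    n_units = 20, n_renditions = 11, n_trials = 10, seed = 1,
    noise_sd = 1.2, purity = 0.4, ensemble_size = 10, n_ensembles = 50,
    feature_mode = "zt", n_folds = 1, unit_pcc_threshold = 12,
    lda_dims = 3), config)
  if (is.null(dataset))
    dataset <- synth_dataset(n_units = cfg$n_units,
                             n_renditions = cfg$n_renditions,
                             n_trials = cfg$n_trials, seed = cfg$seed,
                             noise_sd = cfg$noise_sd, purity = cfg$purity)
  st <- dataset$stimuli$table
  features <- dataset$features
  unit_ids <- unique(features$unit_id)

  # single-unit decoding and unit metrics
  unit_results <- lapply(unit_ids, function(u)
    cross_validate(features, st, u, feature_mode = cfg$feature_mode,
                   n_folds = cfg$n_folds, seed = cfg$seed + 10))
  names(unit_results) <- unit_ids
  unit_pcc <- vapply(unit_results, `[[`, 0, "pcc")
  good_units <- unit_ids[unit_pcc > cfg$unit_pcc_threshold]

  zt <- merge(features, st[, c("stimulus_id", "call_type")],
              by = "stimulus_id")
  unit_stats <- do.call(rbind, lapply(unit_ids, function(u) {
    zu <- zt[zt$unit_id == u, ]
    z_ct <- vapply(split(zu$Z, zu$call_type), mean, 0)
    data.frame(unit_id = u, si = as.numeric(selectivity_index(z_ct)),
               gs = as.numeric(entropy_selectivity(diag(unit_results[[u]]$confusion))),
               noise = within_calltype_noise(zu$Z, zu$call_type),
               pcc = unit_pcc[[u]])
  }))

  # ensemble decoding
  pool <- if (length(good_units) >= cfg$ensemble_size) good_units else unit_ids
  ensembles <- sample_ensembles(pool, cfg$ensemble_size, cfg$n_ensembles,
                                seed = cfg$seed + 20)
  ensemble_results <- lapply(seq_along(ensembles), function(i)
    cross_validate(features, st, ensembles[[i]],
                   feature_mode = cfg$feature_mode, n_folds = cfg$n_folds,
                   seed = cfg$seed + 30 + i))
  pcc <- vapply(ensemble_results, `[[`, 0, "pcc")

  # MRFs, discriminant space, volumes
  labels <- st$call_type[match(names(dataset$deviations), st$stimulus_id)]
  lda <- fit_lda(dataset$deviations, labels, n_dims = cfg$lda_dims)
  mrfs <- lapply(unit_ids, function(u)
    compute_mrf(unit_mean_weights(features, u), dataset$deviations))
  names(mrfs) <- unit_ids
  summaries <- do.call(rbind, lapply(ensembles, function(e)
    ensemble_tuning_summary(e, mrfs, lda, unit_stats)))
  regression <- tuning_vs_performance_regression(
    summaries, pcc, ns = length(pool), ne = cfg$ensemble_size)

  # clustering comparison: neural dendrograms vs call-type and acoustic labels
  feat_tab <- bioacoustic_feature_table(dataset$stimuli)
  ac_dendro <- cluster_acoustic(feat_tab)
  acoustic_labels <- cut_partition(ac_dendro, length(unique(st$call_type)) - 1)
  call_labels <- setNames(st$call_type, st$stimulus_id)
  clustering <- compare_ari_call_vs_acoustic(
    ensembles[seq_len(min(10, length(ensembles)))], features, call_labels,
    acoustic_labels, ns = length(pool), ne = cfg$ensemble_size)

  out <- list(dataset = dataset, config = cfg, unit_results = unit_results,
              unit_stats = unit_stats, good_units = good_units,
              ensembles = ensembles, ensemble_results = ensemble_results,
              pcc = pcc, lda = lda, mrfs = mrfs, summaries = summaries,
              regression = regression, clustering = clustering)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stimulus_table(st, file.path(out_dir, "stimuli.tsv"))
    write_spikes(dataset$responses$spikes, file.path(out_dir, "spikes.tsv"))
    write_features(features, file.path(out_dir, "features.tsv"))
    write_ground_truth(dataset$units, dataset$responses$drives,
                       file.path(out_dir, "ground_truth"))
    er <- data.frame(ensemble = seq_along(ensembles),
                     units = vapply(ensembles, paste, "", collapse = ","),
                     k = cfg$ensemble_size, pcc = pcc,
                     mi_bits = vapply(ensemble_results, `[[`, 0,
                                      "mutual_information_bits"))
    data.table::fwrite(er, file.path(out_dir, "ensemble_results.tsv"),
                       sep = "\t")
    write_confusion(ensemble_results[[which.max(pcc)]],
                    file.path(out_dir, "best_ensemble_confusion.csv"))
    write_dendrogram(ac_dendro, file.path(out_dir, "acoustic_dendrogram.tsv"))
    jsonlite::write_json(list(config = cfg, n_stimuli = nrow(st),
                              n_units = length(unit_ids),
                              timestamp = format(Sys.time(), tz = "UTC")),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
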