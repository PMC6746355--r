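#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected so typos fail loudly; the returned list
#' round-trips losslessly through [save_config()].
#'
#' @param path YAML file, or NULL for all defaults.
#' @param overrides Named list applied on top of the file values.
#' @return Named configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    recording = NULL, images_dir = NULL, manifest = NULL, wordvecs = NULL,
    codebook = NULL, out_dir = "results",
    blocks = c("gabor", "hsv", "sift", "sem"),
    simulate = NULL,
    preprocess = preprocess_config(),
    decode = decode_config(),
    pca_components = NULL,
    grid_step = 8, codebook_k = 1000,
    seeds = list(images = 21L, lexicon = 22L, codebook = 23L, eeg = 11L,
                 schedule = 12L))
  cfg <- defaults
  apply_over <- function(cfg, vals, where) {
    unknown <- setdiff(names(vals), names(cfg))
    if (length(unknown))
      stop_eegr(paste0("unknown config key(s) ", where, ": ",
                       paste(unknown, collapse = ", ")),
                class = "eegretrieve_config_error")
    for (nm in names(vals)) {
      if (is.list(cfg[[nm]]) && is.list(vals[[nm]]) &&
          !is.null(names(cfg[[nm]])))
        cfg[[nm]] <- apply_over(cfg[[nm]], vals[[nm]],
                                paste0(where, "$", nm))
      else cfg[[nm]] <- vals[[nm]]
    }
    cfg
  }
  if (!is.null(path)) cfg <- apply_over(cfg, yaml::read_yaml(path), "")
  if (length(overrides)) cfg <- apply_over(cfg, overrides, "")
  cfg
}

#' @rdname load_config
#' @param config Configuration list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_hash <- function(config) rlang::hash(config)

#' Run the full retrieval pipeline and write a results bundle
#'
#' Chains simulation (or loading), preprocessing, image feature extraction,
#' fusion and zero-shot decoding, then writes a self-describing bundle:
#' `decoding.json` (AUC, config hash, mask summary), `ranks.csv`,
#' `cmc_curve.csv`, `preprocess_report.json` and `config.yaml`. Re-running
#' from the snapshot reproduces the AUC exactly.
#'
#' @param config A [load_config()] list. Either `simulate` (a list of
#'   [synth_spec()] arguments) or `recording` + `images_dir` + `manifest` +
#'   `wordvecs` must be given.
#' @return Invisibly, a list with `epochs`, `report`, `fused`, `result`,
#'   and `out_dir`.
#' @export
run_pipeline <- function(config = load_config()) {
  if (!is.null(config$simulate)) {
    spec <- do.call(synth_spec, c(config$simulate,
                                  list(seeds = config$seeds[c("eeg",
                                                              "schedule")])))
    study <- synth_study(spec, blocks = config$blocks,
                         seeds = config$seeds[c("images", "lexicon",
                                                "codebook")],
                         pca_components = config$pca_components)
    raw <- study$recording
    fused <- study$fused
  } else {
    if (is.null(config$recording) || is.null(config$manifest) ||
        is.null(config$images_dir))
      stop_eegr("config needs either $simulate or recording/images/manifest",
                class = "eegretrieve_config_error")
    raw <- load_recording(config$recording)
    man <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
    wt <- if (!is.null(config$wordvecs)) read_word_vectors(config$wordvecs)
    cb <- if (!is.null(config$codebook)) readRDS(config$codebook)
    if (is.null(cb) && "sift" %in% config$blocks) {
      paths <- file.path(config$images_dir, man$filename)
      descs <- do.call(rbind, lapply(paths[seq_len(min(10, length(paths)))],
                                     function(p) dense_sift(p,
                                       config$grid_step)))
      cb <- train_codebook(descs, k = min(config$codebook_k, nrow(descs)),
                           seed = config$seeds$codebook,
                           corpus_id = config$images_dir)
    }
    blk <- stimulus_feature_blocks(
      file.path(config$images_dir, man$filename), man$name, man$stimulus_id,
      codebook = cb, word_table = wt, blocks = config$blocks,
      grid_step = config$grid_step)
    fused <- fuse_features(blk, pca_components = config$pca_components)
  }
  pre <- preprocess(raw, config$preprocess)
  result <- zero_shot_cv(pre$epochs, fused, config$decode)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  jsonlite::write_json(
    list(cmc_auc = result$auc, n_trials = nrow(result$ranks),
         n_stimuli = result$nS,
         image_features_kept = sum(result$image_mask),
         eeg_features_selected = result$eeg_features_selected,
         channels_interpolated = length(pre$report$bad_channels),
         epochs_rejected = length(pre$report$rejected_epoch_indices),
         components_removed = length(pre$report$removed_components),
         config = result$config, config_hash = hash,
         package_version = as.character(utils::packageVersion("eegretrieve"))),
    file.path(out, "decoding.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(cbind(result$ranks, config_hash = hash),
                   file.path(out, "ranks.csv"), row.names = FALSE)
  utils::write.csv(cbind(result$cmc, config_hash = hash),
                   file.path(out, "cmc_curve.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(bad_channels = pre$report$bad_channels,
         rejected_epoch_indices = pre$report$rejected_epoch_indices,
         removed_components = pre$report$removed_components,
         epoch_repairs = pre$report$epoch_repairs,
         excluded_stimuli = pre$report$excluded_stimuli,
         thresholds = pre$report$thresholds, config_hash = hash),
    file.path(out, "preprocess_report.json"), auto_unbox = TRUE, digits = NA)
  save_config(c(config, list(config_hash = hash)),
              file.path(out, "config.yaml"))
  message(sprintf(
    "pipeline done: %d channels interpolated, %d epochs rejected, %d components removed; CMC AUC %.2f%%",
    length(pre$report$bad_channels),
    length(pre$report$rejected_epoch_indices),
    length(pre$report$removed_components), result$auc))
  invisible(list(epochs = pre$epochs, report = pre$report, fused = fused,
                 result = result, out_dir = out))
}
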