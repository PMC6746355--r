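#' Rearrange epochs into the feature x presentation x stimulus tensor
#'
#' Flattens each epoch to `nF = nC * nT` features (channel-major: feature
#' `f` is channel `(f-1) %/% nT + 1`, timepoint `(f-1) %% nT + 1`) and
#' stacks repeated presentations of each stimulus, giving the 3-D tensor on
#' which per-feature stability is scored. Presentation slots a stimulus is
#' missing (after epoch rejection) are `NA`, never zero-filled.
#'
#' @param epochs An [eeg_epochs()] (or a pre-flattened matrix plus
#'   `stimulus_ids`).
#' @param flat Optional pre-flattened nE x nF matrix (e.g. z-scored) to use
#'   instead of flattening `epochs$data`.
#' @return A `trial_tensor`: `D` (nF x nP x nS array), `stimulus_order`,
#'   `presentation_counts`, and the (nC, nT) geometry.
#' @export
build_trial_tensor <- function(epochs, flat = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  if (is.null(flat)) flat <- flatten_epochs(epochs)
  ids <- epochs$stimulus_ids
  counts <- table(ids)
  drop_stim <- names(counts)[counts < 2]
  if (length(drop_stim)) {
    warn_eegr(paste0("stimuli with < 2 presentations excluded from the ",
                     "trial tensor: ", paste(drop_stim, collapse = ", ")))
    keep <- !(ids %in% drop_stim)
    flat <- flat[keep, , drop = FALSE]
    ids <- ids[keep]
    counts <- table(ids)
  }
  stims <- names(counts)
  nS <- length(stims); nP <- max(counts); nF <- ncol(flat)
  D <- array(NA_real_, c(nF, nP, nS))
  for (s in seq_len(nS)) {
    rows <- which(ids == stims[s])
    for (p in seq_along(rows)) D[, p, s] <- flat[rows[p], ]
  }
  structure(list(D = D, stimulus_order = stims,
                 presentation_counts = as.integer(counts)[match(stims, names(counts))],
                 nC = d[2], nT = d[3]),
            class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$D)
  cat(sprintf("<trial_tensor> nF=%d x nP=%d x nS=%d\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Correlation-stability score per EEG feature
#'
#' For each feature, the Pearson correlation across stimuli is computed for
#' every unordered pair of presentations and averaged: features that respond
#' consistently to the same image across repeated presentations score near
#' 1. Pairs with an absent presentation or a zero-variance row are skipped
#' (`n_pairs_used` records how many of the `nP(nP-1)/2` pairs contributed).
#'
#' @param tensor A `trial_tensor` with at least 3 stimuli.
#' @return A tibble: feature, channel, time_index, score, n_pairs_used.
#'   Features with no usable pair get `NA` score.
#' @export
stability_scores <- function(tensor) {
  stopifnot(inherits(tensor, "trial_tensor"))
  d <- dim(tensor$D)
  nF <- d[1]; nP <- d[2]; nS <- d[3]
  if (nS < 3) stop_eegr("stability needs at least 3 stimuli")
  acc <- numeric(nF); npairs <- integer(nF)
  for (i in seq_len(nP - 1)) {
    for (j in (i + 1):nP) {
      A <- tensor$D[, i, , drop = TRUE]
      B <- tensor$D[, j, , drop = TRUE]
      if (nF == 1) { A <- matrix(A, 1); B <- matrix(B, 1) }
      ok <- rowSums(is.na(A)) == 0 & rowSums(is.na(B)) == 0
      Ac <- A - rowMeans(A); Bc <- B - rowMeans(B)
      sa <- sqrt(rowSums(Ac^2)); sb <- sqrt(rowSums(Bc^2))
      good <- ok & sa > 0 & sb > 0
      r <- rowSums(Ac * Bc) / (sa * sb)
      acc[good] <- acc[good] + r[good]
      npairs[good] <- npairs[good] + 1L
    }
  }
  score <- ifelse(npairs > 0, acc / npairs, NA_real_)
  tibble::tibble(
    feature = seq_len(nF),
    channel = (seq_len(nF) - 1L) %/% tensor$nT + 1L,
    time_index = (seq_len(nF) - 1L) %% tensor$nT + 1L,
    score = score,
    n_pairs_used = npairs)
}

#' Select the k most stable EEG features
#'
#' @param scores Tibble from [stability_scores()].
#' @param k Number of features to keep (1..number of scored features).
#' @return Logical mask of length nF with exactly `k` TRUE entries; ties at
#'   the k-th rank go to the lower feature index, and features with `NA`
#'   scores are never selected.
#' @export
select_features <- function(scores, k) {
  nF <- nrow(scores)
  scored <- which(!is.na(scores$score))
  if (k < 1 || k > length(scored))
    stop_eegr(sprintf("k must be in 1..%d (scored features)", length(scored)))
  ord <- scored[order(-scores$score[scored], scores$feature[scored])]
  mask <- rep(FALSE, nF)
  mask[ord[seq_len(k)]] <- TRUE
  mask
}

#' Fit / apply a train-only z-scaler
#'
#' Column means and SDs are estimated on training epochs only and applied
#' unchanged to held-out epochs, so no test information leaks into the
#' standardisation. Zero-variance columns map to 0.
#'
#' @param train_flat nE x nF numeric matrix of training epochs.
#' @return A `zscaler` with `mean` and `sd` per column.
#' @export
fit_scaler <- function(train_flat) {
  stopifnot(is.matrix(train_flat), nrow(train_flat) >= 1)
  mu <- colMeans(train_flat)
  sdv <- apply(train_flat, 2, stats::sd)
  if (nrow(train_flat) == 1) sdv <- rep(0, ncol(train_flat))
  structure(list(mean = mu, sd = sdv), class = "zscaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `zscaler`.
#' @param flat Matrix to standardise with the training statistics.
#' @export
apply_scaler <- function(scaler, flat) {
  stopifnot(inherits(scaler, "zscaler"))
  sdv <- ifelse(scaler$sd > 0, scaler$sd, Inf)
  sweep(sweep(flat, 2, scaler$mean, "-"), 2, sdv, "/")
}

#' Stability summarised over time (and channels)
#'
#' Collapses per-feature stability scores to a per-timepoint mean across
#' channels (the temporal profile of feature stability) and a per-channel
#' mean across timepoints (the spatial profile).
#'
#' @param scores Tibble from [stability_scores()].
#' @param srate Sampling rate of the scored epochs (for time_ms).
#' @return List of tibbles `by_time` (time_index, time_ms, mean_score) and
#'   `by_channel` (channel, mean_score).
#' @export
stability_topography <- function(scores, srate = 120) {
  by_time <- scores |>
    dplyr::group_by(.data$time_index) |>
    dplyr::summarise(mean_score = mean(.data$score, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(time_ms = (.data$time_index - 1) * 1000 / srate,
                  .after = "time_index")
  by_channel <- scores |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(mean_score = mean(.data$score, na.rm = TRUE),
                     .groups = "drop")
  list(by_time = by_time, by_channel = by_channel)
}
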