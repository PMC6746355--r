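# Zero-phase FIR bandpass applied by FFT convolution. The Hamming
# windowed-sinc design has ~53 dB stopband attenuation; the order is set so
# the transition band is about 1 Hz, and group delay is compensated exactly
# (symmetric kernel, integer shift).
design_bandpass <- function(srate, low_hz, high_hz, transition_hz = 1) {
  order <- 2L * ceiling(1.65 * srate / transition_hz)
  w <- c(low_hz, high_hz) / (srate / 2)
  signal::fir1(order, w, type = "pass")
}

apply_fir <- function(x, h) {
  n <- length(x); m <- length(h)
  gd <- (m - 1L) %/% 2L
  nfft <- stats::nextn(n + m - 1L, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  H <- stats::fft(c(h, numeric(nfft - m)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  y[(gd + 1L):(gd + n)]
}

#' Bandpass filter a raw recording
#'
#' Removes slow drifts (perspiration, electrode polarisation) and
#' high-frequency / mains interference by keeping only the `low_hz`-`high_hz`
#' band, with a zero-phase FIR so ERP latencies are untouched.
#'
#' @param raw An [eeg_recording()].
#' @param low_hz,high_hz Passband edges in Hz; default 1-40.
#' @return A filtered `eeg_recording` of the same shape.
#' @export
bandpass_filter <- function(raw, low_hz = 1, high_hz = 40) {
  stopifnot(inherits(raw, "eeg_recording"))
  nyq <- raw$srate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop_eegr(sprintf(
      "need 0 < low_hz < high_hz < Nyquist (%g Hz); got [%g, %g]",
      nyq, low_hz, high_hz), class = "eegretrieve_config_error")
  h <- design_bandpass(raw$srate, low_hz, high_hz)
  out <- raw
  for (ch in seq_len(nrow(raw$data)))
    out$data[ch, ] <- apply_fir(raw$data[ch, ], h)
  out
}

#' Per-channel quality metrics
#'
#' Computes, for every channel of a continuous recording, the variance, the
#' mean absolute Pearson correlation with all other channels, and the Hurst
#' exponent (rescaled-range estimate). Channels whose metric lies more than
#' three standard deviations from the norm are candidates for interpolation.
#'
#' @param raw An [eeg_recording()] with at least 3 channels and 512 samples.
#' @param max_samples Cap on samples used for the Hurst estimate (speed).
#' @return A tibble with columns channel, name, variance, mean_correlation,
#'   hurst.
#' @export
channel_scores <- function(raw, max_samples = 65536L) {
  stopifnot(inherits(raw, "eeg_recording"))
  nc <- nrow(raw$data); ns <- ncol(raw$data)
  if (nc < 3 || ns < 512)
    stop_eegr("channel_scores() needs >= 3 channels and >= 512 samples")
  v <- apply(raw$data, 1, stats::var)
  cm <- suppressWarnings(abs(stats::cor(t(raw$data))))
  if (any(!is.finite(cm))) {
    warn_eegr("constant channel(s): undefined correlations reported as 0")
    cm[!is.finite(cm)] <- 0
  }
  diag(cm) <- NA
  mean_corr <- rowMeans(cm, na.rm = TRUE)
  idx <- seq_len(min(ns, max_samples))
  hu <- apply(raw$data[, idx, drop = FALSE], 1, hurst_rs)
  hu[!is.finite(hu)] <- 0.5
  tibble::tibble(channel = seq_len(nc), name = raw$channel_names,
                 variance = v, mean_correlation = mean_corr, hurst = hu)
}

flag_bad_channels <- function(scores, z_threshold = 3) {
  sort(unique(c(flag_outliers(scores$variance, z_threshold),
                flag_outliers(scores$mean_correlation, z_threshold),
                flag_outliers(scores$hurst, z_threshold))))
}

# Perrin-style spherical spline basis: g(cos angle) truncated Legendre
# series with stiffness m = 4. Returns the interpolation operator mapping
# values at `good` positions to values at `bad` positions. Constants are
# reproduced exactly via the unpenalised constant term.
spline_gfun <- function(cosang, m = 4, n_terms = 50) {
  # Legendre recurrence, accumulating the series for each entry.
  p_prev <- rep(1, length(cosang))
  p_cur <- cosang
  acc <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  for (n in 2:n_terms) {
    p_next <- ((2 * n - 1) * cosang * p_cur - (n - 1) * p_prev) / n
    acc <- acc + (2 * n + 1) / (n * (n + 1))^m * p_next
    p_prev <- p_cur; p_cur <- p_next
  }
  acc / (4 * pi)
}

spline_operator <- function(layout, good, bad, lambda = 1e-8) {
  pos <- layout / sqrt(rowSums(layout^2))
  G <- spline_gfun(pmin(pmax(tcrossprod(pos[good, , drop = FALSE]), -1), 1))
  Gb <- spline_gfun(pmin(pmax(pos[bad, , drop = FALSE] %*%
                                t(pos[good, , drop = FALSE]), -1), 1))
  ng <- length(good)
  A <- rbind(cbind(G + lambda * diag(ng), rep(1, ng)), c(rep(1, ng), 0))
  # rows: interpolated value = Gb %*% c + c0
  solve_part <- solve(A)
  list(A_inv = solve_part, Gb = Gb, ng = ng)
}

apply_spline <- function(op, values_good) {
  # values_good: ng x nT matrix (or vector); returns |bad| x nT
  vg <- rbind(as.matrix(values_good), 0)
  cw <- op$A_inv %*% vg
  op$Gb %*% cw[seq_len(op$ng), , drop = FALSE] +
    matrix(cw[op$ng + 1, ], nrow(op$Gb), ncol(vg), byrow = TRUE)
}

#' Interpolate bad channels by spherical spline
#'
#' Replaces the listed channels with values interpolated from the remaining
#' clean channels using a spherical spline over the unit-sphere sensor
#' positions. Clean channels are untouched.
#'
#' @param x An [eeg_recording()] or [eeg_epochs()].
#' @param bad_indices Integer channel indices to replace (may be empty).
#' @return The same type of object with bad channels replaced.
#' @export
interpolate_channels <- function(x, bad_indices) {
  if (!length(bad_indices)) return(x)
  layout <- require_layout(x, "interpolate_channels()")
  nc <- if (inherits(x, "eeg_recording")) nrow(x$data) else dim(x$data)[2]
  bad_indices <- sort(unique(as.integer(bad_indices)))
  good <- setdiff(seq_len(nc), bad_indices)
  if (length(bad_indices) >= nc - 3)
    stop_eegr("too many bad channels to interpolate (need > 3 clean ones)")
  op <- spline_operator(layout, good, bad_indices)
  if (inherits(x, "eeg_recording")) {
    x$data[bad_indices, ] <- apply_spline(op, x$data[good, , drop = FALSE])
  } else {
    for (e in seq_len(dim(x$data)[1]))
      x$data[e, bad_indices, ] <-
        apply_spline(op, x$data[e, good, , drop = FALSE])
  }
  x
}

#' Cut stimulus-locked epochs and subtract the pre-stimulus baseline
#'
#' Extracts a half-open `[0, 1000)` ms window from each stimulus onset and
#' subtracts, per channel, the mean of the 500 ms immediately before onset.
#' Events too close to the recording edges are dropped with a warning.
#'
#' @param raw An [eeg_recording()] with events.
#' @param window_ms Epoch window, default `c(0, 1000)`.
#' @param baseline_ms Baseline window, default `c(-500, 0)`.
#' @return An [eeg_epochs()].
#' @export
epoch_and_baseline <- function(raw, window_ms = c(0, 1000),
                               baseline_ms = c(-500, 0)) {
  stopifnot(inherits(raw, "eeg_recording"))
  sr <- raw$srate
  ns <- ncol(raw$data)
  w0 <- round(window_ms[1] * sr / 1000); w1 <- round(window_ms[2] * sr / 1000)
  b0 <- round(baseline_ms[1] * sr / 1000); b1 <- round(baseline_ms[2] * sr / 1000)
  nT <- w1 - w0
  ok <- raw$events$sample + b0 >= 1 & raw$events$sample + w1 - 1 <= ns
  if (any(!ok))
    warn_eegr(sprintf("%d event(s) too close to the recording edge; dropped",
                      sum(!ok)))
  ev <- raw$events[ok, ]
  nE <- nrow(ev)
  out <- array(NA_real_, c(nE, nrow(raw$data), nT))
  for (i in seq_len(nE)) {
    on <- ev$sample[i]
    ep <- raw$data[, (on + w0):(on + w1 - 1), drop = FALSE]
    bl <- rowMeans(raw$data[, (on + b0):(on + b1 - 1), drop = FALSE])
    out[i, , ] <- ep - bl
  }
  eeg_epochs(out, sr, ev$stimulus_id, window_ms, raw$channel_names,
             raw$layout)
}

epoch_metrics <- function(epochs) {
  d <- dim(epochs$data)
  amp <- apply(epochs$data, 1, function(e) max(e) - min(e))
  vr <- apply(epochs$data, 1, function(e) stats::var(as.vector(e)))
  dev <- vapply(seq_len(d[1]), function(i) {
    chm <- rowMeans(epochs$data[i, , , drop = TRUE])
    mean(abs(chm - mean(chm)))
  }, numeric(1))
  tibble::tibble(epoch = seq_len(d[1]), amplitude_range = amp,
                 variance = vr, channel_deviation = dev)
}

#' Reject artefactual epochs by statistical thresholding
#'
#' Flags epochs whose amplitude range, overall variance or channel deviation
#' (mean absolute deviation of channel means from the grand mean) lies more
#' than `z_threshold` SDs from the norm across epochs; the union is removed.
#'
#' @param epochs An [eeg_epochs()] with at least 4 epochs.
#' @param z_threshold z cutoff, default 3.
#' @return List with `epochs` (cleaned) and `rejected` (integer indices).
#' @export
reject_epochs <- function(epochs, z_threshold = 3) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (dim(epochs$data)[1] < 4) stop_eegr("reject_epochs() needs >= 4 epochs")
  met <- epoch_metrics(epochs)
  bad <- sort(unique(c(flag_outliers(met$amplitude_range, z_threshold),
                       flag_outliers(met$variance, z_threshold),
                       flag_outliers(met$channel_deviation, z_threshold))))
  if (length(bad) > dim(epochs$data)[1] / 2)
    stop_eegr("more than half of the epochs flagged as artefactual",
              class = "eegretrieve_quality_error")
  keep <- setdiff(seq_len(dim(epochs$data)[1]), bad)
  list(epochs = subset_epochs(epochs, keep), rejected = bad)
}

#' Repair transient bad channels within single epochs
#'
#' Within each epoch, channels are scored on variance, median gradient
#' (median absolute successive difference), amplitude range and channel
#' deviation; channels flagged at `|z| > 3` across channels of that epoch
#' are replaced by spherical-spline interpolation using only that epoch's
#' data. An epoch with more than half its channels flagged is dropped.
#'
#' @param epochs An [eeg_epochs()] with a sensor layout.
#' @param z_threshold z cutoff, default 3.
#' @return List with `epochs`, `repairs` (tibble epoch/channel) and
#'   `dropped` (epoch indices removed entirely).
#' @export
repair_epoch_channels <- function(epochs, z_threshold = 3) {
  layout <- require_layout(epochs, "repair_epoch_channels()")
  d <- dim(epochs$data)
  repairs <- list(); dropped <- integer(0)
  for (e in seq_len(d[1])) {
    ep <- epochs$data[e, , , drop = TRUE]
    vr <- apply(ep, 1, stats::var)
    mg <- apply(ep, 1, function(x) stats::median(abs(diff(x))))
    rg <- apply(ep, 1, function(x) max(x) - min(x))
    chm <- rowMeans(ep)
    dv <- abs(chm - mean(chm))
    bad <- sort(unique(c(flag_outliers(vr, z_threshold),
                         flag_outliers(mg, z_threshold),
                         flag_outliers(rg, z_threshold),
                         flag_outliers(dv, z_threshold))))
    if (length(bad) > d[2] / 2) {
      dropped <- c(dropped, e)
    } else if (length(bad)) {
      op <- spline_operator(layout, setdiff(seq_len(d[2]), bad), bad)
      epochs$data[e, bad, ] <-
        apply_spline(op, ep[setdiff(seq_len(d[2]), bad), , drop = FALSE])
      repairs[[length(repairs) + 1]] <-
        tibble::tibble(epoch = e, channel = bad)
    }
  }
  if (length(dropped)) {
    warn_eegr(sprintf("%d epoch(s) dropped: more than half their channels bad",
                      length(dropped)))
    epochs <- subset_epochs(epochs, setdiff(seq_len(d[1]), dropped))
  }
  list(epochs = epochs,
       repairs = if (length(repairs)) dplyr::bind_rows(repairs) else
         tibble::tibble(epoch = integer(0), channel = integer(0)),
       dropped = dropped)
}

# Rational-rate polyphase resampling expressed as an n_out x n matrix:
# output sample k sits at upsampled-grid position (k-1)q, and draws on the
# windowed-sinc anti-alias kernel evaluated at (k-1)q - (m-1)p over input
# samples m, with reflection at the edges. Rows are normalised to sum 1 so
# a DC signal is preserved exactly.
resample_matrix <- function(n, p, q, n_out) {
  L <- max(p, q)
  H <- 10L * L
  t <- (-H):H
  sinc <- ifelse(t == 0, 1 / L, sin(pi * t / L) / (pi * t))
  h <- sinc * (0.54 + 0.46 * cos(pi * t / H))   # Hamming window
  M <- matrix(0, n_out, n)
  for (k in seq_len(n_out)) {
    pos <- (k - 1) * q
    m_lo <- ceiling((pos - H) / p) + 1
    m_hi <- floor((pos + H) / p) + 1
    ms <- m_lo:m_hi
    co <- h[pos - (ms - 1) * p + H + 1]
    mr <- ifelse(ms < 1, 2 - ms, ifelse(ms > n, 2 * n - ms, ms))
    for (i in seq_along(ms)) M[k, mr[i]] <- M[k, mr[i]] + co[i]
  }
  M / rowSums(M)
}

#' Downsample epochs with anti-alias polyphase resampling
#'
#' Rational-rate resampling (never naive decimation): the signal is
#' conceptually upsampled, filtered with a windowed-sinc anti-alias kernel
#' and decimated, implemented as one resampling matrix applied to every
#' epoch and channel.
#'
#' @param epochs An [eeg_epochs()].
#' @param target_hz Target rate, default 120 Hz (must be below `srate`).
#' @return An [eeg_epochs()] at the new rate; a 1 s epoch at any source rate
#'   ends up with `round(nT * target_hz / srate)` timepoints (120 for 1 s).
#' @export
downsample <- function(epochs, target_hz = 120) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (target_hz >= epochs$srate)
    stop_eegr("target_hz must be below the current sampling rate",
              class = "eegretrieve_config_error")
  d <- dim(epochs$data)
  g <- gcd_int(round(target_hz * 1000), round(epochs$srate * 1000))
  p <- round(target_hz * 1000) / g; q <- round(epochs$srate * 1000) / g
  nT_out <- round(d[3] * target_hz / epochs$srate)
  M <- resample_matrix(d[3], p, q, nT_out)
  flat <- matrix(epochs$data, d[1] * d[2], d[3])
  out <- array(flat %*% t(M), c(d[1], d[2], nT_out))
  eeg_epochs(out, target_hz, epochs$stimulus_ids, epochs$window_ms,
             epochs$channel_names, epochs$layout)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Default preprocessing configuration
#'
#' @param ... Overrides for any default.
#' @return Named list of preprocessing tunables.
#' @export
preprocess_config <- function(...) {
  cfg <- list(low_hz = 1, high_hz = 40, z_threshold = 3, target_hz = 120,
              window_ms = c(0, 1000), baseline_ms = c(-500, 0),
              ica = TRUE, ica_seed = 1L, ica_maxit = 200, ica_tol = 1e-6)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_eegr(paste0("unknown preprocessing option(s): ",
                     paste(unknown, collapse = ", ")),
              class = "eegretrieve_config_error")
  cfg[names(over)] <- over
  cfg
}

#' Full statistical-thresholding preprocessing pipeline
#'
#' Runs the fixed stage order: bandpass filter, bad-channel detection and
#' spherical-spline interpolation, epoching and baselining, epoch rejection,
#' ICA artefact-component removal, within-epoch channel repair, and
#' downsampling. Deterministic given `config$ica_seed`.
#'
#' @param raw An [eeg_recording()] with events and a sensor layout.
#' @param config A [preprocess_config()] list.
#' @return List with `epochs` (clean [eeg_epochs()]) and `report` (list of
#'   bad channels, rejected epochs, removed components, repairs, thresholds).
#' @export
preprocess <- function(raw, config = preprocess_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_eegr(sprintf("preprocessing stage '%s' failed: %s", name,
                        conditionMessage(e)))
    })
  }
  filtered <- stage("bandpass", bandpass_filter(raw, config$low_hz,
                                                config$high_hz))
  scores <- stage("channel_scores", channel_scores(filtered))
  bad_ch <- flag_bad_channels(scores, config$z_threshold)
  filtered <- stage("interpolate", interpolate_channels(filtered, bad_ch))
  epochs <- stage("epoch", epoch_and_baseline(filtered, config$window_ms,
                                              config$baseline_ms))
  rej <- stage("reject_epochs", reject_epochs(epochs, config$z_threshold))
  epochs <- rej$epochs
  removed_comps <- integer(0)
  if (isTRUE(config$ica)) {
    n_ic <- dim(epochs$data)[2] - length(bad_ch)
    ica <- stage("ica", fastica_epochs(epochs, n_comp = n_ic,
                                       seed = config$ica_seed,
                                       maxit = config$ica_maxit,
                                       tol = config$ica_tol))
    removed_comps <- stage("flag_components",
                           flag_components(ica, eog_proxy_channel(epochs),
                                           config$z_threshold))
    if (length(removed_comps))
      epochs <- stage("reconstruct", reconstruct_without(ica, removed_comps))
  }
  rep_res <- stage("repair", repair_epoch_channels(epochs, config$z_threshold))
  epochs <- rep_res$epochs
  epochs <- stage("downsample", downsample(epochs, config$target_hz))
  zero_stim <- setdiff(unique(raw$events$stimulus_id), epochs$stimulus_ids)
  if (length(zero_stim))
    warn_eegr(paste0("stimuli with zero surviving epochs (excluded from CV): ",
                     paste(zero_stim, collapse = ", ")))
  list(epochs = epochs,
       report = list(bad_channels = bad_ch,
                     channel_scores = scores,
                     rejected_epoch_indices = rej$rejected,
                     removed_components = removed_comps,
                     epoch_repairs = rep_res$repairs,
                     epochs_dropped_in_repair = rep_res$dropped,
                     excluded_stimuli = zero_stim,
                     thresholds = list(z = config$z_threshold,
                                       band_hz = c(config$low_hz,
                                                   config$high_hz),
                                       target_hz = config$target_hz)))
}
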