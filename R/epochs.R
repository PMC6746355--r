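#' Construct an epoched EEG container
#'
#' @param data Numeric array, epochs x channels x timepoints (microvolts).
#' @param srate Sampling rate in Hz.
#' @param stimulus_ids Character vector, one stimulus label per epoch.
#' @param window_ms Length-2 numeric, epoch window relative to stimulus onset
#'   in ms, half-open `[start, end)`.
#' @param channel_names,layout As in [eeg_recording()].
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, srate, stimulus_ids, window_ms = c(0, 1000),
                       channel_names = NULL, layout = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[1] != length(stimulus_ids))
    stop_eegr("one stimulus_id per epoch is required")
  if (is.null(channel_names))
    channel_names <- sprintf("CH%03d", seq_len(dim(data)[2]))
  structure(list(data = data, srate = srate,
                 stimulus_ids = as.character(stimulus_ids),
                 window_ms = window_ms, channel_names = channel_names,
                 layout = layout),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_epochs> %d epochs x %d channels x %d timepoints @ %g Hz (%d stimuli)\n",
    d[1], d[2], d[3], x$srate, length(unique(x$stimulus_ids))))
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

# Subset epochs by index, keeping metadata aligned.
subset_epochs <- function(epochs, idx) {
  eeg_epochs(epochs$data[idx, , , drop = FALSE], epochs$srate,
             epochs$stimulus_ids[idx], epochs$window_ms,
             epochs$channel_names, epochs$layout)
}

# Flatten to an nE x (nC * nT) matrix; feature index f corresponds to
# (channel, time) = ((f - 1) %/% nT + 1, (f - 1) %% nT + 1) — channel-major,
# so masks stay interpretable as (channel, time) pairs.
flatten_epochs <- function(epochs) {
  d <- dim(epochs$data)
  out <- matrix(NA_real_, d[1], d[2] * d[3])
  for (ch in seq_len(d[2]))
    out[, ((ch - 1) * d[3] + 1):(ch * d[3])] <- epochs$data[, ch, ]
  out
}

# Inverse of flatten_epochs.
unflatten_epochs <- function(mat, nC, nT) {
  nE <- nrow(mat)
  arr <- array(NA_real_, c(nE, nC, nT))
  for (ch in seq_len(nC))
    arr[, ch, ] <- mat[, ((ch - 1) * nT + 1):(ch * nT)]
  arr
}
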