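# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small complete synthetic study: 10 stimuli x 4 presentations, 16 channels
# at 250 Hz, high SNR; 4 fused components keep the leave-one-class-out
# mapping identifiable at this gallery size.
fix_study <- function() memo("study", function() {
  synth_study(synth_spec(nS = 10, nP = 4, nC = 16, srate = 250, snr = 10),
              codebook_k = 20, pca_components = 4)
})

fix_preprocessed <- function() memo("preprocessed", function() {
  preprocess(fix_study()$recording)
})

# Epochs carrying an exact linear image-feature signal, bypassing the
# recording stage: for direct decoder checks.
fix_linear_epochs <- function(nS = 10, nP = 4, nC = 16, nT = 120, p = 8,
                              noise_sd = 0.1, seed = 7) {
  set.seed(seed)
  feats <- matrix(rnorm(nS * p), nS, p)
  ids_all <- sprintf("s%02d", seq_len(nS))
  fused <- structure(list(matrix = feats, stimulus_ids = ids_all,
                          blocks = "sem", explained_variance = 1,
                          loadings = diag(p), center = rep(0, p),
                          sdev = rep(1, p)),
                     class = "fused_features")
  W <- matrix(rnorm(nC * nT * p), nC * nT, p)
  ids <- rep(ids_all, each = nP)
  arr <- array(0, c(nS * nP, nC, nT))
  for (e in seq_along(ids)) {
    s <- match(ids[e], ids_all)
    arr[e, , ] <- matrix(W %*% feats[s, ], nC, nT) +
      noise_sd * matrix(rnorm(nC * nT), nC, nT)
  }
  list(epochs = eeg_epochs(arr, 120, ids), fused = fused)
}

# A tiny flat recording with known events, for epoching arithmetic.
fix_flat_recording <- function(nC = 4, srate = 200, value = 0,
                               n_events = 3) {
  ns <- srate * (2 + 2 * n_events)
  onsets <- as.integer(srate * (1 + 2 * seq_len(n_events) - 2) + srate)
  eeg_recording(matrix(value, nC, ns), srate,
                layout = synth_layout_test(nC),
                events = tibble::tibble(
                  sample = onsets,
                  stimulus_id = sprintf("s%d", seq_len(n_events))))
}

# Unit-sphere layout helper mirroring the generator's convention.
synth_layout_test <- function(nC) {
  i <- seq_len(nC) - 0.5
  z <- i / nC
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(1 - z^2)
  pos <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  pos[order(-pos[, "y"]), , drop = FALSE]
}

expect_no_na <- function(x) expect_false(anyNA(x))
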