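# Symmetric FastICA (logcosh contrast) on epoched EEG. Epochs are
# concatenated along time into a channels x samples matrix, channel means
# removed, PCA-whitened to n_comp dimensions, and unmixed with a fixed-seed
# random orthonormal start. Reconstruction from all components recovers the
# input to numerical tolerance.

#' Decompose epoched EEG into independent components
#'
#' @param epochs An [eeg_epochs()].
#' @param n_comp Number of components; defaults to the channel count (reduce
#'   by the number of previously interpolated channels, which lower the rank).
#' @param seed RNG seed for the orthonormal initialisation.
#' @param maxit,tol FastICA iteration controls.
#' @return An `ica_decomposition`: mixing (nC x nIC), sources (nIC x
#'   samples), unmixing (nIC x nC), channel means, and epoch geometry.
#' @export
fastica_epochs <- function(epochs, n_comp = NULL, seed = 1L, maxit = 200,
                           tol = 1e-6) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  X <- matrix(aperm(epochs$data, c(2, 3, 1)), nrow = d[2])  # nC x (nT*nE)
  if (is.null(n_comp)) n_comp <- d[2]
  n_comp <- min(n_comp, d[2])
  mu <- rowMeans(X)
  Xc <- X - mu
  n <- ncol(Xc)
  cv <- tcrossprod(Xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(n_comp)
  dvals <- pmax(eg$values[keep], 1e-12)
  K <- diag(1 / sqrt(dvals), n_comp) %*% t(eg$vectors[, keep, drop = FALSE])
  Z <- K %*% Xc                                     # whitened, nIC x n
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  W <- qr.Q(qr(matrix(stats::rnorm(n_comp^2), n_comp)))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())
  sym_decor <- function(W) {
    s <- eigen(tcrossprod(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(pmax(s$values, 1e-12)), n_comp) %*%
      t(s$vectors) %*% W
  }
  W <- sym_decor(W)
  for (it in seq_len(maxit)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Gp <- 1 - G^2
    W_new <- (G %*% t(Z)) / n - diag(rowMeans(Gp), n_comp) %*% W
    W_new <- sym_decor(W_new)
    delta <- max(abs(abs(rowSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tol) break
  }
  unmixing <- W %*% K                               # nIC x nC
  mixing <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(dvals), n_comp) %*% t(W)              # nC x nIC
  structure(list(mixing = mixing, sources = W %*% Z, unmixing = unmixing,
                 channel_means = mu, n_epochs = d[1], n_times = d[3],
                 srate = epochs$srate, stimulus_ids = epochs$stimulus_ids,
                 window_ms = epochs$window_ms,
                 channel_names = epochs$channel_names,
                 layout = epochs$layout),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d components over %d channels, %d samples\n",
              nrow(x$sources), nrow(x$mixing), ncol(x$sources)))
  invisible(x)
}

# Anterior-most channel by layout (largest posterior-anterior coordinate),
# ties broken by channel index: the stand-in for a dedicated EOG sensor.
eog_proxy_channel <- function(epochs) {
  layout <- require_layout(epochs, "eog_proxy_channel()")
  which.max(layout[, 2])
}

#' Flag artefactual ICA components
#'
#' Scores each component on (i) absolute correlation of its source with the
#' ocular proxy channel (the most anterior sensor), (ii) spatial kurtosis of
#' its mixing column, (iii) Hurst exponent of its source, and (iv) mean
#' absolute gradient of its source; components outside `|z| > 3` on any
#' score are returned for removal.
#'
#' @param ica An `ica_decomposition`.
#' @param eog_proxy_channel Channel index of the ocular proxy.
#' @param z_threshold z cutoff, default 3.
#' @return Integer vector of flagged component indices.
#' @export
flag_components <- function(ica, eog_proxy_channel, z_threshold = 3) {
  stopifnot(inherits(ica, "ica_decomposition"))
  n_ic <- nrow(ica$sources)
  if (n_ic < 4) {
    warn_eegr("fewer than 4 components: artefact flagging skipped")
    return(integer(0))
  }
  proxy <- ica$mixing %*% ica$sources + ica$channel_means
  proxy <- proxy[eog_proxy_channel, ]
  n_hurst <- min(ncol(ica$sources), 65536L)
  sc_cor <- abs(suppressWarnings(
    as.numeric(stats::cor(t(ica$sources), proxy))))
  sc_cor[!is.finite(sc_cor)] <- 0
  sc_kurt <- apply(ica$mixing, 2, moment_kurtosis)
  sc_hurst <- apply(ica$sources[, seq_len(n_hurst), drop = FALSE], 1,
                    hurst_rs)
  sc_hurst[!is.finite(sc_hurst)] <- 0.5
  sc_grad <- apply(ica$sources, 1, function(s) mean(abs(diff(s))))
  sort(unique(c(flag_outliers(sc_cor, z_threshold),
                flag_outliers(sc_kurt, z_threshold),
                flag_outliers(sc_hurst, z_threshold),
                flag_outliers(sc_grad, z_threshold))))
}

#' Reconstruct epochs without the flagged components
#'
#' @param ica An `ica_decomposition`.
#' @param flagged Component indices to drop (may be empty).
#' @return An [eeg_epochs()] rebuilt from the remaining components.
#' @export
reconstruct_without <- function(ica, flagged = integer(0)) {
  stopifnot(inherits(ica, "ica_decomposition"))
  n_ic <- nrow(ica$sources)
  flagged <- as.integer(flagged)
  if (length(setdiff(seq_len(n_ic), flagged)) == 0)
    stop_eegr("cannot remove every component")
  keep <- setdiff(seq_len(n_ic), flagged)
  X <- ica$mixing[, keep, drop = FALSE] %*%
    ica$sources[keep, , drop = FALSE] + ica$channel_means
  arr <- aperm(array(X, c(nrow(X), ica$n_times, ica$n_epochs)), c(3, 1, 2))
  eeg_epochs(arr, ica$srate, ica$stimulus_ids, ica$window_ms,
             ica$channel_names, ica$layout)
}
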