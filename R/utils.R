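#' @importFrom stats cor sd var median fft kmeans prcomp rnorm runif quantile mvfft
#' @importFrom rlang abort warn .data
#' @keywords internal
"_PACKAGE"

# Stops with a classed condition so the CLI can map errors to categories.
stop_eegr <- function(msg, class = "eegretrieve_error", ...) {
  rlang::abort(msg, class = class, ...)
}

warn_eegr <- function(msg, class = "eegretrieve_warning") {
  rlang::warn(msg, class = class)
}

#' Flag outliers of a score vector by z-score
#'
#' Shared statistical-thresholding rule used for bad channels, bad epochs,
#' artefactual ICA components and within-epoch channel repair: an entry is
#' flagged when it lies at least `z_threshold` standard deviations from the
#' mean of the scores (two-sided, population SD). The population SD with an
#' inclusive cutoff is deliberate: among n scores the largest attainable
#' |z| is sqrt(n - 1), so a strict rule on the sample SD (max (n-1)/sqrt(n))
#' could never fire at the default threshold in small sets. A zero-spread
#' score vector flags nothing.
#'
#' @param scores Numeric vector of per-item metric values.
#' @param z_threshold Positive z cutoff; default 3.
#' @return Integer vector of flagged indices (1-based), possibly empty.
#' @examples
#' flag_outliers(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 100))
#' @export
flag_outliers <- function(scores, z_threshold = 3) {
  stopifnot(is.numeric(scores))
  ok <- is.finite(scores)
  if (sum(ok) < 2) stop_eegr("flag_outliers() needs at least 2 finite scores")
  m <- mean(scores[ok])
  s <- sqrt(mean((scores[ok] - m)^2))
  if (!is.finite(s) || s == 0) return(integer(0))
  which(ok & abs(scores - m) / s >= z_threshold * (1 - 1e-12))
}

# Rescaled-range (R/S) Hurst exponent over dyadic block sizes; the slope of
# the log-log fit of mean R/S against block length. ~0.5 for white noise.
hurst_rs <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 32 || stats::sd(x) == 0) return(NA_real_)
  sizes <- 2^(3:floor(log2(n / 2)))
  sizes <- sizes[sizes >= 8]
  rs <- vapply(sizes, function(m) {
    nblk <- n %/% m
    vals <- vapply(seq_len(nblk), function(b) {
      seg <- x[((b - 1) * m + 1):(b * m)]
      dev <- cumsum(seg - mean(seg))
      r <- max(dev) - min(dev)
      s <- stats::sd(seg)
      if (s == 0) NA_real_ else r / s
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  keep <- is.finite(rs) & rs > 0
  if (sum(keep) < 2) return(NA_real_)
  unname(stats::coef(stats::lm(log(rs[keep]) ~ log(sizes[keep])))[2])
}

# Excess-kurtosis-free moment kurtosis (m4 / m2^2); used for spatial kurtosis
# of ICA mixing columns.
moment_kurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(0)
  mean(x^4) / m2^2
}

# Bilinear resize of a 2-D matrix or H x W x 3 array to (h, w).
resize_bilinear <- function(img, h, w) {
  one <- function(m) {
    hi <- nrow(m); wi <- ncol(m)
    ys <- if (hi == 1) rep(1, h) else seq(1, hi, length.out = h)
    xs <- if (wi == 1) rep(1, w) else seq(1, wi, length.out = w)
    y0 <- pmin(floor(ys), hi - 1); x0 <- pmin(floor(xs), wi - 1)
    fy <- ys - y0; fx <- xs - x0
    a <- m[y0, x0, drop = FALSE]; b <- m[y0 + 1, x0, drop = FALSE]
    c2 <- m[y0, x0 + 1, drop = FALSE]; d <- m[y0 + 1, x0 + 1, drop = FALSE]
    (1 - fy) * ((1 - fx)[col(a)] * a + fx[col(a)] * c2) +
      fy * ((1 - fx)[col(a)] * b + fx[col(a)] * d)
  }
  if (length(dim(img)) == 2) return(one(img))
  out <- array(0, c(h, w, dim(img)[3]))
  for (k in seq_len(dim(img)[3])) out[, , k] <- one(img[, , k])
  out
}

# ITU-R BT.601 luma conversion; accepts H x W (passthrough) or H x W x 3.
to_grayscale <- function(img) {
  if (length(dim(img)) == 2) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# 2-D linear convolution via FFT, 'same' output, zero padding.
conv2_same <- function(img, kern) {
  hi <- nrow(img); wi <- ncol(img)
  hk <- nrow(kern); wk <- ncol(kern)
  hp <- hi + hk - 1L; wp <- wi + wk - 1L
  pi_ <- matrix(0, hp, wp); pi_[1:hi, 1:wi] <- img
  pk <- matrix(0, hp, wp); pk[1:hk, 1:wk] <- kern
  full <- Re(stats::fft(stats::fft(pi_) * stats::fft(pk), inverse = TRUE)) / (hp * wp)
  r0 <- (hk - 1L) %/% 2L; c0 <- (wk - 1L) %/% 2L
  full[(r0 + 1L):(r0 + hi), (c0 + 1L):(c0 + wi)]
}
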