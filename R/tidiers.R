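#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a decoding result into per-trial ranks
#'
#' @param x A `decoding_result` from [zero_shot_cv()].
#' @param ... Unused.
#' @return Tibble with trial, stimulus_id, rank.
#' @export
tidy.decoding_result <- function(x, ...) x$ranks

#' One-row summary of a decoding result
#'
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return Tibble: cmc_auc, n_trials, n_stimuli, alpha, k, keep_fraction,
#'   mean_rank.
#' @export
glance.decoding_result <- function(x, ...) {
  tibble::tibble(cmc_auc = x$auc, n_trials = nrow(x$ranks),
                 n_stimuli = x$nS, alpha = x$config$alpha, k = x$config$k,
                 keep_fraction = x$config$keep_fraction,
                 mean_rank = mean(x$ranks$rank))
}

#' Tidy a ridge model into long coefficient form
#'
#' @param x A `ridge_model`.
#' @param ... Unused.
#' @return Tibble: eeg_feature, image_feature, estimate.
#' @export
tidy.ridge_model <- function(x, ...) {
  tibble::tibble(
    eeg_feature = rep(seq_len(nrow(x$weights)), times = ncol(x$weights)),
    image_feature = rep(seq_len(ncol(x$weights)), each = nrow(x$weights)),
    estimate = as.vector(x$weights))
}

#' @rdname tidy.ridge_model
#' @export
glance.ridge_model <- function(x, ...) {
  tibble::tibble(n_eeg_features = nrow(x$weights),
                 n_image_features = ncol(x$weights), alpha = x$alpha)
}

#' Plot the cumulative match curve of a decoding result
#'
#' @param object A `decoding_result`.
#' @param ... Unused.
#' @return A ggplot: CMC with the chance diagonal and the AUC annotated.
#' @export
autoplot.decoding_result <- function(object, ...) {
  df <- object$cmc
  ggplot2::ggplot(df, ggplot2::aes(x = .data$top_x, y = .data$fraction)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(intercept = 0, slope = 1 / object$nS,
                         linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = "top X ranked gallery images",
      y = "fraction of trials containing the target",
      title = sprintf("Cumulative match curve (AUC %.1f%%)", object$auc)) +
    ggplot2::coord_cartesian(ylim = c(0, 1))
}

#' Plot the temporal profile of EEG feature stability
#'
#' @param scores Tibble from [stability_scores()].
#' @param srate Sampling rate for the time axis (default 120).
#' @return A ggplot of mean stability across channels against epoch time.
#' @export
plot_stability_profile <- function(scores, srate = 120) {
  topo <- stability_topography(scores, srate)
  ggplot2::ggplot(topo$by_time,
                  ggplot2::aes(x = .data$time_ms, y = .data$mean_score)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time after stimulus onset (ms)",
                  y = "mean stability across channels")
}
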