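#' Ridge regression EEG-to-feature mapping
#'
#' Solves the L2-penalised least-squares problem column-by-column with an
#' unpenalised intercept: X and Y are centred, `W = (X'X + aI)^-1 X'Y`, and
#' the intercept absorbs the means. With `alpha = 0` and rank-deficient X a
#' pseudo-inverse solution is returned with a warning.
#'
#' @param X nE x nFeat training matrix (z-scored EEG features).
#' @param Y nE x p target matrix (fused image-feature columns).
#' @param alpha Non-negative ridge penalty.
#' @return A `ridge_model` with `weights` (nFeat x p), `intercept` (length
#'   p) and `alpha`.
#' @export
fit_ridge <- function(X, Y, alpha) {
  stopifnot(is.matrix(X), is.matrix(Y), nrow(X) == nrow(Y), alpha >= 0)
  xbar <- colMeans(X); ybar <- colMeans(Y)
  Xc <- sweep(X, 2, xbar); Yc <- sweep(Y, 2, ybar)
  G <- crossprod(Xc)
  if (alpha == 0) {
    W <- tryCatch(solve(G, crossprod(Xc, Yc)), error = function(e) {
      warn_eegr("alpha = 0 with rank-deficient X: using the pseudo-inverse")
      sv <- svd(Xc)
      pos <- sv$d > max(sv$d) * 1e-10
      sv$v[, pos, drop = FALSE] %*%
        (t(sv$u[, pos, drop = FALSE]) %*% Yc / sv$d[pos])
    })
  } else {
    W <- solve(G + diag(alpha, ncol(X)), crossprod(Xc, Yc))
  }
  structure(list(weights = W, intercept = ybar - drop(xbar %*% W),
                 alpha = alpha),
            class = "ridge_model")
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf("<ridge_model> %d EEG features -> %d image features (alpha = %g)\n",
              nrow(x$weights), ncol(x$weights), x$alpha))
  invisible(x)
}

#' Predict image-feature vectors from EEG epochs
#'
#' @param object A [fit_ridge()] model.
#' @param newdata nE x nFeat matrix.
#' @param ... Unused.
#' @return nE x p matrix of predicted feature vectors.
#' @export
predict.ridge_model <- function(object, newdata, ...) {
  sweep(newdata %*% object$weights, 2, object$intercept, "+")
}

#' Coefficient of determination per target column
#'
#' `R2 = 1 - SS_res / SS_tot` computed independently per column; columns
#' whose true values are constant get 0 by convention.
#'
#' @param Y_true,Y_pred Matrices of equal shape.
#' @return Numeric vector, one R2 per column.
#' @export
r2_per_column <- function(Y_true, Y_pred) {
  stopifnot(all(dim(Y_true) == dim(Y_pred)))
  ss_res <- colSums((Y_true - Y_pred)^2)
  ss_tot <- colSums(sweep(Y_true, 2, colMeans(Y_true))^2)
  ifelse(ss_tot > 0, 1 - ss_res / ss_tot, 0)
}

#' Image-feature mask from averaged R2
#'
#' Keeps the `ceiling(keep_fraction * p)` feature-space columns with the
#' highest cross-fold average R2 (ties to the lower column index): columns
#' the EEG mapping cannot predict are excluded from distance ranking.
#'
#' @param mean_r2 Numeric vector of per-column averaged R2.
#' @param keep_fraction Fraction of columns to keep, in (0, 1].
#' @return Logical mask over columns.
#' @export
feature_mask_from_r2 <- function(mean_r2, keep_fraction) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  p <- length(mean_r2)
  n_keep <- ceiling(keep_fraction * p)
  ord <- order(-mean_r2, seq_len(p))
  mask <- rep(FALSE, p)
  mask[ord[seq_len(n_keep)]] <- TRUE
  mask
}

#' Rank of the target image in a gallery
#'
#' All gallery rows are ordered by Euclidean distance from the predicted
#' feature vector; the returned rank is the position of the target row.
#' Distance ties are broken deterministically by gallery index, so
#' `rank = 1 + #\{closer rows\} + #\{tied rows with lower index\}`.
#'
#' @param pred_vector Predicted feature vector (already masked).
#' @param gallery_matrix nS x p gallery (same mask applied).
#' @param target_index Row index of the true stimulus (1-based).
#' @param mask Optional logical column mask applied to both sides.
#' @return Integer rank in `1..nS`.
#' @export
rank_target <- function(pred_vector, gallery_matrix, target_index,
                        mask = NULL) {
  if (!is.null(mask)) {
    pred_vector <- pred_vector[mask]
    gallery_matrix <- gallery_matrix[, mask, drop = FALSE]
  }
  nS <- nrow(gallery_matrix)
  if (target_index < 1 || target_index > nS)
    stop_eegr("target not in the gallery")
  d2 <- rowSums(sweep(gallery_matrix, 2, pred_vector)^2)
  dt <- d2[target_index]
  1L + sum(d2 < dt) + sum(d2[seq_len(target_index - 1)] == dt)
}

#' Cumulative match characteristic curve
#'
#' `curve[x]` is the fraction of trials whose target fell within the top x
#' ranked gallery images; non-decreasing with `curve[nS] = 1`.
#'
#' @param ranks Integer vector of per-trial ranks in `1..nS`.
#' @param nS Gallery size.
#' @return Tibble with columns `top_x` and `fraction`.
#' @export
cmc_curve <- function(ranks, nS) {
  stopifnot(all(ranks >= 1), all(ranks <= nS))
  counts <- tabulate(ranks, nbins = nS)
  tibble::tibble(top_x = seq_len(nS),
                 fraction = cumsum(counts) / length(ranks))
}

#' CMC area under curve, in percent
#'
#' The normalised area below the cumulative match curve, equal to the mean
#' over trials of `(nS - rank + 0.5) / nS`, times 100. Chance level (ranks
#' uniform on 1..nS) is exactly 50%; a single trial ranked 2nd among 7
#' gives 78.57%.
#'
#' @inheritParams cmc_curve
#' @return AUC in `[0, 100]`.
#' @export
cmc_auc <- function(ranks, nS) {
  stopifnot(all(ranks >= 1), all(ranks <= nS))
  100 * mean((nS - ranks + 0.5) / nS)
}

#' Default decoding configuration
#'
#' @param ... Overrides. Tunables: `alpha` (ridge penalty, default 10), `k`
#'   (EEG features retained, default 500), `keep_fraction` (image-feature
#'   columns kept after R2 masking, default 0.5),
#'   `stability_on_zscored` (score stability on z-scored training epochs,
#'   default TRUE).
#' @return Named list.
#' @export
decode_config <- function(...) {
  cfg <- list(alpha = 10, k = 500, keep_fraction = 0.5,
              stability_on_zscored = TRUE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_eegr(paste0("unknown decoding option(s): ",
                     paste(unknown, collapse = ", ")),
              class = "eegretrieve_config_error")
  cfg[names(over)] <- over
  cfg
}

#' Zero-shot leave-one-class-out decoding
#'
#' For each stimulus in turn, all of its epochs are withheld; a z-scaler,
#' stability-based EEG feature selection and a ridge map are fitted on the
#' remaining epochs only, and the withheld epochs' image features are
#' predicted. Per-column training R2 is averaged across folds into a single
#' image-feature mask; every test prediction is then ranked against the
#' full gallery by Euclidean distance in the masked space, and the rank
#' distribution is summarised as a CMC curve and its AUC.
#'
#' @param epochs Preprocessed [eeg_epochs()].
#' @param fused A [fuse_features()] space covering every stimulus present.
#' @param config A [decode_config()] list.
#' @return A `decoding_result`: `auc` (%), `ranks` tibble (trial,
#'   stimulus_id, rank), `cmc` curve tibble, `mean_r2`, `image_mask`,
#'   per-fold EEG masks summary, `nS`, and the config snapshot.
#' @export
zero_shot_cv <- function(epochs, fused, config = decode_config()) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(fused, "fused_features"))
  ids <- epochs$stimulus_ids
  stims <- fused$stimulus_ids
  missing_gal <- setdiff(unique(ids), stims)
  if (length(missing_gal))
    stop_eegr(paste0("gallery does not cover stimuli: ",
                     paste(missing_gal, collapse = ", ")))
  present <- intersect(stims, unique(ids))
  absent <- setdiff(stims, present)
  if (length(absent))
    warn_eegr(paste0("stimuli with zero epochs excluded from folds: ",
                     paste(absent, collapse = ", ")))
  flat <- flatten_epochs(epochs)
  gallery <- fused$matrix
  Y_all <- gallery[match(ids, stims), , drop = FALSE]
  p <- ncol(gallery)
  r2_sum <- numeric(p)
  preds <- vector("list", length(present))
  test_rows <- vector("list", length(present))
  k <- min(config$k, ncol(flat))
  n_eeg_selected <- integer(length(present))
  for (f in seq_along(present)) {
    test_idx <- which(ids == present[f])
    train_idx <- setdiff(seq_len(nrow(flat)), test_idx)
    scaler <- fit_scaler(flat[train_idx, , drop = FALSE])
    Ztr <- apply_scaler(scaler, flat[train_idx, , drop = FALSE])
    Zte <- apply_scaler(scaler, flat[test_idx, , drop = FALSE])
    train_ep <- subset_epochs(epochs, train_idx)
    tens <- build_trial_tensor(train_ep,
      flat = if (config$stability_on_zscored) Ztr else
        flat[train_idx, , drop = FALSE])
    scores <- stability_scores(tens)
    kk <- min(k, sum(!is.na(scores$score)))
    mask_eeg <- select_features(scores, kk)
    n_eeg_selected[f] <- kk
    model <- fit_ridge(Ztr[, mask_eeg, drop = FALSE],
                       Y_all[train_idx, , drop = FALSE], config$alpha)
    r2_sum <- r2_sum + r2_per_column(
      Y_all[train_idx, , drop = FALSE],
      predict(model, Ztr[, mask_eeg, drop = FALSE]))
    preds[[f]] <- predict(model, Zte[, mask_eeg, drop = FALSE])
    test_rows[[f]] <- test_idx
  }
  mean_r2 <- r2_sum / length(present)
  image_mask <- feature_mask_from_r2(mean_r2, config$keep_fraction)
  ranks <- integer(0); trial <- integer(0); stim <- character(0)
  for (f in seq_along(present)) {
    tgt <- match(present[f], stims)
    for (r in seq_len(nrow(preds[[f]]))) {
      ranks <- c(ranks, rank_target(preds[[f]][r, ], gallery, tgt,
                                    mask = image_mask))
      trial <- c(trial, test_rows[[f]][r])
      stim <- c(stim, present[f])
    }
  }
  ord <- order(trial)
  nS <- nrow(gallery)
  structure(list(
    auc = cmc_auc(ranks, nS),
    ranks = tibble::tibble(trial = trial[ord], stimulus_id = stim[ord],
                           rank = ranks[ord]),
    cmc = cmc_curve(ranks, nS),
    mean_r2 = mean_r2,
    image_mask = image_mask,
    eeg_features_selected = n_eeg_selected,
    nS = nS,
    config = config),
    class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> CMC AUC %.2f%% over %d trials, gallery of %d\n",
              x$auc, nrow(x$ranks), x$nS))
  invisible(x)
}

#' Grid search over ridge penalty and EEG feature count
#'
#' Exhaustively evaluates [zero_shot_cv()] over `alphas` x
#' `eeg_feature_counts` on one recording's epochs, returning the argmax
#' (ties to the smaller k, then the smaller alpha) and the full score
#' table.
#'
#' @param epochs Preprocessed [eeg_epochs()] of the scoring recording.
#' @param fused A [fuse_features()] space.
#' @param alphas Ridge penalty grid (default the standard six-point grid
#'   1e-2..1e2).
#' @param eeg_feature_counts EEG feature-count grid (default the 16-point
#'   grid 25..3000).
#' @param config Base [decode_config()] (alpha/k overridden per cell).
#' @return List with `best` (tibble row: alpha, k, auc) and `table` (all
#'   cells).
#' @export
grid_search <- function(epochs, fused,
                        alphas = c(1e-2, 1e-1, 1e0, 1e1, 5e1, 1e2),
                        eeg_feature_counts = c(25, 50, 75, 100, 125, 150,
                                               175, 200, 250, 500, 750, 1000,
                                               1500, 2000, 2500, 3000),
                        config = decode_config()) {
  stopifnot(length(alphas) > 0, length(eeg_feature_counts) > 0)
  cells <- tidyr::expand_grid(alpha = alphas, k = eeg_feature_counts)
  aucs <- purrr::pmap_dbl(cells, function(alpha, k) {
    cfg <- config; cfg$alpha <- alpha; cfg$k <- k
    zero_shot_cv(epochs, fused, cfg)$auc
  })
  tab <- dplyr::mutate(cells, auc = aucs) |>
    dplyr::arrange(dplyr::desc(.data$auc), .data$k, .data$alpha)
  list(best = tab[1, ], table = tab)
}
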