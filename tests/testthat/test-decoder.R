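test_that("ridge recovers exact weights on a noiseless identifiable system", {
  set.seed(40)
  X <- matrix(rnorm(50 * 6), 50, 6)
  W <- matrix(rnorm(6 * 3), 6, 3)
  Y <- X %*% W
  m <- fit_ridge(X, Y, 1e-10)
  expect_equal(m$weights, W, tolerance = 1e-6)
  expect_equal(predict(m, X), Y, tolerance = 1e-6)
})

test_that("ridge weights equal the closed-form matrix-inverse oracle", {
  set.seed(41)
  X <- scale(matrix(rnorm(10 * 3), 10, 3), scale = FALSE)
  Y <- scale(matrix(rnorm(10 * 2), 10, 2), scale = FALSE)
  for (alpha in c(0.1, 1, 10)) {
    m <- fit_ridge(X, Y, alpha)
    want <- solve(t(X) %*% X + alpha * diag(3)) %*% t(X) %*% Y
    expect_equal(m$weights, want, tolerance = 1e-10)
  }
})

test_that("extreme regularisation shrinks predictions to the column means", {
  set.seed(42)
  X <- matrix(rnorm(30 * 4), 30, 4)
  Y <- matrix(rnorm(30 * 2), 30, 2)
  m <- fit_ridge(X, Y, 1e12)
  expect_lt(max(abs(m$weights)), 1e-6)
  expect_equal(predict(m, X),
               matrix(colMeans(Y), 30, 2, byrow = TRUE), tolerance = 1e-4)
})

test_that("alpha zero on rank-deficient X falls back to a pseudo-inverse with a warning", {
  set.seed(43)
  X <- matrix(rnorm(10 * 2), 10, 2)
  X <- cbind(X, X[, 1] + X[, 2])
  Y <- matrix(rnorm(10), 10, 1)
  expect_warning(m <- fit_ridge(X, Y, 0), "pseudo-inverse")
  expect_true(all(is.finite(m$weights)))
})

test_that("per-column R2 matches its definition on worked cases", {
  Y <- cbind(c(1, 2, 3, 4, 5), c(2, 2, 2, 2, 2))
  expect_equal(r2_per_column(Y, Y), c(1, 0))  # constant column -> 0
  pred_mean <- matrix(colMeans(Y), 5, 2, byrow = TRUE)
  expect_equal(r2_per_column(Y, pred_mean), c(0, 0))
  # hand-computed: SS_res = 0.3, SS_tot = 10
  pred <- cbind(c(1.1, 1.9, 3.3, 3.8, 5.1), rep(2, 5))
  ss_res <- sum((Y[, 1] - pred[, 1])^2)
  expect_equal(r2_per_column(Y, pred)[1], 1 - ss_res / 10, tolerance = 1e-12)
})

test_that("R2 masking keeps the best columns with ties to lower index, nested in keep_fraction", {
  expect_equal(feature_mask_from_r2(c(0.2, 0.8), 1), c(TRUE, TRUE))
  expect_equal(which(feature_mask_from_r2(c(0.9, 0.1, 0.5), 2 / 3)),
               c(1L, 3L))
  expect_equal(which(feature_mask_from_r2(c(0.5, 0.5, 0.1), 1 / 3)), 1L)
  set.seed(44)
  r2 <- round(runif(20), 1)
  fr <- c(0.1, 0.3, 0.5, 0.8, 1)
  for (i in seq_len(length(fr) - 1))
    expect_true(all(which(feature_mask_from_r2(r2, fr[i])) %in%
                      which(feature_mask_from_r2(r2, fr[i + 1]))))
})

test_that("gallery ranking matches an exhaustive sort oracle and the tie rule", {
  set.seed(45)
  gal <- matrix(rnorm(7 * 5), 7, 5)
  expect_equal(rank_target(gal[3, ], gal, 3), 1L)
  for (i in 1:20) {
    pred <- rnorm(5); tgt <- sample(7, 1)
    d <- sqrt(rowSums(sweep(gal, 2, pred)^2))
    expect_equal(rank_target(pred, gal, tgt),
                 as.integer(rank(d, ties.method = "first")[tgt]))
  }
  # equidistant gallery: rank equals the target's own index
  gal_eq <- matrix(0, 4, 3); gal_eq[, 1] <- c(1, -1, 1, -1)
  pred <- c(0, 0, 0)
  for (tgt in 1:4) expect_equal(rank_target(pred, gal_eq, tgt), tgt)
  expect_error(rank_target(pred, gal_eq, 9), "not in the gallery")
})

test_that("the CMC curve cumulates rank counts correctly", {
  expect_equal(cmc_curve(rep(1, 5), 3)$fraction, rep(1, 3))
  expect_equal(cmc_curve(2, 7)$fraction, c(0, rep(1, 6)))
  set.seed(46)
  ranks <- sample(10, 100, replace = TRUE)
  crv <- cmc_curve(ranks, 10)
  oracle <- vapply(1:10, function(x) mean(ranks <= x), numeric(1))
  expect_equal(crv$fraction, oracle)
  expect_true(all(diff(crv$fraction) >= 0))
  expect_equal(crv$fraction[10], 1)
})

test_that("CMC AUC hits its closed-form values", {
  expect_equal(cmc_auc(2, 7), 100 * (7 - 2 + 0.5) / 7, tolerance = 1e-12)
  expect_equal(round(cmc_auc(2, 7), 2), 78.57)
  expect_equal(cmc_auc(rep(1, 10), 7), 100 * 6.5 / 7, tolerance = 1e-12)
  expect_equal(cmc_auc(1:60, 60), 50)   # uniform ranks -> exactly chance
})

test_that("the trapezoid and closed-form AUC formulations agree", {
  trapezoid_auc <- function(ranks, nS) {
    crv <- c(0, cmc_curve(ranks, nS)$fraction)
    100 * sum((crv[-1] + crv[-length(crv)]) / 2) / nS
  }
  set.seed(47)
  for (i in 1:25) {
    nS <- sample(3:40, 1)
    ranks <- sample(nS, sample(1:50, 1), replace = TRUE)
    expect_equal(cmc_auc(ranks, nS), trapezoid_auc(ranks, nS),
                 tolerance = 1e-10)
  }
})

test_that("AUC strictly decreases when any single rank worsens", {
  set.seed(48)
  ranks <- sample(8, 20, replace = TRUE)
  ranks[3] <- 4
  worse <- ranks; worse[3] <- 5
  expect_lt(cmc_auc(worse, 8), cmc_auc(ranks, 8))
})

test_that("zero-shot CV withholds each stimulus once and recovers a linear system", {
  fx <- fix_linear_epochs()
  res <- zero_shot_cv(fx$epochs, fx$fused,
                      decode_config(k = 500, keep_fraction = 1))
  expect_equal(sort(unique(res$ranks$stimulus_id)),
               sort(fx$fused$stimulus_ids))
  expect_equal(nrow(res$ranks), 40)
  expect_equal(as.integer(table(res$ranks$stimulus_id)), rep(4L, 10))
  expect_gte(res$auc, 95)
  # determinism
  res2 <- zero_shot_cv(fx$epochs, fx$fused,
                       decode_config(k = 500, keep_fraction = 1))
  expect_equal(res$auc, res2$auc)
})

test_that("keep_fraction = 1 with k = nF equals the unmasked pipeline", {
  fx <- fix_linear_epochs(nS = 6, nP = 3, nC = 4, nT = 20, p = 4)
  nF <- 4 * 20
  res_full <- zero_shot_cv(fx$epochs, fx$fused,
                           decode_config(k = nF, keep_fraction = 1))
  expect_true(all(res_full$image_mask))
  expect_true(all(res_full$eeg_features_selected == nF))
})

test_that("test epochs never influence their own fold's fit", {
  # corrupting the withheld epochs must not change their predictions' rank
  fx <- fix_linear_epochs(nS = 6, nP = 3, nC = 6, nT = 30, p = 4,
                          noise_sd = 0.2)
  res_a <- zero_shot_cv(fx$epochs, fx$fused, decode_config(k = 100))
  # corrupt all epochs of one stimulus: every fold's training set changes
  # except that stimulus's own fold, whose training R2 must stay identical
  ep2 <- fx$epochs
  idx <- which(ep2$stimulus_ids == fx$fused$stimulus_ids[2])
  ep2$data[idx, , ] <- ep2$data[idx, , ] * 100
  res_b <- zero_shot_cv(ep2, fx$fused, decode_config(k = 100))
  # per-trial ranks for the corrupted stimulus come from a model fit without
  # it, on unchanged training data, applied to scaled inputs -> its fold's
  # scaler/stability/ridge are unchanged; verify via the fold-2 R2 path by
  # rebuilding that fold directly
  flat_a <- eegretrieve:::flatten_epochs(fx$epochs)
  flat_b <- eegretrieve:::flatten_epochs(ep2)
  train <- setdiff(seq_along(ep2$stimulus_ids), idx)
  expect_identical(flat_a[train, ], flat_b[train, ])
  sc_a <- fit_scaler(flat_a[train, ])
  sc_b <- fit_scaler(flat_b[train, ])
  expect_identical(sc_a$mean, sc_b$mean)
})

test_that("decoding result tidiers expose ranks and a one-row summary", {
  fx <- fix_linear_epochs(nS = 5, nP = 2, nC = 4, nT = 20, p = 3)
  res <- zero_shot_cv(fx$epochs, fx$fused, decode_config(k = 50))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("trial", "stimulus_id", "rank"))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$cmc_auc, res$auc)
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})

test_that("grid search returns the argmax with deterministic tie-breaking", {
  fx <- fix_linear_epochs(nS = 6, nP = 3, nC = 6, nT = 30, p = 4)
  gs1 <- grid_search(fx$epochs, fx$fused, alphas = 10,
                     eeg_feature_counts = 100)
  expect_equal(nrow(gs1$table), 1)
  expect_equal(gs1$best$k, 100)
  gs2 <- grid_search(fx$epochs, fx$fused, alphas = c(1, 10),
                     eeg_feature_counts = c(50, 100))
  expect_equal(nrow(gs2$table), 4)
})

test_that("grid search finds the feature count carrying the signal", {
  # signal lives in exactly the 25 most stable features; the rest is noise
  set.seed(49)
  nS <- 8; nP <- 4; p <- 4; nC <- 5; nT <- 20; nF <- nC * nT
  feats <- matrix(rnorm(nS * p), nS, p)
  ids_all <- sprintf("s%d", 1:nS)
  fused <- structure(list(matrix = feats, stimulus_ids = ids_all,
                          blocks = "sem", explained_variance = 1,
                          loadings = diag(p), center = rep(0, p),
                          sdev = rep(1, p)), class = "fused_features")
  W <- matrix(rnorm(25 * p), 25, p)
  ids <- rep(ids_all, each = nP)
  flat <- matrix(rnorm(nS * nP * nF, sd = 3), nS * nP, nF)
  for (e in seq_along(ids))
    flat[e, 1:25] <- W %*% feats[match(ids[e], ids_all), ] +
      0.05 * rnorm(25)
  ep <- eeg_epochs(eegretrieve:::unflatten_epochs(flat, nC, nT), 120, ids)
  gs <- grid_search(ep, fused, alphas = 10, eeg_feature_counts = c(25, 100))
  expect_equal(gs$best$k, 25)
})
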