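# Direct nested-loop 'same' linear convolution (zero padding), independent
# of the FFT path.
conv2_loop <- function(img, kern) {
  hi <- nrow(img); wi <- ncol(img); hk <- nrow(kern); wk <- ncol(kern)
  r0 <- (hk - 1) %/% 2; c0 <- (wk - 1) %/% 2
  out <- matrix(0, hi, wi)
  for (i in seq_len(hi)) for (j in seq_len(wi)) {
    acc <- 0
    for (u in seq_len(hk)) for (v in seq_len(wk)) {
      ii <- i + r0 - (u - 1); jj <- j + c0 - (v - 1)
      if (ii >= 1 && ii <= hi && jj >= 1 && jj <= wi)
        acc <- acc + img[ii, jj] * kern[u, v]
    }
    out[i, j] <- acc
  }
  out
}

test_that("the default Gabor bank has 32 filters matching the kernel formula", {
  bank <- build_gabor_bank()
  expect_length(bank$kernels, 32)
  expect_equal(nrow(bank$params), 32)
  expect_equal(sort(unique(bank$params$sigma)), c(2, 3, 4, 5))
  expect_length(unique(bank$params$theta), 8)
  # kernel entries equal the scalar Gabor formula at their coordinates
  k7 <- bank$kernels[[7]]; p7 <- bank$params[7, ]
  half <- (p7$ksize - 1) / 2
  for (pt in list(c(0, 0), c(3, -5), c(-10, 7))) {
    val <- eegretrieve:::gabor_kernel_value(pt[1], pt[2], p7$lambda,
                                            p7$theta, p7$psi, p7$sigma,
                                            p7$gamma)
    expect_equal(k7$real[pt[2] + half + 1, pt[1] + half + 1], Re(val),
                 tolerance = 1e-12)
  }
  expect_error(build_gabor_bank(ksize = 30),
               class = "eegretrieve_config_error")
})

test_that("gamma=1 kernels at 0 and 90 degrees are transposes", {
  bank <- build_gabor_bank(n_orientations = 2, sigmas = 3, gamma = 1)
  expect_equal(bank$kernels[[2]]$real, t(bank$kernels[[1]]$real),
               tolerance = 1e-12)
})

test_that("gabor features match a brute-force convolution oracle on a small image", {
  set.seed(30)
  img <- matrix(runif(64), 8, 8)
  bank <- build_gabor_bank(n_orientations = 2, sigmas = c(1, 2), ksize = 5)
  got <- gabor_features(img, bank, resize_to = NULL, standardise = FALSE)
  expect_length(got, 4)
  want <- vapply(bank$kernels, function(k) sum(conv2_loop(img, k$real)),
                 numeric(1))
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("gabor features are linear in image intensity before standardisation", {
  set.seed(31)
  img <- matrix(runif(256), 16, 16)
  bank <- build_gabor_bank(n_orientations = 2, sigmas = 2, ksize = 7)
  f1 <- gabor_features(img, bank, resize_to = NULL, standardise = FALSE)
  f3 <- gabor_features(3 * img, bank, resize_to = NULL, standardise = FALSE)
  expect_equal(f3, 3 * f1, tolerance = 1e-8)
  zero <- gabor_features(matrix(0, 16, 16), bank, resize_to = NULL,
                         standardise = FALSE)
  expect_equal(zero, rep(0, 2), tolerance = 1e-12)
})

test_that("dense SIFT yields 128-dim grid descriptors with sane gradient content", {
  set.seed(32)
  img <- matrix(runif(64 * 64), 64, 64)
  d <- dense_sift(img, grid_step = 8, resize_to = NULL)
  expect_equal(ncol(d), 128)
  n_centers <- length(seq(9, 56, by = 8))
  expect_equal(nrow(d), n_centers^2)
  # uniform image: no gradients, all-zero descriptors
  du <- dense_sift(matrix(0.5, 64, 64), grid_step = 8, resize_to = NULL)
  expect_lt(max(sqrt(rowSums(du^2))), 1e-8)
  # image smaller than the support window
  expect_warning(dd <- dense_sift(matrix(0.5, 10, 10), resize_to = NULL),
                 "support")
  expect_equal(nrow(dd), 0)
})

test_that("rotating a grating by 90 degrees shifts the dominant orientation bins", {
  x <- matrix(rep(sin(2 * pi * (1:64) / 8), each = 64), 64, 64) # vertical bars
  bin_energy <- function(img) {
    d <- dense_sift(img, grid_step = 16, resize_to = NULL)
    sapply(1:8, function(b) sum(d[, seq(b, 128, by = 8)]))
  }
  e_v <- bin_energy(x)       # gradient along x: orientations 0 / pi
  e_h <- bin_energy(t(x))    # gradient along y: orientations pi/2, 3pi/2
  expect_setequal(order(e_v, decreasing = TRUE)[1:2] %% 8, c(1, 5) %% 8)
  expect_setequal(order(e_h, decreasing = TRUE)[1:2] %% 8, c(3, 7) %% 8)
})

test_that("codebook training is deterministic and recovers separated structure", {
  set.seed(33)
  pts <- matrix(rnorm(40 * 16), 40, 16)
  cb <- train_codebook(pts, k = 40, seed = 5)
  # one point per cluster: centroids are the points themselves
  d <- as.matrix(dist(rbind(cb$centroids, pts)))[1:40, 41:80]
  expect_lt(max(apply(d, 1, min)), 1e-8)
  # two well-separated blobs
  blob <- rbind(matrix(rnorm(200 * 4, mean = 0, sd = 0.05), 200, 4),
                matrix(rnorm(200 * 4, mean = 5, sd = 0.05), 200, 4))
  cb2 <- train_codebook(blob, k = 2, seed = 6)
  mns <- rbind(colMeans(blob[1:200, ]), colMeans(blob[201:400, ]))
  d2 <- as.matrix(dist(rbind(cb2$centroids, mns)))[1:2, 3:4]
  expect_lt(max(apply(d2, 1, min)), 0.1)
  cb3 <- train_codebook(pts, k = 40, seed = 5)
  expect_equal(cb2$centroids, train_codebook(blob, k = 2, seed = 6)$centroids)
  expect_equal(cb$centroids, cb3$centroids)
  expect_error(train_codebook(pts[rep(1, 50), ], k = 10), "distinct")
  expect_error(train_codebook(pts, k = 100), "smaller than k")
})

test_that("VBOW histograms match an exhaustive nearest-centroid oracle", {
  set.seed(34)
  cb <- structure(list(centroids = matrix(rnorm(20 * 8), 20, 8), k = 20L,
                       meta = list()), class = "vbow_codebook")
  descs <- matrix(rnorm(100 * 8), 100, 8)
  h <- vbow_histogram(descs, cb)
  expect_equal(sum(h), 100)
  oracle <- integer(20)
  for (i in 1:100) {
    dd <- apply(cb$centroids, 1, function(ctr) sum((descs[i, ] - ctr)^2))
    oracle[which.min(dd)] <- oracle[which.min(dd)] + 1L
  }
  expect_identical(h, oracle)
  # descriptors placed exactly on centroids
  h2 <- vbow_histogram(cb$centroids[c(3, 3, 7), ], cb)
  expect_equal(h2[3], 2); expect_equal(h2[7], 1); expect_equal(sum(h2), 3)
  # tie between duplicated centroids resolves to the lower index
  cb_tie <- structure(list(centroids = rbind(cb$centroids[1, ],
                                             cb$centroids[1, ]), k = 2L,
                           meta = list()), class = "vbow_codebook")
  expect_equal(vbow_histogram(cb$centroids[1, , drop = FALSE], cb_tie),
               c(1L, 0L))
  expect_equal(vbow_histogram(matrix(numeric(0), 0, 8), cb), integer(20))
})

test_that("HSV histograms quantise to 16 bins per channel and conserve pixels", {
  img <- array(0, c(10, 10, 3)); img[, , 1] <- 1  # pure red
  h <- hsv_histogram(img)
  expect_length(h, 48)
  expect_equal(h[1], 100)                 # hue 0 -> first hue bin
  expect_equal(h[16 + 16], 100)           # saturation 1 -> last sat bin
  expect_equal(h[32 + 16], 100)           # value 1 -> last value bin
  expect_equal(sum(h[1:16]), 100)
  expect_equal(sum(h[17:32]), 100)
  expect_equal(sum(h[33:48]), 100)
  # 2x2 image with hand-derived HSV bins
  px <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0.5, 0.5, 0.5))
  img2 <- array(0, c(2, 2, 3))
  for (k in 1:3) img2[, , k] <- matrix(px[, k], 2, 2, byrow = TRUE)
  h2 <- hsv_histogram(img2)
  # hue: 0 -> bin 1; 1/3 -> bin 6; 2/3 -> bin 11; gray hue 0 -> bin 1
  expect_equal(h2[1:16], c(2, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0))
  # saturation: three saturated pixels -> last bin; gray -> first bin
  expect_equal(h2[17], 1); expect_equal(h2[32], 3)
  # value: three at 1 -> last bin; gray at 0.5 -> bin 9
  expect_equal(h2[32 + 9], 1); expect_equal(h2[48], 3)
  expect_message(hg <- hsv_histogram(matrix(0.5, 4, 4)), "grayscale")
  expect_equal(sum(hg[17:32] > 0), 1)
})

test_that("HSV histogram is invariant to pixel order", {
  set.seed(35)
  img <- array(runif(6 * 6 * 3), c(6, 6, 3))
  h1 <- hsv_histogram(img)
  perm <- sample(36)
  img2 <- array(0, c(6, 6, 3))
  for (k in 1:3) img2[, , k] <- matrix(as.vector(img[, , k])[perm], 6, 6)
  expect_identical(h1, hsv_histogram(img2))
})

test_that("semantic vectors follow the lookup and compound-word mean rules", {
  dirpath <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("axe 1 0 0", "plaster 0 1 0", "trowel 0 0 1",
               "Zebra 0.5 0.5 0"), dirpath)
  tab <- read_word_vectors(dirpath)
  expect_equal(tab$M, 3)
  expect_equal(unname(semantic_vector("axe", tab)), c(1, 0, 0))
  expect_equal(unname(semantic_vector("plaster trowel", tab)),
               c(0, 0.5, 0.5))
  expect_equal(unname(semantic_vector("zebra zebra", tab)), c(0.5, 0.5, 0))
  expect_error(semantic_vector("aardvark", tab),
               class = "eegretrieve_lookup_error")
})

test_that("row range normalisation maps rows onto [0, 1] with the degenerate rule", {
  expect_equal(range_normalize_rows(matrix(c(0, 5, 10), 1)),
               matrix(c(0, 0.5, 1), 1))
  expect_equal(range_normalize_rows(matrix(4, 1, 3)), matrix(0, 1, 3))
  set.seed(36)
  m <- matrix(rnorm(50), 5, 10)
  n <- range_normalize_rows(m)
  expect_equal(apply(n, 1, min), rep(0, 5))
  expect_equal(apply(n, 1, max), rep(1, 5))
})

test_that("fusion with a full-rank single block preserves variance and matches eigen PCA", {
  set.seed(37)
  sem <- matrix(rnorm(20 * 6), 20, 6)
  rownames(sem) <- sprintf("s%02d", 1:20)
  fx <- fuse_features(list(sem = sem), pca_components = 6)
  norm_sem <- range_normalize_rows(sem)
  tot <- sum(apply(norm_sem, 2, var))
  expect_equal(sum(apply(fx$matrix, 2, var)), tot, tolerance = 1e-8)
  # component variances non-increasing
  expect_true(all(diff(fx$sdev) <= 1e-12))
  # eigen-decomposition oracle on a toy block, up to per-component sign
  toy <- matrix(c(2, 4, 1, 7, 3, 5, 8, 2, 9, 1, 4, 6, 2, 8, 3, 7, 5, 9,
                  1, 3, 6, 2, 8, 4), 6, 4)
  rownames(toy) <- letters[1:6]
  fx2 <- fuse_features(list(sem = toy), pca_components = 3)
  tc <- scale(range_normalize_rows(toy), scale = FALSE)
  ev <- eigen(cov(tc))
  want <- tc %*% ev$vectors[, 1:3]
  for (j in 1:3)
    expect_equal(abs(fx2$matrix[, j]), abs(want[, j]), tolerance = 1e-8)
  expect_warning(fuse_features(list(sem = toy), pca_components = 10),
                 "clipped")
})

test_that("fusion concatenates blocks in canonical order and checks row alignment", {
  set.seed(38)
  ids <- sprintf("s%d", 1:8)
  g <- matrix(rnorm(8 * 5), 8, 5); rownames(g) <- ids
  s <- matrix(rnorm(8 * 4), 8, 4); rownames(s) <- ids
  fx <- fuse_features(list(sem = s, gabor = g), pca_components = 3)
  expect_equal(fx$blocks, c("gabor", "sem"))
  bad <- s; rownames(bad) <- rev(ids)
  expect_error(fuse_features(list(gabor = g, sem = bad)), "disagree")
})
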