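#' Read a PNG stimulus image
#'
#' @param path Path to a PNG file.
#' @return H x W x 3 numeric array in `[0, 1]` (grayscale replicated, alpha
#'   dropped).
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 2) img <- array(rep(img[, , 1], 3), c(dim(img)[1:2], 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3]
  img
}

#' Build a Gabor filter bank
#'
#' Oriented sinusoids under a Gaussian envelope, the classical model of V1
#' edge detectors. The default bank crosses 8 evenly spaced orientations on
#' `[0, pi)` with 4 envelope widths (sigma 2-5), 32 filters in all, with
#' wavelength 6, aspect ratio 0.5, phase 0 and 31 x 31 kernels. Filter order:
#' orientations vary fastest within each sigma.
#'
#' @param n_orientations Number of orientations (default 8).
#' @param sigmas Gaussian envelope SDs (default 2:5).
#' @param ksize Odd kernel size (default 31).
#' @param lam Sinusoid wavelength (default 6).
#' @param gamma Spatial aspect ratio (default 0.5).
#' @param psi Phase offset (default 0).
#' @param orientation_spacing `"pi8"` (default; step pi/n on `[0, pi)`) or
#'   `"pi7"` (step pi/7, an alternative reading of the orientation grid).
#' @return A `gabor_bank`: list of kernels (real and imaginary parts) and a
#'   parameter tibble.
#' @export
build_gabor_bank <- function(n_orientations = 8, sigmas = c(2, 3, 4, 5),
                             ksize = 31, lam = 6.0, gamma = 0.5, psi = 0,
                             orientation_spacing = c("pi8", "pi7")) {
  orientation_spacing <- match.arg(orientation_spacing)
  if (n_orientations < 1) stop_eegr("need at least one orientation")
  if (ksize %% 2 == 0)
    stop_eegr("ksize must be odd (the kernel needs a centre pixel)",
              class = "eegretrieve_config_error")
  step <- if (orientation_spacing == "pi8") pi / n_orientations else pi / 7
  thetas <- step * (seq_len(n_orientations) - 1)
  half <- (ksize - 1) / 2
  xs <- matrix(rep(-half:half, each = ksize), ksize)   # column coord
  ys <- matrix(rep(-half:half, times = ksize), ksize)  # row coord
  kernels <- list(); params <- list()
  for (s in sigmas) {
    for (th in thetas) {
      xp <- xs * cos(th) + ys * sin(th)
      yp <- -xs * sin(th) + ys * cos(th)
      env <- exp(-(xp^2 + gamma^2 * yp^2) / (2 * s^2))
      kernels[[length(kernels) + 1]] <- list(
        real = env * cos(2 * pi * xp / lam + psi),
        imag = env * sin(2 * pi * xp / lam + psi))
      params[[length(params) + 1]] <-
        tibble::tibble(theta = th, sigma = s, lambda = lam, gamma = gamma,
                       psi = psi, ksize = ksize)
    }
  }
  structure(list(kernels = kernels, params = dplyr::bind_rows(params)),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf("<gabor_bank> %d filters (%d orientations x %d sigmas)\n",
              length(x$kernels), length(unique(x$params$theta)),
              length(unique(x$params$sigma))))
  invisible(x)
}

# Evaluate the Gabor kernel function at a single (x, y); exposed for tests.
gabor_kernel_value <- function(x, y, lam, theta, psi, sigma, gamma) {
  xp <- x * cos(theta) + y * sin(theta)
  yp <- -x * sin(theta) + y * cos(theta)
  exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2)) *
    exp(1i * (2 * pi * xp / lam + psi))
}

#' Gabor filter-bank energy histogram of an image
#'
#' Converts the image to grayscale, optionally resizes and standardises it
#' (zero mean, unit SD), convolves with every filter in the bank and sums
#' the response over pixels, yielding one value per filter (32 by default).
#'
#' @param image H x W (x 3) numeric array in `[0, 1]`, or a PNG path.
#' @param bank A [build_gabor_bank()] object.
#' @param resize_to Side length images are resized to first (NULL to skip);
#'   default 256.
#' @param standardise Standardise the grayscale image before filtering
#'   (default TRUE).
#' @param aggregate `"real"` (default): sum of the real-part response;
#'   `"magnitude"`: sum of the complex modulus.
#' @return Numeric vector, one entry per filter.
#' @export
gabor_features <- function(image, bank, resize_to = 256, standardise = TRUE,
                           aggregate = c("real", "magnitude")) {
  aggregate <- match.arg(aggregate)
  if (is.character(image)) image <- read_image(image)
  if (length(image) == 0 || prod(dim(image)[1:2]) == 0)
    stop_eegr("zero-size image")
  g <- to_grayscale(image)
  if (!is.null(resize_to)) g <- resize_bilinear(g, resize_to, resize_to)
  if (standardise) {
    s <- stats::sd(g)
    g <- if (s > 0) (g - mean(g)) / s else g - mean(g)
  }
  vapply(bank$kernels, function(k) {
    re <- sum(conv2_same(g, k$real))
    if (aggregate == "real") return(re)
    im <- sum(conv2_same(g, k$imag))
    # modulus aggregated pixel-wise
    sum(Mod(conv2_same(g, k$real) + 1i * conv2_same(g, k$imag)))
  }, numeric(1))
}

#' Dense SIFT descriptors on a regular grid
#'
#' Gradient-orientation descriptors (8 orientation bins over a 4 x 4 cell
#' grid, 16 x 16 pixel support, 128 dimensions) computed at regularly
#' spaced keypoints rather than detected ones. Descriptors are
#' L2-normalised with 0.2 clipping and renormalisation.
#'
#' @param image H x W (x 3) array in `[0, 1]`, or a PNG path.
#' @param grid_step Keypoint spacing in pixels (default 8).
#' @param resize_to Side length for the initial resize (default 256; NULL
#'   keeps the native size).
#' @return n x 128 matrix of descriptors (0 rows, with a warning, if the
#'   image is smaller than one descriptor support window).
#' @export
dense_sift <- function(image, grid_step = 8, resize_to = 256) {
  if (is.character(image)) image <- read_image(image)
  g <- to_grayscale(image)
  if (!is.null(resize_to)) g <- resize_bilinear(g, resize_to, resize_to)
  h <- nrow(g); w <- ncol(g)
  support <- 16L
  if (h < support + 2 || w < support + 2) {
    warn_eegr("image smaller than one descriptor support window")
    return(matrix(numeric(0), 0, 128))
  }
  dx <- matrix(0, h, w); dy <- matrix(0, h, w)
  dx[, 2:(w - 1)] <- (g[, 3:w] - g[, 1:(w - 2)]) / 2
  dy[2:(h - 1), ] <- (g[3:h, ] - g[1:(h - 2), ]) / 2
  mag <- sqrt(dx^2 + dy^2)
  ori <- atan2(dy, dx) %% (2 * pi)
  bin <- pmin(floor(ori / (2 * pi) * 8), 7)  # 0..7
  centers_y <- seq(support / 2 + 1, h - support / 2, by = grid_step)
  centers_x <- seq(support / 2 + 1, w - support / 2, by = grid_step)
  out <- matrix(0, length(centers_y) * length(centers_x), 128)
  r <- 0L
  for (cy in centers_y) {
    for (cx in centers_x) {
      r <- r + 1L
      desc <- numeric(128)
      y0 <- cy - support / 2; x0 <- cx - support / 2
      for (ci in 0:3) {
        for (cj in 0:3) {
          rows <- (y0 + ci * 4):(y0 + ci * 4 + 3)
          cols <- (x0 + cj * 4):(x0 + cj * 4 + 3)
          b <- bin[rows, cols]; m <- mag[rows, cols]
          # cells row-major, 8 orientation bins fastest
          base <- (ci * 4 + cj) * 8
          for (k in 0:7) desc[base + k + 1] <- sum(m[b == k])
        }
      }
      nrm <- sqrt(sum(desc^2))
      if (nrm > 1e-12) {
        desc <- pmin(desc / nrm, 0.2)
        desc <- desc / sqrt(sum(desc^2))
      }
      out[r, ] <- desc
    }
  }
  out
}

#' Train a visual-word codebook by k-means
#'
#' @param descriptor_sample n x 128 matrix of SIFT descriptors (n >= k, with
#'   at least k distinct rows).
#' @param k Number of visual words (default 1000).
#' @param seed RNG seed; the codebook is deterministic given seed + sample.
#' @param corpus_id Free-text provenance tag stored with the codebook.
#' @return A `vbow_codebook` with `centroids` (k x d) and metadata.
#' @export
train_codebook <- function(descriptor_sample, k = 1000, seed = 1L,
                           corpus_id = "unspecified") {
  stopifnot(is.matrix(descriptor_sample))
  if (nrow(descriptor_sample) < k)
    stop_eegr("descriptor sample smaller than k")
  if (nrow(unique(descriptor_sample)) < k)
    stop_eegr("fewer than k distinct descriptors in the sample")
  uniq <- unique(descriptor_sample)
  if (nrow(uniq) == k) {
    centers <- uniq  # one point per cluster: the exact k-means solution
  } else {
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    km <- stats::kmeans(descriptor_sample, centers = k, iter.max = 100,
                        nstart = 1)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
    centers <- km$centers
  }
  structure(list(centroids = unname(centers), k = k,
                 meta = list(corpus_id = corpus_id, seed = seed,
                             sample_size = nrow(descriptor_sample))),
            class = "vbow_codebook")
}

#' @export
print.vbow_codebook <- function(x, ...) {
  cat(sprintf("<vbow_codebook> %d words x %d dims (corpus: %s)\n",
              x$k, ncol(x$centroids), x$meta$corpus_id))
  invisible(x)
}

#' Visual bag-of-words histogram
#'
#' Assigns each descriptor to its nearest centroid (Euclidean; ties to the
#' lowest centroid index) and counts assignments per visual word.
#'
#' @param descriptors n x d matrix (possibly 0 rows).
#' @param codebook A [train_codebook()] object.
#' @return Integer vector of length `k` summing to `nrow(descriptors)`.
#' @export
vbow_histogram <- function(descriptors, codebook) {
  stopifnot(inherits(codebook, "vbow_codebook"))
  k <- codebook$k
  if (!nrow(descriptors)) return(integer(k))
  if (ncol(descriptors) != ncol(codebook$centroids))
    stop_eegr("descriptor length does not match the codebook")
  d2 <- outer(rowSums(descriptors^2), rowSums(codebook$centroids^2), "+") -
    2 * descriptors %*% t(codebook$centroids)
  assign_ <- max.col(-d2, ties.method = "first")
  tabulate(assign_, nbins = k)
}

#' HSV colour histogram (16 bins per channel, 48 features)
#'
#' Pixels are converted to hue-saturation-value and each channel quantised
#' into 16 bins (4 bits); the three 16-bin count vectors are concatenated in
#' H, S, V order, so each channel's bins sum to the pixel count.
#'
#' @param image H x W x 3 array in `[0, 1]`, H x W grayscale (converted,
#'   with a message), or a PNG path.
#' @return Integer vector of length 48.
#' @export
hsv_histogram <- function(image) {
  if (is.character(image)) image <- read_image(image)
  if (length(dim(image)) == 2) {
    message("grayscale image: converting to RGB for the HSV histogram")
    image <- array(rep(image, 3), c(dim(image), 3))
  }
  px <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(px, maxColorValue = 1)
  binit <- function(x) tabulate(pmin(floor(x * 16), 15) + 1L, nbins = 16)
  c(binit(hsv[1, ]), binit(hsv[2, ]), binit(hsv[3, ]))
}

#' Read a word-vector table from whitespace-delimited text
#'
#' One entry per line: token followed by M floats. Tokens are case-folded
#' to lower case; later duplicates are ignored.
#'
#' @param path Path to the text file.
#' @return A `word_table` with `vectors` (tokens x M matrix, rownames =
#'   tokens) and `M`.
#' @export
read_word_vectors <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  toks <- tolower(vapply(parts, `[`, character(1), 1))
  M <- length(parts[[1]]) - 1L
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(M)))
  keep <- !duplicated(toks)
  mat <- mat[keep, , drop = FALSE]
  rownames(mat) <- toks[keep]
  structure(list(vectors = mat, M = M), class = "word_table")
}

#' @export
print.word_table <- function(x, ...) {
  cat(sprintf("<word_table> %d tokens x %d dims\n", nrow(x$vectors), x$M))
  invisible(x)
}

#' Semantic embedding of a stimulus name
#'
#' Single-word names map to their stored vector; multi-word names (and
#' hyphenated words) map to the arithmetic mean of the vectors of their
#' component words present in the table.
#'
#' @param name Stimulus name, e.g. `"plaster trowel"`.
#' @param table A [read_word_vectors()] table.
#' @return Numeric vector of length `table$M`.
#' @export
semantic_vector <- function(name, table) {
  stopifnot(inherits(table, "word_table"))
  toks <- tolower(unlist(strsplit(name, "[\\s-]+", perl = TRUE)))
  toks <- toks[nzchar(toks)]
  hit <- toks %in% rownames(table$vectors)
  if (!any(hit))
    stop_eegr(paste0("no word vector for any token of '", name, "' (missing: ",
                     paste(toks, collapse = ", "), ")"),
              class = "eegretrieve_lookup_error")
  if (any(!hit))
    warn_eegr(paste0("tokens without vectors ignored: ",
                     paste(toks[!hit], collapse = ", ")))
  v <- table$vectors[toks[hit], , drop = FALSE]
  colMeans(v)
}

#' Range-normalise each row of a feature block to [0, 1]
#'
#' Each stimulus row `y` maps to `(y - min y) / (max y - min y)`; constant
#' rows map to all zeros.
#'
#' @param mat nS x d numeric matrix.
#' @return Matrix of the same shape with rows in `[0, 1]`.
#' @export
range_normalize_rows <- function(mat) {
  t(apply(mat, 1, function(y) {
    r <- max(y) - min(y)
    if (r == 0) rep(0, length(y)) else (y - min(y)) / r
  }))
}

#' Extract all feature blocks for a stimulus gallery
#'
#' @param image_paths Character vector of PNG paths, one per stimulus.
#' @param names Stimulus names (for the semantic block), parallel to
#'   `image_paths`.
#' @param stimulus_ids Stimulus identifiers, parallel to `image_paths`.
#' @param codebook A [train_codebook()] object (needed for the sift block).
#' @param word_table A [read_word_vectors()] table (needed for sem).
#' @param blocks Character subset of `c("gabor", "hsv", "sift", "sem")`.
#' @param gabor_bank Optional custom [build_gabor_bank()].
#' @param grid_step Dense-SIFT grid step (default 8).
#' @return Named list of nS x d matrices, one per requested block, with
#'   `stimulus_ids` attached as an attribute.
#' @export
stimulus_feature_blocks <- function(image_paths, names, stimulus_ids,
                                    codebook = NULL, word_table = NULL,
                                    blocks = c("gabor", "hsv", "sift", "sem"),
                                    gabor_bank = NULL, grid_step = 8) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  nS <- length(image_paths)
  imgs <- lapply(image_paths, read_image)
  out <- list()
  if ("gabor" %in% blocks) {
    if (is.null(gabor_bank)) gabor_bank <- build_gabor_bank()
    out$gabor <- t(vapply(imgs, gabor_features, numeric(length(gabor_bank$kernels)),
                          bank = gabor_bank))
  }
  if ("hsv" %in% blocks)
    out$hsv <- t(vapply(imgs, function(im) as.numeric(hsv_histogram(im)),
                        numeric(48)))
  if ("sift" %in% blocks) {
    if (is.null(codebook)) stop_eegr("the sift block needs a codebook")
    out$sift <- t(vapply(imgs, function(im)
      as.numeric(vbow_histogram(dense_sift(im, grid_step), codebook)),
      numeric(codebook$k)))
  }
  if ("sem" %in% blocks) {
    if (is.null(word_table)) stop_eegr("the sem block needs a word table")
    out$sem <- t(vapply(names, semantic_vector, numeric(word_table$M),
                        table = word_table))
  }
  out <- lapply(out, function(m) { rownames(m) <- stimulus_ids; m })
  attr(out, "stimulus_ids") <- stimulus_ids
  out
}

#' Fuse feature blocks into a PCA-reduced visuo-semantic space
#'
#' Each block is row range-normalised, the blocks are concatenated
#' column-wise in the canonical order (gabor, hsv, sift, sem — or the
#' subset supplied), and PCA reduces the concatenation. By default the
#' number of components retains 99% of variance, capped at nS - 1.
#'
#' @param blocks Named list of nS x d matrices (same row order across
#'   blocks), e.g. from [stimulus_feature_blocks()].
#' @param pca_components Number of PCA components, or NULL for the 99%
#'   variance policy. Values above the available rank are clipped with a
#'   warning.
#' @param variance_target Retained-variance fraction for the NULL policy.
#' @return A `fused_features`: `matrix` (nS x p scores), `loadings`,
#'   `center`, per-component `sdev`, `blocks` used, and `stimulus_ids`.
#' @export
fuse_features <- function(blocks, pca_components = NULL,
                          variance_target = 0.99) {
  canonical <- c("gabor", "hsv", "sift", "sem")
  ord <- intersect(canonical, names(blocks))
  if (!length(ord)) stop_eegr("no recognised feature blocks")
  ids <- rownames(blocks[[ord[1]]])
  for (b in ord) {
    if (!identical(rownames(blocks[[b]]), ids))
      stop_eegr("feature blocks disagree on stimulus ids or order")
  }
  norm_cat <- do.call(cbind, lapply(ord, function(b)
    range_normalize_rows(blocks[[b]])))
  nS <- nrow(norm_cat)
  pc <- stats::prcomp(norm_cat, center = TRUE, scale. = FALSE)
  var_exp <- pc$sdev^2
  rank_ <- sum(var_exp > max(var_exp) * 1e-12)
  if (is.null(pca_components)) {
    cum <- cumsum(var_exp) / sum(var_exp)
    pca_components <- min(which(cum >= variance_target)[1], nS - 1, rank_)
  } else if (pca_components > rank_) {
    warn_eegr(sprintf("pca_components clipped from %d to the rank %d",
                      pca_components, rank_))
    pca_components <- rank_
  }
  p <- pca_components
  structure(list(matrix = pc$x[, seq_len(p), drop = FALSE],
                 loadings = pc$rotation[, seq_len(p), drop = FALSE],
                 center = pc$center, sdev = pc$sdev[seq_len(p)],
                 explained_variance = sum(var_exp[seq_len(p)]) / sum(var_exp),
                 blocks = ord, stimulus_ids = ids),
            class = "fused_features")
}

#' @export
print.fused_features <- function(x, ...) {
  cat(sprintf("<fused_features> %d stimuli x %d components (%.1f%% var; blocks: %s)\n",
              nrow(x$matrix), ncol(x$matrix), 100 * x$explained_variance,
              paste(x$blocks, collapse = ", ")))
  invisible(x)
}
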