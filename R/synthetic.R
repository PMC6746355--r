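# Fixture generators: controlled stimulus images, a toy word-vector
# lexicon, randomised presentation schedules, and forward-model EEG
# recordings in which each stimulus evokes a fixed spatiotemporal template
# that is a linear transform of its fused image-feature vector. All are
# deterministic under their seeds, so the whole pipeline is testable with
# no external data.

concept_pool <- c(
  "armadillo", "axe", "badger", "beaver", "camel", "chisel", "corkscrew",
  "crowbar", "dolphin", "drill", "elephant", "ferret", "fox", "giraffe",
  "hammer", "hamster", "hedgehog", "kangaroo", "koala", "lemur", "leopard",
  "mallet", "meerkat", "mongoose", "otter", "pliers", "plaster trowel",
  "rabbit", "raccoon", "rake", "saw", "scissors", "screwdriver", "skunk",
  "sloth", "spanner", "squirrel", "tape measure", "tiger", "tongs",
  "walrus", "weasel", "wheelbarrow", "wolf", "wombat", "wrench", "zebra",
  "anvil", "antelope", "bison", "chainsaw", "cheetah", "clamp", "gazelle",
  "gopher", "grinder", "hacksaw", "hyena", "ibex", "jackal", "ladle",
  "lathe", "lynx", "marmot", "mole", "ocelot", "panther", "pickaxe",
  "porcupine", "puma", "sander", "shears", "shovel", "sickle", "stoat",
  "trowel", "vole", "file rasp", "nail gun", "wire cutter")

hsv_to_rgb_array <- function(h, s, v) {
  # h, s, v equal-length vectors in [0, 1]; returns 3 x n rgb in [0, 1]
  i <- floor(h * 6) %% 6
  f <- h * 6 - floor(h * 6)
  p <- v * (1 - s); q <- v * (1 - f * s); t_ <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
         ifelse(i == 3, p, ifelse(i == 4, t_, v)))))
  g <- ifelse(i == 0, t_, ifelse(i == 1, v, ifelse(i == 2, v,
         ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t_,
         ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  rbind(r, g, b)
}

#' Generate a gallery of controlled synthetic stimulus images
#'
#' Each image carries a distinct dominant hue, an oriented grating at a
#' stimulus-specific angle and spatial frequency, and a bright geometric
#' patch, so the Gabor, HSV and SIFT blocks are all mutually
#' discriminative. Names are drawn from a fixed concept list (including
#' multi-word names, to exercise compound-name embedding).
#'
#' @param nS Number of stimuli.
#' @param seed RNG seed; images are byte-identical given the seed.
#' @param size Image side in pixels (default 64).
#' @param dir Optional directory; when given, PNGs and a `manifest.csv`
#'   (stimulus_id, filename, name) are written there.
#' @return List with `images` (list of H x W x 3 arrays), `manifest`
#'   (tibble), and `paths` (if `dir` was given).
#' @export
synth_images <- function(nS, seed = 1L, size = 64L, dir = NULL) {
  stopifnot(nS >= 1)
  if (nS > length(concept_pool))
    stop_eegr(sprintf("at most %d distinct concept names available",
                      length(concept_pool)))
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  nm <- sample(concept_pool, nS)
  yy <- matrix(rep(seq_len(size), times = size), size)
  xx <- matrix(rep(seq_len(size), each = size), size)
  images <- vector("list", nS)
  for (i in seq_len(nS)) {
    hue <- (i - 1) / nS
    ang <- pi * (i - 1) / nS
    freq <- 0.08 + 0.3 * ((i * 7) %% nS) / nS
    grat <- 0.5 + 0.45 * sin(freq * (xx * cos(ang) + yy * sin(ang)) * 2 * pi)
    cx <- size * (0.25 + 0.5 * stats::runif(1))
    cy <- size * (0.25 + 0.5 * stats::runif(1))
    rad <- size * 0.12
    patch <- ((xx - cx)^2 + (yy - cy)^2) < rad^2
    val <- grat; val[patch] <- 1
    sat <- matrix(0.8, size, size); sat[patch] <- 0.2
    rgb <- hsv_to_rgb_array(rep(hue, size^2), as.vector(sat), as.vector(val))
    images[[i]] <- array(c(rgb[1, ], rgb[2, ], rgb[3, ]), c(size, size, 3))
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())
  manifest <- tibble::tibble(
    stimulus_id = sprintf("stim%03d", seq_len(nS)),
    filename = sprintf("stim%03d.png", seq_len(nS)),
    name = nm)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, manifest$filename)
    for (i in seq_len(nS)) png::writePNG(images[[i]], paths[i])
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(images = images, manifest = manifest, paths = paths)
}

#' Generate a toy word-vector lexicon for a set of stimulus names
#'
#' Unit-norm Gaussian random vectors for every token appearing in the
#' names (multi-word names contribute their component words).
#'
#' @param names Character vector of stimulus names.
#' @param M Embedding dimensionality (default 50).
#' @param seed RNG seed.
#' @param path Optional path: writes the whitespace text format readable by
#'   [read_word_vectors()].
#' @return A `word_table`.
#' @export
synth_lexicon <- function(names, M = 50L, seed = 1L, path = NULL) {
  stopifnot(length(names) >= 1)
  toks <- unique(tolower(unlist(strsplit(names, "[\\s-]+", perl = TRUE))))
  toks <- toks[nzchar(toks)]
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  mat <- matrix(stats::rnorm(length(toks) * M), length(toks), M)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())
  mat <- mat / sqrt(rowSums(mat^2))
  rownames(mat) <- toks
  tab <- structure(list(vectors = mat, M = as.integer(M)),
                   class = "word_table")
  if (!is.null(path)) {
    lines <- vapply(seq_len(nrow(mat)), function(i)
      paste(c(toks[i], format(mat[i, ], digits = 8, scientific = FALSE)),
            collapse = " "), character(1))
    writeLines(lines, path)
  }
  tab
}

#' Randomised stimulus presentation schedule
#'
#' Every stimulus is presented exactly `nP` times in a fully randomised
#' order with a fixed inter-trial interval (at least 1600 ms, leaving room
#' for the 500 ms baseline and the 1000 ms epoch).
#'
#' @param nS,nP Number of stimuli and presentations per stimulus.
#' @param iti_ms Inter-trial onset spacing in ms (>= 1600).
#' @param seed RNG seed.
#' @return Tibble with columns `event`, `stimulus_index`, `onset_ms`.
#' @export
paradigm_schedule <- function(nS, nP, iti_ms = 2000, seed = 1L) {
  stopifnot(nS * nP >= 1)
  if (iti_ms < 1600)
    stop_eegr("iti_ms must be >= 1600 (baseline + epoch window)",
              class = "eegretrieve_config_error")
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  order_ <- sample(rep(seq_len(nS), nP))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())
  tibble::tibble(event = seq_along(order_), stimulus_index = order_,
                 onset_ms = 1000 + (seq_along(order_) - 1) * iti_ms)
}

#' Synthetic-recording specification
#'
#' @param nS,nP,nC Stimuli, presentations, channels (defaults 60 / 6 / 64,
#'   the picture-naming paradigm scale of a 64-channel session).
#' @param srate Sampling rate in Hz (default 500).
#' @param snr Template SD divided by noise SD (default 1).
#' @param noise_sd Background noise SD in microvolts (default 10).
#' @param artefacts Character subset of `c("blink", "dead_channel",
#'   "line_noise")`.
#' @param iti_ms Inter-trial interval (default 2000).
#' @param seeds Named integer list: eeg, schedule.
#' @return Named list spec.
#' @export
synth_spec <- function(nS = 60, nP = 6, nC = 64, srate = 500, snr = 1,
                       noise_sd = 10, artefacts = character(0),
                       iti_ms = 2000,
                       seeds = list(eeg = 11L, schedule = 12L)) {
  stopifnot(nS >= 3, nP >= 2, snr >= 0)
  list(nS = nS, nP = nP, nC = nC, srate = srate, snr = snr,
       noise_sd = noise_sd, artefacts = artefacts, iti_ms = iti_ms,
       seeds = seeds)
}

# Quasi-uniform unit-sphere sensor layout on the upper hemisphere
# (Fibonacci spiral); y is the anterior axis, channel 1 the most anterior.
synth_layout <- function(nC) {
  i <- seq_len(nC) - 0.5
  z <- i / nC                       # upper hemisphere
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(1 - z^2)
  pos <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  pos[order(-pos[, "y"]), , drop = FALSE]
}

#' Forward-model synthetic EEG recording
#'
#' Background Gaussian noise plus, for every presentation of stimulus `s`,
#' a fixed spatiotemporal template `T_s` confined to 100-600 ms post-onset,
#' obtained as a linear transform (drawn once per seed) of the stimulus's
#' fused feature vector and scaled so template SD / noise SD equals
#' `spec$snr`. Optional planted artefacts: ocular blinks on the most
#' anterior channel, one dead channel, and 50 Hz line noise.
#'
#' @param fused A [fuse_features()] space covering all `spec$nS` stimuli.
#' @param spec A [synth_spec()].
#' @return An [eeg_recording()] with events and a unit-sphere layout.
#' @export
synth_recording <- function(fused, spec) {
  stopifnot(inherits(fused, "fused_features"))
  if (nrow(fused$matrix) < spec$nS)
    stop_eegr("fused feature space does not cover all stimuli")
  sched <- paradigm_schedule(spec$nS, spec$nP, spec$iti_ms,
                             spec$seeds$schedule)
  sr <- spec$srate
  onset_samples <- round(sched$onset_ms * sr / 1000) + 1L
  n_samples <- max(onset_samples) + round(2 * sr)
  nC <- spec$nC
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(spec$seeds$eeg)
  data <- matrix(stats::rnorm(nC * n_samples, sd = spec$noise_sd),
                 nC, n_samples)
  sup0 <- round(0.1 * sr); sup1 <- round(0.6 * sr)  # 100-600 ms
  n_sup <- sup1 - sup0
  p <- ncol(fused$matrix)
  Wf <- matrix(stats::rnorm(nC * n_sup * p), nC * n_sup, p) / sqrt(p)
  feats <- scale(fused$matrix[seq_len(spec$nS), , drop = FALSE])
  feats[!is.finite(feats)] <- 0
  templates <- vector("list", spec$nS)
  for (s in seq_len(spec$nS)) {
    tpl <- matrix(Wf %*% feats[s, ], nC, n_sup)
    tpl_sd <- stats::sd(tpl)
    templates[[s]] <- if (tpl_sd > 0)
      tpl / tpl_sd * spec$snr * spec$noise_sd else tpl * 0
  }
  # smooth onset/offset so the template sits cleanly inside the band
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_sup) / n_sup)
  for (e in seq_len(nrow(sched))) {
    s <- sched$stimulus_index[e]
    cols <- (onset_samples[e] + sup0):(onset_samples[e] + sup1 - 1)
    data[, cols] <- data[, cols] +
      templates[[s]] * matrix(taper, nC, n_sup, byrow = TRUE)
  }
  layout <- synth_layout(nC)
  if ("blink" %in% spec$artefacts) {
    # frequent, physiological blinks: a single ocular source projecting
    # onto all sensors with a topography decaying away from the anterior
    # pole, strongest at the proxy sensor. No single channel becomes a
    # variance outlier, so the artefact reaches the ICA stage as one
    # spatially coherent component rather than being interpolated away.
    proxy <- which.max(layout[, "y"])
    d2 <- rowSums(sweep(layout, 2, layout[proxy, ])^2)
    topo <- exp(-d2 / 0.5)
    n_blinks <- max(3L, round(n_samples / sr / 3))
    at <- sort(sample.int(n_samples - sr, n_blinks))
    lobe <- 80 * (0.5 - 0.5 * cos(2 * pi * seq_len(round(0.4 * sr)) /
                                    round(0.4 * sr)))
    for (b in at) {
      cols <- b:(b + length(lobe) - 1)
      data[, cols] <- data[, cols] + topo %o% lobe
    }
  }
  if ("dead_channel" %in% spec$artefacts) {
    dead <- nC  # most posterior channel
    data[dead, ] <- stats::rnorm(n_samples, sd = 1e-4)
  }
  if ("line_noise" %in% spec$artefacts) {
    tvec <- seq_len(n_samples) / sr
    for (ch in seq_len(nC))
      data[ch, ] <- data[ch, ] +
        20 * sin(2 * pi * 50 * tvec + stats::runif(1, 0, 2 * pi))
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())
  events <- tibble::tibble(
    sample = onset_samples,
    stimulus_id = fused$stimulus_ids[sched$stimulus_index])
  eeg_recording(data, sr, sprintf("CH%03d", seq_len(nC)), layout, events)
}

#' One-call synthetic study: images, lexicon, features and EEG
#'
#' Convenience wrapper chaining [synth_images()], [synth_lexicon()], the
#' feature extractors, [fuse_features()] and [synth_recording()] into a
#' complete offline test bench.
#'
#' @param spec A [synth_spec()].
#' @param blocks Feature blocks to build (default all four).
#' @param codebook_k Visual words for the fixture codebook (default 50).
#' @param image_size Stimulus image side in px (default 64).
#' @param M Lexicon dimensionality (default 50).
#' @param seeds Named list: images, lexicon, codebook.
#' @param pca_components Passed to [fuse_features()].
#' @return List: `images`, `manifest`, `lexicon`, `blocks`, `fused`,
#'   `recording`, `spec`.
#' @export
synth_study <- function(spec = synth_spec(),
                        blocks = c("gabor", "hsv", "sift", "sem"),
                        codebook_k = 50, image_size = 64, M = 50,
                        seeds = list(images = 21L, lexicon = 22L,
                                     codebook = 23L),
                        pca_components = NULL) {
  imgs <- synth_images(spec$nS, seed = seeds$images, size = image_size)
  lex <- synth_lexicon(imgs$manifest$name, M = M, seed = seeds$lexicon)
  bank <- if ("gabor" %in% blocks) build_gabor_bank() else NULL
  codebook <- NULL
  if ("sift" %in% blocks) {
    descs <- do.call(rbind, lapply(
      imgs$images[seq_len(min(spec$nS, 10))],
      function(im) dense_sift(im, grid_step = 16, resize_to = 128)))
    codebook <- train_codebook(descs, k = codebook_k,
                               seed = seeds$codebook,
                               corpus_id = "synthetic fixture gallery")
  }
  blk <- list()
  if ("gabor" %in% blocks)
    blk$gabor <- t(vapply(imgs$images, gabor_features,
                          numeric(length(bank$kernels)), bank = bank,
                          resize_to = 128))
  if ("hsv" %in% blocks)
    blk$hsv <- t(vapply(imgs$images, function(im)
      as.numeric(hsv_histogram(im)), numeric(48)))
  if ("sift" %in% blocks)
    blk$sift <- t(vapply(imgs$images, function(im)
      as.numeric(vbow_histogram(dense_sift(im, grid_step = 16,
                                           resize_to = 128), codebook)),
      numeric(codebook_k)))
  if ("sem" %in% blocks)
    blk$sem <- t(vapply(imgs$manifest$name, semantic_vector, numeric(lex$M),
                        table = lex))
  blk <- lapply(blk, function(m) {
    rownames(m) <- imgs$manifest$stimulus_id; m })
  fused <- fuse_features(blk, pca_components = pca_components)
  rec <- synth_recording(fused, spec)
  list(images = imgs$images, manifest = imgs$manifest, lexicon = lex,
       blocks = blk, fused = fused, recording = rec, spec = spec)
}
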