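#' Construct a raw EEG recording
#'
#' Container for a continuous multichannel EEG recording in microvolts,
#' with sensor geometry and stimulus events. All downstream cleaning and
#' decoding stages start from this object.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param srate Sampling rate in Hz (> 0).
#' @param channel_names Character vector, one name per channel.
#' @param layout Numeric matrix, channels x 3, unit-sphere sensor positions.
#'   Column convention: x = left-right, y = posterior-anterior (the most
#'   anterior sensor has the largest y), z = inferior-superior.
#' @param events Data frame / tibble with columns `sample` (1-based sample
#'   index of stimulus onset) and `stimulus_id`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, srate, channel_names = NULL, layout = NULL,
                          events = NULL) {
  stopifnot(is.matrix(data))
  if (!is.numeric(srate) || srate <= 0) stop_eegr("srate must be > 0")
  nc <- nrow(data)
  if (is.null(channel_names)) channel_names <- sprintf("CH%03d", seq_len(nc))
  if (length(channel_names) != nc)
    stop_eegr("channel_names length must equal the number of channels")
  if (!is.null(layout)) {
    layout <- as.matrix(layout)
    if (nrow(layout) != nc || ncol(layout) != 3)
      stop_eegr("layout must be a channels x 3 matrix")
  }
  if (is.null(events)) {
    events <- tibble::tibble(sample = integer(0), stimulus_id = character(0))
  } else {
    events <- tibble::as_tibble(events)
    stopifnot(all(c("sample", "stimulus_id") %in% names(events)))
    if (nrow(events) && (min(events$sample) < 1 ||
                         max(events$sample) > ncol(data)))
      stop_eegr("event sample indices fall outside the recording")
  }
  structure(list(data = data, srate = srate, channel_names = channel_names,
                 layout = layout, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$srate, nrow(x$events)))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Write a recording in the packed array + JSON sidecar format
#'
#' The packed format is a little-endian float32 binary of the channels x
#' samples matrix (R column-major order) beside a JSON sidecar holding the
#' sampling rate, channel names, 3-D positions and events.
#'
#' @param rec An `eeg_recording`.
#' @param stem Output path stem; writes `<stem>.dat` and `<stem>.json`.
#' @return `stem`, invisibly.
#' @export
write_packed <- function(rec, stem) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  sidecar <- list(
    srate = rec$srate,
    n_channels = nrow(rec$data),
    n_samples = ncol(rec$data),
    channel_names = rec$channel_names,
    positions = if (is.null(rec$layout)) NULL else
      lapply(seq_len(nrow(rec$layout)), function(i) unname(rec$layout[i, ])),
    events = lapply(seq_len(nrow(rec$events)), function(i)
      list(sample = rec$events$sample[i],
           stimulus_id = rec$events$stimulus_id[i]))
  )
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

read_packed <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"))
  nc <- side$n_channels; ns <- side$n_samples
  con <- file(paste0(stem, ".dat"), "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = nc * ns + 1L, size = 4,
                  endian = "little")
  if (length(vals) != nc * ns)
    stop_eegr(sprintf(
      "packed array holds %d values but the sidecar declares %d channels x %d samples",
      length(vals), nc, ns), class = "eegretrieve_format_error")
  layout <- if (length(side$positions))
    do.call(rbind, lapply(side$positions, unlist)) else NULL
  events <- if (length(side$events)) tibble::tibble(
    sample = vapply(side$events, function(e) as.integer(e$sample), integer(1)),
    stimulus_id = vapply(side$events, function(e) as.character(e$stimulus_id),
                         character(1))
  ) else NULL
  eeg_recording(matrix(vals, nc, ns), side$srate,
                unlist(side$channel_names), layout, events)
}

# BrainVision: INI-style .vhdr, .vmrk markers, binary .eeg payload
# (multiplexed int16 or float32). Positions are not part of the format and
# are left NULL; spherical-spline stages then refuse to run with a clear
# message.
read_brainvision <- function(vhdr_path) {
  lines <- readLines(vhdr_path, warn = FALSE)
  getval <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^", key, "="), "", hit[1])
  }
  datafile <- getval("DataFile")
  mrkfile <- getval("MarkerFile")
  nc <- as.integer(getval("NumberOfChannels"))
  interval_us <- as.numeric(getval("SamplingInterval"))
  srate <- 1e6 / interval_us
  fmt <- getval("BinaryFormat")
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  channel_names <- vapply(parts, `[`, character(1), 1)
  resol <- vapply(parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, numeric(1))
  dir <- dirname(vhdr_path)
  con <- file(file.path(dir, datafile), "rb")
  on.exit(close(con))
  if (identical(fmt, "IEEE_FLOAT_32")) {
    raw_vals <- readBin(con, numeric(), n = file.size(file.path(dir, datafile)) / 4,
                        size = 4, endian = "little")
  } else {
    raw_vals <- readBin(con, integer(), n = file.size(file.path(dir, datafile)) / 2,
                        size = 2, endian = "little")
  }
  ns <- length(raw_vals) %/% nc
  data <- matrix(raw_vals[seq_len(nc * ns)], nrow = nc) * resol
  events <- NULL
  if (!is.na(mrkfile) && file.exists(file.path(dir, mrkfile))) {
    mlines <- grep("^Mk[0-9]+=", readLines(file.path(dir, mrkfile),
                                           warn = FALSE), value = TRUE)
    mk <- strsplit(sub("^Mk[0-9]+=", "", mlines), ",")
    stim <- vapply(mk, function(m) identical(m[1], "Stimulus"), logical(1))
    events <- tibble::tibble(
      sample = vapply(mk[stim], function(m) as.integer(m[3]), integer(1)),
      stimulus_id = vapply(mk[stim], `[`, character(1), 2))
  }
  eeg_recording(data, srate, channel_names, NULL, events)
}

# EDF: 256-byte ASCII header + per-signal headers, int16 records. Annotation
# channels are not parsed; events must come from a sidecar when using EDF.
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, raw(), n)))
  rd(8); rd(80); rd(80); rd(8); rd(8)          # version, ids, date, time
  as.integer(rd(8))                             # header bytes
  rd(44)
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)                 # transducer
  for (i in seq_len(ns)) rd(8)                  # physical dim
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)                 # prefiltering
  nsamp <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)                 # reserved
  if (length(unique(nsamp)) != 1)
    stop_eegr("EDF with per-signal sampling rates is not supported",
              class = "eegretrieve_format_error")
  srate <- nsamp[1] / record_dur
  data <- matrix(0, ns, n_records * nsamp[1])
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, integer(), n = nsamp[s], size = 2, endian = "little")
      phys <- (dig - dmin_[s]) * (pmax_[s] - pmin_[s]) / (dmax_[s] - dmin_[s]) +
        pmin_[s]
      data[s, ((r - 1) * nsamp[s] + 1):(r * nsamp[s])] <- phys
    }
  }
  eeg_recording(data, srate, labels, NULL, NULL)
}

#' Load an EEG recording, auto-detecting the format
#'
#' Supports the packed float32 + JSON sidecar format (pass the `.json` or
#' `.dat` path or the bare stem), BrainVision (`.vhdr`) and EDF (`.edf`).
#' BrainVision and EDF carry no 3-D sensor positions, so stages that need
#' spherical-spline interpolation will refuse to run until a layout is
#' attached.
#'
#' @param path Path to the recording (format by extension).
#' @return An `eeg_recording`.
#' @export
load_recording <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "vhdr" = read_brainvision(path),
    "edf" = read_edf(path),
    "json" = ,
    "dat" = read_packed(sub("\\.(json|dat)$", "", path)),
    read_packed(path))
}

require_layout <- function(obj, what) {
  if (is.null(obj$layout))
    stop_eegr(paste0(what, " needs 3-D sensor positions, but the recording ",
                     "has none (e.g. loaded from BrainVision/EDF). Attach a ",
                     "layout matrix first."),
              class = "eegretrieve_layout_error")
  invisible(obj$layout)
}
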