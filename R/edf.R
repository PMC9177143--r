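#' Write a continuous multichannel recording to an EDF file
#'
#' Minimal European Data Format (EDF) writer for continuous recordings in
#' which every channel shares one sampling rate. Samples are quantised to
#' 16-bit integers over a symmetric physical range spanning the data, so a
#' write-then-read round trip reproduces the signal up to quantisation error
#' (half of one least-significant bit, i.e. `phys_range / 65534`).
#'
#' @param path output file path.
#' @param data numeric matrix, samples x channels, in microvolts.
#' @param fs sampling rate in Hz; must be a positive integer (EDF data
#'   records of 1 s are written, the last record zero-padded).
#' @param channel_labels character vector, one label per column of `data`.
#' @param phys_dim physical dimension string stored per channel (default
#'   `"uV"`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, data, fs, channel_labels, phys_dim = "uV") {
  data <- as.matrix(data)
  ns <- ncol(data)
  stopifnot(length(channel_labels) == ns, fs > 0, fs == round(fs))
  if (!all(is.finite(data))) stop("non-finite samples cannot be written to EDF")

  spr <- as.integer(fs)                      # samples per 1-s record
  n_rec <- as.integer(ceiling(nrow(data) / spr))
  pad <- n_rec * spr - nrow(data)
  if (pad > 0) data <- rbind(data, matrix(0, pad, ns))

  # round the physical range to what fits the 8-char header field, so the
  # reader rescales with exactly the written calibration
  amax <- as.numeric(formatC(max(abs(data), 1e-6) * 1.001, format = "g",
                             digits = 6))
  phys_min <- -amax
  phys_max <- amax
  dig_min <- -32767L
  dig_max <- 32767L

  pad_field <- function(x, width) {
    x <- substr(format(x, trim = TRUE), 1L, width)
    formatC(x, width = width, flag = "-")
  }
  num_field <- function(x, width)
    pad_field(trimws(formatC(x, format = "g", digits = 6)), width)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(paste0(s, collapse = ""), con, eos = NULL)

  wr(pad_field("0", 8))                              # version
  wr(pad_field("synthetic subject", 80))             # patient id
  wr(pad_field("swcoupling recording", 80))          # recording id
  wr(pad_field("01.01.00", 8))                       # start date
  wr(pad_field("00.00.00", 8))                       # start time
  wr(num_field(256L * (ns + 1L), 8))                 # header bytes
  wr(pad_field("", 44))                              # reserved
  wr(num_field(n_rec, 8))
  wr(num_field(1L, 8))                               # record duration (s)
  wr(num_field(ns, 4))

  wr(pad_field(channel_labels, 16))
  wr(pad_field(rep("", ns), 80))                     # transducer
  wr(pad_field(rep(phys_dim, ns), 8))
  wr(num_field(rep(phys_min, ns), 8))
  wr(num_field(rep(phys_max, ns), 8))
  wr(num_field(rep(dig_min, ns), 8))
  wr(num_field(rep(dig_max, ns), 8))
  wr(pad_field(rep("", ns), 80))                     # prefiltering
  wr(num_field(rep(spr, ns), 8))
  wr(pad_field(rep("", ns), 32))                     # reserved

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  dig <- round((data - phys_min) * scale) + dig_min
  dig <- pmin(pmax(dig, dig_min), dig_max)
  # record-major interleaving: record 1 channel 1..ns, record 2 ...
  arr <- array(as.integer(dig), dim = c(spr, n_rec, ns))
  writeBin(as.integer(aperm(arr, c(1, 3, 2))), con, size = 2L,
           endian = "little")
  invisible(path)
}

#' Read an EDF file
#'
#' Minimal EDF reader for continuous recordings whose channels share a
#' common sampling rate (the format written by [write_edf()] and by most
#' polysomnographs for EEG-only montages). Digital values are rescaled to
#' physical units using the per-channel calibration fields.
#'
#' @param path EDF file path.
#' @return list with `data` (samples x channels matrix, physical units),
#'   `fs` (Hz), `channel_labels`, `phys_dim`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    raw <- readBin(con, "raw", width)
    trimws(rawToChar(raw))
  }
  version <- rd(8)
  if (version != "0") stop("not an EDF file (version field '", version, "'): ", path)
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header: ", path)

  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  dims <- vapply(seq_len(ns), function(i) rd(8), "")
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  stopifnot(256L * (ns + 1L) == header_bytes)
  if (length(unique(spr)) != 1L)
    stop("mixed per-channel sampling rates are not supported")

  total <- n_rec * sum(spr)
  dig <- readBin(con, "integer", n = total, size = 2L, signed = TRUE,
                 endian = "little")
  arr <- array(dig, dim = c(spr[1], ns, n_rec))
  data <- matrix(0, spr[1] * n_rec, ns)
  for (j in seq_len(ns)) {
    x <- as.numeric(arr[, j, ])
    data[, j] <- (x - dig_min[j]) * (phys_max[j] - phys_min[j]) /
      (dig_max[j] - dig_min[j]) + phys_min[j]
  }
  colnames(data) <- labels
  list(data = data, fs = spr[1] / rec_dur, channel_labels = labels,
       phys_dim = dims)
}
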