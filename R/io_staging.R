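#' Construct an EEG recording object
#'
#' @param data numeric matrix (samples x channels) in microvolts, or a
#'   numeric vector for a single channel.
#' @param fs sampling rate, Hz.
#' @param channel_labels one label per channel (e.g. `"F3"`, `"Fz"`, `"F4"`).
#' @param reference_note free-text note on the reference montage.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels, reference_note = "") {
  if (is.vector(data)) data <- matrix(data, ncol = 1)
  data <- as.matrix(data)
  stopifnot(is.numeric(fs), fs > 0, ncol(data) == length(channel_labels))
  colnames(data) <- channel_labels
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels),
                 reference_note = reference_note),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) [%s], %.1f s at %g Hz\n",
              length(x$channel_labels),
              paste(x$channel_labels, collapse = ", "),
              nrow(x$data) / x$fs, x$fs))
  invisible(x)
}

#' Read an EEG recording from disk
#'
#' Reads either an EDF file or the package's plain-text format (a TSV whose
#' first line is `# fs=<Hz>`, followed by a header row of channel labels and
#' one row per sample, in microvolts). Channel label matching is
#' case-insensitive. When both mastoid channels (M1/M2 or A1/A2) are present
#' the requested channels are re-referenced to the mastoid mean; otherwise
#' signals are returned as stored.
#'
#' @param path file path (`.edf` or text).
#' @param wanted_channels channel labels to return, in order.
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, wanted_channels) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    edf <- read_edf(path)
    data <- edf$data
    labels <- edf$channel_labels
    fs <- edf$fs
  } else {
    first <- readLines(path, n = 1)
    if (!grepl("^#\\s*fs\\s*=", first))
      stop("unreadable recording format (expected EDF or '# fs=<Hz>' TSV): ",
           path)
    fs <- as.numeric(sub("^#\\s*fs\\s*=\\s*", "", first))
    tab <- utils::read.delim(path, skip = 1, check.names = FALSE)
    data <- as.matrix(tab)
    labels <- colnames(tab)
  }
  idx <- match(tolower(wanted_channels), tolower(labels))
  if (anyNA(idx)) {
    missing <- wanted_channels[is.na(idx)]
    stop("channel(s) not present in recording: ",
         paste(missing, collapse = ", "))
  }
  mast <- match(c("m1", "m2"), tolower(labels))
  if (anyNA(mast)) mast <- match(c("a1", "a2"), tolower(labels))
  ref_note <- "as stored (no mastoid re-referencing applied)"
  out <- data[, idx, drop = FALSE]
  if (!anyNA(mast)) {
    out <- out - rowMeans(data[, mast, drop = FALSE])
    ref_note <- "re-referenced to the mastoid mean at load"
  }
  eeg_recording(out, fs, wanted_channels, ref_note)
}

#' Construct a hypnogram
#'
#' @param stages ordered character vector of 30-s epoch stage labels, each in
#'   `W`, `N1`, `N2`, `N3`, `R`.
#' @param epoch_length epoch length in seconds (30 by convention).
#' @param start_offset seconds between recording start and the first epoch.
#' @return object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_length = 30, start_offset = 0) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), c("W", "N1", "N2", "N3", "R"))
  if (length(bad) > 0)
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  stopifnot(epoch_length > 0, start_offset >= 0)
  structure(list(stages = stages, epoch_length = epoch_length,
                 start_offset = start_offset),
            class = "hypnogram")
}

#' Read a hypnogram from a two-column TSV (epoch index, stage label)
#'
#' @param path TSV path; a header row is expected.
#' @inheritParams hypnogram
#' @return a [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_length = 30, start_offset = 0) {
  tab <- utils::read.delim(path)
  if (ncol(tab) < 2) stop("hypnogram TSV needs two columns (epoch, stage)")
  tab <- tab[order(tab[[1]]), ]
  hypnogram(tab[[2]], epoch_length = epoch_length,
            start_offset = start_offset)
}

#' Read artifact/arousal mask events from TSV (onset_s, duration_s, kind)
#'
#' @param path TSV path with header `onset_s`, `duration_s`, `kind`.
#' @return data.frame with columns `onset`, `duration`, `kind`.
#' @export
read_mask_events <- function(path) {
  tab <- utils::read.delim(path)
  mask_events(tab$onset_s, tab$duration_s, tab$kind)
}

#' Build a mask-event table
#'
#' @param onset event onsets, seconds from recording start.
#' @param duration event durations, seconds (>= 0).
#' @param kind `"artifact"` or `"arousal"`.
#' @return data.frame with columns `onset`, `duration`, `kind`.
#' @export
mask_events <- function(onset = numeric(), duration = numeric(),
                        kind = character()) {
  stopifnot(length(onset) == length(duration), all(duration >= 0))
  data.frame(onset = as.numeric(onset), duration = as.numeric(duration),
             kind = as.character(kind))
}

#' Select artifact-free N2/N3 analysis segments
#'
#' Returns the sample intervals of every 30-s epoch staged N2 or N3 that does
#' not overlap any artifact/arousal event longer than 5 s. Events of 5 s or
#' shorter do not exclude an epoch; their samples are instead flagged so that
#' amplitude-percentile and band-power computations can skip them.
#'
#' Intervals are 1-based and half-open: `start` is the first sample inside
#' the epoch, `end` is one past the last.
#'
#' @param hypno a [hypnogram()].
#' @param masks a [mask_events()] data.frame (possibly empty).
#' @param fs sampling rate, Hz.
#' @param long_event_s events strictly longer than this (seconds) exclude the
#'   whole overlapped epoch; default 5.
#' @return object of class `analysis_segments`: list with `intervals`
#'   (data.frame `start`, `end`, half-open sample indices, disjoint and
#'   sorted), `flagged` (integer vector of sample indices inside the
#'   intervals to skip in percentile/power estimation), `fs`, and
#'   `n2n3_minutes` (total selected time, minutes).
#' @export
select_analysis_segments <- function(hypno, masks = mask_events(), fs,
                                     long_event_s = 5) {
  stopifnot(inherits(hypno, "hypnogram"), fs > 0)
  ep <- hypno$epoch_length
  n_ep <- length(hypno$stages)
  starts_s <- hypno$start_offset + (seq_len(n_ep) - 1) * ep
  ends_s <- starts_s + ep
  keep <- hypno$stages %in% c("N2", "N3")

  long <- masks[masks$duration > long_event_s, , drop = FALSE]
  short <- masks[masks$duration <= long_event_s & masks$duration > 0, ,
                 drop = FALSE]
  if (nrow(long) > 0) {
    for (i in seq_len(nrow(long))) {
      ov <- starts_s < long$onset[i] + long$duration[i] &
        ends_s > long$onset[i]
      keep <- keep & !ov
    }
  }
  idx <- which(keep)
  intervals <- data.frame(
    start = as.integer(round(starts_s[idx] * fs)) + 1L,
    end = as.integer(round(ends_s[idx] * fs)) + 1L
  )
  flagged <- integer(0)
  if (nrow(short) > 0 && nrow(intervals) > 0) {
    sel <- unlist(lapply(seq_len(nrow(intervals)),
                         function(i) intervals$start[i]:(intervals$end[i] - 1L)))
    for (i in seq_len(nrow(short))) {
      a <- as.integer(floor(short$onset[i] * fs)) + 1L
      b <- as.integer(ceiling((short$onset[i] + short$duration[i]) * fs)) + 1L
      flagged <- c(flagged, sel[sel >= a & sel < b])
    }
    flagged <- sort(unique(flagged))
  }
  if (nrow(intervals) == 0)
    warning("no artifact-free N2/N3 epochs selected")
  structure(list(intervals = intervals, flagged = flagged, fs = fs,
                 n2n3_minutes = nrow(intervals) * ep / 60),
            class = "analysis_segments")
}

#' Sleep macro-structure summary
#'
#' @param hypno a [hypnogram()].
#' @return list with `tst_minutes` (total sleep time: all non-wake epochs)
#'   and `stage_percent`, a named vector of each sleep stage's share of TST
#'   in percent.
#' @export
macro_summary <- function(hypno) {
  stopifnot(inherits(hypno, "hypnogram"))
  sleep <- hypno$stages[hypno$stages != "W"]
  tst_min <- length(sleep) * hypno$epoch_length / 60
  if (tst_min == 0) stop("all-wake hypnogram: TST is zero, percentages undefined")
  pct <- vapply(c(N1 = "N1", N2 = "N2", N3 = "N3", R = "R"),
                function(s) 100 * sum(sleep == s) / length(sleep), 0)
  list(tst_minutes = tst_min, stage_percent = pct)
}
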