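#' Phase on a slow wave at a given time (five-landmark convention)
#'
#' The slow-wave cycle is parameterised by five anchors: ignition at zero
#' microvolts = phase 0, maximum hyperpolarisation (negative peak) = pi/2,
#' up-going zero crossing = pi, maximum depolarisation (positive peak) =
#' 3pi/2, and termination at zero microvolts = 2pi. Between anchors the phase
#' is linear in time, which is the simplest monotone convention honouring all
#' five anchors and is robust to waveform noise.
#'
#' @param sw one slow-wave event (row of [detect_slow_waves()] output).
#' @param t time(s), seconds; must lie in `[sw$t_start, sw$t_end]`.
#' @return phase in radians, in `[0, 2*pi]`, monotone non-decreasing in `t`.
#' @export
sw_phase_at <- function(sw, t) {
  knots_t <- c(sw$t_start, sw$t_neg_peak, sw$t_mid_cross, sw$t_pos_peak,
               sw$t_end)
  if (any(diff(knots_t) <= 0))
    stop("degenerate slow wave: landmarks not strictly increasing")
  if (any(t < knots_t[1]) || any(t > knots_t[5]))
    stop("time outside the slow wave")
  stats::approx(knots_t, c(0, pi / 2, pi, 3 * pi / 2, 2 * pi), xout = t)$y
}

# inverse of sw_phase_at: time at which the wave reaches a given phase
sw_time_at_phase <- function(sw, phase) {
  stopifnot(all(phase >= 0), all(phase <= 2 * pi))
  knots_t <- c(sw$t_start, sw$t_neg_peak, sw$t_mid_cross, sw$t_pos_peak,
               sw$t_end)
  stats::approx(c(0, pi / 2, pi, 3 * pi / 2, 2 * pi), knots_t,
                xout = phase)$y
}

#' Match spindle onsets to co-occurring slow waves
#'
#' A coincidence is the ignition (onset) of a spindle within the time frame
#' of a slow wave on the same channel. Each spindle yields at most one
#' coupling event (slow waves on a channel never overlap by construction);
#' spindles matching no slow wave are uncoupled and yield nothing. Degenerate
#' slow waves with non-increasing landmarks are excluded from phase
#' assignment.
#'
#' @param spindles spindle event data.frame ([detect_spindles()] output).
#' @param sws slow-wave event data.frame from the same channel, classified
#'   (see [classify_switchers()]).
#' @return data.frame of coupling events: `spindle_id`, `sw_id` (row indices
#'   into the inputs), `channel`, `onset` (spindle ignition, s), `phase`
#'   (radians in `[0, 2*pi]`), `cos_phase`, `switcher`.
#' @export
match_spindles_to_sw <- function(spindles, sws) {
  empty <- data.frame(spindle_id = integer(), sw_id = integer(),
                      channel = character(), onset = numeric(),
                      phase = numeric(), cos_phase = numeric(),
                      switcher = character(), stringsAsFactors = FALSE)
  if (nrow(spindles) == 0 || nrow(sws) == 0) return(empty)
  rows <- list()
  for (i in seq_len(nrow(spindles))) {
    on <- spindles$onset[i]
    j <- which(sws$t_start <= on & on <= sws$t_end &
               sws$channel == spindles$channel[i])
    if (length(j) == 0) next
    j <- j[1]
    sw <- sws[j, ]
    if (any(diff(c(sw$t_start, sw$t_neg_peak, sw$t_mid_cross,
                   sw$t_pos_peak, sw$t_end)) <= 0)) next
    ph <- sw_phase_at(sw, on)
    rows[[length(rows) + 1]] <- data.frame(
      spindle_id = i, sw_id = j, channel = spindles$channel[i],
      onset = on, phase = ph, cos_phase = cos(ph),
      switcher = sw$switcher, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Per-subject coupling summary
#'
#' For each switcher type, computes the mean cosine of the spindle-onset
#' phase (arithmetic mean of cosines, the form entering the linear mixed
#' models) per channel and then averaged across channels, together with event
#' counts and coupling rates: the fraction of slow waves of that type
#' carrying a spindle and the fraction of all spindles coupled to that type.
#'
#' @param events coupling events ([match_spindles_to_sw()] output, pooled
#'   over the frontal channels of one subject).
#' @param sw_counts named vector/list with per-type slow-wave totals
#'   (`slow`, `fast`).
#' @param spindle_count total number of detected spindles.
#' @param subject_id identifier stored in the output.
#' @param circular_mean if TRUE, report the cosine of the circular mean phase
#'   instead of the mean of cosines.
#' @return data.frame with one row per switcher type: `subject_id`,
#'   `switcher`, `n_coupled`, `mean_cos_phase` (NA when no events, with a
#'   message), `coupling_rate_sw`, `coupling_rate_spindle`.
#' @export
subject_coupling_summary <- function(events, sw_counts, spindle_count,
                                     subject_id = "s1",
                                     circular_mean = FALSE) {
  out <- lapply(c("slow", "fast"), function(ty) {
    ev <- events[events$switcher == ty, , drop = FALSE]
    n <- nrow(ev)
    if (n == 0) {
      message("no coupled events for ", ty, " switchers in subject ",
              subject_id)
      mcp <- NA_real_
    } else {
      per_chan <- tapply(ev$phase, ev$channel, function(ph) {
        if (circular_mean) cos(atan2(mean(sin(ph)), mean(cos(ph))))
        else mean(cos(ph))
      })
      mcp <- mean(per_chan)
    }
    n_sw <- as.numeric(sw_counts[[ty]])
    data.frame(subject_id = subject_id, switcher = ty, n_coupled = n,
               mean_cos_phase = mcp,
               coupling_rate_sw = if (n_sw > 0) n / n_sw else NA_real_,
               coupling_rate_spindle =
                 if (spindle_count > 0) n / spindle_count else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Coupling-rate bookkeeping from event counts
#'
#' Given per-type slow-wave totals, per-type coupled counts and the spindle
#' total, returns the percentage of each slow-wave type carrying a spindle
#' and the percentage of spindles coupled to any/each slow-wave type,
#' rounded to whole percent as conventionally reported.
#'
#' @param n_sw named list/vector: total slow waves per type (`slow`, `fast`).
#' @param n_coupled named list/vector: coupled counts per type.
#' @param n_spindles total number of spindles detected.
#' @return list with `pct_sw_coupled` (per type), `pct_spindles_coupled`
#'   (`any`, `slow`, `fast`) and `total_coupled`.
#' @export
coupling_bookkeeping <- function(n_sw, n_coupled, n_spindles) {
  total <- as.numeric(n_coupled[["slow"]]) + as.numeric(n_coupled[["fast"]])
  list(
    pct_sw_coupled = c(
      slow = round(100 * as.numeric(n_coupled[["slow"]]) /
                     as.numeric(n_sw[["slow"]])),
      fast = round(100 * as.numeric(n_coupled[["fast"]]) /
                     as.numeric(n_sw[["fast"]]))),
    pct_spindles_coupled = c(
      any = round(100 * total / n_spindles),
      slow = round(100 * as.numeric(n_coupled[["slow"]]) / n_spindles),
      fast = round(100 * as.numeric(n_coupled[["fast"]]) / n_spindles)),
    total_coupled = total)
}
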