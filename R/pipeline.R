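#' Default pipeline configuration
#'
#' Every default equals the study convention it implements: frontal channels
#' F3/Fz/F4; slow-wave band 0.3-4 Hz; sex-adapted amplitude criteria
#' (women: peak-to-peak >= 70 uV, negative peak <= -37 uV; men: >= 60.5 uV,
#' <= -32 uV); negative deflection 125-1500 ms, positive deflection <= 1000
#' ms; spindle band 10-16 Hz, envelope threshold at the 75th percentile,
#' duration 0.5-3 s; artifact/arousal events > 5 s exclude their epoch;
#' switcher threshold from the pooled two-Gaussian intersection initialised
#' at 1.2 Hz.
#'
#' @param ... named overrides of any default.
#' @return a named list of pipeline parameters.
#' @export
default_config <- function(...) {
  cfg <- list(
    channels = c("F3", "Fz", "F4"),
    sw_band = c(0.3, 4.0),
    p2p_min_female = 70, neg_amp_max_female = -37,
    p2p_min_male = 60.5, neg_amp_max_male = -32,
    neg_dur_range = c(0.125, 1.5),
    pos_dur_max = 1.0,
    spindle_band = c(10, 16),
    spindle_percentile = 75,
    spindle_dur_range = c(0.5, 3),
    smooth_win = 0.2,
    epoch_s = 30,
    mask_long_s = 5,
    switcher_scope = "pooled",
    switcher_init_split = 1.2,
    df_method = "Satterthwaite",
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Run the per-subject detection pipeline
#'
#' Segment selection, slow-wave detection, spindle detection and the
#' overnight band-power summary on every configured channel, with per-stage
#' event counts logged via `message()`.
#'
#' @param recording an [eeg_recording()] containing the configured channels.
#' @param hypno a [hypnogram()].
#' @param masks a [mask_events()] table.
#' @param sex `"female"` or `"male"` (selects slow-wave criteria).
#' @param config a [default_config()].
#' @param subject_id identifier carried into the outputs.
#' @return list of class `subject_result`: `sw_events`, `spindle_events`,
#'   `segments`, `band_summary`, `metrics` (one-row data.frame of counts,
#'   densities and the band-power ratio), `sex`, `subject_id`.
#' @export
run_subject <- function(recording, hypno, masks = mask_events(),
                        sex = c("female", "male"),
                        config = default_config(), subject_id = "s1") {
  sex <- match.arg(sex)
  stopifnot(inherits(recording, "eeg_recording"))
  idx <- match(tolower(config$channels), tolower(recording$channel_labels))
  if (anyNA(idx))
    stop("stage: channel check - recording lacks ",
         paste(config$channels[is.na(idx)], collapse = ", "))
  fs <- recording$fs
  segments <- select_analysis_segments(hypno, masks, fs,
                                       long_event_s = config$mask_long_s)
  if (nrow(segments$intervals) == 0)
    stop("stage: segment selection - no artifact-free N2/N3 epochs for ",
         subject_id)
  message(sprintf("[%s] %d N2/N3 epochs (%.1f min)", subject_id,
                  nrow(segments$intervals), segments$n2n3_minutes))
  crit <- sw_criteria(
    sex,
    p2p_min = if (sex == "female") config$p2p_min_female else config$p2p_min_male,
    neg_amp_max = if (sex == "female") config$neg_amp_max_female
                  else config$neg_amp_max_male,
    neg_dur_range = config$neg_dur_range,
    pos_dur_max = config$pos_dur_max)
  sw_all <- list()
  sp_all <- list()
  for (k in seq_along(idx)) {
    x <- recording$data[, idx[k]]
    filt <- fir_bandpass(x, fs, config$sw_band[1], config$sw_band[2])
    sw_all[[k]] <- detect_slow_waves(filt, fs, sex, segments,
                                     channel = config$channels[k],
                                     criteria = crit)
    sp_all[[k]] <- detect_spindles(x, fs, segments,
                                   channel = config$channels[k],
                                   percentile = config$spindle_percentile,
                                   dur_range = config$spindle_dur_range,
                                   smooth_win = config$smooth_win)
  }
  sw <- do.call(rbind, sw_all)
  sp <- do.call(rbind, sp_all)
  message(sprintf("[%s] detected %d slow waves, %d spindles", subject_id,
                  nrow(sw), nrow(sp)))
  band <- overnight_summary(
    eeg_recording(recording$data[, idx, drop = FALSE], fs, config$channels),
    segments, epoch_s = config$epoch_s)
  metrics <- data.frame(
    subject_id = subject_id, sex = sex,
    n2n3_minutes = segments$n2n3_minutes,
    n_sw = nrow(sw), n_spindles = nrow(sp),
    sw_density = sw_density(sw, segments$n2n3_minutes,
                            channels = config$channels)$total,
    spindle_density = spindle_density(sp, segments$n2n3_minutes,
                                      channels = config$channels),
    swe_delta = band$power[["delta"]],
    power_ratio = band$ratio_slow_fast,
    stringsAsFactors = FALSE)
  structure(list(sw_events = sw, spindle_events = sp, segments = segments,
                 band_summary = band, metrics = metrics, sex = sex,
                 subject_id = subject_id),
            class = "subject_result")
}

#' Run the cohort-level analysis
#'
#' Pools transition frequencies across subjects, fits the two-Gaussian
#' switcher model, classifies every slow wave, matches spindles to slow
#' waves per channel, summarises coupling per subject, fits the primary
#' amyloid-association mixed model with post-hoc per-type slopes, runs the
#' circular comparisons of onset-phase distributions, and (when memory
#' scores are present) the memory-change model.
#'
#' @param results list of `subject_result`s from [run_subject()].
#' @param covariates data.frame with one row per subject: `subject_id`,
#'   `age`, `sex`, `education`, `tst`, `centiloid`, optionally
#'   `rm_baseline`, `rm_followup`.
#' @param config a [default_config()].
#' @return list of class `cohort_report`: `switcher_model`, `coupling_long`
#'   (model table), `primary_fit`, `posthoc`, `bookkeeping`, `watson`
#'   (slow-vs-fast phase comparison), `uniformity` (per type), and
#'   `memory_fit` (or NULL).
#' @export
run_cohort <- function(results, covariates, config = default_config()) {
  if (length(results) < 10)
    stop("at least 10 subjects with complete recordings are required")
  need <- c("subject_id", "age", "sex", "tst", "centiloid")
  missing_cols <- setdiff(need, names(covariates))
  if (length(missing_cols) > 0)
    stop("covariate table lacks column(s): ",
         paste(missing_cols, collapse = ", "))

  tf <- unlist(lapply(results, function(r) r$sw_events$transition_freq))
  model <- fit_switcher_model(tf, init_split = config$switcher_init_split)
  message(sprintf("switcher threshold: %.3f Hz (pooled, %d waves)",
                  model$threshold, length(tf)))

  phases <- list(slow = numeric(), fast = numeric())
  long_rows <- list()
  n_coupled <- c(slow = 0, fast = 0)
  n_sw_tot <- c(slow = 0, fast = 0)
  n_spindle_tot <- 0
  for (r in results) {
    sw <- classify_switchers(r$sw_events, model)
    events <- do.call(rbind, lapply(unique(sw$channel), function(ch) {
      match_spindles_to_sw(
        r$spindle_events[r$spindle_events$channel == ch, , drop = FALSE],
        sw[sw$channel == ch, , drop = FALSE])
    }))
    if (is.null(events)) events <- match_spindles_to_sw(r$spindle_events[0, ], sw[0, ])
    counts <- c(slow = sum(sw$switcher == "slow"),
                fast = sum(sw$switcher == "fast"))
    n_sw_tot <- n_sw_tot + counts
    n_spindle_tot <- n_spindle_tot + nrow(r$spindle_events)
    n_coupled <- n_coupled + c(slow = sum(events$switcher == "slow"),
                               fast = sum(events$switcher == "fast"))
    for (ty in c("slow", "fast"))
      phases[[ty]] <- c(phases[[ty]], events$phase[events$switcher == ty])
    summ <- suppressMessages(
      subject_coupling_summary(events, as.list(counts),
                               nrow(r$spindle_events), r$subject_id))
    dur <- tapply(sw$duration, sw$switcher, mean)
    summ$sw_duration <- as.numeric(dur[summ$switcher])
    long_rows[[length(long_rows) + 1]] <- summ
  }
  long <- do.call(rbind, long_rows)
  long <- merge(long, covariates, by = "subject_id")
  bookkeeping <- coupling_bookkeeping(as.list(n_sw_tot),
                                      as.list(n_coupled), n_spindle_tot)

  primary <- fit_primary_model(
    long[stats::complete.cases(long[, c("mean_cos_phase", "sw_duration")]), ],
    df_method = config$df_method)
  ph <- posthoc_slopes(primary)

  watson <- if (min(lengths(phases)) >= 2)
    watson_u2(phases$slow, phases$fast, seed = config$seed) else NULL
  unif <- lapply(phases, function(v) {
    if (length(v) < 2) return(NULL)
    uniformity_by_reference(v, range = range(v), n_reps = 1,
                            seed = config$seed)
  })

  memory_fit <- NULL
  if (all(c("rm_baseline", "rm_followup") %in% names(covariates))) {
    slow_rows <- long[long$switcher == "slow", ]
    tab <- slow_rows[!is.na(slow_rows$rm_followup), ]
    if (nrow(tab) >= 10 && "education" %in% names(tab)) {
      tab$memory_decline <- memory_decline(tab$rm_baseline, tab$rm_followup)
      tab$sex <- factor(tab$sex, levels = c("female", "male"))
      memory_fit <- fit_mixed_model(
        memory_decline ~ mean_cos_phase + age + sex + education, tab)
    }
  }
  structure(list(switcher_model = model, coupling_long = long,
                 primary_fit = primary, posthoc = ph,
                 bookkeeping = bookkeeping, watson = watson,
                 uniformity = unif, memory_fit = memory_fit),
            class = "cohort_report")
}
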