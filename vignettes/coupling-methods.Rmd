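---
title: "Slow-wave/spindle coupling: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slow-wave/spindle coupling: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swcoupling)
```

This vignette is the package's account of its science: the detection and
coupling conventions, the statistical models, what the synthetic-data
generator does and does not emulate, and the choices made where the design
was genuinely open. It states no empirical result that the test suite and
the analysis scripts do not themselves compute.

## Segment selection

All detections run on 30-s epochs staged N2 or N3. An artifact or arousal
event **strictly longer than 5 s** excludes every epoch it overlaps; shorter
events leave their epoch in the analysis but flag their own samples, which
are then skipped when estimating the spindle-envelope percentile and the
per-epoch band powers. The epoch-level reading of the exclusion rule is a
design choice: it preserves contiguous waveforms for event detection (a
wave cannot straddle a hole in the signal) while still honouring the
duration rule; the alternative — masking only the overlapped samples — would
cut waves in half around every long artifact. The boundary is strict:
a 5.000-s event never excludes an epoch, a 5.001-s event does, and the test
suite pins this.

Sample intervals are 1-based and half-open (`start` inclusive, `end`
exclusive), the R-native analogue of the usual half-open convention; all
event times are kept in seconds from recording start and converted to
samples only at the edges.

## Slow-wave detection

The signal is band-passed 0.3–4 Hz with a windowed-sinc (Hamming) linear
phase FIR filter, applied with group-delay compensation so events keep
their timing. The default order is `3.3 fs / tw` with transition width
`tw = min(low, (high − low)/2)` — about 2200 taps for the slow-wave band at
200 Hz — which keeps the attenuation at the stated band edges near the
half-power point.

Candidate waves are **negative-then-positive half-wave pairs between zero
crossings**: a down-going crossing starts the wave, an up-going crossing
separates the hyperpolarised from the depolarised deflection, and the next
down-going crossing ends it. Crossing times are interpolated linearly
between samples. Two refinements matter in practice:

* **Zero plateaus.** In synthetic, noise-free signal a wave is surrounded
  by exact zeros. A run of zero samples separating opposite signs yields a
  *reach* time (where the signal attains zero — the end of the previous
  wave) and a *leave* time (where it departs — the start of the next). For
  noisy signal with isolated exact zeros the two coincide and the behaviour
  reduces to the usual sign-change rule.
* **Wiggle merging.** Crossing pairs delimiting half-waves shorter than
  100 ms are treated as noise wiggles around zero and removed (iteratively,
  nearest pair first). In a 0.3–4 Hz signal a genuine half-wave lasts at
  least 125 ms by the detection criteria themselves, so the 100-ms floor
  removes only sub-criterion structure; without it, a single noise wiggle
  at a zero crossing splits an otherwise valid wave into two rejected
  fragments.

A candidate is kept iff all four criteria hold: peak-to-peak amplitude and
negative-peak amplitude at the sex-adapted thresholds (women ≥ 70 µV and
≤ −37 µV; men ≥ 60.5 µV and ≤ −32 µV — the published criteria adapted for
older adults from the standard 75/−40 µV), negative deflection within
125–1500 ms, positive deflection ≤ 1000 ms. Only sex-specific thresholds
are implemented; all four values are configurable parameters
(`sw_criteria()`), so an age adaptation can be expressed by overriding
them.

## Transition frequency and the switcher split

The transition from the down-state (negative peak) to the up-state
(positive peak) spans half an oscillation cycle, so its characteristic
frequency is taken as

  f_T = 1 / (2 · (t_pos_peak − t_neg_peak)).

The half-cycle convention is a deliberate decision: with it, a symmetric
slow-switcher wave of total duration 906 ms has f_T = 1/(2·0.453) ≈ 1.10 Hz,
matching the transition-frequency scale on which the slow/fast split and
its ~1.2 Hz threshold are defined; the literal reading 1/Δt would place the
same wave at 2.2 Hz and make the threshold meaningless.

The slow/fast split fits a two-component univariate Gaussian mixture to the
pooled transition frequencies by EM (initialised deterministically by
splitting at 1.2 Hz, tolerance 1e-8, at most 500 iterations — no random
state, so the fit is reproducible by construction). The classification
threshold is the root of w₁N(μ₁,σ₁²) = w₂N(μ₂,σ₂²) strictly between the two
means, obtained from the quadratic in x given by equating log-densities. A
wave exactly at the threshold is labelled *fast*; the event has measure
zero and the rule is stable. Pooling across subjects is the default scope
(matching a pooled cohort distribution); per-subject fits are possible by
calling `fit_switcher_model()` on one subject's waves. mclust's EM serves
as an independent cross-check of the mixture fit in the test suite, never
as the implementation.

## Spindle detection

The raw channel is band-passed 10–16 Hz, the modulus of the analytic signal
(FFT Hilbert construction) is smoothed with a centred 0.2-s moving average,
and the threshold is the 75th percentile of the smoothed envelope over all
non-flagged samples of the analysis segments of that channel and recording.
Maximal supra-threshold runs lasting 0.5–3 s are spindles; the onset
("ignition") is the first supra-threshold sample. Open conventions were
resolved as follows, each exposed as a parameter:

* smoothing window 0.2 s — shorter than the minimum spindle (0.5 s), longer
  than one 13 Hz cycle;
* percentile population: per channel, over artifact-free N2/N3 samples of
  the same recording;
* runs longer than 3 s are discarded entirely (not truncated), runs are
  never merged across sub-threshold gaps, and runs cut by the edge of a
  contiguous block of selected epochs are discarded;
* `threshold` can override the percentile with an absolute µV value — a
  percentile threshold is *relative by construction* (it marks 25 % of any
  input, even event-free noise), so detector audits on event-free signal
  use a threshold calibrated on a reference recording.

A percentile threshold also fixes a scale relationship worth stating: if
spindles are detected at ~8/min with a 75th-percentile threshold, supra-
threshold time is ~25 % of the night and the mean detected event must last
roughly 0.25 × 60/8 ≈ 1.8 s. The synthetic generator respects this
arithmetic (durations ~U(1.3, 2.3) s at 8/min), which is also what places
the threshold in the sparse region between the background-envelope and
spindle-envelope distributions — the regime in which a percentile detector
is sharp.

## Coupling phase

A coincidence is the ignition of a spindle inside a slow wave's time frame
on the same channel; each spindle couples to at most one wave (waves never
overlap per channel). The onset phase uses five anchors — ignition 0,
maximum hyperpolarisation π/2, up-going zero crossing π, maximum
depolarisation 3π/2, termination 2π — with **linear interpolation in time**
between anchors: the simplest monotone convention honouring all anchors.
A waveform-based alternative (arcsine of normalised amplitude) was rejected
as noise-sensitive near the peaks. Degenerate waves with non-increasing
landmarks are excluded from phase assignment.

The per-subject statistic is the **arithmetic mean of cosines** (per
channel, then averaged over F3/Fz/F4), matching a pipeline in which each
event's phase is converted to its cosine before entering linear models;
the cosine of the circular mean is available via
`subject_coupling_summary(circular_mean = TRUE)`. Whether events should
instead be pooled across channels before averaging is not determinable from
first principles; averaging per channel first keeps channels equally
weighted regardless of event counts.

## Circular statistics

The two-sample Watson U² is computed from the pooled ordering:
U² = nm/N² (Σd_k² − (Σd_k)²/N), with d_k the running difference of
cumulative fractions and cross-sample ties handled by averaging d over tied
groups (with a warning). The statistic is rotation-invariant and symmetric,
both pinned by property tests.

The asymptotic p-value uses the limiting distribution through the
Kolmogorov identity p = Q_K(π√U²), with the dual theta-series for small
values where the alternating series converges slowly. Because the
permutation null at small N is shifted relative to the limit — its exact
mean is (N+1)/(12N) against 1/12, and its variance is close to
(1/360)((N+1)/N)(1−4/N) against 1/360 — the statistic is first mapped onto
the limiting distribution by a two-moment correction. The correction was
validated against a 9,999-permutation oracle: at n = m = 20 the corrected
asymptotic p agrees with the oracle within ±0.02 across von Mises test
cases, which the acceptance suite re-checks. The seeded label-permutation
method is exact up to Monte-Carlo error and is the automatic choice when
min(n, m) < 20.

Uniformity is tested by comparison against random uniform reference series
of the same size and range. The single-reference variant reproduces the
original procedure exactly but makes the p-value itself random, so the
multi-replicate mode (report per-replicate results and their median p) is
the recommended default in new analyses.

## Band power

Per 30-s epoch, power is the integral of the Hann-tapered periodogram over
the half-open band [lo, hi); the window-energy normalisation makes a
sinusoid of amplitude A contribute A²/2. "Cumulated" overnight power (the
slow-wave-energy convention) is the *sum* of per-epoch band powers across
artifact-free N2/N3 epochs — not a per-night normalisation; total sleep
time enters the downstream models as a covariate instead. Epochs containing
flagged artifact samples are skipped. Because the estimator convention
(taper, summation) is a choice, only scale-invariant downstream statistics
(the 0.5–1/1–4 Hz ratio, covariate-adjusted model effects) should be
compared across pipelines.

## Mixed models and effect sizes

The primary model is a Gaussian identity-link linear mixed model (REML):
the mixed-model framework is "generalised" in name only when the outcome is
a continuous, approximately normal cosine score, so no family switch is
automated; a normality check of the dependent variable is the analyst's
diagnostic. Fixed effects: SW type, Centiloid, their interaction, age,
sex (factor, female reference — an arbitrary but documented coding), TST in
minutes (standardisation optional, not applied), and per-type mean SW
duration; random intercept per subject. Denominator dfs use Kenward-Roger
where pbkrtest is available and Satterthwaite otherwise (for the balanced
two-row-per-subject design the two agree closely; the fit records which was
used). If the random intercept is singular, or the design has one row per
subject (the memory-change model), the fit falls back to OLS with type-III
F tests, which is also the correct limit: with zero subject variance the
mixed fixed-effect estimates coincide with OLS, a property the test suite
checks to 1e-6.

Effect sizes are semi-partial R²β* = (qF/ν)/(1 + qF/ν) from each effect's
F statistic and dfs — strictly increasing in F and mapping [0, ∞) onto
[0, 1). Post-hoc per-type amyloid slopes come from estimated marginal
trends with a Sidak family correction over the two slope tests (the role a
Tukey adjustment plays for a single pairwise set; with two levels the two
coincide in spirit, and emmeans declines "tukey" for non-pairwise
families). Outlier influence is leave-one-subject-out Cook's distance on
the fixed effects, D_i = Δβ' V⁻¹ Δβ / p, flagged above 1.

## The synthetic-data generator

The generator's defaults *are* the study conditions: 200 Hz frontal
channels (F3/Fz/F4, identical injected events, independent 1/f noise per
channel), ~7 SW/min split 70/30 between slow switchers (total duration
906 ms, 104 µV peak-to-peak, transition ≈ 1.1 Hz) and fast switchers
(670 ms, 94 µV, transition 2.0 Hz) with small per-wave jitter; ~8
spindles/min of 12–14 Hz and 1.3–2.3 s, a quarter of them placed on slow
switchers at von Mises(μ = 1.25π, κ = 4) onset phases (late depolarisation)
and a smaller fraction (8 %) on fast switchers with a diffuse preference
(κ = 0.8); pink (1/f) background at 15 µV RMS, giving in-band SNR well
above the ≥ 3 regime the recovery properties assume. The cohort generator
draws age 50–70, 68 % women, TST ~ N(392.8, 45.9²) min, education
~ N(15.2, 3²) years, a right-skewed lognormal Centiloid distribution
(median 10, log-SD 0.5 — no attempt to copy any unpublished distribution),
and generates the per-type coupling cosine as a linear function of
Centiloid (slow-type slope −0.0065, fast-type 0, subject SD 0.09, residual
SD 0.12 — a partial correlation near 0.26 at n = 100, i.e. the small-effect
regime the design targets) and memory decline from the centred slow-type
cosine (slope −0.45, residual SD 0.25, mean 0.07 so the baseline-to-follow-
up change is detectable at n = 66).

Waveforms are piecewise quarter-cosine segments through the five landmarks:
slope is maximal at the zero crossings (robust crossing detection) and zero
at the peaks, and landmark ground truth is exact by construction — filtered
impulses would have no exact landmarks to score against. Spindle bursts use
a Tukey (tapered-cosine, α = 0.1) envelope: waxing-waning in the middle but
fast-rising, so the envelope threshold crossing stays within one smoothing
window of the true ignition. Placements are snapped to the sample grid so
"within one sample" statements are exact. Phase-targeted spindles invert
the five-landmark phase map, and a property test confirms the realised
onset phase matches the request within one sample's phase increment.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: real sleep architecture (cycles, stage
transitions, REM dynamics), non-stationary background spectra, cardiac and
ocular artifacts (mask handling is exercised with synthetic mask events
instead), electrode-specific topography or travelling waves, and any
nonlinear coupling between background and events. Detector operating
characteristics on real recordings must be established against human
scoring, not against this simulator.

## Problem sizes and numerical conventions

The shipped tests and scripts use 5–10-minute recordings at 200 Hz, 12
simulated EEG subjects, cohorts of n = 100 with 1,000-replicate null
calibrations, and 9,999-permutation oracles — sizes chosen so the full
suite exercises every claim at meaningful power while running in minutes.
Key numerical conventions: EM tolerance 1e-8 on the log-likelihood with a
degeneracy guard at σ < 1e-4; EDF output quantised to 16 bits over a
symmetric physical range (round-trip error ≤ range/65534, and the
calibration fields are rounded *before* scaling so reader and writer agree
exactly); quantile type 7 (R default) for the envelope percentile; the
asymptotic Watson series truncated at k = 100 with the theta-dual below
λ = 1; p-values floored at the smallest positive double rather than 0.

## Known limitations

* The detectors implement one published convention per step; alternative
  conventions (peak-locked coupling, gap-merged spindle runs, per-stage
  percentiles) are out of scope.
* The asymptotic Watson correction is validated for min(n, m) ≥ 10; below
  that the permutation method is used automatically.
* Cook's distances refit the model once per subject and are O(n) lmer
  fits; for very large cohorts use the OLS fallback or subsample.
* EDF support covers continuous recordings with one sampling rate across
  channels (EDF+ annotations and discontinuous records are not parsed);
  the plain-text format is the escape hatch.
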