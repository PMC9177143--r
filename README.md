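# swcoupling

Sleep-EEG microstructure analysis for studies linking NREM slow-wave /
spindle coupling to amyloid burden and memory outcomes. The package is
aimed at sleep and ageing researchers who need the full analysis path from
raw frontal EEG to cohort-level mixed-model statistics, together with a
ground-truthed simulator that makes every stage testable without access to
patient recordings.

## What it computes

**Detection.** Slow waves (SW) are detected on the 0.3–4 Hz FIR-filtered
signal as negative-then-positive half-wave pairs between zero crossings,
with sex-adapted amplitude criteria (women: peak-to-peak ≥ 70 µV, negative
peak ≤ −37 µV; men: ≥ 60.5 µV, ≤ −32 µV), negative deflection 125–1500 ms
and positive deflection ≤ 1000 ms. Spindles are detected as 0.5–3 s runs of
the smoothed Hilbert envelope of the 10–16 Hz band above its 75th
percentile. Both run only on artifact-free N2/N3 30-s epochs (events > 5 s
exclude their epoch).

**Switcher classification.** Each SW carries a down-to-up *transition
frequency* f_T = 1 / (2 (t_up − t_down)), the frequency of the half-cycle
from the negative (down-state) to the positive (up-state) peak. Pooled
transition frequencies are fitted with a two-component Gaussian mixture by
EM, and the classification threshold is the intersection of the weighted
component densities: waves below it are *slow switchers*, above it *fast
switchers*.

**Coupling phase.** A spindle couples to a SW when its onset ("ignition")
falls inside the wave. The onset phase follows the five-landmark
convention — ignition 0, maximal hyperpolarisation π/2, mid zero crossing
π, maximal depolarisation 3π/2, termination 2π — interpolated linearly in
time between landmarks. Per subject and SW type the analysis statistic is
the mean of cos(phase).

**Statistics.** Two-sample Watson U² (asymptotic with a finite-sample
moment correction, or label-permutation) compares phase distributions;
uniformity is assessed against random uniform reference series. The
primary association model is a Gaussian linear mixed model,
`cos(phase) ~ SW type × Centiloid + age + sex + TST + SW duration +
(1 | subject)`, with Kenward-Roger or Satterthwaite denominator dfs,
semi-partial effect sizes R²β* = (qF/ν)/(1 + qF/ν), Sidak-adjusted
per-type amyloid slopes, and leave-one-subject-out Cook's distances.
Overnight slow-wave energy and the 0.5–1 / 1–4 Hz power ratio come from
Hann-tapered per-epoch periodograms.

**Simulation.** `generate_recording()` injects piecewise quarter-cosine
slow waves (landmarks exact by construction) and Tukey-enveloped spindle
bursts — optionally placed at a requested SW phase by inverting the phase
map — into 1/f background noise; `generate_cohort()` draws a study-scale
cohort table with designed amyloid and memory-decline associations. Both
are pure functions of their seed.

## Worked example

The numbered scripts under `analysis/` run the whole study design on
synthetic data (about 40 s in total):

```sh
Rscript analysis/01_simulate.R      # EDF recordings + cohort table
Rscript analysis/02_detect.R       # SW + spindle detection, densities
Rscript analysis/03_coupling.R     # switcher split, phases, Watson tests
Rscript analysis/04_cohort_models.R  # mixed models, effect sizes
```

Output of `03` and `04` on the default seed:

```
switcher threshold 1.339 Hz (components 1.09 and 1.75 Hz, weights 0.64/0.36)
43% of slow and 27% of fast switcher waves carry a spindle;
31% of spindles couple to any wave (23% slow, 8% fast), 447 coupled in total
slow vs fast onset-phase distributions: U2 = 1.334, p = 6.7e-12 (asymptotic)

per-type amyloid slopes (Sidak-adjusted):
 level     slope     se       df     t  p_adj
  slow -0.008730 0.0027 160.6634 -3.22 0.0031
  fast -0.000324 0.0027 161.0813 -0.12 0.9900

memory-decline model (decline ~ slow-switcher coupling cosine + covariates):
         effect     F df_num df_den     p r2_beta_star
 mean_cos_phase 10.47      1     61 0.002         0.15
```

Reading: the pooled transition-frequency mixture splits at 1.34 Hz; spindle
onset phases differ clearly between the two SW populations; the amyloid
association is carried by the slow switchers only (negative slope: higher
Centiloid, earlier spindle onset on the depolarisation rise), and the
slow-switcher coupling cosine predicts two-year memory decline. Event
tables and model summaries are written under `results/`.

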