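#!/usr/bin/env Rscript
# Simulate the study's raw materials: frontal sleep-EEG recordings with
# ground-truthed slow waves and spindles for a small EEG cohort, plus a
# study-scale (N = 100) cohort table carrying the designed amyloid and
# memory associations. Writes EDF recordings, hypnograms, ground truth and
# the cohort table under results/sim/.

suppressPackageStartupMessages(library(swcoupling))

seed <- 2026
n_eeg_subjects <- 12
duration_s <- 300          # 10 five-minute recordings keep the run short;
fs <- 200                  # detection behaviour is identical at full length

dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

manifest <- data.frame()
for (i in seq_len(n_eeg_subjects)) {
  s_seed <- seed + i
  rp <- subject_recipes(duration_s, seed = s_seed)
  g <- generate_recording(rp$sw_recipes, rp$spindle_recipes, duration_s,
                          fs = fs, seed = s_seed)
  id <- sprintf("sub%02d", i)
  edf <- file.path("results/sim", paste0(id, ".edf"))
  write_edf(edf, g$recording$data, fs, g$recording$channel_labels)
  hyp <- file.path("results/sim", paste0(id, "_hypnogram.tsv"))
  write.table(data.frame(epoch = seq_along(g$hypnogram$stages),
                         stage = g$hypnogram$stages),
              hyp, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(g$truth$sw, file.path("results/sim", paste0(id, "_truth_sw.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(g$truth$spindles,
              file.path("results/sim", paste0(id, "_truth_spindles.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- rbind(manifest,
                    data.frame(subject_id = id, edf = edf, hypnogram = hyp,
                               sex = ifelse(i %% 3 == 0, "male", "female"),
                               seed = s_seed))
}
write.table(manifest, "results/sim/manifest.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

co <- generate_cohort(cohort_truth(seed = seed))
write.csv(co$subjects, "results/sim/cohort_subjects.csv", row.names = FALSE)
write.csv(co$long, "results/sim/cohort_long.csv", row.names = FALSE)

cat(sprintf("simulated %d EEG subjects (%d s at %g Hz) and a %d-subject cohort table\n",
            n_eeg_subjects, duration_s, fs, nrow(co$subjects)))
cat(sprintf("cohort: %.0f%% women, mean TST %.1f min, median Centiloid %.1f\n",
            100 * mean(co$subjects$sex == "female"), mean(co$subjects$tst),
            median(co$subjects$centiloid)))
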