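#!/usr/bin/env Rscript
# Simulate a full-scale Stranger Test cohort.
#
# 50 overhead-tracked trials: 47 well-tracked (29 neutral, 18 towards) plus
# 3 deliberately under-tracked neutral trials that the 80% coverage gate
# should later remove, exercising the exclusion path end to end. Writes
# one detection JSON per trial plus ratings, C-BARQ profiles and the
# hidden truth table.

library(caninecoping)

out_dir <- "results/cohort"
cfg <- cohort_config(
  n_trials = 47,
  style_proportions = c(towards = 18 / 47, neutral = 29 / 47, away = 0),
  n_low_quality = 3,
  seed = 42)

cohort <- simulate_cohort(cfg)
write_cohort(cohort, out_dir)

cat(sprintf("simulated %d trials -> %s\n", length(cohort$trials), out_dir))
print(table(style = cohort$truth$style, low_quality = cohort$truth$low_quality))
cat(sprintf("trial durations: %.1f-%.1f s at %d fps\n",
            min(cohort$truth$duration), max(cohort$truth$duration),
            cfg$arena$fps))
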