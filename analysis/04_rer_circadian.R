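#!/usr/bin/env Rscript

# Circadian metabolic analysis: simulate the indirect-calorimetry cohort
# (n = 5 per group, 60 h in 30-min bins under a 12-h light/dark cycle),
# aggregate each subject's RER by cycle, and compare tumour vs sham per
# sex with the relative-change statistic plus the male-vs-female Welch
# test. Writes results/rer_comparison.csv and results/rer_subject_means.csv.

suppressPackageStartupMessages(library(mpmri))
dir.create("results", showWarnings = FALSE)

rec <- simulate_rer_cohort(n_per_group = 5, hours = 60, seed = 11)
out <- rer_day_night(rec)

write.csv(out$comparison, "results/rer_comparison.csv", row.names = FALSE)
write.csv(out$subject_means, "results/rer_subject_means.csv", row.names = FALSE)

cat("Day/night RER change of tumour groups vs sham (percent):\n")
print(out$comparison, digits = 3)
cat("\nGenerating offsets were day -4.85 (male) / -1.22 (female) and",
  "night -4.11 / -1.99.\n")
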