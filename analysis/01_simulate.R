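#!/usr/bin/env Rscript
# Simulate the working materials: a two-group adolescent cohort (86 girls,
# 80 boys) with the default per-group distribution of cardiac measures
# and symptom subscale totals, plus a pair of example ambulatory
# recordings (120 min, ~1.9% artifacts) in the plain-text IBI format.

library(hrvcc)

seed <- 20260929
dir.create("results", showWarnings = FALSE)

coh <- gen_cohort(seed = seed)
write.csv(coh, "results/cohort.csv", row.names = FALSE)
cat(sprintf("cohort: %d subjects (%d girls / %d boys), %.1f%% missing symptoms\n",
            nrow(coh), sum(coh$sex_code == 2), sum(coh$sex_code == 1),
            100 * mean(is.na(coh$depression))))

# two 120-minute example recordings: respiratory-modulated and
# long-range-correlated, both with occasional artifacts
rec1 <- gen_series("modulated", duration_minutes = 120, mean_ibi = 650,
                   hf_amp = 25, lf_amp = 12, noise_sd = 8,
                   artifact_rate = 0.02, seed = seed + 1,
                   subject_id = "example_modulated")
rec2 <- gen_series("fgn", duration_minutes = 120, mean_ibi = 660,
                   sd_ibi = 45, hurst = 0.9, artifact_rate = 0.02,
                   seed = seed + 2, subject_id = "example_fgn")
write_ibi_file(rec1, "results/example_modulated.ibi.txt")
write_ibi_file(rec2, "results/example_fgn.ibi.txt")
for (r in list(rec1, rec2))
  cat(sprintf("recording %s: %d intervals, %.1f min\n",
              r$subject_id, length(r$intervals), duration_minutes(r)))
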