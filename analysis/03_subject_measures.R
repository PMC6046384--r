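#!/usr/bin/env Rscript
# Extract the full per-subject measure set (time/frequency HRV, DFA,
# allometric FD, multiscale entropy) from the example recordings.

library(hrvcc)

files <- c("results/example_modulated.ibi.txt",
           "results/example_fgn.ibi.txt")
stopifnot(file.exists(files))

rows <- run_subjects(as.list(files))
write.csv(rows, "results/subject_measures.csv", row.names = FALSE)

for (i in seq_len(nrow(rows))) {
  r <- rows[i, ]
  cat(sprintf(paste0("%s: HR %.1f bpm, RMSSD %.1f ms, lnHF %.2f, ",
                     "alpha1 %.2f, alpha2 %.2f, FD %.3f, MSE(20) %.2f\n"),
              r$subject_id, r$hr, r$rmssd, r$ln_hf,
              r$dfa_alpha1, r$dfa_alpha2, r$fd, r$mse_s20))
}
cat("The long-range-correlated recording shows the higher DFA exponents;\n")
cat("the respiratory-modulated one carries its power in the HF band.\n")
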