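#!/usr/bin/env Rscript
# Preprocess the example recordings: trim 15 min from each end, apply
# the 400/1100 ms band filter and the 11-interval 20% central-window
# filter, and report the exclusions. A healthy ambulatory recording
# loses of the order of 2% of beats at this stage.

library(hrvcc)

files <- c("results/example_modulated.ibi.txt",
           "results/example_fgn.ibi.txt")
stopifnot(file.exists(files))

reports <- do.call(rbind, lapply(files, function(f) {
  cln <- preprocess(read_ibi_file(f))
  out <- sub("\\.ibi\\.txt$", ".nn.txt", f)
  write_ibi_file(cln, out)
  cat(sprintf("%s: kept %d of %d intervals (%.2f%% excluded) -> %s\n",
              cln$subject_id, cln$report$n_output, cln$report$n_input,
              100 * cln$report$excluded_fraction, out))
  cln$report
}))
write.csv(reports, "results/filter_reports.csv", row.names = FALSE)
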