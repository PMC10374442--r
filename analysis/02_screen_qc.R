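#!/usr/bin/env Rscript
# QC cascade on the simulated planted screen: blank correction, replicate
# spread, contamination, positional bias. Reports how many wells each
# filter removed and writes the corrected growth table plus the flag table.

library(syntroscreen)

cfg <- screen_config(seed = 20260929L)
tidy <- read_results("results/screen_tidy.csv")
conditions <- read_results("results/screen_conditions.csv")

qc <- screen_qc(tidy, conditions, cfg)
write_results(qc$growth, "results/screen_growth.csv", cfg)
write_results(qc$flags, "results/screen_qc_flags.csv", cfg)

cat("wells:", nrow(qc$growth), "\n")
cat("hard flags by filter:\n")
for (k in names(qc$counts)) cat(sprintf("  %-18s %d\n", k, qc$counts[[k]]))
cat("soft (neighborhood) warnings:",
    sum(qc$flags$severity == "warning"), "\n")
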