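#!/usr/bin/env Rscript
# Stage 3 - barrier metrics and group inference.
#
# From the fitted parameters: per-device R_b trajectories and fold-changes
# versus the t = 0 baseline, normalised 500 Hz impedance cross-sections,
# endpoint (24 h) fold-changes relative to the control arm, and the
# between-group statistics (Levene gate, one-way ANOVA, Tukey HSD) on the
# endpoint. Writes results/report/.

suppressPackageStartupMessages(library(barrierEIS))

res <- utils::read.csv("results/fits.csv", stringsAsFactors = FALSE)
out <- run_report(res, "results/dataset/manifest.json",
                  out_dir = "results/report")

message("endpoint (24 h) R_b fold-change vs control, mean +/- SD:")
print(out$endpoint$summary, row.names = FALSE, digits = 3)
message("")
print(out$report)
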