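#!/usr/bin/env Rscript
# Normalize the raw plate measurements: bead filter (>= 50 beads), loading
# control division, replicate median/SD, and per-analyte Hill scaling into
# [0.001, 0.999]. Writes the MIDAS training file.

suppressPackageStartupMessages(library(siglogic))

truth <- make_truth(n_nodes = 12, n_sentinels = 5, seed = 101)
raw <- read.csv("results/raw_measurements.csv", stringsAsFactors = FALSE)

ds <- normalize_dataset(raw, truth$design)
print(ds)
for (a in names(ds$hill)) {
  h <- ds$hill[[a]]
  cat(sprintf("  %-8s n = %5.2f  K = %8.3g  range %.3g..%.3g\n",
              a, h$n, h$K, h$minS, h$maxS))
}
to_midas(ds, "results/training_data.midas.csv")
cat("masked cells:", sum(is.na(ds$t1)), "of", length(ds$t1), "\n")
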