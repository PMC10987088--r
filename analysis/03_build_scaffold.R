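#!/usr/bin/env Rscript
# Preprocess the prior network into the trainable scaffold: designate
# measured/targeted nodes, compress uninformative species, screen the data
# for imputable co-regulations, and expand into AND/OR gates.

suppressPackageStartupMessages(library(siglogic))

truth <- make_truth(n_nodes = 12, n_sentinels = 5, seed = 101)
raw <- read.csv("results/raw_measurements.csv", stringsAsFactors = FALSE)
ds <- normalize_dataset(raw, truth$design)

# the distractor network (truth + decoys) plays the role of the curated PKN
pkn <- designate_nodes(truth$full_network, truth$design)
compressed <- compress(pkn, truth$design)
cat(sprintf("compressed: %d -> %d nodes, %d -> %d edges\n",
            nrow(pkn$nodes), nrow(compressed$nodes),
            nrow(pkn$edges), nrow(compressed$edges)))

imputed <- impute_data_edges(compressed, ds, r_threshold = 0.75)
cat(sprintf("imputed %d data-derived edge(s)\n", nrow(imputed)))
with_imputed <- add_edges(compressed, imputed)

scaffold <- expand(with_imputed, max_gate_inputs = 2)
print(scaffold)
write_scaffold_json(scaffold, "results/scaffold.json")
write_scaffold_sif(scaffold, "results/scaffold.sif")
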