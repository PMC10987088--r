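#!/usr/bin/env Rscript
# Train the model family with the genetic algorithm: 100 independent runs,
# keep the 20 best, report edge confidence, select the best model and its
# high-confidence submodel, and check how well the truth was recovered.
# (The study-scale setting is 1000 runs keeping 100; set SIGLOGIC_FULL=1.)

suppressPackageStartupMessages(library(siglogic))

truth <- make_truth(n_nodes = 12, n_sentinels = 5, seed = 101)
raw <- read.csv("results/raw_measurements.csv", stringsAsFactors = FALSE)
ds <- normalize_dataset(raw, truth$design)

full_scale <- identical(Sys.getenv("SIGLOGIC_FULL"), "1")
n_runs <- if (full_scale) 1000 else 100
keep <- if (full_scale) 100 else 20

fam <- build_family(truth$scaffold, ds, truth$design,
                    n_runs = n_runs, keep = keep, base_seed = 1000)
print(fam)
write_family_json(fam, "results/model_family.json")

conf <- edge_frequencies(fam)
write.table(data.frame(gate = names(conf), frequency = unname(conf)),
            "results/edge_confidence.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

best <- select_best(fam)
print(best)
hc <- high_confidence_submodel(best, conf, threshold = 0.4)
write_scaffold_sif(hc$scaffold, "results/best_model_hc.sif",
                   selection = hc$selection)

rec <- recovery_report(truth, conf, threshold = 0.4)
cat(sprintf("gate recovery vs truth: precision %.3f recall %.3f F1 %.3f\n",
            rec$precision, rec$recall, rec$f1))
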