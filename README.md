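# siglogic

Boolean logic models of intracellular signaling, trained on
cue–sentinel–response perturbation data and used for *in silico* drug
screens — built around the FLT3-ITD acute myeloid leukemia setting, where
the insertion domain of the receptor's internal tandem duplication (JMD =
juxtamembrane, sensitive; TKD1 = first tyrosine kinase domain, resistant)
determines the response to FLT3 inhibitors.

The package is for systems biologists who have (i) a curated signed causal
network (a prior knowledge network, PKN, e.g. exported from SIGNOR as a
SIF or causal TSV) and (ii) a multiplexed perturbation dataset (bead-array
median fluorescence intensities across stimulus/inhibitor combinations),
and who want executable, genotype-specific Boolean models plus the
downstream analyses those models enable: combinatorial knockout screens
with apoptosis/proliferation scoring, rescue calling against a sensitive
reference, and patient-specific simulations from binarized mutational
profiles.

## The model

A trained model is an AND/OR hypergraph over the network species: each
candidate gate is an AND of signed literals over a node's regulators
(every +1 input must be 1, every −1 input must be 0), a node's value is
the OR of its *selected* gates, and training chooses the selection
bitstring. States evolve synchronously under condition clamps until a
fixpoint (oscillating nodes are reported unresolved). A genetic algorithm
minimizes

    total = mse + na_penalty + size_penalty

where `mse` is the mean squared deviation between simulated sentinel
states and the measured values normalized into [0, 1] by per-analyte Hill
functions `y = x^n / (K + x^n)`, with `n` and `K` fixed by the boundary
conditions Hill(minS) = 0.001 and Hill(maxS) = 0.999 on each analyte's
observed range. Repeating the optimization yields a model family; per-gate
selection frequencies give edge confidence, and gates with frequency > 0.4
form the high-confidence model used for phenotype analysis.

## Worked example: the knockout screen on the demo model pair

`demo_model_pair()` ships a small synthetic sensitive/resistant pair. Both
share the receptor layer (FLT3 constitutive, IGF1R, TNFR) and a
proliferative PI3K→AKT→RPS6 arm; the pro-apoptotic endpoint BAD is
released by AKT inactivation alone in the sensitive model, but in the
resistant model BAD additionally requires TNFR-driven JNK to be off.

```r
library(siglogic)
dm <- demo_model_pair()
ep_s <- endpoint_regulators(dm$sensitive, dm$regulators)
ep_r <- endpoint_regulators(dm$resistant, dm$regulators)

ref <- run_condition(dm$sensitive, "FLT3i", ep_s)$scores
scr <- ko_screen(dm$resistant, ep_r)
scr
#>       condition target proliferation_activation apoptosis_inhibition
#> 1     untreated   <NA>                        1                    0
#> 2         FLT3i   <NA>                        0                    0
#> 3 FLT3i+IGF1RKO  IGF1R                        0                    0
#> 4   FLT3i+JNKKO    JNK                        0                   -1
#> 5  FLT3i+PI3KKO   PI3K                        0                    0
rescue_hits(scr, ref)
#> [1] "JNK"
```

Reading the numbers: untreated, the resistant model proliferates maximally
(+1) and suppresses apoptosis (inhibition 0 on a scale where −1 means
apoptosis fully engaged). FLT3 inhibition alone stops proliferation but
leaves apoptosis suppressed — the resistant phenotype. Only the JNK
knockout combined with FLT3 inhibition drives apoptosis_inhibition to −1,
the level the sensitive model reaches under FLT3 inhibition alone, so JNK
is the unique rescue hit at ε = 0.

## The analysis workflow

Numbered drivers under `analysis/` run the pipeline end to end on a
seeded synthetic ground truth and write their tables under `results/`:

1. `01_simulate_data.R` — ground-truth network + raw bead-array dataset
2. `02_normalize.R` — bead filter, loading control, Hill scaling, MIDAS
3. `03_build_scaffold.R` — compression, correlation imputation, AND/OR
   expansion
4. `04_train_models.R` — GA model family, edge confidence, best and
   high-confidence models, truth-recovery report
5. `05_ko_screen.R` — combinatorial knockout screen and rescue calls
6. `06_patients.R` — ITD classification, mutation binarization,
   per-patient simulation panels

`vignettes/logic-modeling-methods.Rmd` documents the methods, parameter
choices and limitations.

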