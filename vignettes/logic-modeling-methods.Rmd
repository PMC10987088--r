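---
title: "Training Boolean logic models of FLT3-ITD signaling from perturbation data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training Boolean logic models of FLT3-ITD signaling from perturbation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siglogic)
```

## The modeling problem

Acute myeloid leukemias driven by FLT3 internal tandem duplications (ITD)
respond differently to tyrosine kinase inhibitors depending on where the
duplication inserts: juxtamembrane-domain (JMD) insertions are sensitive,
insertions reaching into the first tyrosine kinase domain (TKD1) are
resistant. `siglogic` implements a pipeline that turns (i) a literature-
curated signed causal network (a prior knowledge network, PKN) and (ii) a
cue–sentinel–response perturbation dataset into genotype-specific Boolean
logic models, and then interrogates those models *in silico*: combinatorial
knockout screens with apoptosis/proliferation scoring, and patient-specific
simulations from binarized mutational profiles.

The pipeline stages map onto the package modules:

1. **Network I/O** — parse SIF / SIGNOR-style causal tables into a
   `causal_network`; parse phenotype-regulator tables.
2. **Data preparation** — bead filter, loading-control normalization,
   replicate aggregation, per-analyte Hill scaling, MIDAS serialization.
3. **Preprocessing** — compression, AND/OR expansion into a
   `scaffold_model`, correlation-based edge imputation.
4. **Boolean core** — synchronous simulation with steady-state and cycle
   detection, model fitness against the normalized data.
5. **Training** — genetic-algorithm model families, edge confidence,
   best-model and high-confidence-model selection.
6. **Phenotype screen** — endpoint regulators, phenotype scores, knockout
   screen, rescue calling.
7. **Patients** — ITD domain classification, mutation binarization, model
   matching, per-patient condition panels, expression z-scores.
8. **Synthetic data** — a ground-truth generator emulating the whole
   experimental design, so every stage is testable without external data.

## The experimental design being modeled

The training data come from a 16-condition perturbation panel: seven small
molecule inhibitors (a FLT3 inhibitor anchoring the panel, plus p38, JNK,
PI3K, mTOR, MEK1/2 and GSK3 inhibitors) combined with two stimuli — IGF1
activating the AKT/MAPK branch and TNFa the p38/JNK branch. Each pathway
inhibitor is paired with the stimulus of its branch, run with and without
the FLT3 inhibitor (except the GSK3 pairing, which is run only without),
and each stimulus and the FLT3 inhibitor are also run alone.
`flt3_design()` enumerates exactly this panel, in a deterministic order,
together with the 14 phospho-sentinel analytes and their activity
annotation (+1 when the measured site reports activation, −1 when it
reports inhibition, e.g. inhibitory GSK3 phosphosites). FLT3 itself is
marked *constitutive*: the ITD receptor is ligand-independent, so it is
clamped ON in every condition that does not inhibit it.

```{r}
d <- flt3_design()
d$conditions$name
```

## Normalization

Raw bead-array readouts are median fluorescence intensities (MFI) paired
with bead counts. The pipeline:

* drops measurements with fewer than 50 detected beads (a count of exactly
  50 is kept — exclusion is strictly below the threshold);
* divides each analyte by the loading-control channel (β-Tubulin by
  default) of the same well, masking wells whose control is missing;
* takes the median and sample SD (n−1) of the biological replicates;
* rescales each analyte with a Hill curve `y = x^n / (K + x^n)` fitted so
  the analyte's observed minimum maps to 0.001 and its observed maximum to
  0.999. With `b = maxS/minS`, the two boundary conditions give
  `n = log(((1 − minT)·maxT) / ((1 − maxT)·minT)) / log(b)` and
  `K = ((1 − maxT)/maxT)·maxS^n`. A range spanning 1–999 gives the
  closed-form `n = 2`, `K = 999`:

```{r}
h <- fit_hill_params(1:999)
c(n = h$n, K = h$K, at_max = apply_hill(h, 999), at_min = apply_hill(h, 1))
```

The Hill parameters are fitted per analyte on the pooled T0 and T1
condition medians: the experiment is designed so that each analyte's
dynamic range spans from inhibitor-suppressed minimum to
stimulus-saturated maximum, and pooling both timepoints anchors the fit on
exactly that range. Scaling is per cell line (each dataset is normalized
independently). The trainer fits the normalized T1 states; T0 is retained
only for the display quantity "activity modulation (T1 − T0)".

## From network to trainable scaffold

**Compression** removes species that are neither measured, nor targeted by
a cue, nor phenotypes: pass-through nodes are bypassed by connecting each
upstream/downstream pair with the product of the two edge signs; dangling
undesignated sources and sinks are deleted; the rule iterates to a
fixpoint. Two bounds keep this conservative: nodes with a self-loop are
never bypassed (the bypass rule is only sound for pass-through species),
and a node is bypassed only when in-degree × out-degree ≤ 4 — larger hubs
are kept rather than risking a quadratic edge blow-up. Parallel edges of
opposite sign produced by a bypass are both kept; the gate machinery
disambiguates them during training.

**Expansion** turns every node with regulator set *R* into OR branches
(one single-input gate per regulator) plus one AND gate per subset of
2..`max_gate_inputs` regulators, inheriting the edge signs as literals: a
gate fires when every +1 input is 1 and every −1 input is 0, and a node is
the OR over its *selected* gates. The default arity cap is 2 (configurable
to 4): pairwise AND co-regulation is the common convention in this model
class, and the cap bounds the search space the optimizer must cover.

**Imputation** adds co-regulations present in the data but absent from
prior knowledge: for every ordered pair of measured analytes with no
existing edge, the Pearson correlation of their normalized T1 profiles
across conditions is screened at |r| ≥ 0.75, and passing pairs become
candidate edges signed by the correlation. Cue on/off vectors are screened
the same way; a stimulus contributes edges from the stimulus node, a drug
from its *target* node with the sign flipped (drug applied means target
off). Imputed edges are tagged with `provenance = "imputed"` so they can
be ablated, and enter expansion exactly like curated edges.

## Simulation and fitness

The simulator is synchronous: all nodes update simultaneously, clamps
(stimuli ON, inhibited targets OFF, constitutive receptors ON unless
inhibited) are reapplied after every step, and the trajectory stops at a
fixpoint. If a state recurs with period > 1 the trajectory has entered a
limit cycle: nodes constant across the cycle keep their value, oscillating
nodes are reported *unresolved*. All non-clamped nodes start at 0 — the
inactive, serum-starved baseline; nodes with no selected gate hold their
initial value, so unclamped receptors behave as constants. The inner loop
is compiled (C++); the test suite checks it against a naive pure-R
trajectory oracle on randomized models.

Fitness of a gate selection is the mean squared deviation between
simulated sentinel states and normalized T1 values over unmasked cells.
Two additional terms are reported separately so pure-mse behavior is
recoverable by zeroing them: unresolved predictions contribute a penalty
`theta_na` (default 1) per affected cell instead of a squared deviation,
and a parsimony term `theta_size × selected-gate-inputs/total-gate-inputs`
(default `theta_size = 1e-4`) breaks ties toward smaller models — it is
orders of magnitude below one data point's contribution, so it never
overrides the fit, but it gives the optimizer a consistent preference
against redundant gates. Sentinels with activity annotation −1 are
compared against the complement of the simulated state.

## Genetic-algorithm training

The study-scale protocol trains a family of 1000 models and keeps the 100
best; the package's desk-scale default is 100 runs keeping 20, with the
full scale one flag away. Each run is an independent GA over the selection
bitstring: population 50, up to 200 generations, tournament selection
(size 3), uniform crossover, per-bit mutation 0.01, elitism 2, and an
early stop after 50 generations without improvement. These hyperparameters
are implementation choices sized so that a hundred runs on a ~30-node
scaffold complete in minutes; all are configurable through `ga_params()`.
The initial population is random at 50% density plus one all-ones
individual, so the full scaffold is always evaluated. Fitness evaluations
are memoized per bitstring, every run records its seed, and a rerun with
the same seed is bit-identical. On scaffolds small enough to enumerate,
the GA's optimum is tested to equal the exhaustive-search optimum.

Family post-processing: `edge_frequencies()` gives each gate's selection
fraction across the kept family; `select_best()` picks the lowest total
fitness (ties: fewer gates, then lexicographically smallest bitstring);
`high_confidence_submodel()` retains the best model's gates with frequency
strictly above 0.4 — strict, following the headline "frequency > 0.4"
rule, which at threshold 1 means even unanimous gates are dropped (the
boundary case is documented rather than special-cased).

## Phenotype scoring and the knockout screen

Phenotype inference uses only *endpoint* regulators: nodes annotated as
apoptosis or proliferation regulators that feed no selected gate in the
high-confidence model. Scores give equal weight to every endpoint (OR
logic): the raw score is the sum of activator states minus inhibitor
states, normalized by the endpoint count into [−1, 1] so models with
different endpoint counts are comparable. `apoptosis_inhibition` is the
*negative* of the normalized apoptosis score — high means apoptosis is
suppressed, i.e. tumor-like. Unresolved endpoints contribute 0.5, a
neutral imputation flagged in the output.

The screen simulates `untreated` (all receptors ON), `FLT3i` (FLT3 OFF),
and `FLT3i+<target>KO` for each target (FLT3 and the target OFF — so
`FLT3i+FLT3KO` is identical to `FLT3i` by construction). Knockouts are
binary clamps; complex labels such as `ERK1/2` or `GSK3A/B` expand to all
member nodes, all clamped. A rescue hit is a knockout whose combination
brings the resistant model to the treated sensitive reference on *both*
axes (`score ≤ reference + ε`, with ε = 0 by default — the reference
criterion is a conjunction, and the default is strict because any slack is
a modeling judgement the user should make explicitly).

`demo_model_pair()` packages a minimal worked example: both models share a
receptor layer and the proliferative PI3K→AKT→RPS6 arm; the pro-apoptotic
endpoint BAD is released by AKT inactivation alone in the sensitive model
but additionally requires JNK inactivation in the resistant one, making
the JNK knockout the unique rescue.

```{r}
dm <- demo_model_pair()
ep_r <- endpoint_regulators(dm$resistant, dm$regulators)
ref <- run_condition(dm$sensitive, "FLT3i",
                     endpoint_regulators(dm$sensitive, dm$regulators))$scores
scr <- ko_screen(dm$resistant, ep_r)
scr
rescue_hits(scr, ref)
```

## Patient simulations

Patients are classified from their ITD insertion positions:
`classify_itd()` calls a site below the JMD/TKD boundary JMD and at or
above it TKD, with mixed-site patients JMD+TKD. The boundary defaults to
residue 610 — consistent with the canonical exemplars of a JMD insertion
at residue 598 and a TKD1 insertion at 613 — and is configurable because
domain annotations differ by a few residues between sources. JMD and
JMD+TKD patients are simulated on the JMD-derived model (the JMD lesion is
dominant); TKD patients on the TKD-derived model.

Mutational profiles binarize by OncoKB effect class: gain-of-function
(and likely) clamps the gene's node to 1, loss-of-function (and likely) to
0; Unknown, Inconclusive, Likely Neutral and Switch-of-function variants
are dropped. Gene symbols map to model nodes only through an explicit
alias table — no fuzzy matching. Patient clamps are applied on top of each
condition's clamps, and condition clamps win on conflict: a drug acts
downstream of genotype, so a gain-of-function FLT3 is still silenced by
the FLT3 inhibitor. Expression z-scores (per-patient standardization) are
computed for description only and never alter clamps; an optional hook for
expression-derived clamps exists in principle but is deliberately not a
default, because the simulation recipe is mutational.

## The synthetic ground truth

`make_truth()` emulates the study's structure rather than any particular
dataset: stimuli and inhibitable kinases wired under the same 16-condition
panel, FLT3 constitutive, the downstream-most nodes measured as sentinels,
and terminal phenotype regulators. Signs are mostly activating with 25%
inhibitory off-backbone edges; shortcut-edge density is 0.15 per ordered
downstream pair, which lands the truth at the 1–1.5 regulators-per-node
scale typical of the published toy models in this model class. Two
quality criteria are enforced by deterministic redraws: every sentinel
must respond to the design (otherwise its Hill fit is degenerate and
recovery of its regulators is impossible), and true edges with no
observable signature — identical condition × sentinel steady states and
baseline with and without them — are pruned, so the truth is *minimal
with respect to the design* and "recovering the truth" is well defined.
Decoy gates come from degree-preserving rewiring of the true edges, which
keeps the distractors on the same nodes and degree profile as the truth.

`simulate_dataset()` maps states to MFI through a per-analyte affine range
(about 500–20000 arbitrary units; any positive affine map works because
the Hill normalization is scale-free between the observed extremes),
multiplies a shared per-well loading factor and per-measurement log-normal
noise (SD 0.05 by default, the scale of a replicate CV a practitioner
would call good for this platform), emits a β-Tubulin loading channel, and
draws bead counts around 120 with 2% of wells forced below the 50-bead
threshold. What this generator does *not* emulate: analyte cross-talk,
plate-position effects, saturation nonlinearity, or heavy-tailed outliers
— so passing recovery tests show the pipeline recovers structure under
its own stated noise model, not that it is robust to every artifact of
real bead arrays.

## Problem sizes and numerical choices

The packaged benchmark truth is 12 nodes / 5 sentinels (seed 101), trained
with 100 GA runs keeping 20, five replicate seeds — sizes chosen so the
whole suite, including the recovery benchmark, runs on a laptop-class
single core in minutes while still exercising a scaffold with decoys.
Simulation caps at 100 synchronous iterations (far above the longest
transient of networks this size); fixpoints are verified by re-applying
the update rule; tie-breaks in model selection are fully deterministic;
and degenerate inputs (constant analytes, empty scaffolds, fully masked
data, conflicting clamps) raise errors rather than propagating silently.

## Known limitations

* Synchronous updating only; no asynchronous or probabilistic schemes, and
  attractor search is limited to cycle detection from one initial state.
* Imputation is a plain correlation screen — a deliberate, transparent
  stand-in for richer network-inference methods, tracked by provenance so
  its contribution can be ablated.
* Knockouts and patient clamps are binary; no dose–response modeling.
* Published scaffold sizes from the original curated network depend on the
  original curation and imputation internals and are not reproduced
  number-for-number; the pipeline reports its own counts deterministically.
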