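---
title: "Mechanism-based biomarkers: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanism-based biomarkers: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitry)
```

This vignette is the package's account of the science it implements: the
probabilistic model, every tunable parameter that matters, what the
synthetic-data generator does and does not emulate, and the design choices
made where the design was genuinely open.

## 1. From expression to activation probabilities

### The ON/OFF mixture

Across a large, heterogeneous reference compendium, the distribution of a
probeset's (log2) intensity is modeled as a mixture of an OFF and an ON
Gaussian component. `fit_mixture()` fits it by EM with a fixed,
deterministic policy:

| parameter | default | meaning |
|---|---|---|
| initialization | means at the 25th/75th percentiles, sds at the sample sd, weights 0.5/0.5 | removes run-to-run EM variability |
| max iterations | 200 | EM budget |
| tolerance | 1e-8 relative log-likelihood change | convergence |
| `min_n` | 50 values | below this a calibration is refused |
| sd floor | 1e-4 × sample sd | prevents component collapse |

Components are relabeled so the ON mean is the larger one ("the highest
peak is the active state"). A study sample's value is then scored as the
posterior `P(ON | x)`, clipped to `[1e-12, 1 − 1e-12]` so downstream
products never hit exact 0/1 from rounding.

**Degeneracy.** Genome-scale matrices contain features that carry no
ON/OFF information; they are flagged, never errored, and scored 0.5
(uninformative). A vector with sample sd below 1e-8 is `constant`. A fit
whose component means are separated by less than **two pooled standard
deviations** (`sqrt((σ_off² + σ_on²)/2)`) is `unimodal`: below that
separation a balanced two-Gaussian mixture has a single mode, so the two
fitted "components" describe one peak. We chose the unimodality boundary
rather than a 1-sd heuristic because EM applied to genuinely unimodal data
routinely converges to spurious splits 0.9–1.3 pooled sd apart; a 1-sd
threshold would flag such data as bimodal about half the time, while true
ON/OFF features (separations of 4–6 sd on this platform model) sit far
above 2 sd.

### Combination to genes and nodes

The probeset→gene and gene→node combination rule is the probability of a
union under independence, `1 − Π(1 − p_i)`. The modeling argument: pathway
nodes are typically redundant protein families (an ADCY node with nine
adenylate cyclases, an NFKB node with NFKB1 and RELA), and a signal can be
carried by any active member. The rule is exposed as a strategy
(`rule = "union" | "mean" | "min"`) for sensitivity analyses. Genes of a
node absent from the platform are dropped from the combination; a node
with no measured gene at all scores 0.5 with a warning, so a sparse
platform degrades gracefully instead of failing. Calibration is fitted
once on the reference compendium and **frozen**; all study cohorts —
including external validation cohorts — are scored against the same
calibration, which is what makes cross-dataset transfer meaningful.

## 2. Circuit transmission probability

A pathway is a signed directed graph whose vertices are multi-protein
nodes with explicit receptor/effector annotations (we require the
annotation file and never guess endpoints from topology). A **circuit** is
the merged union of all activation-edge paths between one
(receptor, effector) pair — bi- and multi-furcations are one circuit, not
many, which matches the receptor–effector naming convention
(`hsa04920:TNF-NPY`). Inhibition edges never carry forward flow; each
inhibition edge whose target is a member node joins the circuit's
*inhibitor context*.

Given independent Bernoulli node states with the calibrated probabilities,
the transmission event is Boolean: node *n* transmits iff

* *n* is active, and
* *n* is the receptor, or at least one activating parent among the member
  nodes transmits, and
* no inhibitor impinging on *n* blocks.

`transmission_probability()` computes the exact probability of "the
effector transmits" by enumerating the joint states of the involved nodes
(members plus inhibitor sources), in chunks of at most 2^16 states, with
per-state weights multiplied node by node. Exact enumeration is what makes
shared nodes between parallel paths come out right: the all-0.5 diamond is
0.1875, not the 0.4375 a path-union approximation would give. Circuits
with more than `max_exact_nodes = 22` involved nodes are refused and
routed to the seeded Monte-Carlo estimator
(`transmission_probability_mc()`, binomial standard error reported);
real KEGG-derived circuits are far smaller per circuit.

**Inhibitor semantics** (an open modeling question; both modes shipped,
neither claimed as "the" original):

* `mode = "context"` (default): an inhibitor blocks while its node is
  active, whether or not the inhibitor itself receives signal. This is the
  semantics used in all worked examples and tests.
* `mode = "signal"`: a member inhibitor must additionally be reached from
  the receptor in an activation-only pass (inhibition ignored during that
  pass — this keeps the definition acyclic under feedback inhibition);
  an inhibitor outside the member set still blocks by activity alone,
  since its upstream context is not modeled.

**Cycles** are rejected at load time (one offending strongly-connected
set is reported): the Boolean recursion is defined on acyclic structure
only. KEGG-derived inputs must be pre-acyclified upstream; this is a
documented limitation, not a silent fix.

**Differential activation** between two sample groups uses a Wilcoxon
rank-sum test per circuit (Welch t as an option) with Benjamini–Hochberg
adjustment; direction is the sign of the group-mean difference, `"none"`
when means are equal, and ties in the report ordering are broken
lexicographically by circuit id for reproducibility.

## 3. Feature selection

Circuits whose activity range across samples is at most `tol = 1e-6`
(exactly invariant, up to floating point) are discarded first — they
cannot discriminate anything. CFS then scores a subset S of k circuits by

    merit(S) = k · r̄_cf / sqrt(k + k(k−1) · r̄_ff)

with r̄_cf the mean |Pearson| against the continuous IC50 target and r̄_ff
the mean pairwise |Pearson| within S — relevance rewarded, redundancy
penalized. Published CFS is usually stated for classification; absolute
Pearson correlation on both terms is the minimal continuous-target
extension, and zero-variance features contribute correlation 0. The search
is best-first over subsets with the classic stop rule of 5 consecutive
non-improving expansions; with at most 15 candidates the package switches
to exhaustive search (`search = "auto"`). Merit ties break toward the
lexicographically smaller circuit-id subset, making the result invariant
to column permutation. CFS can be skipped entirely
(`use_cfs = FALSE` / `--no-cfs`) since an SVR does not require it for
prediction; the flag reproduces the all-features configuration.

## 4. The ε-SVR predictor

`train_predictor()` tunes an RBF-kernel ε-regression SVM over the grid
cost ∈ {10, 100} × γ ∈ {10⁻⁶, 10⁻⁵, 10⁻⁴, 10⁻³} by 10-fold
cross-validated MSE (seeded fold assignment, recorded in the model), then
refits at the winner on all training data. Ties break toward smaller
cost, then smaller γ. Choices the method leaves open:

* **ε = 0.1** (tube width): not part of the grid; exposed as an argument.
* **Scaling**: circuit activities already live in [0, 1] and are used
  as-is; `scale = TRUE` standardizes columns for raw gene-expression
  features, freezing training-set statistics into the model so validation
  data are transformed identically.
* **Per-drug models**: `cross_dataset_run()` trains one model per shared
  drug and pools predictions for reporting; a joint model with drug
  context is deliberately out of scope.

Evaluation reports global MSE/RMSE/Pearson r/r² and a per-(cancer, drug)
RMSE table in which cells with fewer than `min_cell = 2` samples are `NA`
rather than an unstable estimate. The per-group and global numbers obey
the exact identity: global MSE = size-weighted mean of group MSEs.

## 5. Phospho-proteomic concordance

Phosphosite SILAC ratios are averaged per (protein, cell line, condition
pair) — arithmetic mean by default, geometric by flag since ratios are
multiplicative — then classified: > 1.1 increased, 0.9–1.1 (closed
interval) unchanged, < 0.9 decreased. States follow the stated rule
verbatim: (decreased stimulated/control, increased treated/stimulated) →
hyperP; (increased, decreased) → deP; everything else NC. The rule's
direction is counter-intuitive for an inhibitor experiment; we implement
it literally and do not reinterpret it. `concordance_table()` joins each
profiled protein to the circuit nodes containing it and reports the
circuit's predicted direction next to the protein's state, one row per
(protein, circuit), dropping (and counting) proteins in no circuit.

## 6. The synthetic study conditions

The generator exists so the whole pipeline is exercisable with no
downloads. Defaults are the package's study conditions and are not tuned
per test:

| quantity | default |
|---|---|
| reference arrays | 500 (2000 in the calibration-recovery check) |
| train / validate samples | 200 / 150 |
| pathways | 5 random toy DAGs + the TNF-NPY miniature |
| member nodes per circuit | 3–5; 1–3 genes per node; 1–2 probesets per gene |
| informative circuits | 4, effect β = 1 ln µM each, alternating signs across 2 drugs |
| IC50 noise | 0.5 ln µM around β₀ = 2 |
| OFF / ON components | N(4, 1) / N(10, 1), means jittered per probeset (sd 0.15) |
| batch shift (validate) | +0.3 intensity units |

Per sample, each informative circuit draws an activity driver
u ~ U(0, 1) that sets its member-node activation probabilities
(0.05 + 0.9u); gene states are drawn so the node-level union reproduces
the node probability; probeset intensities come from the matching ON/OFF
component. The **ground-truth circuit activity is the realized Boolean
transmission state** evaluated on the drawn node states, and IC50 is
linear in those states. We chose realized states (rather than the
marginal transmission probability) as the truth because with 6-sd
component separation the calibrated posteriors are nearly 0/1, so the
pipeline's activity estimate targets the realized state; this makes
recovery a well-posed question with an unambiguous answer recorded in
`truth.json`. The 0.3 batch shift is large enough that frozen-calibration
cross-dataset scoring is genuinely exercised and small enough that
validation r ≥ 0.7 remains attainable — the desk-scale analogue of a
cross-compendium transfer.

What the generator does **not** emulate: probe-level artifacts and spatial
noise, probe–gene many-to-many ambiguity, correlated pathway cross-talk,
dose-response curve fitting (IC50s are inputs by design), and the
pharmacology of any real compound. Passing tests therefore demonstrate
internal correctness and recoverability under the stated generative
model — not performance on real cell-line panels, which requires the
external compendia this package deliberately does not download.

## 7. Numerical and reproducibility notes

* All RNG consumers (generators, fold assignment, Monte-Carlo) take
  explicit seeds, save and restore the caller's RNG state, and derive
  sub-streams deterministically from the config seed, so every primary
  output is byte-identical under a seeded rerun.
* Probabilities are handled in log space where tails matter (posterior
  odds), and state-weight products are clamped to [0, 1] at the end.
* Exact propagation is validated against an independent brute-force
  enumeration oracle (recursion over every joint state) in the test
  suite; test problem sizes (200 random circuits of 3–10 member nodes,
  2000-array calibration, 200/150-sample cross-dataset runs) keep the full
  suite under a minute while leaving every contract asserted at its stated
  tolerance.

## 8. Known limitations

* Acyclic circuits only; feedback loops must be resolved upstream.
* Independence assumptions at three levels (probesets within gene, genes
  within node, nodes within circuit) are modeling choices, not estimates.
* The continuous-target CFS extension and the best-first stop rule are
  sensible defaults, not uniquely determined by the method description.
* External inhibitors in `mode = "signal"` still block by activity alone;
  modeling their upstream signal would require pathway-wide propagation
  beyond the circuit boundary.
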