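---
title: "Methods: network-fusion multi-omics biomarker discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-fusion multi-omics biomarker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical procedure
it implements, the assumptions behind each stage, the defaults and why
they were chosen, and what the synthetic cohorts do and do not tell you
about real data.

## The problem

Clinically defined syndrome subtypes of a disease — here two case groups
("Cold" and "Hot" pattern) against normal controls — are to be
discriminated at the molecular level by joining a gene-expression layer,
a metabolite layer, curated symptom-to-gene annotation, a gene–gene
interaction graph, pathway gene sets, and curated metabolite–gene
(enzyme/transport) associations into one typed multi-level network, from
which candidate biomarkers are ranked and then validated as single-marker
classifiers on an independent cohort.

## Stage by stage

### Differential screening

Each feature is tested between a case group and the controls with the
two-sided Mann–Whitney rank test. The statistic U counts pairs
(x, y) with x > y, ties credited one half; the p-value is the exact
permutation probability when the pooled size is at most 12 and no ties
occur, otherwise the normal approximation with tie and continuity
correction (delegated to `stats::wilcox.test`, which implements exactly
this contract). The exact/approximate switch at 12 keeps hand-countable
toy cases exact while staying fast at cohort scale. A rank test is used
for both layers because microarray intensities and MS peak areas are
continuous, often skewed, and the downstream decision rule only consumes
the adjusted p-value; a Welch t-test is provided as a utility but feeds
nothing.

Fold change is the ratio of **linear-scale** group means, case over
control; log2-stored tables are de-logged first (`log_base = 2`, set
`NULL` for linear tables), with an optional pseudocount for zero-laden
data. The source workflow does not state the scale or orientation of its
fold change, so both are explicit arguments with these defaults.

Multiple testing uses Benjamini–Hochberg step-up adjustment
(`stats::p.adjust`). The composite call is

* up: q < 0.05 and FC > 2 (and VIP > 1 when a VIP vector is supplied),
* down: q < 0.05 and FC < 0.5 (same VIP gate),
* otherwise not significant.

When no VIP vector is available the rule degrades to FC + q, and says so.
All cutoffs live in `sf_config()` and are validated
(`fc_up > 1 > fc_down > 0`, `0 < q_max < 1`, ...).

### PCA, PLS-DA and VIP

PCA is `stats::prcomp` on samples-by-features (centering always,
unit-variance scaling optional). PLS-DA is PLS1 regression of the
centered 0/1 class indicator on centered X, fitted by NIPALS with
X-deflation per component; weight vectors are unit norm and score
vectors mutually orthogonal, which the tests assert. Autoscaling is the
default for metabolite tables (peak areas span orders of magnitude) and
centering-only for gene tables; both are flags.

VIP uses Wold's formulation with SSY weighting,
`VIP_j = sqrt(p * sum_a(SSY_a w_ja^2) / sum_a SSY_a)`,
`SSY_a = q_a^2 t_a' t_a`, so the mean squared VIP is exactly 1 — the
natural scale behind the conventional VIP > 1 screening threshold. The
number of components is chosen by stratified k-fold cross-validation
(default 10 folds, deterministic under the seed):
`Q^2(A) = 1 - PRESS(A)/TSS` on held-out samples, and A* is the smallest
A within 0.01 of the maximum (parsimony; beyond-noise components add
nothing but variance). If every Q² is non-positive the model is declared
uninformative with a warning and A* = 1. OPLS-DA is approximated by
plain PLS-DA — VIP is used purely as a ranking/threshold device here, and
no orthogonal-variation diagnostics are consumed downstream — but a
single orthogonal-signal-correction step is available behind
`orthogonal = TRUE` for users who want the OPLS-style filtered fit.

### Association network and key targets

Gene nodes are, by default, the **union** of the differential genes and
the symptom-set members ("union" policy); the alternative
"intersection_neighbors" policy seeds on the intersection and expands by
first neighbours in the interaction graph. Both are offered because the
exact seed rule behind published "key network target" counts is
typically under-specified; the union policy is the default since
intersection alone cannot produce target sets larger than the
differential set. Gene–gene edges are the interaction edges induced on
the node set (confidences, on the STRING 0–1000 combined-score scale,
are a load filter only — default minimum 400, "medium confidence" — never
shortest-path weights). Symptom nodes wire to their member genes and one
syndrome node to all symptoms.

Centralities are computed on the gene–gene subgraph (igraph): degree;
betweenness as unnormalized unordered-pair counts (so a path a–b–c gives
b exactly 1 and a 3-leaf star centre exactly 3, matching hand counts);
and Wasserman–Faust component-adjusted closeness
`(r-1)^2 / ((n-1) * sum d)`, which handles disconnected graphs without
infinities and gives isolated nodes 0.

Key targets default to the `median_all` rule: all three centralities at
or above their medians, ties kept. The medians are taken over the
**connected** (degree ≥ 1) nodes: symptom annotation contributes many
genes with no interaction edges, and including them would drag all three
medians to zero and make the rule vacuous. A multiplier on the medians,
a `median_any` variant and a `top_frac:x` variant are configurable.

### Enrichment

Over-representation of the key targets in each pathway set restricted to
the universe, by the exact hypergeometric upper tail
(`stats::phyper`), BH across sets; only the enrichment tail is computed
(no depletion). The universe defaults to all genes in the expression
table plus all annotated genes — backgrounds are rarely reported in
published workflows, so it is explicit and configurable. An EASE-style
conservative variant (overlap reduced by one) is available as a flag.

### Fusion and candidate ranking

Two cross-layer edge sources are kept as distinct types: thresholded
Spearman correlation edges (average-rank ties; t-approximation for the
p-value, exact permutation for n ≤ 9; BH across pairs; retained iff
q < 0.05 and |r| > 0.2) and curated metabolite–gene association edges
with a relation attribute (enzyme / transport / association). Pathway
membership of a **metabolite** flows through the curated edges only:
membership is a biochemical fact about the metabolite's enzymes, and
routing it through sample correlations would let any co-regulated
metabolite inherit pathway evidence it does not have.

Candidates are (i) differential genes that are key targets, (ii)
differential metabolites, and (iii) enzyme genes of differential
metabolites. Each carries five evidence flags (differential, key target,
symptom-linked, cross-layer-linked, enriched-pathway member) and

```
composite_score = sum_f w_f * flag_f + w_c * z(degree in fused network)
```

with all weights defaulting to 1. Two conventions make the score
comparable across entity kinds, both deliberate design choices: the
degree z-score is standardized **within** node type (gene-layer and
metabolite-layer degrees differ by an order of magnitude), and flags
that cannot apply to a kind — a metabolite cannot be a network key
target — are dropped with the remaining flag weights rescaled. A
metabolite's symptom link is carried by a curated partner gene that is a
symptom-set member. Ranking is by score descending with lexicographic
tie-breaks, so results are deterministic. This score is a deliberate
formalization of what published workflows do narratively when they read
candidates off the fused network figure; the weights are exposed
precisely because that narrative step is subjective.

### Validation

Each candidate is evaluated as a single-marker classifier on a held-out
cohort, separately per pairwise contrast (Cold/NC, Hot/NC, Cold/Hot by
default). The ROC curve runs over all distinct thresholds
(positive iff score ≥ t); AUC is the rank/U statistic with half-credit
ties, identical to the trapezoidal area; markers lower in cases than
controls are flipped so AUC ≥ 0.5 corresponds to the discriminating
direction. The classification threshold maximizes Youden's
J = sensitivity + specificity − 1 (ties toward higher specificity),
because published confusion panels rarely state their threshold rule and
Youden is the standard neutral choice; the full confusion panel
(accuracy, precision, sensitivity, specificity, F1 — reported as 0 with a
flag when undefined — and J) is returned. A seeded bootstrap percentile
CI for the AUC is optional (2000 resamples).

## The synthetic cohort generator

`sim_config()` defaults define the reference conditions used by the
test-suite and the acceptance experiments: 2000 genes, 200 metabolites,
20 samples per group, 5% differential features (split disjointly between
Cold-true and Hot-true), signed log2 effects ~ N(2, 0.5) with magnitudes
floored at 0.25, N(0, 1) log2 noise on per-feature baselines ~
N(10, 1.5), and 5 planted biomarkers (3 genes, 2 metabolites). These
sizes are typical of a two-syndrome discovery cohort with a microarray
gene layer and an MS metabolite layer, and they keep the full 20-run
acceptance experiment within a few minutes on one CPU.

The planted evidence chain mirrors how real biomarkers earn their
status:

* biomarker genes and metabolites are the **strongest-effect** true
  features of their syndrome (real candidates are picked for
  "significant differences", not at random);
* biomarker genes are wired as hubs among the true differential genes of
  their syndrome (15 extra interaction edges by default) on top of a
  preferential-attachment backbone (seed clique of m+1 nodes, m distinct
  degree-weighted attachments per new node, hence exactly
  `choose(m+1,2) + m(n-m-1)` edges; an Erdős–Rényi model is the
  alternative);
* symptom sets oversample true differential genes of their syndrome
  (weight factor 10 by default; factor 1 reduces to uniform sampling,
  which the tests verify against the hypergeometric expectation), and
  when the factor exceeds 1 each biomarker gene is placed in the first
  symptom set of its syndrome;
* each biomarker metabolite receives three curated enzyme links to true
  differential genes of its syndrome, at least one of them a biomarker
  gene — the annotation density of a well-characterized metabolite —
  while background metabolites get Poisson(1.2) uniform associations;
* one pathway per syndrome is seeded with the biomarker genes, their
  neighbours and the biomarker metabolites' linked genes; the rest are
  uniform background sets.

Abundances are Gaussian on the log2 scale rather than negative-binomial
counts: the emulated assays are microarray intensities and MS peak
areas, and every downstream test is rank-based, so the distributional
family is a free choice. What the generator does **not** emulate: batch
effects and drift, non-MCAR missingness (only a half-minimum imputation
pre-step is offered), correlated noise between features, annotation
errors, or shared Cold/Hot signatures (the true sets are disjoint by
construction so that recovery is unambiguous; real syndromes share
pathways). Passing tests therefore demonstrate the pipeline's internal
correctness and its power under clean group-shift signal — not robustness
to those artifacts.

## Numerical conventions and degenerate inputs

* All randomness flows from explicit seeds; every stage is deterministic
  given config and inputs, and RNG state is restored after use.
* Completely constant features: Mann–Whitney returns p = 1 with a
  degenerate flag; constant vectors are skipped (and counted) in
  correlation.
* Zero class covariance makes the PLS weight vector undefined; this is a
  hard error rather than a silent zero-component model.
* Duplicate undirected edges keep the maximum confidence; self-loops are
  dropped at load.
* BH never exceeds 1; enrichment p-values are exact tails, not normal
  approximations.
* Contrasts with no differential genes short-circuit to empty network /
  candidate results rather than erroring, so null cohorts flow through
  `run_pipeline()`.

## Problem sizes used by the tests

Unit tests run on reduced cohorts (300–400 genes, 8–12 samples per
group) chosen to finish in seconds while keeping every stage
non-trivial; the acceptance experiment uses the full reference
conditions above with 20 seeded runs, and brute-force oracle comparisons
use graphs of up to 50 nodes and 200 random enrichment configurations —
sizes at which exhaustive enumeration is itself fast and trustworthy.

## Known limitations

* The Cold/Hot effect sets are disjoint; an overlap knob would be needed
  to study shared signatures.
* Identifier namespaces are opaque strings; no symbol mapping layer.
* Single-marker validation only — no multi-marker classifier and no
  DeLong AUC comparisons.
* The composite biomarker score is a formalization choice; different
  weightings legitimately reorder mid-list candidates, which is why the
  weights are exposed.
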