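# syndromefuse

Integrative network-fusion multi-omics analysis for discriminating
clinically defined disease syndrome subtypes — the setting is rheumatoid
arthritis patients stratified into Cold-pattern and Hot-pattern syndrome
groups against normal controls (NC), but the machinery is generic: two
case groups, one control group, a gene layer and a metabolite layer.

The package is aimed at systems-biology analysts who want the complete
evidence chain of such a study as tested, reusable code:

1. **Differential screening** per syndrome contrast: Mann–Whitney rank
   test, linear-scale fold change FC, Benjamini–Hochberg adjusted
   q-values, and the composite call rule
   *VIP > 1, FC > 2 or < 0.5, q < 0.05*.
2. **Multivariate modelling**: PCA, two-class PLS-DA fitted by NIPALS,
   k-fold cross-validated component selection via
   Q² = 1 − PRESS/TSS, and Wold's variable importance in projection,
   VIPⱼ = √( p · Σₐ SSYₐ wⱼₐ² / Σₐ SSYₐ ) with SSYₐ = qₐ² tₐᵀtₐ,
   so that Σⱼ VIPⱼ² = p.
3. **Association network**: a disease–syndrome–symptom–gene graph built
   from symptom gene sets (GMT) and a gene–gene interaction table
   (STRING-style 0–1000 confidences), with node degree k, betweenness
   C_B(v) = Σ σ_st(v)/σ_st over unordered pairs, and Wasserman–Faust
   closeness C_C(v) = (r−1)² / ((n−1) Σ d); **key network targets** are
   the genes whose three centralities all reach their median thresholds.
4. **Pathway enrichment** of the key targets by the exact hypergeometric
   upper tail, BH-adjusted across sets.
5. **Network fusion**: thresholded Spearman correlation edges
   (|r| > 0.2, q < 0.05) and curated metabolite–gene association edges
   join the layers into one typed
   disease–syndrome–symptom–gene–metabolite–pathway network, and
   candidates are ranked by a composite evidence score (five evidence
   flags plus a degree z-score).
6. **Validation**: single-marker ROC/AUC on a held-out cohort, Youden-J
   optimal thresholds, and the confusion panel (accuracy, precision,
   sensitivity, specificity, F1).

Because the original clinical cohorts are not reproducible at desk
scale, the package ships a first-class **synthetic cohort simulator**
that plants a fully known evidence chain (differential features, hub
biomarker genes, symptom-set membership, enzyme-linked biomarker
metabolites, seeded pathways) so that every downstream stage can be
tested against ground truth.

## Worked example

```r
library(syndromefuse)

cfg     <- sim_config(seed = 42)                 # 2000 genes, 200 metabolites, 20/group
sim     <- simulate_cohort(cfg)                  # discovery cohort + truth
heldout <- simulate_cohort(cfg, seed = 4242, truth = sim$truth)  # validation cohort
run     <- run_pipeline(sim, sf_config(seed = 42), validation = heldout)
print(run)
#> sf_run: network-fusion pipeline result
#>   Cold: 45 differential genes, 5 differential metabolites, 27 key targets, 1 enriched pathways, 31 candidates
#>   Hot: 49 differential genes, 5 differential metabolites, 16 key targets, 1 enriched pathways, 22 candidates

head(run$syndromes$Cold$biomarkers[, c("entity_id", "entity_kind", "composite_score", "rank")], 5)
#>  entity_id entity_kind composite_score rank
#>      g1203        gene        9.276757    1
#>      g0475        gene        9.023779    2
#>      g1205        gene        6.241023    3
#>      m0085  metabolite        6.079591    4
#>      g1159        gene        5.482090    5

head(run$syndromes$Cold$validation[, c("marker", "contrast", "auc", "sensitivity", "specificity", "F1")], 5)
#>  marker   contrast    auc sensitivity specificity        F1
#>   g1203 Cold_vs_NC 0.9875        0.95        0.95 0.9500000
#>   g0475 Cold_vs_NC 0.9450        0.90        0.85 0.8780488
#>   g1205 Cold_vs_NC 0.8500        0.80        0.85 0.8205128
#>   m0085 Cold_vs_NC 1.0000        1.00        1.00 1.0000000
#>   g1159 Cold_vs_NC 0.9775        0.90        1.00 0.9473684

sim$truth$planted_biomarker_ids
#> [1] "g1203" "g0475" "g0720" "m0085" "m0071"
```

The five planted biomarkers (three hub genes, two enzyme-linked
metabolites) surface at the top of the per-syndrome rankings, and each
validates with AUC well above 0.7 on the held-out cohort — the
qualitative behaviour expected of the workflow on real syndrome cohorts.

Every stage is also callable on its own (`call_differential_features()`,
`fit_plsda()` / `vip_scores()`, `build_association_network()` /
`node_centralities()` / `select_key_targets()`,
`hypergeometric_enrich()`, `correlate_gene_metabolite()` /
`rank_biomarker_candidates()`, `roc_curve_auc()` /
`confusion_metrics()`), and cohorts round-trip through plain TSV/GMT
files via `write_cohort()` and the `read_*` family, so external data in
those formats can be fed straight into the same stages.

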