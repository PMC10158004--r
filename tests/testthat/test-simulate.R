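small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 300, n_metabolites = 60, n_per_group = 8,
         frac_diff = 0.1, n_symptom_sets = 4, symptom_set_size = 20,
         n_pathways = 8, pathway_size = 20, hub_extra_links = 6),
    list(...))
  do.call(sim_config, args)
}

test_that("cohort generation is deterministic under the seed", {
  cfg <- small_cfg(seed = 9)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$genes$values, s2$genes$values)
  expect_identical(s1$metabolites$values, s2$metabolites$values)
  expect_identical(as.data.frame(s1$interactions), as.data.frame(s2$interactions))
  expect_identical(lapply(s1$symptom_sets, `[[`, "members"),
                   lapply(s2$symptom_sets, `[[`, "members"))
  s3 <- simulate_cohort(cfg, seed = 10)
  expect_false(identical(s1$genes$values, s3$genes$values))
})

test_that("a null cohort plants nothing and group means differ only by noise", {
  ch <- generate_cohort(small_cfg(frac_diff = 0, seed = 2))
  expect_length(ch$truth$true_deg_ids, 0)
  expect_length(ch$truth$true_diff_metabolite_ids, 0)
  expect_length(ch$truth$planted_biomarker_ids, 0)
  grp <- ch$genes$sample_meta$group
  gap <- abs(rowMeans(ch$genes$values[, grp == "Cold"]) -
               rowMeans(ch$genes$values[, grp == "NC"]))
  # noise-only gaps: s.d. of a mean difference is noise_sd * sqrt(2/n)
  expect_lt(max(gap), 1 * sqrt(2 / 8) * 6)
})

test_that("Cold-true and Hot-true feature sets are disjoint and effects nonzero", {
  for (s in 1:5) {
    tr <- generate_cohort(small_cfg(seed = s))$truth
    expect_length(intersect(names(tr$gene_effects$Cold), names(tr$gene_effects$Hot)), 0)
    expect_length(intersect(names(tr$metabolite_effects$Cold),
                            names(tr$metabolite_effects$Hot)), 0)
    expect_true(all(abs(unlist(tr$gene_effects)) > 0))
  }
})

test_that("tiny groups warn or error as the power contract requires", {
  expect_warning(sim_config(n_per_group = 2), "underpowered")
  expect_error(sim_config(n_per_group = 1), "at least 2")
})

test_that("preferential attachment yields the closed-form edge count", {
  # seed clique of m+1 nodes, then m distinct attachments per node:
  # choose(m+1, 2) + m * (n - m - 1) edges
  cfg <- sim_config(n_genes = 100, pa_m = 2, n_biomarker_genes = 0,
                    n_biomarker_metabolites = 0, hub_extra_links = 0, seed = 4)
  ch <- generate_cohort(cfg)
  net <- generate_interaction_network(cfg, rownames(ch$genes$values), ch$truth)
  expect_equal(nrow(net$edges), choose(3, 2) + 2 * (100 - 3))
  # degrees must account for every edge twice
  expect_equal(sum(table(c(net$edges$node_a, net$edges$node_b))), 2 * nrow(net$edges))
})

test_that("Erdos-Renyi with p = 0 gives an empty graph; same seed gives identical edges", {
  cfg <- sim_config(n_genes = 120, graph_model = "erdos_renyi", er_p = 0,
                    n_biomarker_genes = 0, n_biomarker_metabolites = 0, seed = 6)
  ch <- generate_cohort(cfg)
  net <- generate_interaction_network(cfg, rownames(ch$genes$values), ch$truth)
  expect_equal(nrow(net$edges), 0L)

  cfg2 <- small_cfg(graph_model = "erdos_renyi", er_p = 0.02, seed = 8)
  ch2 <- generate_cohort(cfg2)
  n1 <- generate_interaction_network(cfg2, rownames(ch2$genes$values), ch2$truth)
  n2 <- generate_interaction_network(cfg2, rownames(ch2$genes$values), ch2$truth)
  expect_identical(as.data.frame(n1$edges), as.data.frame(n2$edges))
})

test_that("a strong enrichment factor forces planted biomarker genes into symptom sets", {
  cfg <- small_cfg(overlap_enrichment = 50, seed = 12)
  sim <- simulate_cohort(cfg)
  members <- unique(unlist(lapply(sim$symptom_sets, `[[`, "members")))
  expect_true(all(names(sim$truth$biomarker_genes) %in% members))
})

test_that("planted biomarkers satisfy the full evidence chain, from truth alone", {
  for (s in 1:5) {
    sim <- simulate_cohort(small_cfg(seed = s))
    tr <- sim$truth
    expect_true(all(names(tr$biomarker_genes) %in% tr$true_deg_ids))
    expect_true(all(names(tr$biomarker_metabolites) %in% tr$true_diff_metabolite_ids))
    # every biomarker metabolite is linked to a gene in the association table
    expect_true(all(names(tr$biomarker_metabolites) %in% sim$met_gene$node_a))
    # biomarker genes are network-connected (wired as hubs)
    deg <- table(c(sim$interactions$node_a, sim$interactions$node_b))
    expect_true(all(deg[names(tr$biomarker_genes)] >= 1))
    expect_true(all(names(tr$biomarker_genes) %in% tr$network_hub_ids))
  }
})

test_that("with enrichment factor 1 symptom-set overlap matches the hypergeometric expectation", {
  overlaps <- integer(0); expected <- numeric(0)
  for (s in 1:50) {
    cfg <- small_cfg(overlap_enrichment = 1, seed = s)
    ch <- generate_cohort(cfg)
    ann <- generate_annotation_maps(cfg, ch$truth, rownames(ch$genes$values),
                                    rownames(ch$metabolites$values))
    overlaps <- c(overlaps, ann$truth$symptom_sets_planted_overlap)
    expected <- c(expected, rep(cfg$symptom_set_size *
                                  length(ch$truth$true_deg_ids) / cfg$n_genes,
                                cfg$n_symptom_sets))
  }
  # Monte-Carlo check: mean within 4 binomial standard errors
  p <- mean(expected) / 20
  se <- sqrt(20 * p * (1 - p) / length(overlaps))
  expect_lt(abs(mean(overlaps) - mean(expected)), 4 * se)
  expect_error(generate_annotation_maps(small_cfg(overlap_enrichment = 0.5)),
               "overlap_enrichment")
})

test_that("a rank-test screen recovers most planted features at controlled FDR", {
  sens <- fdr <- numeric(0)
  for (s in 1:5) {
    cfg <- sim_config(n_genes = 400, n_metabolites = 50, n_per_group = 20,
                      frac_diff = 0.05, effect_mean = 2, noise_sd = 1, seed = s)
    ch <- generate_cohort(cfg)
    called <- character(0)
    for (syn in c("Cold", "Hot")) {
      sub <- subset_samples(ch$genes, ch$genes$sample_meta$group %in% c(syn, "NC"))
      dr <- suppressMessages(call_differential_features(sub, c(syn, "NC")))
      called <- union(called, dr$feature_id[dr$q < 0.05])
    }
    truth <- ch$truth$true_deg_ids
    sens <- c(sens, mean(truth %in% called))
    fdr <- c(fdr, if (length(called)) mean(!(called %in% truth)) else 0)
  }
  expect_gte(mean(sens), 0.8)
  expect_lte(mean(fdr), 0.1)
})

test_that("cohort files written to disk reload identically", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(small_cfg(seed = 21))
  write_cohort(sim, dir)
  genes <- read_feature_table(file.path(dir, "genes.tsv"),
                              file.path(dir, "samples.tsv"), "gene")
  expect_equal(genes$values, sim$genes$values, tolerance = 1e-12)
  ss <- read_gmt(file.path(dir, "symptom_sets.gmt"), "symptom")
  expect_equal(lapply(ss, `[[`, "members"), lapply(sim$symptom_sets, `[[`, "members"))
  et <- read_edge_list(file.path(dir, "interactions.tsv"), conf_min = 0)
  expect_equal(nrow(et), nrow(sim$interactions))
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_setequal(truth$feature_id[truth$is_biomarker], sim$truth$planted_biomarker_ids)
})
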