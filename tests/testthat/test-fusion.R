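mini_tables <- function(G, M, groups = rep(c("NC", "Cold"), length.out = ncol(G))) {
  ids <- sprintf("s%02d", seq_len(ncol(G)))
  colnames(G) <- colnames(M) <- ids
  meta <- data.frame(sample_id = ids, group = groups, tissue = "serum")
  list(genes = omics_table(G, meta, "gene"),
       metabolites = omics_table(M, meta, "metabolite"))
}

test_that("Spearman correlation reproduces hand-computed coefficients", {
  G <- rbind(g1 = c(1, 2, 3, 4, 5))
  M <- rbind(m_up = c(10, 20, 30, 40, 50),
             m_dn = c(5, 4, 3, 2, 1),
             m_mix = c(2, 1, 4, 3, 5))
  tb <- mini_tables(G, M)
  ce <- suppressMessages(correlate_gene_metabolite(tb$genes, tb$metabolites))
  r <- setNames(ce$r, ce$metabolite_id)
  expect_equal(r[["m_up"]], 1)
  expect_equal(r[["m_dn"]], -1)
  expect_equal(r[["m_mix"]], 0.8)     # 1 - 6*4 / (5*24)
})

test_that("Spearman r is invariant under strictly monotone transforms", {
  set.seed(40)
  G <- matrix(rnorm(3 * 12), 3, dimnames = list(paste0("g", 1:3), NULL))
  M <- matrix(rnorm(2 * 12), 2, dimnames = list(paste0("m", 1:2), NULL))
  tb1 <- mini_tables(G, M)
  tb2 <- mini_tables(exp(G), M^3 + 7 * M)   # monotone maps of each layer
  c1 <- correlate_gene_metabolite(tb1$genes, tb1$metabolites)
  c2 <- correlate_gene_metabolite(tb2$genes, tb2$metabolites)
  expect_equal(c1$r, c2$r, tolerance = 1e-12)
})

test_that("correlation p-values match the reference t-approximation and exact cases", {
  set.seed(41)
  G <- matrix(rnorm(2 * 20), 2, dimnames = list(paste0("g", 1:2), NULL))
  M <- matrix(rnorm(2 * 20), 2, dimnames = list(paste0("m", 1:2), NULL))
  tb <- mini_tables(G, M)
  ce <- correlate_gene_metabolite(tb$genes, tb$metabolites)
  for (i in seq_len(nrow(ce))) {
    ref <- cor.test(G[ce$gene_id[i], ], M[ce$metabolite_id[i], ],
                    method = "spearman", exact = FALSE)
    expect_equal(ce$p[i], ref$p.value, tolerance = 1e-10)
  }

  # n <= 9 without ties: exact permutation p
  G8 <- matrix(rnorm(8), 1, dimnames = list("g1", NULL))
  M8 <- matrix(rnorm(8), 1, dimnames = list("m1", NULL))
  tb8 <- mini_tables(G8, M8)
  ce8 <- correlate_gene_metabolite(tb8$genes, tb8$metabolites)
  ref8 <- cor.test(G8[1, ], M8[1, ], method = "spearman", exact = TRUE)
  expect_equal(ce8$p, ref8$p.value, tolerance = 1e-12)
})

test_that("constant vectors are skipped with a message", {
  G <- rbind(gc = rep(3, 10), gv = rnorm(10))
  M <- rbind(m1 = rnorm(10))
  tb <- mini_tables(G, M)
  expect_message(ce <- correlate_gene_metabolite(tb$genes, tb$metabolites),
                 "constant")
  expect_equal(nrow(ce), 1L)
  expect_equal(ce$gene_id, "gv")
})

test_that("metabolite-gene mapping joins associations and reports unmapped ids", {
  assoc <- edge_table(data.frame(node_a = c("m1", "m1", "m2"),
                                 node_b = c("g1", "g2", "g3"),
                                 relation = c("enzyme", "association", "enzyme")))
  mp <- map_metabolites_to_genes("m1", assoc)
  expect_setequal(mp$gene_id, c("g1", "g2"))
  expect_length(attr(mp, "unmapped"), 0)

  mp2 <- map_metabolites_to_genes(c("m1", "mX"), assoc)
  expect_equal(attr(mp2, "unmapped"), "mX")

  empty <- edge_table(data.frame(node_a = character(0), node_b = character(0)))
  mp3 <- map_metabolites_to_genes(c("m1", "m2"), empty)
  expect_equal(nrow(mp3), 0L)
  expect_setequal(attr(mp3, "unmapped"), c("m1", "m2"))
})

minimal_fusion_inputs <- function() {
  deg <- stub_deg_records(c("gA", "gB"), c("up", "up"))
  ss <- gene_set_collection(list(sym1 = list(description = "s",
                                             members = c("gA", "gB"))), "symptom")
  ints <- edge_table(data.frame(node_a = "gA", node_b = "gB"))
  net <- build_association_network(deg, ss, ints)
  gm <- data.frame(gene_id = "gA", metabolite_id = "m1", edge_type = "association")
  paths <- gene_set_collection(list(pw1 = list(description = "p",
                                               members = c("gA", "gB"))), "pathway")
  enr <- suppressMessages(
    hypergeometric_enrich(c("gA", "gB"), paths, c("gA", "gB", "gC", "gD", "gE",
                                                  "gF", "gG", "gH")))
  list(net = net, gm = gm, paths = paths, enr = enr, deg = deg)
}

test_that("the minimal multi-level network has the constructed node and edge types", {
  inp <- minimal_fusion_inputs()
  expect_true(inp$enr$enriched[1])
  ml <- assemble_multilevel_network(inp$net, key_targets = c("gA", "gB"),
                                    diff_metabolites = "m1", gm_edges = inp$gm,
                                    enrichment = inp$enr, pathway_sets = inp$paths)
  # disease + syndrome + 1 symptom + 2 genes + 1 metabolite + 1 pathway
  expect_equal(nrow(ml$nodes), 7L)
  type_of <- setNames(ml$nodes$type, ml$nodes$id)
  ends <- strsplit(sub(":.*$", "", ml$edges$type), "-")
  for (i in seq_len(nrow(ml$edges))) {
    expect_setequal(unname(type_of[c(ml$edges$from[i], ml$edges$to[i])]), ends[[i]])
  }
  expect_error(assemble_multilevel_network(inp$net, character(0), "m1", inp$gm,
                                           inp$enr, inp$paths), "empty key-target")
})

test_that("without enriched pathways the fused network has no pathway nodes", {
  inp <- minimal_fusion_inputs()
  enr0 <- inp$enr
  enr0$enriched <- FALSE
  ml <- assemble_multilevel_network(inp$net, c("gA", "gB"), "m1", inp$gm,
                                    enr0, inp$paths)
  expect_equal(sum(ml$nodes$type == "pathway"), 0L)
})

test_that("fused gene-gene edges are a subgraph of the association network", {
  sim <- simulate_cohort(sim_config(n_genes = 300, n_metabolites = 40,
                                    n_per_group = 10, frac_diff = 0.1,
                                    n_symptom_sets = 4, symptom_set_size = 20,
                                    n_pathways = 6, pathway_size = 15, seed = 3))
  run <- suppressMessages(suppressWarnings(run_pipeline(sim, sf_config(seed = 3))))
  for (syn in c("Cold", "Hot")) {
    r <- run$syndromes[[syn]]
    key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
    fg <- r$fused$edges[r$fused$edges$type == "gene-gene", ]
    ag <- r$network$edges[r$network$edges$type == "gene-gene", ]
    expect_true(all(key(fg) %in% key(ag)))
    # every edge's endpoint types are consistent (invariant sweep)
    type_of <- setNames(r$fused$nodes$type, r$fused$nodes$id)
    ends <- strsplit(sub(":.*$", "", r$fused$edges$type), "-")
    ok <- vapply(seq_len(nrow(r$fused$edges)), function(i) {
      setequal(unname(type_of[c(r$fused$edges$from[i], r$fused$edges$to[i])]),
               ends[[i]])
    }, logical(1))
    expect_true(all(ok))
  }
})

test_that("candidate ranking respects dominance, scale invariance and tie-breaks", {
  inp <- minimal_fusion_inputs()
  ml <- assemble_multilevel_network(inp$net, c("gA", "gB"), "m1", inp$gm,
                                    inp$enr, inp$paths)
  dm <- stub_deg_records("m1", "up")
  mm <- data.frame(gene_id = "gA", metabolite_id = "m1", relation = "enzyme")
  b <- rank_biomarker_candidates(ml, NULL, inp$deg, dm, mm)
  expect_equal(b$rank, seq_len(nrow(b)))
  # gA carries the metabolite link that gB lacks: strict dominance
  expect_lt(b$rank[b$entity_id == "gA"], b$rank[b$entity_id == "gB"])

  w <- c(is_differential = 1, is_key_target = 1, linked_symptom = 1,
         linked_metabolite_or_gene = 1, in_enriched_pathway = 1, centrality = 1)
  b2 <- rank_biomarker_candidates(ml, NULL, inp$deg, dm, mm, weights = 3 * w)
  expect_equal(b2$entity_id, b$entity_id)   # ranking is scale-invariant
  expect_error(rank_biomarker_candidates(ml, NULL, inp$deg, dm, mm,
                                         weights = 0 * w), "zero")

  # a single candidate always ranks first
  dm0 <- stub_deg_records("m1", "ns")
  b3 <- rank_biomarker_candidates(ml, NULL, stub_deg_records("gA", "up"), dm0,
                                  mm[0, ])
  expect_equal(nrow(b3), 1L)
  expect_equal(b3$rank, 1L)
})
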