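toy_interactions <- function() {
  edge_table(data.frame(node_a = c("a", "b", "c"), node_b = c("b", "c", "d")))
}

test_that("association network node and edge sets follow the union policy", {
  deg <- stub_deg_records(c("a", "b"), c("up", "down"))
  ss <- gene_set_collection(list(S1 = list(description = "s", members = c("b", "c"))),
                            "symptom")
  net <- build_association_network(deg, ss, toy_interactions())
  genes <- net$nodes$id[net$nodes$type == "gene"]
  expect_setequal(genes, c("a", "b", "c"))
  gg <- net$edges[net$edges$type == "gene-gene", ]
  expect_setequal(paste(gg$from, gg$to), c("a b", "b c"))
  sg <- net$edges[net$edges$type == "symptom-gene", ]
  expect_setequal(sg$to, c("b", "c"))
  expect_equal(sum(net$edges$type == "syndrome-symptom"), 1L)
})

test_that("the intersection policy seeds on the overlap and expands by first neighbors", {
  deg <- stub_deg_records(c("a", "b"), c("up", "down"))
  ss <- gene_set_collection(list(S1 = list(description = "s", members = c("b", "c"))),
                            "symptom")
  net <- build_association_network(deg, ss, toy_interactions(),
                                   policy = "intersection_neighbors")
  genes <- net$nodes$id[net$nodes$type == "gene"]
  expect_setequal(genes, c("a", "b", "c"))   # seed {b} + neighbors {a, c}
})

test_that("path and star centralities match hand counts", {
  p3 <- as_gene_net(data.frame(from = c("a", "b"), to = c("b", "c")), c("a", "b", "c"))
  cent <- node_centralities(p3)
  cc <- setNames(cent$betweenness, cent$node_id)
  expect_equal(cc[["b"]], 1)
  expect_equal(unname(cc[c("a", "c")]), c(0, 0))
  expect_equal(setNames(cent$degree, cent$node_id)[["b"]], 2)

  star <- as_gene_net(data.frame(from = "hub", to = c("l1", "l2", "l3")),
                      c("hub", "l1", "l2", "l3"))
  sc <- node_centralities(star)
  expect_equal(sc$degree[sc$node_id == "hub"], 3)
  expect_equal(sc$betweenness[sc$node_id == "hub"], 3)   # choose(3,2) leaf pairs
})

test_that("centralities equal a brute-force BFS oracle on random graphs", {
  set.seed(20)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    ids <- sprintf("v%02d", 1:n)
    e <- random_graph(ids, p_edge = runif(1, 0.04, 0.25))
    got <- node_centralities(as_gene_net(e, ids))
    want <- centrality_oracle(e, ids)
    got <- got[match(ids, got$node_id), ]
    expect_equal(got$degree, want$degree)
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-9)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-12)
  }
})

test_that("centralities are invariant under node relabeling", {
  set.seed(21)
  ids <- sprintf("v%02d", 1:20)
  e <- random_graph(ids, 0.15)
  base <- node_centralities(as_gene_net(e, ids))
  relab <- setNames(sprintf("w%02d", sample(20)), ids)
  e2 <- data.frame(from = unname(relab[e$from]), to = unname(relab[e$to]))
  perm <- node_centralities(as_gene_net(e2, unname(relab[ids])))
  perm <- perm[match(unname(relab[ids]), perm$node_id), ]
  base <- base[match(ids, base$node_id), ]
  expect_equal(perm$degree, base$degree)
  expect_equal(perm$betweenness, base$betweenness, tolerance = 1e-9)
  expect_equal(perm$closeness, base$closeness, tolerance = 1e-12)
})

test_that("isolated nodes score zero and added edges never reduce degree", {
  ids <- c("a", "b", "c", "iso")
  e <- data.frame(from = c("a", "b"), to = c("b", "c"))
  cent <- node_centralities(as_gene_net(e, ids))
  iso <- cent[cent$node_id == "iso", ]
  expect_equal(unlist(iso[c("degree", "betweenness", "closeness")]),
               c(degree = 0, betweenness = 0, closeness = 0))
  e2 <- rbind(e, data.frame(from = "iso", to = "a"))
  cent2 <- node_centralities(as_gene_net(e2, ids))
  expect_true(all(cent2$degree[match(ids, cent2$node_id)] >=
                    cent$degree[match(ids, cent$node_id)]))
})

test_that("key-target selection applies the median rules with tie retention", {
  rec <- data.frame(node_id = paste0("n", 1:5), degree = 1:5,
                    betweenness = rep(2, 5), closeness = rep(0.5, 5))
  kept <- suppressMessages(select_key_targets(rec, "median_all"))
  expect_setequal(kept, c("n3", "n4", "n5"))

  same <- data.frame(node_id = paste0("n", 1:4), degree = 2, betweenness = 1,
                     closeness = 0.3)
  expect_setequal(suppressMessages(select_key_targets(same, "median_all")),
                  same$node_id)
  expect_error(select_key_targets(rec, "bogus"), "unknown rule")
  expect_length(suppressMessages(select_key_targets(rec, "top_frac:0.4")), 2)
})

test_that("median_all selections are always a subset of median_any", {
  set.seed(22)
  for (i in 1:10) {
    rec <- data.frame(node_id = sprintf("n%02d", 1:30),
                      degree = rpois(30, 4), betweenness = rexp(30),
                      closeness = runif(30))
    all_r <- suppressMessages(select_key_targets(rec, "median_all"))
    any_r <- suppressMessages(select_key_targets(rec, "median_any"))
    expect_true(all(all_r %in% any_r))
  }
})

test_that("planted hubs are selected as key targets across seeds", {
  hits <- 0; total <- 0
  for (s in 1:10) {
    cfg <- sim_config(n_genes = 300, n_metabolites = 40, n_per_group = 10,
                      frac_diff = 0.1, n_symptom_sets = 4, symptom_set_size = 20,
                      n_pathways = 6, pathway_size = 15, seed = s)
    sim <- simulate_cohort(cfg)
    run <- suppressMessages(suppressWarnings(run_pipeline(sim, sf_config(seed = s))))
    for (syn in c("Cold", "Hot")) {
      bg <- names(sim$truth$biomarker_genes)[sim$truth$biomarker_genes == syn]
      dg <- differential_ids(run$syndromes[[syn]]$differential_genes)
      bg <- intersect(bg, dg)    # hubs that survived the screen
      total <- total + length(bg)
      hits <- hits + sum(bg %in% run$syndromes[[syn]]$key_targets)
    }
  }
  expect_gte(hits / total, 0.95)
})
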