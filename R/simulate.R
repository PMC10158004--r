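#' Simulation configuration for synthetic multi-omics cohorts
#'
#' Defaults describe the reference study conditions used throughout the
#' test-suite and the acceptance experiments: 2000 genes, 200 metabolites,
#' 20 samples per group (NC / Cold / Hot), 5% differential features with
#' mean log2 effect 2 and unit log2 noise, and 5 planted biomarkers
#' (3 genes, 2 metabolites).
#'
#' @param n_genes,n_metabolites feature counts per layer.
#' @param n_per_group samples in each of NC, Cold, Hot.
#' @param frac_diff fraction of features planted as differential, split
#'   equally (and disjointly) between Cold-true and Hot-true sets;
#'   may be 0 for a null cohort.
#' @param effect_mean,effect_sd log2-scale effect-size distribution of
#'   planted shifts (signs random, magnitudes floored at 0.25).
#' @param noise_sd log2-scale Gaussian noise s.d.
#' @param baseline_mean,baseline_sd per-feature baseline log2 abundance
#'   distribution.
#' @param n_biomarker_genes,n_biomarker_metabolites planted biomarkers
#'   drawn from the true differential sets (genes: 2 Cold + remainder
#'   Hot; metabolites: alternating Cold/Hot).
#' @param n_symptom_sets symptom gene sets, split between the syndromes.
#' @param symptom_set_size genes per symptom set.
#' @param n_pathways,pathway_size pathway gene sets.
#' @param overlap_enrichment sampling weight multiplier making true
#'   differential genes of the matching syndrome more likely symptom-set
#'   members; must be >= 1, 1 = uniform sampling.
#' @param graph_model `"preferential_attachment"` or `"erdos_renyi"`.
#' @param pa_m edges attached per new node (preferential attachment).
#' @param er_p edge probability (Erdos-Renyi).
#' @param hub_extra_links interaction edges wired from each planted
#'   biomarker gene to true differential genes of its syndrome, making
#'   biomarker genes hubs among the differential set.
#' @param tissue tissue label stamped on all simulated samples.
#' @param seed master seed; every random draw in the simulator flows
#'   from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_metabolites = 200, n_per_group = 20,
                       frac_diff = 0.05, effect_mean = 2, effect_sd = 0.5,
                       noise_sd = 1, baseline_mean = 10, baseline_sd = 1.5,
                       n_biomarker_genes = 3, n_biomarker_metabolites = 2,
                       n_symptom_sets = 6, symptom_set_size = 30,
                       n_pathways = 20, pathway_size = 30,
                       overlap_enrichment = 10,
                       graph_model = c("preferential_attachment", "erdos_renyi"),
                       pa_m = 2, er_p = 0.005, hub_extra_links = 15,
                       tissue = "synovial_tissue", seed = 1) {
  graph_model <- match.arg(graph_model)
  cfg <- as.list(environment())
  counts <- c("n_genes", "n_metabolites", "n_per_group", "n_symptom_sets",
              "symptom_set_size", "n_pathways", "pathway_size", "pa_m")
  for (k in counts)
    if (cfg[[k]] < 1) stop("`", k, "` must be at least 1")
  if (frac_diff < 0 || frac_diff >= 1) stop("`frac_diff` must lie in [0, 1)")
  if (noise_sd <= 0) stop("`noise_sd` must be positive")
  if (overlap_enrichment < 1) stop("`overlap_enrichment` must be >= 1")
  if (n_per_group < 2) stop("`n_per_group` must be at least 2")
  if (n_per_group < 3)
    warning("n_per_group < 3: downstream tests may be underpowered")
  structure(cfg, class = "sim_config")
}

#' Generate a three-group multi-omics cohort with planted truth
#'
#' Log2 abundances are baseline + group-specific shift (for planted
#' features, in their syndrome's samples only) + Gaussian noise.  NC
#' carries no shifts; Cold-true and Hot-true feature sets are disjoint.
#'
#' @param cfg a [sim_config()].
#' @param truth optionally, a truth object from a previous call: the same
#'   planted effects are then re-used with fresh noise, producing an
#'   independent validation cohort of the same population.
#' @param seed overrides `cfg$seed` (e.g. for replicate cohorts).
#' @return A list with `genes` and `metabolites` ([omics_table()]s) and
#'   `truth` (class `sim_truth`): per-layer true feature ids with signed
#'   log2 effects, planted biomarker ids, and slots filled later by the
#'   network/annotation generators.
#' @export
generate_cohort <- function(cfg, truth = NULL, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  groups <- rep(c("NC", "Cold", "Hot"), each = cfg$n_per_group)
  samples <- sprintf("s%03d_%s", seq_along(groups), groups)
  meta <- data.frame(sample_id = samples, group = groups,
                     tissue = cfg$tissue, stringsAsFactors = FALSE)
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  met_ids <- sprintf("m%04d", seq_len(cfg$n_metabolites))

  if (is.null(truth)) {
    truth <- with_seed(sub_seed(seed, 1), plant_truth(cfg, gene_ids, met_ids))
  }
  sim_layer <- function(ids, eff, sub) {
    with_seed(sub_seed(seed, sub), {
      base <- stats::rnorm(length(ids), cfg$baseline_mean, cfg$baseline_sd)
      m <- matrix(stats::rnorm(length(ids) * length(samples), 0, cfg$noise_sd),
                  nrow = length(ids),
                  dimnames = list(ids, samples)) + base
      for (grp in c("Cold", "Hot")) {
        e <- eff[[grp]]
        if (length(e))
          m[names(e), groups == grp] <- m[names(e), groups == grp] + e
      }
      pmax(m, 0)
    })
  }
  genes <- sim_layer(gene_ids, truth$gene_effects, 2)
  mets <- sim_layer(met_ids, truth$metabolite_effects, 3)
  list(
    genes = omics_table(genes, meta, "gene"),
    metabolites = omics_table(mets, meta, "metabolite"),
    truth = truth
  )
}

# Draw the planted ground truth: which features are differential, with
# what signed log2 effect, and which of them are the biomarkers.
plant_truth <- function(cfg, gene_ids, met_ids) {
  draw_effects <- function(ids, n_true) {
    if (n_true == 0)
      return(list(Cold = stats::setNames(numeric(0), character(0)),
                  Hot = stats::setNames(numeric(0), character(0))))
    chosen <- sample(ids, n_true)
    half <- ceiling(n_true / 2)
    eff <- sample(c(-1, 1), n_true, replace = TRUE) *
      pmax(abs(stats::rnorm(n_true, cfg$effect_mean, cfg$effect_sd)), 0.25)
    list(Cold = stats::setNames(eff[seq_len(half)], chosen[seq_len(half)]),
         Hot = stats::setNames(eff[-seq_len(half)], chosen[-seq_len(half)]))
  }
  ge <- draw_effects(gene_ids, round(cfg$frac_diff * length(gene_ids)))
  me <- draw_effects(met_ids, round(cfg$frac_diff * length(met_ids)))
  # biomarkers are the strongest-effect true features of their syndrome
  # (mirrors selection "due to significant differences")
  pick <- function(eff, n, syndromes) {
    out <- character(0); syn <- character(0)
    for (s in syndromes) {
      pool <- setdiff(names(eff[[s]]), out)
      if (length(pool) && length(out) < n) {
        best <- pool[which.max(abs(eff[[s]][pool]))]
        out <- c(out, best); syn <- c(syn, s)
      }
    }
    stats::setNames(syn, out)
  }
  n_bg <- cfg$n_biomarker_genes; n_bm <- cfg$n_biomarker_metabolites
  bg <- pick(ge, n_bg, rep_len(c("Cold", "Cold", "Hot"), n_bg))
  bm <- pick(me, n_bm, rep_len(c("Cold", "Hot"), n_bm))
  structure(list(
    true_deg_ids = c(names(ge$Cold), names(ge$Hot)),
    gene_effects = ge,
    true_diff_metabolite_ids = c(names(me$Cold), names(me$Hot)),
    metabolite_effects = me,
    biomarker_genes = bg,          # named vector: id -> syndrome
    biomarker_metabolites = bm,
    planted_biomarker_ids = c(names(bg), names(bm)),
    network_hub_ids = character(0),
    symptom_sets_planted_overlap = integer(0)
  ), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d true DEGs, %d true differential metabolites, %d planted biomarkers\n",
              length(x$true_deg_ids), length(x$true_diff_metabolite_ids),
              length(x$planted_biomarker_ids)))
  invisible(x)
}

#' Generate a gene-gene interaction network
#'
#' Either a preferential-attachment graph (seed clique of `pa_m + 1`
#' nodes, every later node attaching to `pa_m` distinct degree-weighted
#' targets, hence exactly `choose(pa_m + 1, 2) + pa_m * (n - pa_m - 1)`
#' edges) or an Erdos-Renyi G(n, p) graph.  Planted biomarker genes are
#' additionally wired to `hub_extra_links` true differential genes of
#' their syndrome so that they are hubs among the differential set; hub
#' ids are recorded in the returned truth.
#'
#' @param cfg a [sim_config()].
#' @param gene_ids gene identifiers from [generate_cohort()].
#' @param truth the matching `sim_truth`.
#' @param seed overrides `cfg$seed`.
#' @return A list with `edges` (an [edge_table()] with STRING-scale
#'   confidences) and the updated `truth` (`network_hub_ids` filled).
#' @export
generate_interaction_network <- function(cfg, gene_ids, truth, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  n <- length(gene_ids)
  with_seed(sub_seed(seed, 4), {
    if (cfg$graph_model == "preferential_attachment") {
      m <- cfg$pa_m
      if (n < m + 2) stop("need at least pa_m + 2 nodes")
      ord <- sample(gene_ids)                 # hub identity is random
      deg <- stats::setNames(integer(n), ord)
      a <- b <- character(choose(m + 1, 2) + m * (n - m - 1)); k <- 0L
      for (i in seq_len(m + 1)) for (j in seq_len(m + 1)) if (i < j) {
        k <- k + 1L; a[k] <- ord[i]; b[k] <- ord[j]
        deg[c(i, j)] <- deg[c(i, j)] + 1L
      }
      for (v in (m + 2):n) {
        targets <- sample(ord[seq_len(v - 1)], m, prob = deg[seq_len(v - 1)])
        for (tg in targets) {
          k <- k + 1L; a[k] <- ord[v]; b[k] <- tg
          deg[tg] <- deg[tg] + 1L
        }
        deg[ord[v]] <- deg[ord[v]] + m
      }
      edges <- data.frame(node_a = a, node_b = b, stringsAsFactors = FALSE)
    } else {
      g <- igraph::sample_gnp(n, cfg$er_p)
      el <- igraph::as_edgelist(g)
      edges <- data.frame(node_a = gene_ids[as.integer(el[, 1])],
                          node_b = gene_ids[as.integer(el[, 2])],
                          stringsAsFactors = FALSE)
    }
    # wire planted biomarker genes as hubs among the true DEGs
    bg <- truth$biomarker_genes
    for (id in names(bg)) {
      pool <- setdiff(names(truth$gene_effects[[bg[[id]]]]), id)
      extra <- sample(pool, min(cfg$hub_extra_links, length(pool)))
      edges <- rbind(edges, data.frame(node_a = id, node_b = extra,
                                       stringsAsFactors = FALSE))
    }
    edges$confidence <- round(stats::runif(nrow(edges), 400, 1000))
    et <- edge_table(edges)
    deg_final <- table(c(et$node_a, et$node_b))
    top <- names(sort(deg_final, decreasing = TRUE))[seq_len(min(10, length(deg_final)))]
    truth$network_hub_ids <- union(names(bg), top)
    list(edges = et, truth = truth)
  })
}

#' Generate symptom sets, pathway sets and metabolite-gene associations
#'
#' Symptom sets (half per syndrome) sample genes with
#' `overlap_enrichment`-fold higher weight for true differential genes of
#' the matching syndrome; when the factor exceeds 1 each planted biomarker
#' gene is deterministically included in the first symptom set of its
#' syndrome.  One pathway per syndrome is seeded with that syndrome's
#' biomarker genes, their interaction neighbours and the genes linked to
#' its biomarker metabolites; remaining pathways are uniform draws.
#' Every planted biomarker metabolite receives three curated `enzyme`
#' links to true differential genes of its syndrome (at least one of them
#' a planted biomarker gene); other metabolites get Poisson(1.2) uniform
#' `association` links.
#'
#' @param cfg a [sim_config()].
#' @param truth a `sim_truth` (after [generate_interaction_network()]).
#' @param gene_ids,met_ids feature id vectors.
#' @param interactions the interaction [edge_table()] (used to seed
#'   pathway neighbourhoods; may be `NULL`).
#' @param seed overrides `cfg$seed`.
#' @return A list with `symptom_sets`, `pathway_sets`
#'   (both [gene_set_collection()]s), `met_gene` (an [edge_table()] with
#'   a `relation` column), and the updated `truth`
#'   (`symptom_sets_planted_overlap` filled).
#' @export
generate_annotation_maps <- function(cfg, truth, gene_ids, met_ids,
                                     interactions = NULL, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  with_seed(sub_seed(seed, 5), {
    syndromes <- rep_len(c("Cold", "Hot"), cfg$n_symptom_sets)
    symptom_sets <- list()
    for (i in seq_len(cfg$n_symptom_sets)) {
      syn <- syndromes[i]
      w <- rep(1, length(gene_ids))
      w[gene_ids %in% names(truth$gene_effects[[syn]])] <- cfg$overlap_enrichment
      forced <- character(0)
      if (cfg$overlap_enrichment > 1 && i <= 2) {      # first set of each syndrome
        forced <- names(truth$biomarker_genes)[truth$biomarker_genes == syn]
      }
      rest <- sample(setdiff(gene_ids, forced), cfg$symptom_set_size - length(forced),
                     prob = w[!(gene_ids %in% forced)])
      symptom_sets[[sprintf("symptom_%s_%d", syn, ceiling(i / 2))]] <-
        list(description = sprintf("%s-syndrome symptom set", syn),
             members = c(forced, rest))
    }
    symptom_sets <- gene_set_collection(symptom_sets, "symptom")

    # metabolite-gene association table
    assoc <- list()
    bm <- truth$biomarker_metabolites
    for (id in met_ids) {
      if (id %in% names(bm)) {
        syn <- bm[[id]]
        pool <- names(truth$gene_effects[[syn]])
        bg_syn <- names(truth$biomarker_genes)[truth$biomarker_genes == syn]
        link <- unique(c(
          if (length(bg_syn)) sample(bg_syn, 1) else character(0),
          sample(setdiff(pool, bg_syn), min(2, length(setdiff(pool, bg_syn))))
        ))
        assoc[[id]] <- data.frame(node_a = id, node_b = link,
                                  relation = "enzyme", stringsAsFactors = FALSE)
      } else {
        nl <- stats::rpois(1, 1.2)
        if (nl > 0)
          assoc[[id]] <- data.frame(node_a = id,
                                    node_b = sample(gene_ids, min(nl, length(gene_ids))),
                                    relation = "association",
                                    stringsAsFactors = FALSE)
      }
    }
    assoc <- do.call(rbind, assoc)
    met_gene <- edge_table(assoc)

    # pathway sets; the first two are seeded around the planted biomarkers
    nbrs <- function(ids) {
      if (is.null(interactions) || !length(ids)) return(character(0))
      hit <- interactions$node_a %in% ids | interactions$node_b %in% ids
      setdiff(unique(c(interactions$node_a[hit], interactions$node_b[hit])), ids)
    }
    pathway_sets <- list()
    for (i in seq_len(cfg$n_pathways)) {
      if (i <= 2) {
        syn <- c("Cold", "Hot")[i]
        bg_syn <- names(truth$biomarker_genes)[truth$biomarker_genes == syn]
        bm_syn <- names(bm)[bm == syn]
        linked <- met_gene$node_b[met_gene$node_a %in% bm_syn]
        core <- unique(c(bg_syn, linked))
        nb <- nbrs(bg_syn)
        extra_n <- max(cfg$pathway_size - length(core), 0)
        fill <- c(sample(nb, min(length(nb), ceiling(extra_n / 2))),
                  sample(setdiff(gene_ids, core), extra_n))
        members <- unique(c(core, fill))[seq_len(min(cfg$pathway_size + length(core),
                                                     length(unique(c(core, fill)))))]
        desc <- sprintf("%s-syndrome seeded pathway", syn)
      } else {
        members <- sample(gene_ids, cfg$pathway_size)
        desc <- "background pathway"
      }
      pathway_sets[[sprintf("pathway_%02d", i)]] <-
        list(description = desc, members = members)
    }
    pathway_sets <- gene_set_collection(pathway_sets, "pathway")

    truth$symptom_sets_planted_overlap <- vapply(
      names(symptom_sets),
      function(s) sum(set_members(symptom_sets, s) %in% truth$true_deg_ids),
      integer(1)
    )
    list(symptom_sets = symptom_sets, pathway_sets = pathway_sets,
         met_gene = met_gene, truth = truth)
  })
}

#' Simulate a complete multi-omics cohort bundle
#'
#' Convenience wrapper chaining [generate_cohort()],
#' [generate_interaction_network()] and [generate_annotation_maps()].
#'
#' @param cfg a [sim_config()].
#' @param seed overrides `cfg$seed`.
#' @param truth re-use planted effects from a previous cohort (fresh
#'   noise), e.g. to create a validation cohort.
#' @return A list with `genes`, `metabolites`, `interactions`,
#'   `symptom_sets`, `pathway_sets`, `met_gene`, `truth`.
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = cfg$seed, truth = NULL) {
  ch <- generate_cohort(cfg, truth = truth, seed = seed)
  net <- generate_interaction_network(cfg, feature_ids(ch$genes), ch$truth, seed = seed)
  ann <- generate_annotation_maps(cfg, net$truth, feature_ids(ch$genes),
                                  feature_ids(ch$metabolites),
                                  interactions = net$edges, seed = seed)
  list(genes = ch$genes, metabolites = ch$metabolites,
       interactions = net$edges, symptom_sets = ann$symptom_sets,
       pathway_sets = ann$pathway_sets, met_gene = ann$met_gene,
       truth = ann$truth)
}

#' Write a simulated cohort bundle to a directory
#'
#' Emits the six pipeline input files in the formats the readers accept,
#' plus `truth.tsv` listing every planted effect.
#'
#' @param sim output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_feature_table(sim$genes, fp("genes.tsv"), fp("samples.tsv"))
  write_feature_table(sim$metabolites, fp("metabolites.tsv"))
  write_edge_list(sim$interactions, fp("interactions.tsv"))
  write_gmt(sim$symptom_sets, fp("symptom_sets.gmt"))
  write_gmt(sim$pathway_sets, fp("pathway_sets.gmt"))
  write_edge_list(sim$met_gene, fp("metabolite_gene.tsv"))
  tr <- sim$truth
  eff <- c(tr$gene_effects$Cold, tr$gene_effects$Hot,
           tr$metabolite_effects$Cold, tr$metabolite_effects$Hot)
  syn <- c(rep("Cold", length(tr$gene_effects$Cold)),
           rep("Hot", length(tr$gene_effects$Hot)),
           rep("Cold", length(tr$metabolite_effects$Cold)),
           rep("Hot", length(tr$metabolite_effects$Hot)))
  utils::write.table(
    data.frame(feature_id = names(eff), syndrome = syn, log2_effect = eff,
               is_biomarker = names(eff) %in% tr$planted_biomarker_ids),
    fp("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
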