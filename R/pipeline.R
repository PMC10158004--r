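#' Run the full network-fusion pipeline on a cohort bundle
#'
#' For each syndrome contrast (Cold vs NC, Hot vs NC): PLS-DA VIP scoring
#' and composite differential calling on both omics layers, association
#' network construction from the syndrome's symptom sets, centrality
#' computation and key-target selection, hypergeometric pathway
#' enrichment of the key targets, gene-metabolite correlation plus
#' curated association mapping, multi-level network assembly, and
#' composite biomarker ranking.  Optionally the ranked candidates are
#' validated by ROC on a held-out cohort.
#'
#' @param sim a cohort bundle from [simulate_cohort()] or an equivalent
#'   list of loaded inputs (`genes`, `metabolites`, `interactions`,
#'   `symptom_sets`, `pathway_sets`, `met_gene`).
#' @param cfg an [sf_config()].
#' @param validation optional held-out bundle (only `genes` and
#'   `metabolites` are used) for [validate_biomarkers()].
#' @param vip_components PLS-DA components for VIP scoring; `NULL`
#'   selects by cross-validation per contrast.
#' @param top_k candidates carried into validation (default 10).
#' @return An object of class `sf_run`: per-syndrome list with
#'   `differential_genes`, `differential_metabolites`, `network`,
#'   `centralities`, `key_targets`, `enrichment`, `correlations`,
#'   `met_map`, `fused`, `biomarkers`, `validation`.
#' @export
run_pipeline <- function(sim, cfg = sf_config(), validation = NULL,
                         vip_components = 2, top_k = 10) {
  stopifnot(inherits(sim$genes, "omics_table"),
            inherits(sim$metabolites, "omics_table"))
  res <- list()
  for (syndrome in c("Cold", "Hot")) {
    contrast <- c(syndrome, "NC")
    dg <- screen_layer(sim$genes, contrast, cfg, scale = FALSE, vip_components)
    dm <- screen_layer(sim$metabolites, contrast, cfg, scale = TRUE, vip_components)

    if (!length(differential_ids(dg))) {
      res[[syndrome]] <- empty_syndrome_result(dg, dm)
      next
    }
    sympt <- symptom_subset(sim$symptom_sets, syndrome)
    net <- build_association_network(dg, sympt, sim$interactions, cfg,
                                     syndrome = syndrome,
                                     policy = if (cfg$key_target_rule == "intersection_neighbors")
                                       "intersection_neighbors" else "union")
    cent <- node_centralities(net)
    kt <- select_key_targets(cent, rule = cfg$key_target_rule,
                             multiplier = cfg$median_multiplier)
    universe <- union(feature_ids(sim$genes),
                      unlist(lapply(names(sim$pathway_sets),
                                    function(s) set_members(sim$pathway_sets, s))))
    enr <- hypergeometric_enrich(kt, sim$pathway_sets, universe, cfg)

    dg_ids <- differential_ids(dg)
    dm_ids <- differential_ids(dm)
    corr <- if (length(dg_ids) && length(dm_ids))
      correlate_gene_metabolite(sim$genes, sim$metabolites, dg_ids, dm_ids, cfg)
    else empty_correlation_table()
    met_map <- map_metabolites_to_genes(dm_ids, sim$met_gene)
    gm <- rbind(
      if (nrow(corr)) data.frame(gene_id = corr$gene_id[corr$retained],
                                 metabolite_id = corr$metabolite_id[corr$retained],
                                 edge_type = "correlation", stringsAsFactors = FALSE),
      if (nrow(met_map)) data.frame(gene_id = met_map$gene_id,
                                    metabolite_id = met_map$metabolite_id,
                                    edge_type = "association", stringsAsFactors = FALSE)
    )
    if (is.null(gm))
      gm <- data.frame(gene_id = character(0), metabolite_id = character(0),
                       edge_type = character(0), stringsAsFactors = FALSE)
    fused <- assemble_multilevel_network(net, kt, dm_ids, gm, enr,
                                         sim$pathway_sets, syndrome = syndrome)
    bio <- rank_biomarker_candidates(fused, cent, dg, dm, met_map)
    val <- NULL
    if (!is.null(validation) && nrow(bio)) {
      top <- bio$entity_id[seq_len(min(top_k, nrow(bio)))]
      val <- validate_biomarkers(top, validation$genes, validation$metabolites,
                                 contrasts = list(contrast))
    }
    res[[syndrome]] <- list(
      differential_genes = dg, differential_metabolites = dm,
      network = net, centralities = cent, key_targets = kt,
      enrichment = enr, correlations = corr, met_map = met_map,
      fused = fused, biomarkers = bio, validation = val
    )
  }
  structure(list(syndromes = res, cfg = cfg,
                 truth = sim$truth), class = "sf_run")
}

# Result shell for a contrast with no differential genes (null cohorts):
# the evidence chain cannot start, so every network-level slot is empty.
empty_syndrome_result <- function(dg, dm) {
  bio <- data.frame(entity_id = character(0), entity_kind = character(0),
                    composite_score = numeric(0), rank = integer(0))
  class(bio) <- c("biomarker_table", "data.frame")
  enr <- data.frame(set_id = character(0), k = integer(0), n = integer(0),
                    K = integer(0), N = integer(0), p = numeric(0),
                    q = numeric(0), enriched = logical(0))
  class(enr) <- c("enrichment_table", "data.frame")
  list(differential_genes = dg, differential_metabolites = dm,
       network = NULL, centralities = NULL, key_targets = character(0),
       enrichment = enr, correlations = empty_correlation_table(),
       met_map = data.frame(gene_id = character(0), metabolite_id = character(0),
                            relation = character(0)),
       fused = NULL, biomarkers = bio, validation = NULL)
}

# VIP-scored differential screen of one omics layer for one contrast.
screen_layer <- function(table, contrast, cfg, scale, vip_components) {
  sub <- subset_samples(table, table$sample_meta$group %in% contrast)
  labels <- sub$sample_meta$group
  A <- vip_components
  if (is.null(A)) {
    cv <- cross_validate_components(sub, labels, A_max = 3, k = 10,
                                    seed = cfg$seed, scale = scale)
    A <- cv$A_star
  }
  A <- min(A, ncol(sub$values) - 1, nrow(sub$values))
  vip <- tryCatch(vip_scores(fit_plsda(sub, labels, A = A, scale = scale)),
                  error = function(e) NULL)
  suppressMessages(
    call_differential_features(sub, contrast, vip = vip, cfg = cfg)
  )
}

# Symptom sets belonging to one syndrome (by the naming convention of the
# simulator); collections without the convention are used whole.
symptom_subset <- function(symptom_sets, syndrome) {
  hit <- grepl(paste0("_", syndrome, "_"), names(symptom_sets), fixed = TRUE)
  if (!any(hit)) return(symptom_sets)
  gene_set_collection(symptom_sets[hit], "symptom")
}

#' @export
print.sf_run <- function(x, ...) {
  cat("sf_run: network-fusion pipeline result\n")
  for (s in names(x$syndromes)) {
    r <- x$syndromes[[s]]
    cat(sprintf("  %s: %d differential genes, %d differential metabolites, %d key targets, %d enriched pathways, %d candidates\n",
                s, length(differential_ids(r$differential_genes)),
                length(differential_ids(r$differential_metabolites)),
                length(r$key_targets), sum(r$enrichment$enriched),
                nrow(r$biomarkers)))
  }
  invisible(x)
}

#' @export
summary.sf_run <- function(object, top_k = 10, ...) {
  print(object)
  for (s in names(object$syndromes)) {
    b <- object$syndromes[[s]]$biomarkers
    cat(sprintf("\n  top candidates (%s):\n", s))
    print(utils::head(b[, c("entity_id", "entity_kind", "composite_score", "rank")],
                      top_k), row.names = FALSE)
  }
  invisible(object)
}

#' Top-ranked candidate ids across syndromes
#'
#' @param run an `sf_run`.
#' @param top_k per-syndrome depth (default 10).
#' @return Named list of character vectors, one per syndrome.
#' @export
top_candidates <- function(run, top_k = 10) {
  lapply(run$syndromes, function(r) {
    b <- r$biomarkers
    b$entity_id[seq_len(min(top_k, nrow(b)))]
  })
}

#' Write every stage's result tables to a directory
#'
#' @param run an `sf_run`.
#' @param dir output directory.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(as.data.frame(df), file.path(dir, f),
                                           sep = "\t", quote = FALSE, row.names = FALSE)
  write_config(run$cfg, file.path(dir, "config.yaml"))
  for (s in names(run$syndromes)) {
    r <- run$syndromes[[s]]
    wt(r$differential_genes, sprintf("differential_genes_%s.tsv", s))
    wt(r$differential_metabolites, sprintf("differential_metabolites_%s.tsv", s))
    wt(r$centralities, sprintf("centralities_%s.tsv", s))
    wt(r$enrichment, sprintf("enrichment_%s.tsv", s))
    wt(r$biomarkers, sprintf("biomarker_candidates_%s.tsv", s))
    write_network(r$fused, file.path(dir, sprintf("fused_nodes_%s.tsv", s)),
                  file.path(dir, sprintf("fused_edges_%s.tsv", s)))
    if (!is.null(r$validation)) wt(r$validation, sprintf("validation_%s.tsv", s))
  }
  invisible(dir)
}
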