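#' Spearman correlation edges between genes and metabolites
#'
#' Spearman's rank correlation (average ranks for ties) between every
#' supplied gene and metabolite over the shared samples.  P-values come
#' from the t approximation, or the exact permutation distribution when
#' `n <= 9` (and no ties); BH adjustment runs across all tested pairs.
#' A pair is `retained` iff `q < q_max` and `|r| > r_min`.
#'
#' @param genes,metabolites [omics_table()]s sharing sample ids.
#' @param gene_ids,met_ids feature subsets to test (default: all rows;
#'   in the pipeline, the differential features).
#' @param cfg an [sf_config()].
#' @return A data.frame of class `correlation_table` with columns
#'   `gene_id`, `metabolite_id`, `r`, `p`, `q`, `retained`; pairs with a
#'   constant vector are skipped (count reported via a message).
#' @export
correlate_gene_metabolite <- function(genes, metabolites,
                                      gene_ids = feature_ids(genes),
                                      met_ids = feature_ids(metabolites),
                                      cfg = sf_config()) {
  shared <- intersect(sample_ids(genes), sample_ids(metabolites))
  if (length(shared) < 4) stop("need at least 4 shared samples")
  G <- genes$values[gene_ids, shared, drop = FALSE]
  M <- metabolites$values[met_ids, shared, drop = FALSE]
  const_g <- apply(G, 1, function(v) length(unique(v)) == 1L)
  const_m <- apply(M, 1, function(v) length(unique(v)) == 1L)
  n_skip <- sum(const_g) * nrow(M) + sum(const_m) * nrow(G) -
    sum(const_g) * sum(const_m)
  if (n_skip > 0)
    message(n_skip, " pair(s) with a constant vector skipped")
  G <- G[!const_g, , drop = FALSE]; M <- M[!const_m, , drop = FALSE]
  if (!nrow(G) || !nrow(M))
    return(empty_correlation_table())
  n <- length(shared)
  Rg <- t(apply(G, 1, rank)); Rm <- t(apply(M, 1, rank))
  r <- stats::cor(t(Rg), t(Rm))                    # genes x metabolites
  if (n <= 9 && !anyDuplicated(c(G)) && !anyDuplicated(c(M))) {
    p <- matrix(NA_real_, nrow(G), nrow(M))
    for (i in seq_len(nrow(G))) for (j in seq_len(nrow(M))) {
      p[i, j] <- suppressWarnings(
        stats::cor.test(G[i, ], M[j, ], method = "spearman", exact = TRUE)$p.value)
    }
  } else {
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p[abs(r) >= 1] <- 0
  }
  out <- data.frame(
    gene_id = rep(rownames(G), times = nrow(M)),
    metabolite_id = rep(rownames(M), each = nrow(G)),
    r = as.vector(r), p = pmin(as.vector(p), 1),
    stringsAsFactors = FALSE
  )
  out$q <- bh_adjust(out$p)
  out$retained <- out$q < cfg$q_max & abs(out$r) > cfg$r_min
  class(out) <- c("correlation_table", "data.frame")
  out
}

empty_correlation_table <- function() {
  out <- data.frame(gene_id = character(0), metabolite_id = character(0),
                    r = numeric(0), p = numeric(0), q = numeric(0),
                    retained = logical(0), stringsAsFactors = FALSE)
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' Map differential metabolites to their associated genes
#'
#' Join against a curated metabolite-gene association table; metabolites
#' without any association are listed in the `unmapped` attribute.
#'
#' @param diff_metabolites metabolite ids.
#' @param assoc an [edge_table()] with metabolites in `node_a`, genes in
#'   `node_b` and an optional `relation` column
#'   (`enzyme` / `transport` / `association`).
#' @return A data.frame with `gene_id`, `metabolite_id`, `relation` and
#'   attribute `unmapped`.
#' @export
map_metabolites_to_genes <- function(diff_metabolites, assoc) {
  hit <- assoc$node_a %in% diff_metabolites
  out <- data.frame(gene_id = assoc$node_b[hit],
                    metabolite_id = assoc$node_a[hit],
                    relation = if ("relation" %in% names(assoc))
                      assoc$relation[hit] else rep("association", sum(hit)),
                    stringsAsFactors = FALSE)
  attr(out, "unmapped") <- setdiff(diff_metabolites, out$metabolite_id)
  out
}

#' Assemble the multi-level disease-syndrome-symptom-gene-metabolite-pathway network
#'
#' The gene layer is restricted to the key targets plus genes that carry
#' a correlation or association edge to a differential metabolite;
#' pathway nodes exist only for enriched sets and are wired to their
#' member genes in the layer and, through the metabolite-gene
#' associations, to metabolites (orphan pathways are dropped).
#'
#' @param assoc_net the `association_network` of the syndrome.
#' @param key_targets gene ids from [select_key_targets()].
#' @param diff_metabolites differential metabolite ids.
#' @param gm_edges gene-metabolite edges: data.frame with `gene_id`,
#'   `metabolite_id` and an `edge_type` column (`"correlation"` or
#'   `"association"`), e.g. the union of retained [correlate_gene_metabolite()]
#'   rows and [map_metabolites_to_genes()] rows.
#' @param enrichment an `enrichment_table` for the key targets.
#' @param pathway_sets the pathway [gene_set_collection()].
#' @param disease,syndrome labels for the apex nodes.
#' @return A `multilevel_network`: list with typed `nodes`
#'   (`id`, `type`, `status`) and typed `edges` (`from`, `to`, `type`).
#' @export
assemble_multilevel_network <- function(assoc_net, key_targets, diff_metabolites,
                                        gm_edges, enrichment, pathway_sets,
                                        disease = "disease", syndrome = "syndrome") {
  if (!length(key_targets)) stop("empty key-target set")
  gm_edges <- gm_edges[gm_edges$metabolite_id %in% diff_metabolites, , drop = FALSE]
  genes <- union(key_targets, unique(gm_edges$gene_id))
  mets <- unique(c(diff_metabolites, gm_edges$metabolite_id))

  an <- assoc_net$nodes
  status <- stats::setNames(an$status, an$id)
  symptoms <- an$id[an$type == "symptom"]
  gene_status <- unname(ifelse(is.na(status[genes]) | status[genes] == "none",
                               "ns", status[genes]))

  e_synd <- data.frame(from = disease, to = syndrome, type = "disease-syndrome",
                       stringsAsFactors = FALSE)
  ae <- assoc_net$edges
  e_sym <- ae[ae$type == "syndrome-symptom", , drop = FALSE]
  e_sym$from <- syndrome
  e_sg <- ae[ae$type == "symptom-gene" & ae$to %in% genes, , drop = FALSE]
  e_gg <- ae[ae$type == "gene-gene" & ae$from %in% genes & ae$to %in% genes, ,
             drop = FALSE]
  e_gm <- if (nrow(gm_edges))
    data.frame(from = gm_edges$gene_id, to = gm_edges$metabolite_id,
               type = paste0("gene-metabolite:", gm_edges$edge_type),
               stringsAsFactors = FALSE)
  else NULL

  enr <- enriched_ids(enrichment)
  e_gp <- e_mp <- NULL
  if (length(enr)) {
    e_gp <- do.call(rbind, lapply(enr, function(s) {
      m <- intersect(set_members(pathway_sets, s), genes)
      if (!length(m)) return(NULL)
      data.frame(from = m, to = s, type = "gene-pathway", stringsAsFactors = FALSE)
    }))
    # metabolite-pathway membership is biochemical: it flows through the
    # curated association edges only, never through correlation edges
    cur <- gm_edges[gm_edges$edge_type == "association", , drop = FALSE]
    if (nrow(cur)) {
      e_mp <- do.call(rbind, lapply(enr, function(s) {
        linked <- unique(cur$metabolite_id[
          cur$gene_id %in% set_members(pathway_sets, s)])
        if (!length(linked)) return(NULL)
        data.frame(from = linked, to = s, type = "metabolite-pathway",
                   stringsAsFactors = FALSE)
      }))
    }
  }
  pathways <- unique(c(e_gp$to, e_mp$to))   # orphan pathways never enter

  nodes <- rbind(
    data.frame(id = disease, type = "disease", status = "none", stringsAsFactors = FALSE),
    data.frame(id = syndrome, type = "syndrome", status = "none", stringsAsFactors = FALSE),
    if (length(symptoms))
      data.frame(id = symptoms, type = "symptom", status = "none", stringsAsFactors = FALSE),
    data.frame(id = genes, type = "gene", status = gene_status, stringsAsFactors = FALSE),
    if (length(mets))
      data.frame(id = mets, type = "metabolite", status = "none", stringsAsFactors = FALSE),
    if (length(pathways))
      data.frame(id = pathways, type = "pathway", status = "none", stringsAsFactors = FALSE)
  )
  rownames(nodes) <- NULL
  edges <- rbind(e_synd, e_sym, e_sg, e_gg, e_gm, e_gp, e_mp)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, key_targets = key_targets),
            class = "multilevel_network")
}

#' @export
print.multilevel_network <- function(x, ...) {
  tab <- table(x$nodes$type)
  cat("multilevel_network: ",
      paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
      "; ", nrow(x$edges), " edge(s)\n", sep = "")
  invisible(x)
}

#' Export a multi-level network as Cytoscape-loadable TSVs
#'
#' @param net a `multilevel_network` (or `association_network`).
#' @param node_path,edge_path output TSV paths.
#' @export
write_network <- function(net, node_path, edge_path) {
  utils::write.table(net$nodes, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(node_path)
}

#' Rank biomarker candidates by composite evidence score
#'
#' Candidates are (i) differential genes that are key targets, (ii)
#' differential metabolites, and (iii) enzyme genes of differential
#' metabolites (relation `enzyme` in the association table).  Each
#' candidate carries five evidence flags — differential, key target,
#' symptom-linked (for a metabolite: through a curated partner gene that
#' is a symptom-set member), linked across layers, member of an enriched
#' pathway — and the composite score
#' `sum(weight_f * flag_f) + w_centrality * z(degree)`, the degree
#' z-score taken within the fused network and standardized within entity
#' kind.  Flags that cannot apply to an entity kind (a metabolite cannot
#' be a network key target) are excluded and the remaining flag weights
#' rescaled, so that the evidence score is comparable across kinds.
#' Ranking is by score descending, ties broken lexicographically by id.
#'
#' @param net a `multilevel_network`.
#' @param centralities data.frame from [node_centralities()] (association
#'   network scope; used to keep key-target bookkeeping, may be `NULL`).
#' @param diff_genes,diff_metabolites `differential_table`s of the two
#'   layers.
#' @param met_map output of [map_metabolites_to_genes()].
#' @param weights named numeric vector of flag weights plus `centrality`;
#'   defaults to all ones.  All-zero weights are an error.
#' @return A data.frame of class `biomarker_table` with the flags,
#'   `composite_score` and `rank`.
#' @export
rank_biomarker_candidates <- function(net, centralities, diff_genes, diff_metabolites,
                                      met_map,
                                      weights = c(is_differential = 1, is_key_target = 1,
                                                  linked_symptom = 1,
                                                  linked_metabolite_or_gene = 1,
                                                  in_enriched_pathway = 1,
                                                  centrality = 1)) {
  stopifnot(inherits(net, "multilevel_network"))
  defaults <- c(is_differential = 1, is_key_target = 1, linked_symptom = 1,
                linked_metabolite_or_gene = 1, in_enriched_pathway = 1,
                centrality = 1)
  w <- defaults; w[names(weights)] <- weights
  if (all(w == 0)) stop("all weights are zero")

  ed <- net$edges
  gm <- ed[startsWith(ed$type, "gene-metabolite"), , drop = FALSE]
  symptom_genes <- unique(ed$to[ed$type == "symptom-gene"])
  pathway_genes <- unique(ed$from[ed$type == "gene-pathway"])
  pathway_mets <- unique(ed$from[ed$type == "metabolite-pathway"])

  # degree within the fused network
  all_ids <- net$nodes$id
  deg <- stats::setNames(numeric(length(all_ids)), all_ids)
  tab <- table(c(ed$from, ed$to))
  deg[names(tab)] <- as.numeric(tab)

  dg_ids <- differential_ids(diff_genes)
  dm_ids <- differential_ids(diff_metabolites)
  gene_cand <- intersect(intersect(dg_ids, net$key_targets), all_ids)
  met_cand <- intersect(dm_ids, all_ids)
  enzyme_genes <- unique(met_map$gene_id[met_map$relation == "enzyme" &
                                           met_map$metabolite_id %in% dm_ids])
  enzyme_only <- setdiff(intersect(enzyme_genes, all_ids), gene_cand)

  gm_cur <- gm[gm$type == "gene-metabolite:association", , drop = FALSE]
  row_of <- function(id, kind) {
    is_gene <- kind != "metabolite"
    linked <- if (is_gene) id %in% gm$from else id %in% gm$to
    sym <- if (is_gene) id %in% symptom_genes
           else any(gm_cur$from[gm_cur$to == id] %in% symptom_genes)
    data.frame(
      entity_id = id, entity_kind = kind,
      is_differential = id %in% c(dg_ids, dm_ids),
      is_key_target = id %in% net$key_targets,
      linked_symptom = sym,
      linked_metabolite_or_gene = linked,
      in_enriched_pathway = if (is_gene) id %in% pathway_genes
                            else id %in% pathway_mets,
      degree = unname(deg[id]),
      stringsAsFactors = FALSE
    )
  }
  rows <- c(lapply(gene_cand, row_of, kind = "gene"),
            lapply(met_cand, row_of, kind = "metabolite"),
            lapply(enzyme_only, row_of, kind = "enzyme-of-metabolite"))
  if (!length(rows)) {
    out <- data.frame(entity_id = character(0), entity_kind = character(0),
                      composite_score = numeric(0), rank = integer(0))
    class(out) <- c("biomarker_table", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)

  # degree z-score standardized within entity kind (gene-layer degrees and
  # metabolite-layer degrees live on different scales)
  z <- numeric(nrow(out))
  layer <- ifelse(out$entity_kind == "metabolite", "metabolite", "gene")
  for (ly in unique(layer)) {
    ref <- deg[net$nodes$id[net$nodes$type == ly]]
    i <- layer == ly
    s <- stats::sd(ref)
    z[i] <- if (is.na(s) || s == 0) 0 else (out$degree[i] - mean(ref)) / s
  }
  out$degree_z <- z
  flags <- c("is_differential", "is_key_target", "linked_symptom",
             "linked_metabolite_or_gene", "in_enriched_pathway")
  evidence <- drop(as.matrix(out[flags]) %*% w[flags])
  # metabolites have no key-target flag: rescale their remaining weights so
  # evidence scores are comparable across entity kinds
  is_met <- out$entity_kind == "metabolite"
  w_applicable <- sum(w[setdiff(flags, "is_key_target")])
  if (w_applicable > 0)
    evidence[is_met] <- evidence[is_met] * sum(w[flags]) / w_applicable
  out$composite_score <- evidence + w["centrality"] * z
  out <- out[order(-out$composite_score, out$entity_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("biomarker_table", "data.frame")
  out
}
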