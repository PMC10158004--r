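#' Build the disease-syndrome-symptom association network
#'
#' Gene nodes are, under the default `union` policy, the union of the
#' differential genes and the symptom-set members; under
#' `intersection_neighbors` the seed is their intersection expanded by
#' first neighbours in the interaction graph.  Gene-gene edges are the
#' interaction edges with both endpoints present; each symptom node is
#' wired to its member genes, and one syndrome node to all symptoms.
#'
#' @param deg_records a `differential_table` (from
#'   [call_differential_features()]) with at least one non-`ns` feature.
#' @param symptom_sets a symptom [gene_set_collection()].
#' @param interactions an interaction [edge_table()].
#' @param cfg an [sf_config()].
#' @param syndrome label for the syndrome node (default `"syndrome"`).
#' @param policy `"union"` or `"intersection_neighbors"`.
#' @return An `association_network`: list with `nodes`
#'   (`id`, `type`, `is_deg`, `status`) and `edges` (`from`, `to`, `type`).
#' @export
build_association_network <- function(deg_records, symptom_sets, interactions,
                                      cfg = sf_config(), syndrome = "syndrome",
                                      policy = c("union", "intersection_neighbors")) {
  policy <- match.arg(policy)
  degs <- differential_ids(deg_records)
  if (!length(degs)) stop("no differential genes to build the network from")
  members <- unique(unlist(lapply(names(symptom_sets),
                                  function(s) set_members(symptom_sets, s))))
  if (policy == "union") {
    genes <- union(degs, members)
  } else {
    seeds <- intersect(degs, members)
    hit <- interactions$node_a %in% seeds | interactions$node_b %in% seeds
    genes <- union(seeds, unique(c(interactions$node_a[hit], interactions$node_b[hit])))
  }
  if (!length(genes)) stop("zero gene nodes after applying the node policy")

  keep <- interactions$node_a %in% genes & interactions$node_b %in% genes
  gg <- data.frame(from = interactions$node_a[keep], to = interactions$node_b[keep],
                   type = "gene-gene", stringsAsFactors = FALSE)
  sg <- do.call(rbind, lapply(names(symptom_sets), function(s) {
    m <- intersect(set_members(symptom_sets, s), genes)
    if (!length(m)) return(NULL)
    data.frame(from = s, to = m, type = "symptom-gene", stringsAsFactors = FALSE)
  }))
  symptoms <- unique(sg$from)
  ss <- data.frame(from = syndrome, to = symptoms, type = "syndrome-symptom",
                   stringsAsFactors = FALSE)
  status <- stats::setNames(deg_records$status, deg_records$feature_id)
  nodes <- rbind(
    data.frame(id = genes, type = "gene",
               is_deg = genes %in% degs,
               status = unname(ifelse(is.na(status[genes]), "ns", status[genes])),
               stringsAsFactors = FALSE),
    data.frame(id = symptoms, type = "symptom", is_deg = FALSE, status = "none",
               stringsAsFactors = FALSE),
    data.frame(id = syndrome, type = "syndrome", is_deg = FALSE, status = "none",
               stringsAsFactors = FALSE)
  )
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = rbind(gg, sg, ss), policy = policy),
            class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  tab <- table(x$nodes$type)
  cat("association_network: ",
      paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
      "; ", nrow(x$edges), " edge(s)\n", sep = "")
  invisible(x)
}

#' Degree, betweenness and closeness of gene nodes
#'
#' Computed on the gene-gene interaction subgraph.  Betweenness uses
#' unnormalized undirected pair counts (each unordered pair of distinct
#' endpoints counted once); closeness uses the Wasserman-Faust
#' component-adjusted form `(r - 1)^2 / ((n - 1) * sum d)` where `r` is
#' the number of nodes reachable from `v` (including itself) and the sum
#' runs over their distances.  Isolated nodes score 0 everywhere.
#'
#' @param net an `association_network`.
#' @param scope node type whose induced subgraph is analysed
#'   (default `"gene"`).
#' @return A data.frame with `node_id`, `degree`, `betweenness`,
#'   `closeness`.
#' @export
node_centralities <- function(net, scope = "gene") {
  stopifnot(inherits(net, "association_network"))
  ids <- net$nodes$id[net$nodes$type == scope]
  etype <- paste(scope, scope, sep = "-")
  e <- net$edges[net$edges$type == etype, c("from", "to"), drop = FALSE]
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = data.frame(name = ids))
  g <- igraph::simplify(g)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  n <- length(ids)
  D <- igraph::distances(g)
  clo <- apply(D, 1, function(d) {
    reach <- is.finite(d)
    r <- sum(reach)                      # includes the node itself
    if (r <= 1 || n <= 1) return(0)
    (r - 1)^2 / ((n - 1) * sum(d[reach]))
  })
  data.frame(node_id = igraph::V(g)$name, degree = as.numeric(deg),
             betweenness = as.numeric(btw), closeness = as.numeric(clo),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select key network targets by topological importance
#'
#' Default rule `median_all`: keep nodes whose degree, betweenness and
#' closeness are all at or above `median_multiplier` times the respective
#' medians (ties at the threshold are kept).  The medians are taken over
#' the connected (degree >= 1) nodes: isolated genes carry no topological
#' information and would otherwise drag all three thresholds to zero,
#' making the rule vacuous.  When every node is isolated the medians fall
#' back to all scored nodes.
#' `median_any` requires any one centrality to reach its threshold;
#' `top_frac:x` keeps the top fraction `x` of nodes ranked by the sum of
#' within-metric ranks.
#'
#' @param records centrality data.frame from [node_centralities()].
#' @param rule selection rule string.
#' @param multiplier threshold multiplier on the medians (default 1).
#' @return Character vector of selected node ids.
#' @export
select_key_targets <- function(records, rule = "median_all", multiplier = 1) {
  if (!nrow(records)) stop("no centrality records")
  metrics <- c("degree", "betweenness", "closeness")
  if (rule %in% c("median_all", "median_any")) {
    ref <- records[records$degree >= 1, , drop = FALSE]
    if (!nrow(ref)) ref <- records
    thr <- vapply(metrics, function(m) multiplier * stats::median(ref[[m]]),
                  numeric(1))
    ok <- sapply(metrics, function(m) records[[m]] >= thr[[m]])
    keep <- if (rule == "median_all") rowSums(ok) == 3L else rowSums(ok) >= 1L
    message(sprintf("key-target rule %s: thresholds degree>=%.3g, betweenness>=%.3g, closeness>=%.3g; %d of %d kept",
                    rule, thr[1], thr[2], thr[3], sum(keep), nrow(records)))
    records$node_id[keep]
  } else if (grepl("^top_frac:", rule)) {
    frac <- as.numeric(sub("^top_frac:", "", rule))
    if (is.na(frac) || frac <= 0 || frac > 1) stop("unknown rule: ", rule)
    score <- rowSums(sapply(metrics, function(m) rank(records[[m]])))
    k <- max(1L, ceiling(frac * nrow(records)))
    records$node_id[order(-score, records$node_id)][seq_len(k)]
  } else {
    stop("unknown rule: ", rule)
  }
}
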