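#' Hypergeometric over-representation of a query gene set
#'
#' For each set in the collection (restricted to the universe) the
#' upper-tail hypergeometric probability of observing at least the
#' realised overlap `k` between the query (size `n`) and the set
#' (size `K`) in a universe of size `N`:
#' `p = sum_{i>=k} C(K,i) C(N-K, n-i) / C(N,n)`.
#' BH adjustment is applied across all tested sets.
#'
#' @param query character vector of gene ids; members outside the
#'   universe are dropped with a message.
#' @param collection a pathway [gene_set_collection()].
#' @param universe background gene ids.
#' @param cfg an [sf_config()] (`enrich_q_max` declares enrichment).
#' @param ease use the conservative EASE variant (overlap reduced by one
#'   before the tail computation; default `FALSE`).
#' @return A data.frame of class `enrichment_table`, sorted by `p`, with
#'   columns `set_id`, `k`, `n`, `K`, `N`, `p`, `q`, `enriched`.
#' @export
hypergeometric_enrich <- function(query, collection, universe, cfg = sf_config(),
                                  ease = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  dropped <- setdiff(query, universe)
  if (length(dropped))
    message(length(dropped), " query gene(s) outside the universe dropped")
  query <- intersect(query, universe)
  if (!length(query)) stop("empty query after restriction to the universe")
  N <- length(universe); n <- length(query)
  rec <- lapply(names(collection), function(s) {
    members <- intersect(set_members(collection, s), universe)
    K <- length(members)
    k <- length(intersect(query, members))
    keff <- if (ease) max(k - 1L, 0L) else k
    p <- if (keff == 0) 1.0 else
      stats::phyper(keff - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = s, k = k, n = n, K = K, N = N, p = min(p, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rec)
  out$q <- bh_adjust(out$p)
  out$enriched <- out$q < cfg$enrich_q_max
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Ids of enriched sets
#' @param records an `enrichment_table`.
#' @return Character vector of set ids flagged enriched.
#' @export
enriched_ids <- function(records) records$set_id[records$enriched]
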