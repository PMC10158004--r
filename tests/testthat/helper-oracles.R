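# Independent brute-force oracles used to cross-check the package's
# implementations.  These are deliberately naive and share no code with
# the package internals.

# Benjamini-Hochberg by the literal step-up definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  ps <- p[o]
  for (i in seq_len(m)) {
    q_sorted[i] <- min(pmin(m * ps[i:m] / (i:m), 1))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exact two-sided Mann-Whitney p by full enumeration of group labelings.
mw_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  u_of <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  u_obs <- u_of(x, y)
  combos <- utils::combn(length(pooled), m)
  us <- apply(combos, 2, function(i) u_of(pooled[i], pooled[-i]))
  lo <- mean(us <= u_obs + 1e-9)
  hi <- mean(us >= u_obs - 1e-9)
  list(U = u_obs, p = min(1, 2 * min(lo, hi)))
}

# Upper-tail hypergeometric probability by exact log-binomial sums.
hyper_oracle <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(n, K)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# All-pairs BFS giving distances and shortest-path counts from `s`.
bfs_paths <- function(adj, s) {
  n <- length(adj)
  dist <- rep(Inf, n); sigma <- numeric(n)
  dist[s] <- 0; sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- unique(nxt)
    for (w in frontier) {
      preds <- adj[[w]][dist[adj[[w]]] == dist[w] - 1]
      sigma[w] <- sum(sigma[preds])
    }
  }
  list(dist = dist, sigma = sigma)
}

# Degree / betweenness / closeness (Wasserman-Faust) by brute force.
centrality_oracle <- function(edges, ids) {
  n <- length(ids)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(nrow(edges))) {
    a <- match(edges$from[r], ids); b <- match(edges$to[r], ids)
    if (!(b %in% adj[[a]])) { adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a) }
  }
  deg <- vapply(adj, length, integer(1))
  bfs <- lapply(seq_len(n), function(s) bfs_paths(adj, s))
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (is.infinite(bfs[[s]]$dist[t])) next
    dst <- bfs[[s]]$dist[t]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (bfs[[s]]$dist[v] + bfs[[t]]$dist[v] == dst)
        btw[v] <- btw[v] + bfs[[s]]$sigma[v] * bfs[[t]]$sigma[v] / bfs[[s]]$sigma[t]
    }
  }
  clo <- vapply(seq_len(n), function(v) {
    d <- bfs[[v]]$dist
    reach <- is.finite(d)
    r <- sum(reach)
    if (r <= 1 || n <= 1) return(0)
    (r - 1)^2 / ((n - 1) * sum(d[reach]))
  }, numeric(1))
  data.frame(node_id = ids, degree = as.numeric(deg), betweenness = btw,
             closeness = clo, stringsAsFactors = FALSE)
}

# AUC as the average pairwise win probability, ties half-credited.
auc_pair_oracle <- function(pos, neg) {
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# A random simple undirected graph as an edge data.frame over `ids`.
random_graph <- function(ids, p_edge = 0.1) {
  pairs <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  data.frame(from = pairs[1, keep], to = pairs[2, keep], stringsAsFactors = FALSE)
}

# Wrap an edge data.frame as a gene-only association network so
# node_centralities() can run on it.
as_gene_net <- function(edges, ids) {
  structure(list(
    nodes = data.frame(id = ids, type = "gene", is_deg = FALSE, status = "ns",
                       stringsAsFactors = FALSE),
    edges = if (nrow(edges))
      data.frame(from = edges$from, to = edges$to, type = "gene-gene",
                 stringsAsFactors = FALSE)
    else data.frame(from = character(0), to = character(0), type = character(0))
  ), class = "association_network")
}

# A small differential_table stub for network construction tests.
stub_deg_records <- function(ids, status) {
  data.frame(feature_id = ids, fc = 1, log2fc = 0, U = 0, p = 0.5, q = 0.5,
             vip = NA_real_, status = status, stringsAsFactors = FALSE)
}
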