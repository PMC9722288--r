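# Independent brute-force oracles.
#
# Centralities: distances by Floyd-Warshall; shortest-path counts by matrix
# powers (a walk whose length equals the distance cannot revisit a vertex,
# so (A^d)[s, t] counts shortest s-t paths exactly); betweenness by explicit
# pair-dependency summation. Deliberately shares no code with the package's
# igraph-based route.

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  d
}

oracle_centralities <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  pow <- vector("list", max(1, n - 1))
  pow[[1]] <- adj
  if (n > 2) for (L in 2:(n - 1)) pow[[L]] <- pow[[L - 1]] %*% adj
  sigma <- function(i, j) {
    if (i == j) return(1)
    if (!is.finite(d[i, j])) return(0)
    pow[[d[i, j]]][i, j]
  }
  btw_raw <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || !is.finite(d[s, t])) next
    st <- sigma(s, t)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        btw_raw[v] <- btw_raw[v] + sigma(s, v) * sigma(v, t) / st
      }
    }
  }
  denom <- (n - 1) * (n - 2) / 2
  closeness <- vapply(seq_len(n), function(v) {
    comp <- which(is.finite(d[v, ]))
    if (length(comp) <= 1) return(0)
    (length(comp) - 1) / sum(d[v, comp])
  }, numeric(1))
  list(degree = rowSums(adj),
       betweenness_raw = btw_raw,
       betweenness = if (n > 2) btw_raw / denom else rep(0, n),
       closeness = closeness)
}

random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- upper.tri(adj)
  adj[up] <- as.integer(runif(sum(up)) < p)
  adj + t(adj)
}

adj_to_network <- function(adj, labels = sprintf("N%02d", seq_len(nrow(adj)))) {
  idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
  edges <- tibble::tibble(a = labels[idx[, 1]], b = labels[idx[, 2]],
                          combined_score = 0.9)
  ppi_network(edges, nodes = labels)
}

# Hypergeometric upper tail by direct count summation over draw outcomes.
oracle_hyper_sum <- function(k, K, n, N) {
  i <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Full subset enumeration (small N only): draw n of N items, items 1..K
# annotated; fraction of draws with at least k annotated items.
oracle_hyper_enum <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}
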