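# Independent oracles and small fixture builders shared across tests.

# Dense linear-system solution of personalized PageRank:
# x = (1 - d) (I - d M)^{-1} p, with M the mass-flow matrix A diag(1/deg).
ppr_dense_oracle <- function(net, weights, damping) {
  nodes <- igraph::V(net)$name
  A <- as.matrix(igraph::as_adjacency_matrix(net))
  deg <- colSums(A)
  M <- A %*% diag(1 / pmax(deg, 1), nrow = length(deg))
  p <- numeric(length(nodes))
  p[match(names(weights), nodes)] <- weights
  p <- p / sum(p)
  x <- solve(diag(length(nodes)) - damping * M, (1 - damping) * p)
  setNames(as.numeric(x / sum(x)), nodes)
}

# One-sided two-sample KS statistic for "x stochastically greater than y":
# the maximum by which the ECDF of y exceeds the ECDF of x.
ks_stat_greater <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  Fx <- vapply(grid, function(t) mean(x <= t), 0)
  Fy <- vapply(grid, function(t) mean(y <= t), 0)
  max(Fy - Fx)
}

# Exhaustive permutation tail probability of the one-sided KS statistic:
# all C(n+m, n) assignments of the pooled values to the "member" group.
ks_perm_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  d_obs <- ks_stat_greater(x, y)
  splits <- utils::combn(seq_along(pooled), n)
  tail_hits <- apply(splits, 2, function(idx) {
    ks_stat_greater(pooled[idx], pooled[-idx]) >= d_obs - 1e-12
  })
  mean(tail_hits)
}

# Upper hypergeometric tail by explicit binomial-coefficient summation.
hyper_tail_oracle <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up with monotone enforcement, written out.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Trapezoidal area under a stepwise ROC curve.
trapezoid_auc <- function(curve) {
  sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
}

# Adjusted Rand index between a community list and planted labels.
ari_vs_labels <- function(communities, labels) {
  genes <- unlist(communities)
  memb <- rep(seq_along(communities), lengths(communities))
  igraph::compare(memb, as.integer(labels[genes]), method = "adjusted.rand")
}

# --- fixture builders ---

path_graph <- function(names) {
  igraph::make_graph(rbind(names[-length(names)], names[-1]), directed = FALSE)
}

two_cliques_graph <- function(size = 20) {
  g1 <- igraph::make_full_graph(size)
  igraph::V(g1)$name <- sprintf("A%02d", seq_len(size))
  g2 <- igraph::make_full_graph(size)
  igraph::V(g2)$name <- sprintf("B%02d", seq_len(size))
  g <- igraph::disjoint_union(g1, g2)
  igraph::add_edges(g, c("A01", "B01"))
}

write_tsv_tmp <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

random_gnp_named <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
  g
}
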