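# Independent brute-force oracles used to check the package's fast paths.

# P(X >= k) for X ~ Hypergeometric(N, K, n) by exhaustive enumeration of all
# C(N, n) equally likely n-subsets of 1..N, with 1..K the annotated genes.
enum_hyper_upper <- function(k, K, n, N) {
  subsets <- utils::combn(N, n)
  overlap <- colSums(subsets <= K)
  mean(overlap >= k)
}

# Benjamini-Hochberg step-up written out directly from its definition.
bh_manual <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  vals <- pmin(1, m * sorted / seq_len(m))
  adj_sorted <- rev(cummin(rev(vals)))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Highest k such that some induced subgraph has minimum degree >= k, by
# exhaustive search over all non-empty vertex subsets (feasible for <= 8).
brute_kcore_k <- function(g) {
  nv <- igraph::vcount(g)
  if (nv == 0L) return(0L)
  best <- 0L
  for (size in seq_len(nv)) {
    subsets <- utils::combn(nv, size)
    for (idx in seq_len(ncol(subsets))) {
      sub <- igraph::induced_subgraph(g, subsets[, idx])
      mindeg <- if (size < 2L || igraph::ecount(sub) == 0L) 0L
                else min(igraph::degree(sub))
      best <- max(best, mindeg)
    }
  }
  as.integer(best)
}

# Undirected named graph from an edge matrix/vector of pairs.
named_graph <- function(edges, isolates = character(0)) {
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2, byrow = TRUE)
  verts <- sort(unique(c(as.vector(edges), isolates)))
  igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE, vertices = verts)
}

# Random named ER graph for property checks.
rand_named_gnp <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# Small simulation config for fast unit tests.
small_sim <- function(rng_seed = 7L, ...) {
  sim_config(rng_seed = rng_seed, n_genes = 300L, n_seed_genes = 30L,
             n_terms = 60L, n_true_terms = 10L, term_size_range = c(2L, 80L),
             p_seed_in_true = 0.6, p_gene_in_term = 0.05,
             net_n = 80L, p_background_edge = 0.03,
             planted_modules = data.frame(size = c(6L, 5L),
                                          intra_edge_prob = c(1, 1),
                                          n_seed_members = c(3L, 2L)), ...)
}
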