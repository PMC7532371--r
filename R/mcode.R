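#' MCODE parameter set
#'
#' Parameters of the molecular-complex detection algorithm. The defaults are
#' the Cytoscape plugin's standard settings: degree cutoff 2, k-core 2, node
#' score cutoff 0.2, maximum search depth 100, haircut on, fluff off.
#'
#' @param degree_cutoff minimum degree for a vertex to receive a nonzero
#'   weight.
#' @param k_core a final cluster must contain a k-core of at least this
#'   order.
#' @param node_score_cutoff fraction in `[0, 1)`: a neighbour joins a
#'   growing cluster when its weight is at least
#'   `seed_weight * (1 - node_score_cutoff)`.
#' @param max_depth maximum breadth-first distance from the cluster seed.
#' @param haircut iteratively remove cluster members with fewer than two
#'   intra-cluster edges.
#' @param fluff add boundary neighbours whose closed-neighbourhood density
#'   exceeds `fluff_density` (clusters may then overlap).
#' @param fluff_density density threshold for fluff.
#' @param loop_density use the loop-inclusive density denominator
#'   `n(n+1)/2` instead of the simple-graph `n(n-1)/2`; some plugin
#'   versions score this way.
#' @param score_pre_haircut score clusters on the member set before haircut
#'   (plugin-parity option); default scores the final member set.
#' @return An object of class `mcode_params`.
#' @export
mcode_params <- function(degree_cutoff = 2L, k_core = 2L,
                         node_score_cutoff = 0.2, max_depth = 100L,
                         haircut = TRUE, fluff = FALSE, fluff_density = 0.1,
                         loop_density = FALSE, score_pre_haircut = FALSE) {
  if (node_score_cutoff < 0 || node_score_cutoff >= 1)
    stop("node_score_cutoff must lie in [0, 1)")
  if (degree_cutoff < 1L || k_core < 1L || max_depth < 1L)
    stop("degree_cutoff, k_core and max_depth must be >= 1")
  structure(list(degree_cutoff = as.integer(degree_cutoff),
                 k_core = as.integer(k_core),
                 node_score_cutoff = node_score_cutoff,
                 max_depth = as.integer(max_depth),
                 haircut = isTRUE(haircut), fluff = isTRUE(fluff),
                 fluff_density = fluff_density,
                 loop_density = isTRUE(loop_density),
                 score_pre_haircut = isTRUE(score_pre_haircut)),
            class = "mcode_params")
}

graph_density_simple <- function(n_vertices, n_edges, loop_density = FALSE) {
  if (n_vertices < 2L && !loop_density) return(0)
  denom <- if (loop_density) n_vertices * (n_vertices + 1) / 2
           else n_vertices * (n_vertices - 1) / 2
  if (denom == 0) return(0)
  n_edges / denom
}

#' Highest k-core of a graph
#'
#' The maximum `k` for which a subgraph with minimum degree `k` exists,
#' found by iterative peeling, together with that maximal k-core (the
#' induced subgraph on all vertices of core number `k`).
#'
#' @param g an undirected igraph.
#' @return List with elements `k` (0 for an empty or edgeless graph) and
#'   `subgraph` (the highest k-core; empty graph when `k = 0` and `g` has
#'   no vertices).
#' @export
highest_kcore <- function(g) {
  if (igraph::vcount(g) == 0L)
    return(list(k = 0L, subgraph = g))
  core <- igraph::coreness(g)
  k <- max(core)
  list(k = as.integer(k),
       subgraph = igraph::induced_subgraph(g, which(core == k)))
}

#' MCODE vertex weighting
#'
#' Stage 1 of MCODE: each vertex with degree at or above the degree cutoff
#' is weighted by `k * density` of the highest k-core of its closed
#' neighbourhood (the vertex plus its neighbours, induced); vertices below
#' the cutoff get weight 0. Dense, cliquish neighbourhoods therefore score
#' high, and the weights drive the cluster-growth stage.
#'
#' @param g an undirected igraph with named vertices.
#' @param p an [mcode_params()].
#' @return data.frame with columns `vertex`, `degree`, `core_k`,
#'   `core_density`, `weight`, one row per vertex in vertex order.
#' @export
vertex_weights <- function(g, p = mcode_params()) {
  stopifnot(inherits(p, "mcode_params"))
  nv <- igraph::vcount(g)
  vnames <- igraph::V(g)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(nv))
  deg <- igraph::degree(g)
  core_k <- integer(nv); core_den <- numeric(nv); w <- numeric(nv)
  if (nv > 0L) {
    adj <- igraph::adjacent_vertices(g, igraph::V(g))
    for (i in seq_len(nv)) {
      if (deg[i] < p$degree_cutoff) next
      nbhd <- igraph::induced_subgraph(g, unique(c(i, as.integer(adj[[i]]))))
      hk <- highest_kcore(nbhd)
      if (hk$k == 0L) next
      den <- graph_density_simple(igraph::vcount(hk$subgraph),
                                  igraph::ecount(hk$subgraph),
                                  p$loop_density)
      core_k[i] <- hk$k
      core_den[i] <- den
      w[i] <- hk$k * den
    }
  }
  data.frame(vertex = vnames, degree = as.integer(deg), core_k = core_k,
             core_density = core_den, weight = w,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Detect molecular complexes with MCODE
#'
#' From-scratch implementation of the three MCODE stages on an undirected
#' graph. Stage 1 weights vertices by the density of the highest k-core of
#' their closed neighbourhood ([vertex_weights()]). Stage 2 repeatedly takes
#' the highest-weight unassigned vertex as a cluster seed and grows the
#' cluster breadth-first over unassigned neighbours whose weight is at least
#' `seed_weight * (1 - node_score_cutoff)`, to at most `max_depth` steps
#' from the seed. Stage 3 discards clusters lacking a `k_core`-core, applies
#' the haircut (iterative removal of members with fewer than two
#' intra-cluster edges) and, optionally, fluff. Clusters are scored as
#' `density * n` on the final member set and ranked by score descending,
#' ties broken by size descending then seed symbol; with fluff off the
#' clusters are vertex-disjoint and the whole procedure is deterministic.
#'
#' @param g an undirected igraph with named vertices.
#' @param p an [mcode_params()].
#' @return An object of class `mcode_result`: a list of clusters, each a
#'   list with `members` (sorted symbols), `seed_vertex`, `n`, `density`,
#'   `score`, `rank` and `label` (`"A"`, `"B"`, ... by rank).
#' @export
mcode_clusters <- function(g, p = mcode_params()) {
  stopifnot(inherits(p, "mcode_params"))
  nv <- igraph::vcount(g)
  if (nv == 0L || igraph::ecount(g) == 0L)
    return(structure(list(), class = "mcode_result"))
  vw <- vertex_weights(g, p)
  w <- vw$weight
  names(w) <- vw$vertex
  # deterministic seed order: weight desc, then symbol
  order_idx <- order(-w, vw$vertex, method = "radix")
  assigned <- logical(nv)
  names(assigned) <- vw$vertex
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  adj <- lapply(adj, as.integer)
  raw_clusters <- list()

  for (s in order_idx) {
    if (assigned[s]) next
    threshold <- w[s] * (1 - p$node_score_cutoff)
    members <- s
    assigned[s] <- TRUE
    frontier <- s
    depth <- 0L
    while (length(frontier) && depth < p$max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in adj[[v]]) {
          if (!assigned[u] && w[u] >= threshold) {
            assigned[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    if (length(members) > 1L)
      raw_clusters[[length(raw_clusters) + 1L]] <-
        list(seed = vw$vertex[s], members = vw$vertex[members])
  }

  final <- list()
  for (cl in raw_clusters) {
    sub <- igraph::induced_subgraph(g, cl$members)
    if (highest_kcore(sub)$k < p$k_core) next
    members <- cl$members
    pre_haircut <- members
    if (p$haircut) {
      repeat {
        sub <- igraph::induced_subgraph(g, members)
        deg_in <- igraph::degree(sub)
        drop <- igraph::V(sub)$name[deg_in < 2L]
        if (length(drop) == 0L) break
        members <- setdiff(members, drop)
        if (length(members) == 0L) break
      }
      if (length(members) == 0L) next
      sub <- igraph::induced_subgraph(g, members)
      if (highest_kcore(sub)$k < p$k_core) next
    }
    if (p$fluff) {
      boundary <- setdiff(
        unique(unlist(lapply(match(members, vw$vertex), function(i) adj[[i]]))),
        match(members, vw$vertex))
      add <- vapply(boundary, function(u) {
        nbhd <- igraph::induced_subgraph(g, unique(c(u, adj[[u]])))
        graph_density_simple(igraph::vcount(nbhd), igraph::ecount(nbhd),
                             p$loop_density) > p$fluff_density
      }, logical(1))
      members <- unique(c(members, vw$vertex[boundary[add]]))
      sub <- igraph::induced_subgraph(g, members)
    }
    seed <- cl$seed
    if (!(seed %in% members)) {
      # haircut removed the original seed: re-root at the heaviest member
      mw <- w[members]
      seed <- members[order(-mw, members, method = "radix")][1L]
    }
    score_members <- if (p$score_pre_haircut) pre_haircut else members
    ssub <- igraph::induced_subgraph(g, score_members)
    den <- graph_density_simple(igraph::vcount(ssub), igraph::ecount(ssub),
                                p$loop_density)
    final[[length(final) + 1L]] <- list(
      members = sym_sort(members), seed_vertex = seed,
      n = length(members), density = den, score = den * length(score_members))
  }
  if (length(final) == 0L) return(structure(list(), class = "mcode_result"))
  scores <- vapply(final, `[[`, 0, "score")
  sizes <- vapply(final, `[[`, 0L, "n")
  seeds <- vapply(final, `[[`, "", "seed_vertex")
  ord <- order(-scores, -sizes, seeds, method = "radix")
  final <- final[ord]
  for (i in seq_along(final)) {
    final[[i]]$rank <- i
    final[[i]]$label <- cluster_label(i)
  }
  structure(final, class = "mcode_result")
}

# rank 1 -> "A", 27 -> "AA", ...
cluster_label <- function(i) {
  out <- character(0)
  while (i > 0L) {
    r <- (i - 1L) %% 26L
    out <- c(LETTERS[r + 1L], out)
    i <- (i - 1L) %/% 26L
  }
  paste(out, collapse = "")
}

#' @export
print.mcode_result <- function(x, ...) {
  cat(sprintf("mcode_result: %d clusters\n", length(x)))
  for (cl in head(x, 10L))
    cat(sprintf("  %s (rank %d): n=%d, density=%.3f, score=%.3f, seed=%s\n",
                cl$label, cl$rank, cl$n, cl$density, cl$score,
                cl$seed_vertex))
  invisible(x)
}

#' Summarize MCODE clusters against a seed gene set
#'
#' Reports, per cluster, the member count, how many members belong to the
#' seed (disease) gene set, and the seed percentage rendered to two
#' decimals — the usual way PPI-cluster composition is reported.
#'
#' @param clusters an `mcode_result`.
#' @param seeds a [gene_set()].
#' @return data.frame with columns `label`, `rank`, `n`, `score`,
#'   `n_seed`, `n_nonseed`, `seed_pct`, `nonseed_pct` (formatted
#'   percentages, e.g. `"30.00%"`).
#' @export
summarize_clusters <- function(clusters, seeds) {
  stopifnot(inherits(clusters, "mcode_result"), inherits(seeds, "gene_set"))
  rows <- lapply(clusters, function(cl) {
    n_seed <- sum(cl$members %in% seeds$members)
    data.frame(label = cl$label, rank = cl$rank, n = cl$n, score = cl$score,
               n_seed = n_seed, n_nonseed = cl$n - n_seed,
               seed_pct = sprintf("%.2f%%", 100 * n_seed / cl$n),
               nonseed_pct = sprintf("%.2f%%", 100 * (cl$n - n_seed) / cl$n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(label = character(0), rank = integer(0), n = integer(0),
                      score = numeric(0), n_seed = integer(0),
                      n_nonseed = integer(0), seed_pct = character(0),
                      nonseed_pct = character(0), stringsAsFactors = FALSE)
  out
}

#' Extract non-seed candidate genes from top-ranked clusters
#'
#' The candidate list: every gene of the `top_k` highest-scoring clusters
#' that is not in the seed set, labelled with each cluster containing it,
#' sorted by the number of clusters (descending) then symbol.
#'
#' @param clusters an `mcode_result` (ranked).
#' @param seeds a [gene_set()].
#' @param top_k number of top clusters to draw from (default 3); when more
#'   than available, all clusters are used with a warning.
#' @return data.frame with columns `gene`, `clusters` (comma-separated
#'   labels), `n_clusters`, `label` (human-readable, e.g.
#'   `"Clusters A and B"`).
#' @export
extract_candidates <- function(clusters, seeds, top_k = 3L) {
  stopifnot(inherits(clusters, "mcode_result"), inherits(seeds, "gene_set"))
  if (top_k > length(clusters)) {
    if (length(clusters) > 0L)
      warning("top_k exceeds the number of clusters; using all ",
              length(clusters))
    top_k <- length(clusters)
  }
  top <- clusters[seq_len(top_k)]
  hits <- list()
  for (cl in top) {
    cand <- setdiff(cl$members, seeds$members)
    for (gn in cand) hits[[gn]] <- c(hits[[gn]], cl$label)
  }
  if (length(hits) == 0L)
    return(data.frame(gene = character(0), clusters = character(0),
                      n_clusters = integer(0), label = character(0),
                      stringsAsFactors = FALSE))
  genes <- sym_sort(names(hits))
  labs <- lapply(hits[genes], sort)
  n_cl <- vapply(labs, length, 1L)
  pretty <- vapply(labs, function(l) {
    if (length(l) == 1L) paste("Cluster", l)
    else if (length(l) == 2L) sprintf("Clusters %s and %s", l[1L], l[2L])
    else sprintf("Clusters %s, and %s",
                 paste(l[-length(l)], collapse = ", "), l[length(l)])
  }, character(1))
  out <- data.frame(gene = genes,
                    clusters = vapply(labs, paste, "", collapse = ","),
                    n_clusters = n_cl, label = pretty,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$n_clusters, out$gene, method = "radix"), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}

#' Write MCODE cluster membership to TSV
#'
#' @param clusters an `mcode_result`.
#' @param seeds a [gene_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(clusters, seeds, path) {
  rows <- lapply(clusters, function(cl)
    data.frame(cluster_label = cl$label, rank = cl$rank,
               score = format_num(cl$score), n = cl$n, gene = cl$members,
               is_seed = cl$members %in% seeds$members,
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cluster_label = character(0), rank = integer(0),
                      score = character(0), n = integer(0),
                      gene = character(0), is_seed = logical(0))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the candidate-gene table to TSV
#'
#' @param candidates output of [extract_candidates()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidate_tsv <- function(candidates, path) {
  write.table(candidates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export one cluster's induced subgraph as GraphML
#'
#' @param g the graph the clusters were detected in.
#' @param cluster one element of an `mcode_result`.
#' @param seeds a [gene_set()]; membership is stored as a vertex attribute
#'   `is_seed`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_cluster_graphml <- function(g, cluster, seeds, path) {
  sub <- igraph::induced_subgraph(g, cluster$members)
  sub <- igraph::set_vertex_attr(sub, "is_seed",
                                 value = igraph::V(sub)$name %in%
                                   seeds$members)
  igraph::write_graph(sub, path, format = "graphml")
  invisible(path)
}
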