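#' Read an undirected interaction table
#'
#' TSV with at least two columns (`symbol_a`, `symbol_b`, optional
#' `confidence`); `#` comment lines allowed, no header expected. Symbols are
#' canonicalized (trimmed, uppercased), self-loops are dropped and duplicate
#' edges collapsed keeping the maximum confidence; the numbers removed are
#' recorded as graph attributes.
#'
#' @param path path to the TSV file.
#' @return An undirected simple [igraph][igraph::graph] whose vertex names
#'   are gene symbols, with graph attributes `n_self_loops_dropped` and
#'   `n_duplicates_collapsed`, and an edge attribute `confidence` when the
#'   input provides one. An empty file yields an empty graph.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop("cannot read interaction table: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::set_graph_attr(g, "n_self_loops_dropped", 0L)
    g <- igraph::set_graph_attr(g, "n_duplicates_collapsed", 0L)
    return(g)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  if (any(nf < 2L))
    stop("interaction table parse error: line ", which(nf < 2L)[1L],
         " has fewer than 2 columns")
  a <- toupper(trimws(vapply(parts, `[[`, "", 1L)))
  b <- toupper(trimws(vapply(parts, `[[`, "", 2L)))
  conf <- vapply(parts, function(p)
    if (length(p) >= 3L) suppressWarnings(as.numeric(p[[3L]])) else NA_real_,
    numeric(1))
  edges_from_pairs(a, b, conf)
}

# shared constructor: canonical orientation, loop removal, dedup (max conf)
edges_from_pairs <- function(a, b, conf = rep(NA_real_, length(a))) {
  loops <- a == b
  n_loops <- sum(loops)
  a2 <- pmin(a[!loops], b[!loops])
  b2 <- pmax(a[!loops], b[!loops])
  conf <- conf[!loops]
  key <- paste(a2, b2, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  if (n_dup && any(!is.na(conf))) {
    conf <- vapply(split(conf, key)[unique(key)], function(v)
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE), numeric(1))
  } else {
    conf <- conf[!dup]
  }
  a2 <- a2[!dup]; b2 <- b2[!dup]
  verts <- sym_sort(unique(c(a2, b2)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a2, to = b2, stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
  if (any(!is.na(conf)))
    g <- igraph::set_edge_attr(g, "confidence", value = unname(conf))
  g <- igraph::set_graph_attr(g, "n_self_loops_dropped", as.integer(n_loops))
  g <- igraph::set_graph_attr(g, "n_duplicates_collapsed", as.integer(n_dup))
  g
}

#' Write an interaction network to TSV
#'
#' @param net an undirected igraph with named vertices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(net, path) {
  el <- igraph::as_edgelist(net)
  if (nrow(el)) {
    a <- pmin(el[, 1L], el[, 2L]); b <- pmax(el[, 1L], el[, 2L])
    ord <- order(a, b, method = "radix")
    lines <- paste(a[ord], b[ord], sep = "\t")
  } else lines <- character(0)
  writeLines(c("# symbol_a\tsymbol_b", lines), path)
  invisible(path)
}

#' Expand a seed gene set into its first-neighbour subnetwork
#'
#' Maps the seed genes onto the interactome and takes the subgraph induced
#' by the mapped seeds plus all of their direct interaction partners —
#' neighbour-neighbour edges are kept, since module density is meaningless
#' without them. This mirrors the seed-centred expansion used to build a
#' disease-specific PPI network from a reference interactome.
#'
#' @param net an undirected igraph (vertex names are gene symbols).
#' @param seeds a [gene_set()].
#' @return A list of class `seed_expansion`: `graph` (the induced subgraph),
#'   `n_seeds_mapped` (seeds present in `net`), `n_extended` (non-seed
#'   first neighbours), `seeds_mapped` and `extended` (symbol vectors).
#' @export
expand_seed_network <- function(net, seeds) {
  stopifnot(inherits(seeds, "gene_set"))
  vnames <- igraph::V(net)$name
  mapped <- intersect(seeds$members, vnames)
  if (length(mapped) == 0L) stop("no seeds in interactome")
  nb <- unique(unlist(igraph::adjacent_vertices(net, mapped), use.names = FALSE))
  nb_names <- vnames[nb]
  keep <- sym_sort(unique(c(mapped, nb_names)))
  sub <- igraph::induced_subgraph(net, keep)
  extended <- sym_sort(setdiff(keep, seeds$members))
  structure(list(graph = sub,
                 n_seeds_mapped = length(mapped),
                 n_extended = length(extended),
                 seeds_mapped = sym_sort(mapped),
                 extended = extended),
            class = "seed_expansion")
}

#' @export
print.seed_expansion <- function(x, ...) {
  cat(sprintf(
    "seed_expansion: %d seeds mapped, %d extended genes, %d nodes / %d edges\n",
    x$n_seeds_mapped, x$n_extended,
    igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}
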