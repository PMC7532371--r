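#' Jaccard coefficient between two gene sets
#'
#' `|A intersect B| / |A union B|`.
#'
#' @param a,b character vectors of gene symbols (nonempty).
#' @return Coefficient in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("jaccard undefined for empty sets")
  length(intersect(a, b)) / length(union(a, b))
}

#' Overlap (Szymkiewicz-Simpson) coefficient between two gene sets
#'
#' `|A intersect B| / min(|A|, |B|)`.
#'
#' @inheritParams jaccard
#' @return Coefficient in `[0, 1]`; always `>=` the Jaccard coefficient.
#' @export
overlap_coef <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("overlap coefficient undefined for empty sets")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Build the term crosstalk network
#'
#' Constructs the crosstalk graph over significantly enriched terms. Two
#' filters are applied before scoring: terms annotated to fewer than
#' `min_term_genes` query genes are removed (too little information), and a
#' term pair is connected only when it shares at least `min_shared` query
#' genes. Each surviving pair is scored by the average of its Jaccard and
#' Overlap coefficients over the per-term query gene sets; edges are ranked
#' by score descending.
#'
#' @param rows significant `enrichment_result` rows (typically the output of
#'   [filter_significant()]); the `overlap_genes` column supplies each
#'   term's query gene set.
#' @param query the query [gene_set()]; members absent from it are ignored.
#' @param min_term_genes minimum query genes per term node (default 5).
#' @param min_shared minimum shared query genes per edge (default 3).
#' @return An object of class `crosstalk_graph`: list with `nodes`
#'   (data.frame `term_id`, `n_genes`, `isolated`), `edges` (data.frame
#'   `term_a`, `term_b`, `n_shared`, `jc`, `oc`, `score`, `rank`, with
#'   `term_a < term_b`), and `term_genes` (named list of the per-term gene
#'   sets).
#' @export
build_crosstalk <- function(rows, query, min_term_genes = 5L,
                            min_shared = 3L) {
  stopifnot(is.data.frame(rows), inherits(query, "gene_set"))
  term_genes <- lapply(strsplit(rows$overlap_genes, ",", fixed = TRUE),
                       function(g) sym_sort(intersect(unique(g),
                                                      query$members)))
  names(term_genes) <- rows$term_id
  keep <- vapply(term_genes, length, 1L) >= min_term_genes
  term_genes <- term_genes[keep]
  ids <- sym_sort(names(term_genes))
  term_genes <- term_genes[ids]

  edges <- data.frame(term_a = character(0), term_b = character(0),
                      n_shared = integer(0), jc = numeric(0), oc = numeric(0),
                      score = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE)
  if (length(ids) < 2L) {
    if (length(ids) < 2L && length(ids) > 0L)
      warning("fewer than 2 terms survive the crosstalk filters; empty edge set")
    nodes <- data.frame(term_id = ids,
                        n_genes = vapply(term_genes, length, 1L),
                        isolated = rep(TRUE, length(ids)),
                        stringsAsFactors = FALSE, row.names = NULL)
    return(structure(list(nodes = nodes, edges = edges,
                          term_genes = term_genes),
                     class = "crosstalk_graph"))
  }

  pairs <- combn(ids, 2L)
  elist <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    shared <- length(intersect(term_genes[[a]], term_genes[[b]]))
    if (shared < min_shared) return(NULL)
    data.frame(term_a = a, term_b = b, n_shared = shared,
               jc = jaccard(term_genes[[a]], term_genes[[b]]),
               oc = overlap_coef(term_genes[[a]], term_genes[[b]]),
               stringsAsFactors = FALSE)
  })
  elist <- do.call(rbind, elist)
  if (!is.null(elist) && nrow(elist)) {
    elist$score <- (elist$jc + elist$oc) / 2
    ord <- order(-elist$score, elist$term_a, elist$term_b, method = "radix")
    elist <- elist[ord, , drop = FALSE]
    elist$rank <- seq_len(nrow(elist))
    rownames(elist) <- NULL
    edges <- elist
  }
  connected <- unique(c(edges$term_a, edges$term_b))
  nodes <- data.frame(term_id = ids,
                      n_genes = vapply(term_genes, length, 1L),
                      isolated = !(ids %in% connected),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(nodes = nodes, edges = edges, term_genes = term_genes),
            class = "crosstalk_graph")
}

#' @export
print.crosstalk_graph <- function(x, ...) {
  cat(sprintf("crosstalk_graph: %d terms (%d isolated), %d edges\n",
              nrow(x$nodes), sum(x$nodes$isolated), nrow(x$edges)))
  if (nrow(x$edges)) print(head(as.data.frame(x$edges), 5L), ...)
  invisible(x)
}

# crosstalk_graph -> igraph (nodes carry n_genes; edges jc/oc/score/n_shared)
crosstalk_igraph <- function(g) {
  stopifnot(inherits(g, "crosstalk_graph"))
  igraph::graph_from_data_frame(
    g$edges[, c("term_a", "term_b", "n_shared", "jc", "oc", "score")],
    directed = FALSE,
    vertices = g$nodes[, c("term_id", "n_genes")])
}

#' Connected components of a crosstalk graph
#'
#' Components under edge connectivity, sorted by size descending with ties
#' broken by the lexicographically smallest member term id. Isolated nodes
#' form singleton components.
#'
#' @param g a `crosstalk_graph`.
#' @return List of character vectors of term ids (each sorted).
#' @export
graph_components <- function(g) {
  stopifnot(inherits(g, "crosstalk_graph"))
  if (nrow(g$nodes) == 0L) return(list())
  ig <- crosstalk_igraph(g)
  comp <- igraph::components(ig)
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, sym_sort)
  first <- vapply(groups, `[[`, "", 1L)
  ord <- order(-vapply(groups, length, 1L), first, method = "radix")
  unname(groups[ord])
}

#' Export a crosstalk graph
#'
#' GraphML (Cytoscape-loadable, node attribute `n_genes`, edge attributes
#' `n_shared`, `jc`, `oc`, `score`) or a 6-column edge TSV with coefficients
#' rendered to 6 significant digits.
#'
#' @param g a `crosstalk_graph`.
#' @param path output path.
#' @param format `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_crosstalk <- function(g, path, format = c("graphml", "tsv")) {
  stopifnot(inherits(g, "crosstalk_graph"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(crosstalk_igraph(g), path, format = "graphml")
  } else {
    out <- g$edges[, c("term_a", "term_b", "n_shared", "jc", "oc", "score")]
    out$jc <- format_num(signif(out$jc, 6))
    out$oc <- format_num(signif(out$oc, 6))
    out$score <- format_num(signif(out$score, 6))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
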