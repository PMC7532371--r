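#' Upper-tail hypergeometric probability
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' sampled without replacement from a universe of `N` genes of which `K`
#' carry the annotation — the one-sided Fisher exact test used for
#' over-representation analysis.
#'
#' @param k observed overlap count.
#' @param K number of universe genes annotated to the term.
#' @param n number of query genes in the universe.
#' @param N universe size.
#' @return `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, in `(0, 1]`.
#' @examples
#' hypergeom_upper_tail(5, 5, 5, 20)  # 1 / choose(20, 5)
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(!is.finite(c(k, K, n, N))) || any(c(k, K, n, N) < 0))
    stop("hypergeometric arguments must be non-negative finite numbers")
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k > min(K, n)) stop("k must not exceed min(K, n)")
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH false-discovery-rate adjustment: with `m` tests and sorted
#' p-values, `adj_i = min_{j >= i} (m * p_(j) / j)` capped at 1, returned in
#' the input order.
#'
#' @param p_values numeric vector of raw p-values, each in `(0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Enrichment configuration
#'
#' @param fdr_threshold significance threshold on BH-adjusted p-values;
#'   strict comparison (`p_bh < fdr_threshold`).
#' @param min_overlap minimum query/term overlap for a term to be tested.
#' @param background `"annotated"` to use the database universe, or a
#'   [gene_set()] / character vector giving an explicit background.
#' @return An object of class `enrichment_config`.
#' @export
enrichment_config <- function(fdr_threshold = 0.05, min_overlap = 1L,
                              background = "annotated") {
  if (!is.numeric(fdr_threshold) || fdr_threshold <= 0 || fdr_threshold >= 1)
    stop("fdr_threshold must lie in (0, 1)")
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  structure(list(fdr_threshold = fdr_threshold,
                 min_overlap = as.integer(min_overlap),
                 background = background),
            class = "enrichment_config")
}

#' Over-representation analysis of a gene set
#'
#' Tests every term of the annotation database whose overlap with the query
#' reaches `cfg$min_overlap`, using the one-sided hypergeometric test against
#' the database universe (or an explicit background). Query genes absent from
#' the universe are excluded from the test and reported via the
#' `genes_outside_universe` attribute. BH adjustment is applied across
#' exactly the tested terms.
#'
#' @param query a [gene_set()].
#' @param db an [annotation_db()].
#' @param cfg an [enrichment_config()].
#' @return A data.frame of class `enrichment_result`, one row per tested
#'   term with columns `term_id`, `term_name`, `N`, `K`, `n`, `k`,
#'   `overlap_genes` (comma-separated), `p_value`, `p_bh`; sorted by
#'   `p_value` ascending with ties broken by `term_id`. Attributes:
#'   `n_query_input`, `n_query_used`, `genes_outside_universe`, `namespace`.
#' @export
enrich <- function(query, db, cfg = enrichment_config()) {
  stopifnot(inherits(query, "gene_set"), inherits(db, "annotation_db"),
            inherits(cfg, "enrichment_config"))
  universe <- db$universe
  if (!identical(cfg$background, "annotated")) {
    bg <- if (inherits(cfg$background, "gene_set")) cfg$background$members
          else toupper(trimws(cfg$background))
    universe <- sym_sort(unique(bg))
  }
  in_univ <- query$members %in% universe
  used <- query$members[in_univ]
  outside <- query$members[!in_univ]
  if (length(used) == 0L) stop("no query genes in background")
  N <- length(universe)
  n <- length(used)

  rows <- lapply(names(db$terms), function(id) {
    members <- intersect(db$terms[[id]]$members, universe)
    ov <- intersect(used, members)
    k <- length(ov)
    if (k < cfg$min_overlap) return(NULL)
    K <- length(members)
    data.frame(term_id = id, term_name = db$terms[[id]]$name,
               N = N, K = K, n = n, k = k,
               overlap_genes = paste(sym_sort(ov), collapse = ","),
               p_value = hypergeom_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) stop("no term overlaps the query at min_overlap = ",
                          cfg$min_overlap)
  rows$p_bh <- bh_adjust(rows$p_value)
  ord <- order(rows$p_value, rows$term_id, method = "radix")
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  structure(rows,
            class = c("enrichment_result", "data.frame"),
            n_query_input = length(query$members),
            n_query_used = n,
            genes_outside_universe = outside,
            namespace = db$namespace)
}

#' Filter enrichment rows at the FDR threshold
#'
#' Keeps rows whose BH-adjusted p-value is strictly below
#' `cfg$fdr_threshold`; row order is preserved.
#'
#' @param rows an `enrichment_result` (or any data.frame with a `p_bh`
#'   column).
#' @param cfg an [enrichment_config()].
#' @return The significant subset, same class and attributes.
#' @export
filter_significant <- function(rows, cfg = enrichment_config()) {
  stopifnot(is.data.frame(rows), "p_bh" %in% names(rows))
  keep <- rows$p_bh < cfg$fdr_threshold
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("n_query_input", "n_query_used", "genes_outside_universe",
              "namespace"))
    attr(out, a) <- attr(rows, a)
  class(out) <- class(rows)
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result [%s]: %d terms tested, %d query genes used",
              attr(x, "namespace") %||% "?", nrow(x),
              attr(x, "n_query_used") %||% NA_integer_), "\n")
  out <- as.data.frame(x)
  print(head(out[, c("term_id", "term_name", "K", "k", "p_value", "p_bh")],
             10L), ...)
  if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Write an enrichment table to TSV
#'
#' Column layout mirrors a pathway-enrichment report: term id, name, raw and
#' BH-adjusted p-values, the overlapping genes, then the test counts.
#'
#' @param rows an `enrichment_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- data.frame(term_id = rows$term_id, term_name = rows$term_name,
                    p_value = format_num(rows$p_value),
                    p_bh = format_num(rows$p_bh),
                    overlap_genes = rows$overlap_genes,
                    N = rows$N, K = rows$K, n = rows$n, k = rows$k,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# fixed-format numeric rendering so reruns are byte-identical
format_num <- function(x) {
  if (length(x) == 0L) return(character(0))
  sprintf("%.6g", x)
}
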