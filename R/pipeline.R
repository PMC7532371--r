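#' Pipeline configuration
#'
#' Collects the input paths and stage parameters for the full analysis:
#' enrichment of the seed gene set, crosstalk construction over the
#' significant terms, and interactome expansion with MCODE module detection.
#' Thresholds default to the standard study settings: FDR 0.05, at least 5
#' query genes per crosstalk term, at least 3 shared genes per pair, MCODE
#' 2/2/0.2/100, top 3 clusters for candidate extraction.
#'
#' @param genes path to the seed gene list.
#' @param gmt path to the GMT annotation database.
#' @param interactome path to the interaction TSV.
#' @param out_dir output directory.
#' @param alias_map optional path to an alias TSV applied before analysis.
#' @param enrichment an [enrichment_config()].
#' @param min_term_genes,min_shared crosstalk filters (see
#'   [build_crosstalk()]).
#' @param mcode an [mcode_params()].
#' @param top_k clusters used for candidate extraction.
#' @param namespace annotation namespace label.
#' @param sim a [sim_config()] used by [run_simulate()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(genes = NULL, gmt = NULL, interactome = NULL,
                            out_dir = ".", alias_map = NULL,
                            enrichment = enrichment_config(),
                            min_term_genes = 5L, min_shared = 3L,
                            mcode = mcode_params(), top_k = 3L,
                            namespace = "BP", sim = sim_config()) {
  structure(list(genes = genes, gmt = gmt, interactome = interactome,
                 out_dir = out_dir, alias_map = alias_map,
                 enrichment = enrichment, min_term_genes = min_term_genes,
                 min_shared = min_shared, mcode = mcode,
                 top_k = as.integer(top_k), namespace = namespace,
                 sim = sim),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Recognized keys mirror the [pipeline_config()] arguments; nested objects
#' `enrichment`, `mcode` and `sim` map onto [enrichment_config()],
#' [mcode_params()] and [sim_config()].
#'
#' @param path path to a JSON file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (key in c("genes", "gmt", "interactome", "out_dir", "alias_map",
                "min_term_genes", "min_shared", "top_k", "namespace"))
    if (!is.null(j[[key]])) args[[key]] <- j[[key]]
  if (!is.null(j$enrichment))
    args$enrichment <- do.call(enrichment_config, as.list(j$enrichment))
  if (!is.null(j$mcode))
    args$mcode <- do.call(mcode_params, as.list(j$mcode))
  if (!is.null(j$sim)) {
    s <- as.list(j$sim)
    if (!is.null(s$planted_modules))
      s$planted_modules <- as.data.frame(s$planted_modules)
    args$sim <- do.call(sim_config, s)
  }
  do.call(pipeline_config, args)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

load_curated_genes <- function(config) {
  genes <- read_gene_list(config$genes, name = "seed_set")
  if (!is.null(config$alias_map)) {
    aliases <- read_alias_map(config$alias_map)
    genes <- normalize_symbols(genes, aliases)$gene_set
  }
  genes
}

#' Run the enrichment stage
#'
#' Reads the seed genes and GMT database, runs [enrich()], writes the full
#' and significant enrichment tables to `out_dir` and returns the stage
#' manifest counts.
#'
#' @param config a [pipeline_config()] with `genes` and `gmt` set.
#' @return Invisibly, a list with the enrichment result, the significant
#'   subset and the manifest entry.
#' @export
run_enrichment <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$genes) || is.null(config$gmt))
    stop("run_enrichment requires 'genes' and 'gmt' paths")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  genes <- load_curated_genes(config)
  db <- read_gmt(config$gmt, namespace = config$namespace)
  log_stage("enrich", length(genes), " seed genes vs ", length(db$terms),
            " terms")
  res <- enrich(genes, db, config$enrichment)
  sig <- filter_significant(res, config$enrichment)
  write_enrichment_tsv(res, file.path(config$out_dir, "enrichment.tsv"))
  write_enrichment_tsv(sig, file.path(config$out_dir,
                                      "enrichment_significant.tsv"))
  manifest <- list(terms_tested = nrow(res), terms_significant = nrow(sig),
                   n_query_used = attr(res, "n_query_used"),
                   n_query_outside_universe =
                     length(attr(res, "genes_outside_universe")))
  log_stage("enrich", manifest$terms_significant, " of ",
            manifest$terms_tested, " terms significant at FDR < ",
            config$enrichment$fdr_threshold)
  invisible(list(enrichment = res, significant = sig, manifest = manifest))
}

#' Run the crosstalk stage
#'
#' Builds the crosstalk network over the significant terms (running the
#' enrichment stage first) and writes the GraphML, the edge TSV and a
#' component listing.
#'
#' @param config a [pipeline_config()].
#' @param enrichment optional result of [run_enrichment()] to reuse.
#' @return Invisibly, a list with the `crosstalk_graph`, components and the
#'   manifest entry.
#' @export
run_crosstalk <- function(config, enrichment = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(enrichment)) enrichment <- run_enrichment(config)
  genes <- load_curated_genes(config)
  g <- build_crosstalk(enrichment$significant, genes,
                       min_term_genes = config$min_term_genes,
                       min_shared = config$min_shared)
  comps <- graph_components(g)
  export_crosstalk(g, file.path(config$out_dir, "crosstalk.graphml"),
                   "graphml")
  export_crosstalk(g, file.path(config$out_dir, "crosstalk_edges.tsv"), "tsv")
  comp_df <- if (length(comps))
    data.frame(component = rep(seq_along(comps),
                               vapply(comps, length, 1L)),
               term_id = unlist(comps), stringsAsFactors = FALSE)
  else data.frame(component = integer(0), term_id = character(0))
  write.table(comp_df, file.path(config$out_dir, "crosstalk_components.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(crosstalk_nodes = nrow(g$nodes),
                   crosstalk_nodes_connected = sum(!g$nodes$isolated),
                   crosstalk_edges = nrow(g$edges),
                   crosstalk_components = length(comps))
  log_stage("crosstalk", manifest$crosstalk_nodes, " terms, ",
            manifest$crosstalk_edges, " edges, ",
            manifest$crosstalk_components, " components")
  invisible(list(graph = g, components = comps, manifest = manifest))
}

#' Run the interactome / MCODE stage
#'
#' Expands the seed genes into their first-neighbour subnetwork, detects
#' MCODE clusters, and writes the expansion summary, cluster membership,
#' cluster summaries, candidate table and per-cluster GraphML files.
#'
#' @param config a [pipeline_config()] with `genes` and `interactome` set.
#' @return Invisibly, a list with the expansion, clusters, summary,
#'   candidates and the manifest entry.
#' @export
run_ppi <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$genes) || is.null(config$interactome))
    stop("run_ppi requires 'genes' and 'interactome' paths")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  genes <- load_curated_genes(config)
  net <- read_interactions(config$interactome)
  if (igraph::vcount(net) == 0L) stop("empty interactome")
  exp <- expand_seed_network(net, genes)
  log_stage("ppi", exp$n_seeds_mapped, " of ", length(genes),
            " seed genes mapped; ", exp$n_extended, " extended genes")
  clusters <- mcode_clusters(exp$graph, config$mcode)
  summary_df <- summarize_clusters(clusters, genes)
  candidates <- extract_candidates(clusters, genes, top_k = config$top_k)
  write.table(data.frame(n_seeds_input = length(genes),
                         n_seeds_mapped = exp$n_seeds_mapped,
                         n_extended = exp$n_extended),
              file.path(config$out_dir, "expansion_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_cluster_tsv(clusters, genes,
                    file.path(config$out_dir, "clusters.tsv"))
  write.table(summary_df, file.path(config$out_dir, "cluster_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_candidate_tsv(candidates,
                      file.path(config$out_dir, "candidates.tsv"))
  for (cl in head(clusters, config$top_k))
    export_cluster_graphml(exp$graph, cl, genes,
                           file.path(config$out_dir,
                                     sprintf("cluster_%s.graphml", cl$label)))
  manifest <- list(n_seeds_mapped = exp$n_seeds_mapped,
                   n_extended = exp$n_extended,
                   clusters_found = length(clusters),
                   candidates = nrow(candidates))
  log_stage("ppi", manifest$clusters_found, " clusters, ",
            manifest$candidates, " candidate genes")
  invisible(list(expansion = exp, clusters = clusters, summary = summary_df,
                 candidates = candidates, manifest = manifest))
}

#' Generate the synthetic fixture bundle
#'
#' @param config a [pipeline_config()]; the bundle is written to
#'   `config$out_dir` using `config$sim`.
#' @return Invisibly, the paths written (see [write_fixture_bundle()]).
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_stage("simulate", "writing fixture bundle to ", config$out_dir)
  write_fixture_bundle(config$sim, config$out_dir)
}

#' Run the full pipeline
#'
#' Enrichment, then crosstalk, then the PPI/MCODE stage; writes every stage
#' table plus a deterministic `manifest.json` whose counts equal the row
#' counts of the emitted tables.
#'
#' @param config a [pipeline_config()] with all three input paths set.
#' @return Invisibly, a list with every stage result and the combined
#'   manifest.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  enr <- run_enrichment(config)
  cross <- run_crosstalk(config, enrichment = enr)
  ppi <- run_ppi(config)
  manifest <- c(list(config = list(
                  fdr_threshold = config$enrichment$fdr_threshold,
                  min_term_genes = config$min_term_genes,
                  min_shared = config$min_shared,
                  mcode = unclass(config$mcode),
                  top_k = config$top_k)),
                enr$manifest, cross$manifest, ppi$manifest)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(enrichment = enr, crosstalk = cross, ppi = ppi,
                 manifest = manifest))
}
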