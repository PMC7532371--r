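#' Simulation configuration with known ground truth
#'
#' Describes a synthetic study: a gene universe with a disease seed set, an
#' annotation database in which a known subset of terms is truly enriched
#' for the seed genes, and an interactome of Erdos-Renyi background edges
#' with planted dense modules mixing seed and non-seed genes. The defaults
#' emulate the structure of a curated-disease-gene study: 100 seed genes in
#' a universe of 2000, 50 truly enriched terms among 500 (seed inclusion
#' probability 0.5 against a 0.05 background), and a 200-node interactome
#' (edge probability 0.02) with three planted cliques of sizes 8, 7 and 6
#' carrying 3, 2 and 2 seed genes — a seed share in the 25-40% range typical
#' of disease-specific PPI modules — with 88% of seeds mappable to the
#' interactome.
#'
#' @param rng_seed single integer seeding every generator; each generator
#'   draws from its own derived stream so regenerating one artifact never
#'   perturbs another.
#' @param n_genes universe size.
#' @param n_seed_genes number of seed (disease) genes.
#' @param n_terms number of annotation terms.
#' @param n_true_terms number of terms truly enriched for seed genes.
#' @param term_size_range length-2 integer vector; terms outside the range
#'   are resampled.
#' @param p_seed_in_true probability a seed gene enters a true term.
#' @param p_gene_in_term background inclusion probability.
#' @param net_n interactome node count.
#' @param p_background_edge Erdos-Renyi edge probability.
#' @param seed_map_prob probability each seed gene is present in the
#'   interactome.
#' @param planted_modules data.frame with columns `size`,
#'   `intra_edge_prob`, `n_seed_members`, one row per planted module.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(rng_seed = 1L,
                       n_genes = 2000L, n_seed_genes = 100L,
                       n_terms = 500L, n_true_terms = 50L,
                       term_size_range = c(10L, 300L),
                       p_seed_in_true = 0.5, p_gene_in_term = 0.05,
                       net_n = 200L, p_background_edge = 0.02,
                       seed_map_prob = 0.88,
                       planted_modules = data.frame(
                         size = c(8L, 7L, 6L),
                         intra_edge_prob = c(1, 1, 1),
                         n_seed_members = c(3L, 2L, 2L))) {
  probs <- c(p_seed_in_true, p_gene_in_term, p_background_edge, seed_map_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p_seed_in_true <= p_gene_in_term)
    stop("p_seed_in_true must exceed p_gene_in_term")
  if (n_true_terms > n_terms) stop("n_true_terms must not exceed n_terms")
  if (length(term_size_range) != 2L ||
      term_size_range[1L] < 1L || term_size_range[1L] > term_size_range[2L])
    stop("term_size_range must be (min, max) with 1 <= min <= max")
  stopifnot(is.data.frame(planted_modules),
            all(c("size", "intra_edge_prob", "n_seed_members") %in%
                  names(planted_modules)))
  if (any(planted_modules$size > net_n))
    stop("planted module sizes must not exceed net_n")
  if (any(planted_modules$n_seed_members > planted_modules$size))
    stop("n_seed_members must not exceed the module size")
  structure(list(rng_seed = as.integer(rng_seed), n_genes = as.integer(n_genes),
                 n_seed_genes = as.integer(n_seed_genes),
                 n_terms = as.integer(n_terms),
                 n_true_terms = as.integer(n_true_terms),
                 term_size_range = as.integer(term_size_range),
                 p_seed_in_true = p_seed_in_true,
                 p_gene_in_term = p_gene_in_term,
                 net_n = as.integer(net_n),
                 p_background_edge = p_background_edge,
                 seed_map_prob = seed_map_prob,
                 planted_modules = planted_modules),
            class = "sim_config")
}

# derived, generator-specific RNG streams from the one config seed
stream_seed <- function(cfg, stream) {
  offsets <- c(seeds = 11L, annotation = 23L, interactome = 37L)
  (abs(cfg$rng_seed) * 7919L + offsets[[stream]]) %% 2147483647L
}

gene_universe <- function(cfg) {
  width <- max(4L, nchar(as.character(cfg$n_genes)))
  sprintf(paste0("G%0", width, "d"), seq_len(cfg$n_genes))
}

#' Simulate a seed (disease) gene set
#'
#' Draws `n_seed_genes` symbols uniformly from the synthetic universe
#' (`"G0001"`-style names); deterministic given `cfg$rng_seed`.
#'
#' @param cfg a [sim_config()].
#' @return A [gene_set()] named `"synthetic_seed_set"`.
#' @export
simulate_seed_set <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_seed_genes < 1L) stop("n_seed_genes must be >= 1")
  if (cfg$n_seed_genes > cfg$n_genes)
    stop("n_seed_genes must not exceed n_genes")
  universe <- gene_universe(cfg)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(cfg, "seeds"))
  gene_set(sample(universe, cfg$n_seed_genes), name = "synthetic_seed_set")
}

# save/restore the global RNG state so generators are pure functions
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate an annotation database with known enriched terms
#'
#' The first `n_true_terms` terms are truly enriched: seed genes enter with
#' probability `p_seed_in_true`, all other genes with `p_gene_in_term`.
#' The remaining (null) terms include every gene independently with
#' `p_gene_in_term`. Terms falling outside `term_size_range` are redrawn;
#' an impossible range raises an error after a bounded number of attempts.
#'
#' @param cfg a [sim_config()].
#' @param seeds the seed [gene_set()] (from [simulate_seed_set()]).
#' @return List with `db` (an [annotation_db()], namespace `"BP"`) and
#'   `truth` (list with `true_term_ids` and `seed_genes`).
#' @export
simulate_annotation <- function(cfg, seeds) {
  stopifnot(inherits(cfg, "sim_config"), inherits(seeds, "gene_set"))
  universe <- gene_universe(cfg)
  is_seed <- universe %in% seeds$members
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(cfg, "annotation"))
  lo <- cfg$term_size_range[1L]; hi <- cfg$term_size_range[2L]
  width <- max(4L, nchar(as.character(cfg$n_terms)))
  ids <- sprintf(paste0("T%0", width, "d"), seq_len(cfg$n_terms))
  terms <- vector("list", cfg$n_terms)
  for (i in seq_len(cfg$n_terms)) {
    p_incl <- if (i <= cfg$n_true_terms)
      ifelse(is_seed, cfg$p_seed_in_true, cfg$p_gene_in_term)
    else rep(cfg$p_gene_in_term, cfg$n_genes)
    ok <- FALSE
    for (attempt in 1:1000) {
      members <- universe[runif(cfg$n_genes) < p_incl]
      if (length(members) >= lo && length(members) <= hi) { ok <- TRUE; break }
    }
    if (!ok) stop("term_size_range infeasible for the configured ",
                  "inclusion probabilities")
    terms[[i]] <- list(name = paste("synthetic process", i),
                       members = members)
  }
  names(terms) <- ids
  # universe defaults to the union of members, so a GMT round-trip through
  # read_gmt() reproduces the database exactly
  db <- annotation_db(terms, namespace = "BP")
  truth <- list(true_term_ids = ids[seq_len(cfg$n_true_terms)],
                seed_genes = seeds$members)
  list(db = db, truth = truth)
}

#' Simulate an interactome with planted dense modules
#'
#' Network nodes are a subset of the gene universe: each seed gene enters
#' with probability `seed_map_prob` (emulating incomplete interactome
#' coverage of curated genes), and non-seed genes fill the node count to
#' `net_n`. Background edges are Erdos-Renyi with probability
#' `p_background_edge`; each planted module draws its members (the
#' configured number from the mapped seeds, the rest non-seed, all disjoint
#' across modules) and adds intra-module edges with its `intra_edge_prob`.
#'
#' @param cfg a [sim_config()].
#' @param seeds the seed [gene_set()].
#' @return List with `net` (an undirected simple igraph) and `truth` (list
#'   with `planted_modules`, a list of sorted member vectors, and
#'   `nodes`).
#' @export
simulate_interactome <- function(cfg, seeds) {
  stopifnot(inherits(cfg, "sim_config"), inherits(seeds, "gene_set"))
  universe <- gene_universe(cfg)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(cfg, "interactome"))
  seed_in <- seeds$members[runif(length(seeds$members)) < cfg$seed_map_prob]
  n_fill <- cfg$net_n - length(seed_in)
  if (n_fill < 0L) stop("net_n smaller than the number of mapped seeds")
  nonseed_pool <- setdiff(universe, seeds$members)
  if (n_fill > length(nonseed_pool))
    stop("not enough non-seed genes to fill the interactome")
  nodes <- sym_sort(c(seed_in, sample(nonseed_pool, n_fill)))
  n <- length(nodes)

  # ER background over canonical (i < j) pairs
  pairs_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  pairs_j <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  draw <- runif(length(pairs_i)) < cfg$p_background_edge
  from <- nodes[pairs_i[draw]]
  to <- nodes[pairs_j[draw]]

  planted <- list()
  seed_pool <- intersect(nodes, seeds$members)
  free_nonseed <- setdiff(nodes, seeds$members)
  pm <- cfg$planted_modules
  for (m in seq_len(nrow(pm))) {
    k_seed <- pm$n_seed_members[m]
    k_non <- pm$size[m] - k_seed
    if (k_seed > length(seed_pool) || k_non > length(free_nonseed))
      stop("not enough unassigned nodes for planted module ", m)
    mem_seed <- if (k_seed) sample(seed_pool, k_seed) else character(0)
    mem_non <- if (k_non) sample(free_nonseed, k_non) else character(0)
    seed_pool <- setdiff(seed_pool, mem_seed)
    free_nonseed <- setdiff(free_nonseed, mem_non)
    members <- sym_sort(c(mem_seed, mem_non))
    planted[[m]] <- members
    if (length(members) >= 2L) {
      mp <- combn(members, 2L)
      keep <- runif(ncol(mp)) < pm$intra_edge_prob[m]
      from <- c(from, mp[1L, keep])
      to <- c(to, mp[2L, keep])
    }
  }
  net <- edges_from_pairs(from, to)
  # keep isolated nodes so the node census matches the configuration
  missing <- setdiff(nodes, igraph::V(net)$name)
  if (length(missing)) net <- igraph::add_vertices(net, length(missing),
                                                   name = missing)
  list(net = net, truth = list(planted_modules = planted, nodes = nodes))
}

#' Write a complete synthetic fixture bundle
#'
#' Emits `genes.txt`, `annotations.gmt`, `interactome.tsv` and `truth.json`
#' into `dir`. Re-reading the files through the package readers reproduces
#' the in-memory objects, and regenerating with the same configuration is
#' byte-identical.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly; the
#'   generated objects are attached as the `"objects"` attribute.
#' @export
write_fixture_bundle <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seeds <- simulate_seed_set(cfg)
  ann <- simulate_annotation(cfg, seeds)
  net <- simulate_interactome(cfg, seeds)
  paths <- c(genes = file.path(dir, "genes.txt"),
             gmt = file.path(dir, "annotations.gmt"),
             interactome = file.path(dir, "interactome.tsv"),
             truth = file.path(dir, "truth.json"))
  write_gene_list(seeds, paths[["genes"]])
  write_gmt(ann$db, paths[["gmt"]])
  write_interactions(net$net, paths[["interactome"]])
  truth <- list(seed_genes = seeds$members,
                true_term_ids = ann$truth$true_term_ids,
                planted_modules = net$truth$planted_modules)
  jsonlite::write_json(truth, paths[["truth"]], pretty = TRUE)
  out <- paths
  attr(out, "objects") <- list(seeds = seeds, db = ann$db, net = net$net,
                               truth = truth)
  invisible(out)
}
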