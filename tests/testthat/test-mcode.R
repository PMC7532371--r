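complete_named <- function(n, prefix = "v") {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- sprintf("%s%02d", prefix, seq_len(n))
  g
}

test_that("highest k-core matches hand cases and exhaustive search", {
  # K5 has a 4-core equal to the whole graph
  k5 <- complete_named(5)
  hk <- highest_kcore(k5)
  expect_identical(hk$k, 4L)
  expect_identical(as.integer(igraph::vcount(hk$subgraph)), 5L)

  # a 4-path is 1-degenerate
  p4 <- named_graph(c("a", "b", "b", "c", "c", "d"))
  expect_identical(highest_kcore(p4)$k, 1L)

  # K4 plus a pendant: peel the pendant, the K4 remains
  k4p <- named_graph(rbind(t(utils::combn(paste0("k", 1:4), 2)),
                           c("k1", "pend")))
  hk2 <- highest_kcore(k4p)
  expect_identical(hk2$k, 3L)
  expect_identical(sort(igraph::V(hk2$subgraph)$name), paste0("k", 1:4))

  # empty graph
  e <- igraph::make_empty_graph(0, directed = FALSE)
  expect_identical(highest_kcore(e)$k, 0L)

  # oracle equivalence on sampled graphs with <= 7 vertices
  set.seed(5)
  for (i in 1:40) {
    g <- rand_named_gnp(sample(2:7, 1), runif(1, 0.2, 0.9))
    expect_identical(highest_kcore(g)$k, brute_kcore_k(g))
  }
})

test_that("vertex weighting follows the closed-neighbourhood k-core rule", {
  k5 <- complete_named(5)
  vw <- vertex_weights(k5)
  expect_equal(vw$weight, rep(4, 5))
  expect_equal(vw$core_k, rep(4L, 5))
  expect_equal(vw$core_density, rep(1, 5))

  # isolated and degree-1 vertices get weight zero under degree_cutoff = 2
  g <- named_graph(c("a", "b", "b", "c", "c", "a", "c", "d"),
                   isolates = "iso")
  vw2 <- vertex_weights(g)
  w <- stats::setNames(vw2$weight, vw2$vertex)
  expect_identical(unname(w["iso"]), 0)
  expect_identical(unname(w["d"]), 0)
  expect_gt(w["a"], 0)
})

test_that("MCODE reproduces the hand-worked cluster cases", {
  # disjoint K5 and K4: two clique clusters scored 5 and 4, in that order
  g <- igraph::disjoint_union(complete_named(5, "a"), complete_named(4, "b"))
  cl <- mcode_clusters(g)
  expect_length(cl, 2L)
  expect_equal(vapply(cl, `[[`, 0, "score"), c(5, 4))
  expect_equal(vapply(cl, `[[`, 0L, "n"), c(5L, 4L))
  expect_equal(vapply(cl, `[[`, 0, "density"), c(1, 1))
  expect_identical(vapply(cl, `[[`, "", "label"), c("A", "B"))

  # triangle with a pendant: haircut trims the pendant, score 3.0
  tp <- named_graph(c("a", "b", "a", "c", "b", "c", "a", "d"))
  cl2 <- mcode_clusters(tp)
  expect_length(cl2, 1L)
  expect_identical(cl2[[1]]$members, c("a", "b", "c"))
  expect_equal(cl2[[1]]$score, 3)

  # edgeless graph: no clusters
  el <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(el)$name <- c("x", "y", "z")
  expect_length(mcode_clusters(el), 0L)
})

test_that("MCODE clusters satisfy the structural invariants deterministically", {
  set.seed(9)
  for (i in 1:8) {
    g <- rand_named_gnp(40, 0.12)
    p <- mcode_params()
    cl <- mcode_clusters(g, p)
    cl_again <- mcode_clusters(g, p)
    expect_identical(cl, cl_again)  # no randomness anywhere
    all_members <- unlist(lapply(cl, `[[`, "members"))
    expect_identical(anyDuplicated(all_members), 0L)  # disjoint, fluff off
    for (c in cl) {
      sub <- igraph::induced_subgraph(g, c$members)
      expect_identical(as.integer(igraph::components(sub)$no), 1L)  # connected
      expect_gte(highest_kcore(sub)$k, p$k_core)  # contains a k-core
      expect_true(c$seed_vertex %in% c$members)
      expect_true(c$score > 0 && c$score <= c$n)
      is_clique <- as.integer(igraph::ecount(sub)) == c$n * (c$n - 1) / 2
      expect_identical(isTRUE(all.equal(c$score, as.numeric(c$n))), is_clique)
    }
  }
})

test_that("a single bridging edge merges two cliques whose weights pass the cutoff", {
  # documented MCODE behaviour: a K7 vertex (weight 6) clears the threshold
  # of a K8-seeded cluster (7 * 0.8 = 5.6), so one bridge merges the cliques
  g <- igraph::disjoint_union(complete_named(8, "a"), complete_named(7, "b"))
  g <- igraph::add_edges(g, c("a01", "b01"))
  cl <- mcode_clusters(g)
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$n, 15L)
})

test_that("interaction reading canonicalizes, deduplicates and drops loops", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# a\tb", "A\tB", "B\tA", "C\tC"), path)
  net <- read_interactions(path)
  expect_identical(as.integer(igraph::ecount(net)), 1L)
  expect_identical(sort(igraph::V(net)$name), c("A", "B"))
  expect_identical(igraph::graph_attr(net, "n_self_loops_dropped"), 1L)
  expect_identical(igraph::graph_attr(net, "n_duplicates_collapsed"), 1L)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# nothing", empty)
  expect_identical(as.integer(igraph::vcount(read_interactions(empty))), 0L)

  tri <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tC", "C\tA"), tri)
  net3 <- read_interactions(tri)
  expect_identical(as.integer(igraph::vcount(net3)), 3L)
  expect_identical(as.integer(igraph::ecount(net3)), 3L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "single-column"), bad)
  expect_error(read_interactions(bad), "line 2")

  # duplicate edges keep the maximum confidence
  conf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t0.3", "B\tA\t0.9", "B\tC\t0.5"), conf)
  netc <- read_interactions(conf)
  ab <- igraph::E(netc)[igraph::V(netc)["A"] %--% igraph::V(netc)["B"]]
  expect_equal(igraph::E(netc)$confidence[as.integer(ab)], 0.9)
})

test_that("seed expansion takes the induced first-neighbour subnetwork", {
  # star around a seed plus an unrelated edge far away
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("S\tX1", "S\tX2", "S\tX3", "S\tX4", "X9\tX10"), path)
  net <- read_interactions(path)
  ex <- expand_seed_network(net, gene_set("S"))
  expect_identical(sort(igraph::V(ex$graph)$name),
                   c("S", "X1", "X2", "X3", "X4"))
  expect_identical(as.integer(igraph::ecount(ex$graph)), 4L)
  expect_identical(ex$n_seeds_mapped, 1L)
  expect_identical(ex$n_extended, 4L)

  expect_error(expand_seed_network(net, gene_set("ABSENT")),
               "no seeds in interactome")

  # two adjacent seeds and nothing else
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("S1\tS2", p2)
  ex2 <- expand_seed_network(read_interactions(p2), gene_set(c("S1", "S2")))
  expect_identical(as.integer(igraph::vcount(ex2$graph)), 2L)
  expect_identical(as.integer(igraph::ecount(ex2$graph)), 1L)
  expect_identical(ex2$n_extended, 0L)
})

test_that("cluster summaries render seed percentages to two decimals", {
  mk <- function(n, n_seed, rank) {
    members <- c(sprintf("SEED%02d", seq_len(n_seed)),
                 sprintf("EXT%02d", seq_len(n - n_seed)))
    list(members = members, seed_vertex = members[1], n = as.integer(n),
         density = 0.5, score = 2, rank = rank, label = LETTERS[rank])
  }
  seeds <- gene_set(sprintf("SEED%02d", 1:40))
  clusters <- structure(list(mk(40, 12, 1), mk(43, 13, 2), mk(27, 10, 3)),
                        class = "mcode_result")
  s <- summarize_clusters(clusters, seeds)
  expect_identical(s$seed_pct, c("30.00%", "30.23%", "37.04%"))
  expect_identical(s$nonseed_pct[1], "70.00%")
  expect_identical(s$n_nonseed, c(28L, 30L, 17L))
})

test_that("candidate extraction labels non-seed genes by their clusters", {
  seeds <- gene_set(c("S1", "S2", "S3"))
  clusters <- structure(list(
    list(members = c("S1", "S2", "X"), seed_vertex = "S1", n = 3L,
         density = 1, score = 3, rank = 1L, label = "A"),
    list(members = c("S3", "X", "Y"), seed_vertex = "S3", n = 3L,
         density = 1, score = 2.5, rank = 2L, label = "B")),
    class = "mcode_result")
  cand <- extract_candidates(clusters, seeds, top_k = 2)
  expect_identical(cand$gene, c("X", "Y"))
  expect_identical(cand$label, c("Clusters A and B", "Cluster B"))
  expect_identical(cand$clusters, c("A,B", "B"))

  # all-seed clusters yield an empty candidate table
  allseed <- structure(list(
    list(members = c("S1", "S2"), seed_vertex = "S1", n = 2L,
         density = 1, score = 2, rank = 1L, label = "A")),
    class = "mcode_result")
  expect_identical(nrow(extract_candidates(allseed, seeds, top_k = 1)), 0L)

  # with no seeds, every member is a candidate
  noseed <- gene_set("UNRELATED")
  cand2 <- extract_candidates(clusters, noseed, top_k = 2)
  expect_identical(sort(cand2$gene), c("S1", "S2", "S3", "X", "Y"))

  expect_warning(extract_candidates(clusters, seeds, top_k = 5), "top_k")
})
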