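three_term_rows <- function() {
  data.frame(term_id = c("T1", "T2", "T3"),
             term_name = c("a", "b", "c"),
             overlap_genes = c("G1,G2,G3,G4,G5", "G3,G4,G5,G6,G7",
                               "G8,G9,G10,G11,G12"),
             p_bh = c(0.001, 0.002, 0.003),
             stringsAsFactors = FALSE)
}
q12 <- gene_set(paste0("G", 1:12), "query")

test_that("Jaccard and Overlap coefficients match hand counts and order", {
  a <- paste0("g", 1:5); b <- paste0("g", 3:6)
  expect_equal(jaccard(a, b), 3 / 6)
  expect_equal(overlap_coef(a, b), 3 / 4)
  expect_equal(jaccard(a, a), 1)
  expect_equal(overlap_coef(c("x", "y"), a), 0)
  expect_equal(overlap_coef(a[1:2], a), 1)  # subset case
  expect_error(jaccard(character(0), a), "empty")
  expect_error(overlap_coef(a, character(0)), "empty")

  # 0 <= jc <= oc <= 1 and symmetry, over random set pairs
  set.seed(3)
  pool <- paste0("g", 1:30)
  for (i in 1:50) {
    x <- sample(pool, sample(1:20, 1)); y <- sample(pool, sample(1:20, 1))
    jc <- jaccard(x, y); oc <- overlap_coef(x, y)
    expect_true(jc >= 0 && jc <= oc && oc <= 1)
    expect_equal(jc, jaccard(y, x))
    expect_equal(oc, overlap_coef(y, x))
  }
})

test_that("crosstalk construction applies the term and pair filters of the method", {
  g <- build_crosstalk(three_term_rows(), q12)
  expect_identical(nrow(g$nodes), 3L)
  expect_identical(nrow(g$edges), 1L)
  e <- g$edges[1, ]
  expect_identical(c(e$term_a, e$term_b), c("T1", "T2"))
  expect_identical(e$n_shared, 3L)
  expect_equal(e$jc, 3 / 7)
  expect_equal(e$oc, 3 / 5)
  expect_equal(e$score, (3 / 7 + 3 / 5) / 2)
  expect_identical(g$nodes$isolated, c(FALSE, FALSE, TRUE))

  # a pair sharing only 2 genes gets no edge
  rows2 <- data.frame(term_id = c("A", "B"), term_name = c("a", "b"),
                      overlap_genes = c("G1,G2,G3,G4,G5", "G4,G5,G6,G7,G8"),
                      p_bh = 0.01, stringsAsFactors = FALSE)
  g2 <- build_crosstalk(rows2, q12)
  expect_identical(nrow(g2$edges), 0L)

  # a term with fewer than five query genes is excluded from the nodes
  rows3 <- rbind(three_term_rows(),
                 data.frame(term_id = "T4", term_name = "small",
                            overlap_genes = "G1,G2,G3,G4", p_bh = 0.01))
  g3 <- build_crosstalk(rows3, q12)
  expect_false("T4" %in% g3$nodes$term_id)

  # fewer than 2 surviving nodes: empty edge set with a warning, not an error
  expect_warning(g4 <- build_crosstalk(three_term_rows()[1, ], q12),
                 "fewer than 2")
  expect_identical(nrow(g4$edges), 0L)
})

test_that("edge set equals brute-force pair enumeration on random fixtures", {
  set.seed(42)
  pool <- paste0("G", 1:40)
  query <- gene_set(pool, "q")
  for (rep in 1:5) {
    n_terms <- 20L
    genes <- lapply(1:n_terms, function(i) sample(pool, sample(3:15, 1)))
    rows <- data.frame(term_id = sprintf("T%02d", 1:n_terms),
                       term_name = "t",
                       overlap_genes = vapply(genes, paste, "", collapse = ","),
                       p_bh = 0.01, stringsAsFactors = FALSE)
    g <- build_crosstalk(rows, query)
    # brute force over all pairs of surviving terms
    keep <- vapply(genes, length, 1L) >= 5L
    ids <- rows$term_id[keep]
    sets <- genes[keep]
    expected <- 0L
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i < j && length(intersect(sets[[i]], sets[[j]])) >= 3L)
        expected <- expected + 1L
    }
    expect_identical(nrow(g$edges), expected)
    if (nrow(g$edges)) {
      expect_true(all(g$edges$jc <= g$edges$oc))
      expect_true(all(g$edges$term_a < g$edges$term_b))
      expect_identical(g$edges$rank, seq_len(nrow(g$edges)))
      expect_true(all(diff(g$edges$score) <= 0))
    }
  }
})

test_that("a gene in no intersection never changes edge scores", {
  rows <- three_term_rows()
  g_before <- build_crosstalk(rows, q12)
  # G1 belongs only to T1 and to no pairwise intersection
  rows$overlap_genes[1] <- "G2,G3,G4,G5,G99"
  q <- gene_set(c(paste0("G", 2:12), "G99"))
  g_after <- build_crosstalk(rows, q)
  expect_equal(g_after$edges$score, g_before$edges$score)
  expect_identical(g_after$edges$n_shared, g_before$edges$n_shared)
})

test_that("components are sorted by size then smallest member", {
  g <- build_crosstalk(three_term_rows(), q12)
  expect_identical(graph_components(g), list(c("T1", "T2"), "T3"))

  # empty graph
  expect_warning(g1 <- build_crosstalk(three_term_rows()[0, ], q12), NA)
  expect_identical(graph_components(g1), list())

  # fully connected toy graph is a single component
  rows <- data.frame(term_id = c("A", "B", "C"), term_name = "t",
                     overlap_genes = c("G1,G2,G3,G4,G5", "G1,G2,G3,G4,G6",
                                       "G1,G2,G3,G5,G6"),
                     p_bh = 0.01, stringsAsFactors = FALSE)
  comps <- graph_components(build_crosstalk(rows, q12))
  expect_identical(comps, list(c("A", "B", "C")))
})

test_that("crosstalk export produces loadable GraphML and a faithful TSV", {
  g <- build_crosstalk(three_term_rows(), q12)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_crosstalk(g, gml, "graphml")
  back <- igraph::read_graph(gml, format = "graphml")
  expect_identical(as.integer(igraph::vcount(back)), 3L)
  expect_identical(as.integer(igraph::ecount(back)), 1L)
  expect_equal(igraph::E(back)$score, g$edges$score, tolerance = 1e-9)
  expect_identical(sort(igraph::V(back)$n_genes), c(5, 5, 5))

  # empty graph still yields a valid GraphML document
  expect_warning(g0 <- build_crosstalk(three_term_rows()[1, ], q12))
  gml0 <- withr::local_tempfile(fileext = ".graphml")
  export_crosstalk(g0, gml0, "graphml")
  back0 <- igraph::read_graph(gml0, format = "graphml")
  expect_identical(as.integer(igraph::vcount(back0)), 1L)

  # TSV round-trip reproduces the edge table at 6 significant digits
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_crosstalk(g, tsv, "tsv")
  tab <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_identical(tab$term_a, g$edges$term_a)
  expect_identical(tab$n_shared, g$edges$n_shared)
  expect_equal(tab$jc, signif(g$edges$jc, 6))
  expect_equal(tab$score, signif(g$edges$score, 6))

  expect_error(export_crosstalk(g, tsv, "dot"))
})
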