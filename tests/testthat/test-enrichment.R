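test_that("only pathways with at least one overlapping gene are reported", {
  pc <- PathwayCollection(list(HIT = c("TNF", "AKT1"), MISS = c("EGF", "NGF")),
                          universe = c("TNF", "AKT1", "EGF", "NGF", "IL6"))
  res <- fisherEnrichment(c("TNF", "IL6"), pc)
  expect_equal(res$pathway, "HIT")
  expect_equal(res$k, 1L)
})

test_that("saturated overlap reproduces the closed-form draw probability", {
  # universe of 20, pathway of 5, query of 5, all 5 overlapping:
  # only one of the C(20,5) equally likely draws achieves X >= 5
  universe <- sprintf("G%02d", 1:20)
  pc <- PathwayCollection(list(P = universe[1:5]), universe = universe)
  res <- fisherEnrichment(universe[1:5], pc)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p, enumHyperP(20, 5, 5, 5), tolerance = 1e-12)

  # k = 1 with q = 1 and the pathway spanning the whole universe: certain
  pc1 <- PathwayCollection(list(P = universe), universe = universe)
  expect_equal(fisherEnrichment(universe[1], pc1)$p, 1)
})

test_that("p-values match the exhaustive hypergeometric oracle to 1e-12", {
  set.seed(61)
  for (i in 1:20) {
    N <- sample(8:20, 1)
    m <- sample(2:(N - 2), 1)
    q <- sample(2:min(7, N - 1), 1)
    universe <- sprintf("G%02d", 1:N)
    pc <- PathwayCollection(list(P = universe[1:m]), universe = universe)
    query <- sample(universe, q)
    res <- fisherEnrichment(query, pc)
    k <- length(intersect(query, universe[1:m]))
    if (k == 0L) {
      expect_equal(nrow(res), 0L)
    } else {
      expect_equal(res$p, enumHyperP(N, m, q, k), tolerance = 1e-12)
      # independent cross-check: one-sided Fisher's exact test
      ft <- stats::fisher.test(
        matrix(c(k, m - k, q - k, N - m - q + k), 2), alternative = "greater")
      expect_equal(res$p, ft$p.value, tolerance = 1e-12)
    }
  }
})

test_that("enrichment is invariant under gene relabeling", {
  set.seed(62)
  universe <- sprintf("G%02d", 1:18)
  pc <- PathwayCollection(list(P = universe[1:6]), universe = universe)
  query <- universe[c(1, 2, 3, 10, 11)]
  p1 <- fisherEnrichment(query, pc)$p
  relabel <- setNames(sample(sprintf("X%02d", 1:18)), universe)
  pc2 <- PathwayCollection(list(P = relabel[universe[1:6]]),
                           universe = relabel)
  p2 <- fisherEnrichment(relabel[query], pc2)$p
  expect_equal(p1, p2, tolerance = 1e-15)
})

test_that("query genes outside the universe are dropped with a warning", {
  pc <- PathwayCollection(list(P = c("TNF", "AKT1")),
                          universe = c("TNF", "AKT1", "IL6"))
  expect_warning(res <- fisherEnrichment(c("TNF", "NOPE"), pc), "NOPE")
  expect_equal(res$q, 1L)
  expect_error(suppressWarnings(fisherEnrichment("NOPE", pc)),
               "no query genes")
})

test_that("consolidation keeps the best row per pathway under the sort key", {
  a <- data.frame(pathway = "P", k = 3L, q = 10L, m = 5L, N = 50L, p = 0.01,
                  overlapGenes = "A,B,C", source = "c1", negLog10P = 2)
  b <- data.frame(pathway = "P", k = 5L, q = 12L, m = 7L, N = 50L, p = 0.02,
                  overlapGenes = "A,B,C,D,E", source = "c2", negLog10P = 1.7)
  out <- consolidate(a, b)
  expect_equal(nrow(out), 1L)
  expect_equal(out$k, 5L)
  expect_equal(out$source, "c2")

  # all-distinct names: a pure sort by overlap desc then p asc
  rows <- data.frame(pathway = c("A", "B", "C"), k = c(1L, 3L, 3L),
                     q = 5L, m = 5L, N = 20L, p = c(0.5, 0.2, 0.1),
                     overlapGenes = "", source = "s", negLog10P = 0)
  expect_equal(consolidate(rows)$pathway, c("C", "B", "A"))
})

test_that("consolidation agrees with a brute-force argmax oracle", {
  set.seed(71)
  for (i in 1:10) {
    rows <- data.frame(
      pathway = sample(LETTERS[1:5], 30, replace = TRUE),
      k = sample(1:8, 30, replace = TRUE),
      q = 10L, m = 8L, N = 40L,
      p = round(stats::runif(30), 3),
      overlapGenes = "", source = "s", negLog10P = 0)
    out <- consolidate(rows)
    for (nm in unique(rows$pathway)) {
      sub <- rows[rows$pathway == nm, ]
      sub <- sub[order(-sub$k, sub$p), ]
      expect_equal(out$k[out$pathway == nm], sub$k[1])
      expect_equal(out$p[out$pathway == nm], sub$p[1])
    }
  }
})

test_that("topK truncates without reordering", {
  tab <- data.frame(pathway = letters[1:26], p = (1:26) / 100)
  expect_equal(nrow(topK(tab, 10)), 10L)
  expect_equal(topK(tab, 10)$pathway, letters[1:10])
  expect_equal(nrow(topK(tab, 100)), 26L)
  expect_error(topK(tab, 0), ">= 1")
})

test_that("optional BH correction appends monotone adjusted p-values", {
  universe <- sprintf("G%02d", 1:20)
  pc <- PathwayCollection(list(P1 = universe[1:5], P2 = universe[3:9]),
                          universe = universe)
  res <- fisherEnrichment(universe[1:6], pc, correction = "BH")
  expect_true("padj" %in% names(res))
  expect_equal(res$padj, stats::p.adjust(res$p, "BH"))
})

test_that("the planted pathway is recovered at the top after consolidation", {
  hits <- 0L
  for (s in 1:20) {
    sim <- generateGraph(generatorParams(seed = s))
    tab <- consolidate(fisherEnrichment(startTargets(sim$graph),
                                        sim$pathways, source = "sim"))
    if (tab$pathway[1] == sim$groundTruth$plantedPathway)
      hits <- hits + 1L
  }
  expect_gte(hits, 18L)  # >= 90% of 20 seeds
})
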