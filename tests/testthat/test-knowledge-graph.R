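test_that("loadEdges collapses duplicates and validates layer pairs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1\tAKT1", "c1\tAKT1"), f)
  g <- loadEdges(f, layers = c("COMPONENT", "TARGET"))
  expect_equal(nrow(graphEdges(g)), 1L)
  expect_equal(nrow(graphNodes(g)), 2L)

  writeLines("AKT1\tginseng", f)
  expect_error(loadEdges(f, layers = c("TARGET", "HERB")),
               "disallowed layer pair.*TARGET.*HERB")

  writeLines(c("c1\tAKT1", "lonely-field"), f)
  expect_error(loadEdges(f, layers = c("COMPONENT", "TARGET")),
               "line 2")
})

test_that("loadEdges honours per-row layer columns and headers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("src\ttgt\tlayers",
               "ginseng\tc1\tHERB>COMPONENT",
               "c1\tAKT1\tCOMPONENT>TARGET"), f)
  g <- loadEdges(f, header = TRUE)
  expect_setequal(graphNodes(g)$layer, c("HERB", "COMPONENT", "TARGET"))
  writeLines("a\tb\tBAD", f)
  expect_error(loadEdges(f), "line 1.*layer column")
})

test_that("loading is order-independent and the fixture TSV round-trips", {
  dir <- withr::local_tempdir()
  exportFixture(dir)
  f <- file.path(dir, "edges.tsv")
  g1 <- loadEdges(f)
  lines <- readLines(f)
  writeLines(rev(lines), f)
  g2 <- loadEdges(f)
  expect_identical(graphNodes(g1), graphNodes(g2))
  expect_identical(graphEdges(g1), graphEdges(g2))
  expect_equal(sum(graphNodes(g1)$layer == "COMPONENT"), 5L)
  fx <- redGinsengFixture()
  expect_identical(graphEdges(g1), graphEdges(fx$graph))
})

test_that("GMT loading applies set semantics and flags bad input", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines("P1\tdesc\tTNF\tAKT1", f)
  pc <- loadGeneSets(f)
  expect_equal(length(pc), 1L)
  expect_setequal(geneSets(pc)$P1, c("TNF", "AKT1"))

  writeLines("P1\tdesc\ttnf \tTNF", f)
  expect_equal(lengths(geneSets(loadGeneSets(f))), c(P1 = 1L))

  writeLines(c("P1\td\tTNF", "P1\td\tAKT1"), f)
  expect_error(loadGeneSets(f), "duplicate pathway name")
  writeLines("P1\td\t  ", f)
  expect_error(loadGeneSets(f), "empty gene set")
})

test_that("node degree is direction-blind and errors on unknown nodes", {
  fx <- redGinsengFixture()
  tp <- buildTPNetwork(fx$pathways, unique(unlist(fx$componentTargets)))
  expect_equal(
    unname(nodeDegree(tp,
      nodeId("PATHWAY", "Vascular Endothelial Cell Activation by Growth Factors"))),
    11L)
  expect_equal(unname(nodeDegree(tp, nodeId("PATHWAY", "GFs/TNF Ion Channels"))),
               4L)
  iso <- LayeredGraph(nodes = data.frame(id = "TARGET:AKT1", layer = "TARGET",
                                         label = "AKT1"))
  expect_equal(unname(nodeDegree(iso, "TARGET:AKT1")), 0L)
  expect_error(nodeDegree(iso, "TARGET:TNF"), "unknown node")
})

test_that("degree conservation holds on random graphs", {
  set.seed(42)
  for (i in 1:25) {
    g <- randomLayeredGraph()
    expect_equal(sum(nodeDegree(g)), 2L * nrow(graphEdges(g)))
  }
})

test_that("layer subgraphs are induced and preserve invariants", {
  fx <- redGinsengFixture()
  ctp <- layerSubgraph(fx$graph, c("COMPONENT", "TARGET", "PATHWAY"))
  expect_false(any(graphNodes(ctp)$layer %in% c("HERB", "PHENOTYPE")))
  expect_true(validObject(ctp))

  all_layers <- layerSubgraph(fx$graph, layerTags())
  expect_identical(graphNodes(all_layers), graphNodes(fx$graph))
  expect_identical(graphEdges(all_layers), graphEdges(fx$graph))

  herb <- layerSubgraph(fx$graph, "HERB")
  expect_equal(nrow(graphNodes(herb)), 1L)
  expect_equal(nrow(graphEdges(herb)), 0L)
  expect_error(layerSubgraph(fx$graph, character()), "nonempty")
})

test_that("SIF and GraphML exports round-trip exactly", {
  set.seed(7)
  for (i in 1:10) {
    g <- randomLayeredGraph()
    for (fmt in c("sif", "graphml")) {
      f <- withr::local_tempfile(fileext = paste0(".", fmt))
      exportNetwork(g, f, format = fmt)
      g2 <- importNetwork(f, format = fmt)
      expect_identical(graphNodes(g2), graphNodes(g))
      expect_identical(graphEdges(g2), graphEdges(g))
    }
  }
})

test_that("edge cases of export: empty graph and fixture C-T-P node count", {
  empty <- LayeredGraph()
  f <- withr::local_tempfile(fileext = ".sif")
  exportNetwork(empty, f, format = "sif")
  expect_equal(length(readLines(f)), 0L)

  fx <- redGinsengFixture()
  tp <- buildTPNetwork(fx$pathways, unique(unlist(fx$componentTargets)))
  ctp <- buildCTPNetwork(fx$componentTargets, tp)
  exportNetwork(ctp, f, format = "sif")
  g2 <- importNetwork(f, format = "sif")
  n <- graphNodes(g2)
  expect_equal(nrow(n),
               sum(n$layer == "COMPONENT") + sum(n$layer == "TARGET") +
                 sum(n$layer == "PATHWAY"))
})

test_that("graph validity rejects malformed objects", {
  expect_error(
    LayeredGraph(edges = data.frame(from = "TARGET:A", to = "TARGET:A")),
    "self-loop")
  expect_error(
    LayeredGraph(nodes = data.frame(id = "TARGET:A", layer = "TARGET",
                                    label = "A"),
                 edges = data.frame(from = "TARGET:A", to = "TARGET:B")),
    "missing from node set")
  expect_error(
    LayeredGraph(edges = data.frame(from = "PATHWAY:p", to = "TARGET:A")),
    "disallowed layer pair")
})
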