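chainGraph <- function() {
  LayeredGraph(edges = data.frame(
    from = c("COMPONENT:c1", "TARGET:t1"),
    to = c("TARGET:t1", "PHENOTYPE:ph")))
}

# brute-force triple oracle: (component, target, endpoint) with endpoint the
# phenotype or a pathway/bioprocess touching it
bruteRoutes <- function(g, ph) {
  e <- graphEdges(g)
  phid <- nodeId("PHENOTYPE", ph)
  adj <- unique(c(e$from[e$to == phid], e$to[e$from == phid]))
  ends <- c(phid, adj[grepl("^(PATHWAY|BIOPROCESS):", adj)])
  n <- 0L
  ct <- e[grepl("^COMPONENT:", e$from) & grepl("^TARGET:", e$to), ]
  for (i in seq_len(nrow(ct)))
    for (x in ends)
      if (any(e$from == ct$to[i] & e$to == x)) n <- n + 1L
  n
}

test_that("route enumeration follows the three-layer template", {
  r <- enumerateRoutes(chainGraph(), "ph")
  expect_equal(nrow(r), 1L)
  expect_equal(r$component, "COMPONENT:c1")
  expect_equal(r$terminal, "PHENOTYPE:ph")

  # a component with no target edges contributes no routes
  g <- LayeredGraph(
    nodes = rbind(graphNodes(chainGraph()),
                  data.frame(id = "COMPONENT:c2", layer = "COMPONENT",
                             label = "c2")),
    edges = graphEdges(chainGraph()))
  expect_equal(nrow(enumerateRoutes(g, "ph")), 1L)
  expect_error(enumerateRoutes(g, "nope"), "unknown phenotype")
})

test_that("route counts match the brute-force triple oracle", {
  fx <- redGinsengFixture()
  for (ph in fx$phenotypes)
    expect_equal(nrow(enumerateRoutes(fx$graph, ph)),
                 bruteRoutes(fx$graph, ph))
  set.seed(21)
  for (i in 1:10) {
    g <- randomLayeredGraph()
    phs <- graphNodes(g)$label[graphNodes(g)$layer == "PHENOTYPE"]
    for (ph in phs)
      expect_equal(nrow(enumerateRoutes(g, ph)), bruteRoutes(g, ph))
  }
})

test_that("four-layer template requires explicit pathway-phenotype edges", {
  g <- LayeredGraph(edges = data.frame(
    from = c("COMPONENT:c1", "TARGET:t1", "PATHWAY:p1", "TARGET:t1"),
    to = c("TARGET:t1", "PATHWAY:p1", "PHENOTYPE:ph", "PHENOTYPE:ph")))
  r4 <- enumerateRoutes(g, "ph", includePathway = TRUE)
  expect_equal(nrow(r4), 1L)
  expect_equal(names(r4), c("component", "target", "pathway", "terminal"))
  expect_equal(r4$pathway, "PATHWAY:p1")
})

test_that("node frequencies match a brute-force recount", {
  r <- data.frame(component = c("COMPONENT:a", "COMPONENT:a"),
                  target = c("TARGET:b", "TARGET:c"),
                  terminal = c("PHENOTYPE:x", "PHENOTYPE:y"))
  nf <- nodeFrequencies(r)
  expect_equal(nf$total, 2L)
  expect_equal(nf$freq[["COMPONENT:a"]], 2L)
  expect_equal(nf$freq[["TARGET:b"]], 1L)
  expect_error(nodeFrequencies(r[0, ]), "empty")

  set.seed(31)
  for (i in 1:10) {
    g <- randomLayeredGraph()
    phs <- graphNodes(g)$label[graphNodes(g)$layer == "PHENOTYPE"]
    for (ph in phs) {
      r <- enumerateRoutes(g, ph)
      if (!nrow(r)) next
      nf <- nodeFrequencies(r)
      for (nd in names(nf$freq)) {
        manual <- sum(r$component == nd | r$target == nd | r$terminal == nd)
        expect_equal(nf$freq[[nd]], manual)
      }
    }
  }
})

test_that("path score reproduces the worked examples and its bounds", {
  # a corpus of one path scores 1: every node frequency equals the total
  expect_equal(pathScore(c("a", "b", "c"),
                         freq = c(a = 1, b = 1, c = 1), total = 1), 1)
  # corpus {(a,b),(a,c)}: score of (a,b) = (2/2 + 1/2) / 2
  expect_equal(pathScore(c("a", "b"), freq = c(a = 2, b = 1, c = 1),
                         total = 2), 0.75)
  # a route whose nodes occur in every path attains the upper bound
  expect_equal(pathScore(c("a", "b"), freq = c(a = 5, b = 5), total = 5), 1)
  expect_error(pathScore(c("a", "z"), freq = c(a = 1), total = 1),
               "missing from frequency map")
})

test_that("scores lie in (0,1] and are invariant to corpus row order", {
  set.seed(41)
  for (i in 1:10) {
    g <- randomLayeredGraph()
    phs <- graphNodes(g)$label[graphNodes(g)$layer == "PHENOTYPE"]
    for (ph in phs) {
      r <- enumerateRoutes(g, ph)
      if (!nrow(r)) next
      s1 <- scoreRoutes(r)
      expect_true(all(s1$score > 0 & s1$score <= 1))
      perm <- r[sample(nrow(r)), , drop = FALSE]
      s2 <- scoreRoutes(perm)
      key <- function(d) paste(d$component, d$target, d$terminal)
      expect_equal(s2$score[match(key(s1), key(s2))], s1$score)
    }
  }
})

test_that("adding a node-disjoint path lowers every other score", {
  r <- data.frame(component = "COMPONENT:a", target = "TARGET:b",
                  terminal = "PHENOTYPE:x")
  base <- scoreRoutes(r)$score
  r2 <- rbind(r, data.frame(component = "COMPONENT:q", target = "TARGET:r",
                            terminal = "PHENOTYPE:s"))
  s2 <- scoreRoutes(r2)
  expect_lt(s2$score[1], base)
  # frequencies of the original route's nodes are unchanged
  expect_equal(nodeFrequencies(r2)$freq[["COMPONENT:a"]], 1L)
})

test_that("ranking keeps the best route per endpoint, sorted by score", {
  r <- data.frame(
    component = c("COMPONENT:a", "COMPONENT:a", "COMPONENT:b"),
    target = c("TARGET:t1", "TARGET:t2", "TARGET:t1"),
    terminal = c("PHENOTYPE:x", "PHENOTYPE:x", "PHENOTYPE:y"),
    score = c(0.75, 0.5, 0.6))
  rk <- rankRoutes(r)
  expect_equal(nrow(rk), 2L)
  expect_equal(rk$score, c(0.75, 0.6))
  expect_equal(rk$target[1], "TARGET:t1")

  # all-distinct endpoints: a pure sort
  r2 <- data.frame(component = "COMPONENT:a", target = "TARGET:t",
                   terminal = paste0("PHENOTYPE:", letters[1:3]),
                   score = c(0.2, 0.9, 0.5))
  expect_equal(rankRoutes(r2)$score, c(0.9, 0.5, 0.2))

  set.seed(51)
  for (i in 1:10) {
    g <- randomLayeredGraph()
    phs <- graphNodes(g)$label[graphNodes(g)$layer == "PHENOTYPE"]
    for (ph in phs) {
      r <- enumerateRoutes(g, ph)
      if (!nrow(r)) next
      rk <- rankRoutes(scoreRoutes(r))
      expect_equal(nrow(rk), length(unique(r$terminal)))
      expect_true(all(diff(rk$score) <= 0))
    }
  }
})
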