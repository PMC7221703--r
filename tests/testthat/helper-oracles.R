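# Independent oracles and generators used across the suite.

# Exhaustive hypergeometric upper tail: enumerate every size-q draw from a
# universe of N genes of which the first m form the pathway, and count draws
# overlapping the pathway in at least k genes. Brute force; N <= 20 only.
enumHyperP <- function(N, m, q, k) {
  draws <- utils::combn(N, q)
  hits <- colSums(draws <= m)  # pathway = genes 1..m
  sum(hits >= k) / ncol(draws)
}

# Random valid layered graph for property tests. Always at least one node;
# may contain isolated nodes.
randomLayeredGraph <- function(nC = 3, nT = 6, nP = 3, nPh = 2,
                               prob = 0.4) {
  comps <- sprintf("c%02d", seq_len(nC))
  targs <- sprintf("T%02d", seq_len(nT))
  pws <- sprintf("pw%02d", seq_len(nP))
  phs <- sprintf("ph%02d", seq_len(nPh))
  pick <- function(from, to) {
    grid <- expand.grid(f = from, t = to, stringsAsFactors = FALSE)
    grid[stats::runif(nrow(grid)) < prob, , drop = FALSE]
  }
  ct <- pick(nodeId("COMPONENT", comps), nodeId("TARGET", targs))
  tp <- pick(nodeId("TARGET", targs), nodeId("PATHWAY", pws))
  tf <- pick(nodeId("TARGET", targs), nodeId("PHENOTYPE", phs))
  pf <- pick(nodeId("PATHWAY", pws), nodeId("PHENOTYPE", phs))
  edges <- rbind(
    data.frame(from = ct$f, to = ct$t),
    data.frame(from = tp$f, to = tp$t),
    data.frame(from = tf$f, to = tf$t),
    data.frame(from = pf$f, to = pf$t))
  nodes <- data.frame(
    id = c(nodeId("COMPONENT", comps), nodeId("TARGET", targs),
           nodeId("PATHWAY", pws), nodeId("PHENOTYPE", phs)),
    layer = c(rep("COMPONENT", nC), rep("TARGET", nT),
              rep("PATHWAY", nP), rep("PHENOTYPE", nPh)),
    label = c(comps, targs, pws, phs))
  LayeredGraph(nodes = nodes, edges = edges)
}

# Component-associated target labels of a graph (the walk's start set).
startTargets <- function(g) {
  e <- graphEdges(g)
  ct <- e[grepl("^COMPONENT:", e$from) & grepl("^TARGET:", e$to), ]
  sort(unique(sub("^TARGET:", "", ct$to)))
}
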