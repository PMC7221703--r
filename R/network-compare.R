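## Cross-phenotype and herb-vs-herb pathway comparison, plus construction of
## the bipartite target-pathway (T-P) and tripartite component-target-pathway
## (C-T-P) networks with degree ranking. Pathway names are matched
## exact-string after trimming and case-folding.

.foldName <- function(x) tolower(trimws(x))

#' Pathways shared by every phenotype of a profile
#'
#' The COUNTIF-style intersection: given per-phenotype pathway lists, returns
#' the pathways present in all of them (matching is case-insensitive on
#' trimmed names; the spelling from the first list is returned).
#'
#' @param profile named list: phenotype label -> character vector of pathway
#'   names (e.g. the `pathway` column of a consolidated enrichment table).
#' @return character vector of shared pathway names.
#' @export
sharedPathways <- function(profile) {
  stopifnot(is.list(profile), length(profile) >= 1L)
  if (anyDuplicated(names(profile)))
    stop("phenotype labels must be distinct")
  keys <- lapply(profile, function(x) unique(.foldName(x)))
  shared <- Reduce(intersect, keys)
  first <- trimws(profile[[1L]])
  first[!duplicated(.foldName(first))][
    .foldName(first[!duplicated(.foldName(first))]) %in% shared]
}

#' Pathways exclusive to one herb's shared set
#'
#' @param sharedA,sharedB character vectors of pathway names (the shared sets
#'   of herbs A and B).
#' @return the set difference A minus B (case-insensitive on trimmed names),
#'   in A's spelling.
#' @export
exclusivePathways <- function(sharedA, sharedB) {
  a <- trimws(sharedA)
  a <- a[!duplicated(.foldName(a))]
  a[!.foldName(a) %in% .foldName(trimws(sharedB))]
}

#' Build the bipartite target-pathway (T-P) network
#'
#' One edge per (target, pathway) pair with the target in the pathway's gene
#' set and in the supplied target set. Pathways left without any member and
#' targets without any edge are omitted.
#'
#' @param collection a [PathwayCollection-class].
#' @param targets character vector of target gene symbols.
#' @return a [LayeredGraph-class] over TARGET and PATHWAY nodes.
#' @examples
#' fx <- redGinsengFixture()
#' tp <- buildTPNetwork(fx$pathways, unique(unlist(fx$componentTargets)))
#' max(nodeDegree(tp))  # 11
#' @export
buildTPNetwork <- function(collection, targets) {
  stopifnot(is(collection, "PathwayCollection"))
  targets <- unique(.normGene(targets))
  sets <- lapply(geneSets(collection), intersect, targets)
  sets <- sets[lengths(sets) > 0L]
  edges <- data.frame(
    from = nodeId("TARGET", unlist(sets, use.names = FALSE)),
    to = nodeId("PATHWAY", rep(names(sets), lengths(sets))))
  LayeredGraph(edges = edges)
}

#' Build the component-target-pathway (C-T-P) network
#'
#' Union of the component-target edges with an existing T-P network.
#'
#' @param componentTargets named list: component label -> target gene vector
#'   (or a two-column data.frame `component`, `target` of labels).
#' @param tpNetwork a T-P [LayeredGraph-class] from [buildTPNetwork()].
#' @return a [LayeredGraph-class] over COMPONENT, TARGET and PATHWAY nodes.
#' @export
buildCTPNetwork <- function(componentTargets, tpNetwork) {
  stopifnot(is(tpNetwork, "LayeredGraph"))
  if (is.data.frame(componentTargets)) {
    ct <- data.frame(component = componentTargets$component,
                     target = componentTargets$target)
  } else {
    ct <- data.frame(
      component = rep(names(componentTargets), lengths(componentTargets)),
      target = unlist(componentTargets, use.names = FALSE))
  }
  edges <- rbind(
    data.frame(from = nodeId("COMPONENT", ct$component),
               to = nodeId("TARGET", .normGene(ct$target))),
    graphEdges(tpNetwork))
  comps <- unique(as.character(ct$component))
  targs <- unique(.normGene(as.character(ct$target)))
  nodes <- unique(rbind(
    graphNodes(tpNetwork),
    data.frame(id = nodeId("COMPONENT", comps),
               layer = rep("COMPONENT", length(comps)), label = comps),
    data.frame(id = nodeId("TARGET", targs),
               layer = rep("TARGET", length(targs)), label = targs)))
  LayeredGraph(nodes = nodes, edges = edges)
}

#' Degree ranking of one layer's nodes
#'
#' @param g a [LayeredGraph-class].
#' @param layer layer tag whose nodes to rank.
#' @param top number of top rows to keep (default 10).
#' @return data.frame with columns `node`, `label`, `degree`, sorted by
#'   degree descending with ties broken lexicographically by label.
#' @examples
#' fx <- redGinsengFixture()
#' tp <- buildTPNetwork(fx$pathways, unique(unlist(fx$componentTargets)))
#' degreeRanking(tp, "PATHWAY", top = 1)
#' @export
degreeRanking <- function(g, layer, top = 10L) {
  stopifnot(is(g, "LayeredGraph"), layer %in% .LAYERS)
  n <- graphNodes(g)
  n <- n[n$layer == layer, , drop = FALSE]
  if (!nrow(n))
    stop("layer ", layer, " has no nodes in this graph")
  deg <- nodeDegree(g)[n$id]
  out <- data.frame(node = n$id, label = n$label, degree = as.integer(deg))
  out <- out[order(-out$degree, out$label), , drop = FALSE]
  rownames(out) <- NULL
  head(out, top)
}
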