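#' @import methods
#' @importFrom stats phyper rbinom runif setNames
#' @importFrom utils head read.table write.table packageVersion
NULL

## ---- layer vocabulary -------------------------------------------------------

.LAYERS <- c("HERB", "COMPONENT", "TARGET", "PATHWAY", "BIOPROCESS", "PHENOTYPE")

## Directed layer pairs an edge may connect. Degree and random-walk
## connectivity are direction-blind; the direction only records which layer
## is upstream in the herb -> phenotype cascade.
.ALLOWED_PAIRS <- matrix(c(
  "HERB",      "COMPONENT",
  "COMPONENT", "TARGET",
  "TARGET",    "PATHWAY",
  "TARGET",    "BIOPROCESS",
  "TARGET",    "PHENOTYPE",
  "PATHWAY",   "PHENOTYPE"
), ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("from", "to")))

#' Layer vocabulary of the knowledge graph
#'
#' The closed set of node layers: `HERB`, `COMPONENT`, `TARGET`, `PATHWAY`,
#' `BIOPROCESS`, `PHENOTYPE`. Edges may only connect the pairs
#' HERB-COMPONENT, COMPONENT-TARGET, TARGET-PATHWAY, TARGET-BIOPROCESS,
#' TARGET-PHENOTYPE and PATHWAY-PHENOTYPE (stored in that direction).
#'
#' @return character vector of layer tags.
#' @export
layerTags <- function() .LAYERS

#' Build a node id from layer and label
#'
#' Node ids are `"LAYER:label"` so that, e.g., a gene and a pathway sharing
#' the same string remain distinct nodes, and the layer of a node survives a
#' round trip through formats (such as SIF) that carry no node attributes.
#'
#' @param layer layer tag(s), see [layerTags()].
#' @param label node label(s).
#' @return character vector of node ids.
#' @export
nodeId <- function(layer, label) {
  stopifnot(all(layer %in% .LAYERS))
  if (length(label) == 0L)
    return(character(0))
  paste0(layer, ":", label)
}

.idLayer <- function(id) sub(":.*$", "", id)
.idLabel <- function(id) sub("^[A-Z]+:", "", id)

## ---- LayeredGraph -----------------------------------------------------------

#' LayeredGraph: a layered pharmacology knowledge graph
#'
#' Container for the herb-component-target-pathway/bioprocess-phenotype
#' knowledge graph all analysis stages consume. Nodes carry exactly one layer
#' tag; edges are stored directed from the upstream layer to the downstream
#' one but all degree and connectivity computations treat them as undirected.
#' Node and edge tables are kept in a canonical (sorted, deduplicated) order,
#' so two graphs built from row-permuted inputs compare identical.
#'
#' @slot nodes data.frame with columns `id`, `layer`, `label`.
#' @slot edges data.frame with columns `from`, `to` holding node ids.
#' @seealso [LayeredGraph()], [loadEdges()], [layerSubgraph()], [nodeDegree()]
#' @export
setClass("LayeredGraph",
  representation(nodes = "data.frame", edges = "data.frame"))

setValidity("LayeredGraph", function(object) {
  n <- object@nodes
  e <- object@edges
  if (!all(c("id", "layer", "label") %in% names(n)))
    return("nodes must have columns id, layer, label")
  if (!all(c("from", "to") %in% names(e)))
    return("edges must have columns from, to")
  if (anyDuplicated(n$id))
    return("node ids must be unique")
  bad <- setdiff(n$layer, .LAYERS)
  if (length(bad))
    return(paste0("unknown layer tag(s): ", paste(bad, collapse = ", ")))
  if (nrow(e)) {
    if (any(e$from == e$to))
      return("self-loops are not allowed")
    miss <- setdiff(c(e$from, e$to), n$id)
    if (length(miss))
      return(paste0("edge endpoint(s) missing from node set: ",
                    paste(head(miss, 3L), collapse = ", ")))
    lf <- .idLayer(e$from)
    lt <- .idLayer(e$to)
    ok <- paste(lf, lt) %in% paste(.ALLOWED_PAIRS[, 1L], .ALLOWED_PAIRS[, 2L])
    if (!all(ok)) {
      i <- which(!ok)[1L]
      return(sprintf("disallowed layer pair: %s -> %s", lf[i], lt[i]))
    }
  }
  TRUE
})

#' Construct a LayeredGraph
#'
#' @param nodes data.frame with columns `id`, `layer`, `label`, or NULL to
#'   derive the node set from the edges (ids must then be `"LAYER:label"`).
#' @param edges data.frame with columns `from`, `to` (node ids). Duplicate
#'   edges are collapsed.
#' @return a validated [LayeredGraph-class] in canonical node/edge order.
#' @examples
#' g <- LayeredGraph(
#'   edges = data.frame(from = nodeId("COMPONENT", "ginsenoside Rg1"),
#'                      to   = nodeId("TARGET", "AKT1")))
#' nodeDegree(g)
#' @export
LayeredGraph <- function(nodes = NULL, edges = NULL) {
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character())
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to))
  if (is.null(nodes)) {
    id <- unique(c(edges$from, edges$to))
    nodes <- data.frame(id = id, layer = .idLayer(id), label = .idLabel(id))
  }
  nodes <- data.frame(id = as.character(nodes$id),
                      layer = as.character(nodes$layer),
                      label = as.character(nodes$label))
  nodes <- unique(nodes)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges <- unique(edges)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  new("LayeredGraph", nodes = nodes, edges = edges)
}

setMethod("show", "LayeredGraph", function(object) {
  tab <- table(factor(object@nodes$layer, levels = .LAYERS))
  tab <- tab[tab > 0L]
  cat(sprintf("LayeredGraph: %d nodes, %d edges\n",
              nrow(object@nodes), nrow(object@edges)))
  if (length(tab))
    cat("  layers:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
})

#' @rdname graphNodes
#' @export
setMethod("graphNodes", "LayeredGraph", function(x) x@nodes)

#' @rdname graphNodes
#' @export
setMethod("graphEdges", "LayeredGraph", function(x) x@edges)

## ---- PathwayCollection ------------------------------------------------------

#' PathwayCollection: named gene sets plus a gene universe
#'
#' Gene sets (pathways, typically read from a GMT file) together with the
#' universe of genes eligible for draw in over-representation tests. Gene
#' symbols are uppercased and whitespace-trimmed on construction; each set is
#' deduplicated. By default the universe is the union of all sets, which
#' mirrors treating the pathway database itself as the sampling frame; pass
#' an explicit universe (e.g. the graph's target genes) to change that.
#'
#' @slot sets named list of character gene vectors.
#' @slot universe character vector of genes; every set is a subset of it.
#' @seealso [PathwayCollection()], [loadGeneSets()], [fisherEnrichment()]
#' @export
setClass("PathwayCollection",
  representation(sets = "list", universe = "character"))

setValidity("PathwayCollection", function(object) {
  s <- object@sets
  if (length(s)) {
    if (is.null(names(s)) || any(!nzchar(names(s))))
      return("every gene set must be named")
    if (anyDuplicated(names(s)))
      return("duplicate pathway names")
    if (any(lengths(s) == 0L))
      return("empty gene sets are not allowed")
    if (!all(unlist(s) %in% object@universe))
      return("every gene set must be a subset of the universe")
  }
  TRUE
})

.normGene <- function(x) toupper(trimws(x))

#' Construct a PathwayCollection
#'
#' @param sets named list of character gene vectors.
#' @param universe gene universe; defaults to the union of `sets`.
#' @return a validated [PathwayCollection-class].
#' @examples
#' pc <- PathwayCollection(list(P1 = c("tnf ", "Akt1")))
#' geneSets(pc)
#' @export
PathwayCollection <- function(sets, universe = NULL) {
  sets <- lapply(sets, function(g) unique(.normGene(g)))
  if (is.null(universe))
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  else
    universe <- sort(unique(.normGene(universe)))
  new("PathwayCollection", sets = sets, universe = universe)
}

setMethod("show", "PathwayCollection", function(object) {
  cat(sprintf("PathwayCollection: %d gene sets over a universe of %d genes\n",
              length(object@sets), length(object@universe)))
  if (length(object@sets))
    cat(sprintf("  set sizes: %d-%d (median %g)\n",
                min(lengths(object@sets)), max(lengths(object@sets)),
                stats::median(lengths(object@sets))))
})

#' @rdname geneSets
#' @export
setMethod("geneSets", "PathwayCollection", function(x) x@sets)

#' @rdname geneSets
#' @export
setMethod("geneUniverse", "PathwayCollection", function(x) x@universe)

#' @describeIn PathwayCollection number of gene sets.
#' @param x a PathwayCollection.
#' @export
setMethod("length", "PathwayCollection", function(x) length(x@sets))

#' @describeIn PathwayCollection pathway names.
#' @export
setMethod("names", "PathwayCollection", function(x) names(x@sets))

## ---- RWResult ---------------------------------------------------------------

#' RWResult: converged random-walk-with-restart scores
#'
#' The fixed point of the propagation F_{t+1} = alpha * F_t A + (1 - alpha) * F0
#' on a row-stochastic connectivity matrix, together with the iteration count
#' and final L1 residual. Scores are a probability vector: nonnegative,
#' summing to 1.
#'
#' @slot scores named numeric vector over graph nodes.
#' @slot iterations number of iterations performed.
#' @slot residual final L1 difference between successive iterates.
#' @slot alpha restart-complement rate control factor used.
#' @slot threshold convergence bound used.
#' @seealso [rwr()], [rwrClosedForm()], [phenotypeScores()]
#' @export
setClass("RWResult",
  representation(scores = "numeric", iterations = "integer",
                 residual = "numeric", alpha = "numeric",
                 threshold = "numeric"))

setValidity("RWResult", function(object) {
  if (any(object@scores < -1e-12))
    return("scores must be nonnegative")
  if (abs(sum(object@scores) - 1) > 1e-9)
    return("scores must sum to 1")
  if (object@residual >= object@threshold)
    return("residual must be below the convergence threshold")
  TRUE
})

setMethod("show", "RWResult", function(object) {
  cat(sprintf(
    "RWResult: %d nodes, alpha=%g, converged in %d iteration(s) (L1 residual %.3g < %g)\n",
    length(object@scores), object@alpha, object@iterations,
    object@residual, object@threshold))
})

#' @rdname rwScores
#' @export
setMethod("rwScores", "RWResult", function(x) x@scores)
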