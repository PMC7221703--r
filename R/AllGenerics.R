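#' Node table of a layered graph
#'
#' @param x a [LayeredGraph-class] object.
#' @return `graphNodes` returns a data.frame with columns `id`, `layer`,
#'   `label`; `graphEdges` a data.frame with columns `from`, `to` (node ids).
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname graphNodes
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' Direction-blind node degree
#'
#' Degree counts incident edges regardless of the stored edge direction:
#' a pathway's degree is its number of member targets, a target's degree the
#' number of components, pathways and phenotypes it touches.
#'
#' @param x a [LayeredGraph-class].
#' @param node optional character vector of node ids; unknown ids are an
#'   error. When missing, degrees for all nodes are returned.
#' @return named integer vector of degrees.
#' @export
setGeneric("nodeDegree", function(x, node) standardGeneric("nodeDegree"))

#' Induced subgraph on a set of layers
#'
#' @param x a [LayeredGraph-class].
#' @param layers character vector of layer tags (see [layerTags()]).
#' @return a [LayeredGraph-class] restricted to nodes in `layers` and the
#'   edges among them.
#' @export
setGeneric("layerSubgraph", function(x, layers) standardGeneric("layerSubgraph"))

#' Export a layered graph to an interchange format
#'
#' SIF files are tab-separated with the relation word `links`, one edge per
#' line; isolated nodes are written as single-column lines. GraphML files
#' store the layer and label as node attributes. Both formats round-trip
#' through [importNetwork()].
#'
#' @param x a [LayeredGraph-class].
#' @param path output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
setGeneric("exportNetwork", function(x, path, format = c("sif", "graphml"))
  standardGeneric("exportNetwork"))

#' Gene sets and gene universe of a pathway collection
#'
#' @param x a [PathwayCollection-class].
#' @return `geneSets` returns the named list of character gene vectors;
#'   `geneUniverse` the character vector of all genes eligible for draw in
#'   enrichment tests.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname geneSets
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' Score vector of a random-walk result
#'
#' @param x an [RWResult-class].
#' @return named numeric vector of converged node scores (sums to 1).
#' @export
setGeneric("rwScores", function(x) standardGeneric("rwScores"))
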