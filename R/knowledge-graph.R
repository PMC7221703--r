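#' Load a layered edge list from a TSV file
#'
#' Reads a tab-separated edge list into a [LayeredGraph-class]. Each row is
#' one edge: column 1 the source label, column 2 the target label. Layers are
#' taken from the `layers` argument (one source/target layer pair applied to
#' the whole file) or, when the file carries a third column, from that column
#' as a per-row `"SRCLAYER>TGTLAYER"` pair, which overrides `layers`.
#' Duplicate rows collapse to a single edge.
#'
#' @param path TSV file path.
#' @param layers length-2 character vector: layer of column 1 and of column 2
#'   (see [layerTags()]). May be omitted when every row has a layer column.
#' @param header logical; skip a header line.
#' @return a [LayeredGraph-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("ginsenoside Rg1\tAKT1", "ginsenoside Rg1\tTNF"), f)
#' loadEdges(f, layers = c("COMPONENT", "TARGET"))
#' @export
loadEdges <- function(path, layers = NULL, header = FALSE) {
  lines <- readLines(path)
  off <- 0L
  if (header && length(lines)) {
    lines <- lines[-1L]
    off <- 1L
  }
  keep <- nzchar(trimws(lines))
  lineno <- which(keep) + off
  lines <- lines[keep]
  if (!is.null(layers)) {
    if (length(layers) != 2L || !all(layers %in% .LAYERS))
      stop("'layers' must be two layer tags from layerTags()")
  }
  from <- to <- character(length(lines))
  lf <- lt <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L)
      stop(sprintf("parse error at line %d: expected >= 2 tab-separated fields, got %d",
                   lineno[i], length(f)))
    if (length(f) >= 3L && nzchar(f[3L])) {
      pair <- strsplit(f[3L], ">", fixed = TRUE)[[1L]]
      if (length(pair) != 2L || !all(pair %in% .LAYERS))
        stop(sprintf("parse error at line %d: bad layer column '%s' (expected 'SRC>TGT')",
                     lineno[i], f[3L]))
      lf[i] <- pair[1L]; lt[i] <- pair[2L]
    } else {
      if (is.null(layers))
        stop(sprintf("parse error at line %d: no layer column and no 'layers' argument",
                     lineno[i]))
      lf[i] <- layers[1L]; lt[i] <- layers[2L]
    }
    from[i] <- trimws(f[1L])
    to[i] <- trimws(f[2L])
  }
  LayeredGraph(edges = data.frame(from = nodeId(lf, from), to = nodeId(lt, to)))
}

#' @rdname nodeDegree
setMethod("nodeDegree", "LayeredGraph", function(x, node) {
  e <- x@edges
  deg <- table(factor(c(e$from, e$to), levels = x@nodes$id))
  deg <- setNames(as.integer(deg), names(deg))
  if (missing(node))
    return(deg)
  miss <- setdiff(node, names(deg))
  if (length(miss))
    stop("unknown node(s): ", paste(miss, collapse = ", "))
  deg[node]
})

#' @rdname layerSubgraph
setMethod("layerSubgraph", "LayeredGraph", function(x, layers) {
  if (!length(layers))
    stop("'layers' must be nonempty")
  stopifnot(all(layers %in% .LAYERS))
  n <- x@nodes[x@nodes$layer %in% layers, , drop = FALSE]
  e <- x@edges[x@edges$from %in% n$id & x@edges$to %in% n$id, , drop = FALSE]
  LayeredGraph(nodes = n, edges = e)
})

## ---- interchange formats ----------------------------------------------------

#' @rdname exportNetwork
setMethod("exportNetwork", "LayeredGraph",
  function(x, path, format = c("sif", "graphml")) {
    format <- match.arg(format)
    if (format == "sif") {
      e <- x@edges
      lines <- if (nrow(e)) paste(e$from, "links", e$to, sep = "\t") else character()
      lone <- setdiff(x@nodes$id, c(e$from, e$to))
      writeLines(c(lines, lone), path)
    } else {
      ig <- igraph::graph_from_data_frame(
        x@edges, directed = TRUE,
        vertices = data.frame(name = x@nodes$id, layer = x@nodes$layer,
                              label = x@nodes$label))
      igraph::write_graph(ig, path, format = "graphml")
    }
    invisible(path)
  })

#' Read a network written by exportNetwork
#'
#' @param path file path.
#' @param format `"sif"` or `"graphml"`.
#' @return a [LayeredGraph-class] with the same node and edge sets as the
#'   exported graph (layer tags are recovered from the `"LAYER:"` id prefix
#'   for SIF, from node attributes for GraphML).
#' @export
importNetwork <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf == 2L | nf > 3L))
      stop("malformed SIF: expected 1 or 3 tab-separated fields per line")
    eds <- fields[nf == 3L]
    edges <- data.frame(from = vapply(eds, `[`, "", 1L),
                        to = vapply(eds, `[`, "", 3L))
    lone <- vapply(fields[nf == 1L], `[`, "", 1L)
    id <- unique(c(edges$from, edges$to, lone))
    nodes <- data.frame(id = id, layer = .idLayer(id), label = .idLabel(id))
    LayeredGraph(nodes = nodes, edges = edges)
  } else {
    ig <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(id = igraph::V(ig)$name,
                        layer = igraph::V(ig)$layer,
                        label = igraph::V(ig)$label)
    el <- igraph::as_edgelist(ig, names = TRUE)
    LayeredGraph(nodes = nodes,
                 edges = data.frame(from = el[, 1L], to = el[, 2L]))
  }
}
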