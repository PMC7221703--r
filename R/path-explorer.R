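## Route exploration: enumerate component -> target -> endpoint paths toward
## a phenotype of interest and score each route by the mean, over its nodes,
## of the fraction of all enumerated routes that contain the node. Routes are
## then deduplicated per endpoint (best score kept) and ranked.

#' Enumerate component-target-endpoint routes toward a phenotype
#'
#' Follows the three-layer route template component - associated target -
#' endpoint, where the endpoint is either the queried PHENOTYPE node itself
#' or a PATHWAY/BIOPROCESS node adjacent (direction-blind) to it. With
#' `includePathway = TRUE` a four-layer template is used instead:
#' component - target - pathway - phenotype, requiring an explicit
#' pathway-phenotype edge. Routes are returned in deterministic
#' lexicographic order of their node ids.
#'
#' @param g a [LayeredGraph-class].
#' @param phenotype label (or node id) of a PHENOTYPE node.
#' @param includePathway logical; use the four-layer template.
#' @return data.frame with one route per row: columns `component`, `target`,
#'   (`pathway` if four-layer), `terminal` -- all node ids -- and the queried
#'   phenotype as attribute `"phenotype"`.
#' @examples
#' fx <- redGinsengFixture()
#' r <- enumerateRoutes(fx$graph, "hyperlipidemia")
#' nrow(r)  # one route per component-target edge
#' @export
enumerateRoutes <- function(g, phenotype, includePathway = FALSE) {
  stopifnot(is(g, "LayeredGraph"))
  ids <- graphNodes(g)$id
  ph <- if (phenotype %in% ids) phenotype else nodeId("PHENOTYPE", phenotype)
  if (!ph %in% ids || .idLayer(ph) != "PHENOTYPE")
    stop("unknown phenotype: ", phenotype)
  e <- graphEdges(g)
  lf <- .idLayer(e$from)
  lt <- .idLayer(e$to)
  ct <- e[lf == "COMPONENT" & lt == "TARGET", , drop = FALSE]
  if (includePathway) {
    tp <- e[lf == "TARGET" & lt == "PATHWAY", , drop = FALSE]
    pp <- e[lf == "PATHWAY" & lt == "PHENOTYPE" & e$to == ph, , drop = FALSE]
    tp <- tp[tp$to %in% pp$from, , drop = FALSE]
    out <- merge(ct, tp, by.x = "to", by.y = "from")
    out <- data.frame(component = out$from, target = out$to,
                      pathway = out$to.y, terminal = ph)
    ord <- order(out$component, out$target, out$pathway)
  } else {
    ## endpoints: the phenotype itself plus pathways/bioprocesses touching it
    adj <- unique(c(e$from[e$to == ph], e$to[e$from == ph]))
    ends <- c(ph, adj[.idLayer(adj) %in% c("PATHWAY", "BIOPROCESS")])
    te <- e[lf == "TARGET" & e$to %in% ends, , drop = FALSE]
    out <- merge(ct, te, by.x = "to", by.y = "from")
    out <- data.frame(component = out$from, target = out$to,
                      terminal = out$to.y)
    ord <- order(out$component, out$target, out$terminal)
  }
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "phenotype") <- ph
  out
}

.routeCols <- function(routes)
  intersect(c("component", "target", "pathway", "terminal"), names(routes))

#' Node frequencies over a route corpus
#'
#' @param routes data.frame of routes as returned by [enumerateRoutes()]
#'   (nonempty).
#' @return list with `freq`, a named integer count of routes containing each
#'   node, and `total`, the number of routes.
#' @export
nodeFrequencies <- function(routes) {
  if (!NROW(routes))
    stop("empty route corpus")
  cols <- .routeCols(routes)
  nodes <- unlist(routes[cols], use.names = FALSE)
  tab <- table(nodes)
  list(freq = setNames(as.integer(tab), names(tab)),
       total = nrow(routes))
}

#' Frequency path score of one route
#'
#' The score of a route with nodes v_1..v_n in a corpus of N routes is
#' `mean_i( count(routes containing v_i) / N )` -- the average corpus
#' frequency of its nodes. It lies in (0, 1] and equals 1 exactly when every
#' node of the route occurs in every route of the corpus.
#'
#' @param route character vector of node ids.
#' @param freq named frequency vector from [nodeFrequencies()].
#' @param total number of routes in the corpus.
#' @return numeric score in (0, 1].
#' @examples
#' pathScore(c("a", "b"), freq = c(a = 2, b = 1), total = 2)  # 0.75
#' @export
pathScore <- function(route, freq, total) {
  if (total < 1)
    stop("'total' must be >= 1")
  miss <- setdiff(route, names(freq))
  if (length(miss))
    stop("node(s) missing from frequency map: ", paste(miss, collapse = ", "))
  mean(freq[route] / total)
}

#' Score every route of a corpus
#'
#' @param routes data.frame of routes from [enumerateRoutes()].
#' @return the same data.frame with a `score` column.
#' @export
scoreRoutes <- function(routes) {
  nf <- nodeFrequencies(routes)
  cols <- .routeCols(routes)
  routes$score <- apply(routes[cols], 1L, pathScore,
                        freq = nf$freq, total = nf$total)
  routes
}

#' Rank scored routes and keep the best per endpoint
#'
#' Retains, for each terminal endpoint, the route with the highest score
#' (ties resolved lexicographically by the route's node ids), then sorts by
#' score descending with ties broken lexicographically by the endpoint label.
#'
#' @param routes scored routes from [scoreRoutes()].
#' @return deduplicated, ranked data.frame.
#' @export
rankRoutes <- function(routes) {
  stopifnot("score" %in% names(routes))
  if (!NROW(routes))
    return(routes)
  cols <- .routeCols(routes)
  key <- do.call(paste, c(routes[cols], sep = "\r"))
  ord <- order(routes$terminal, -routes$score, key)
  routes <- routes[ord, , drop = FALSE]
  routes <- routes[!duplicated(routes$terminal), , drop = FALSE]
  routes <- routes[order(-routes$score, .idLabel(routes$terminal)), ,
                   drop = FALSE]
  rownames(routes) <- NULL
  routes
}
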