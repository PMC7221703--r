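## Over-representation analysis: one-sided Fisher's exact test (upper-tail
## hypergeometric) of a query gene list against each pathway gene set, then
## the consolidation step that merges per-component / per-phenotype result
## tables into one ranked, name-deduplicated table.

#' One-sided Fisher pathway enrichment
#'
#' For a query of q genes against a pathway of m genes in a universe of N,
#' with k genes overlapping, the p-value is the upper-tail hypergeometric
#' probability `P(X >= k)`, identical to the one-sided Fisher exact test on
#' the 2x2 membership table. Query genes outside the universe are dropped
#' with a warning; pathways with no overlapping gene are omitted from the
#' result.
#'
#' @param query character vector of gene symbols (normalized like the
#'   collection: uppercased, trimmed, deduplicated).
#' @param collection a [PathwayCollection-class].
#' @param universe gene universe; defaults to the collection's.
#' @param source optional label (component or phenotype of origin) stored in
#'   a `source` column for downstream [consolidate()].
#' @param correction `"none"` (default; raw p-values as reported) or `"BH"`
#'   to append a Benjamini-Hochberg `padj` column.
#' @return data.frame with columns `pathway`, `k` (overlap count), `q`, `m`,
#'   `N`, `p`, `negLog10P`, `overlapGenes` (comma-separated), `source`,
#'   sorted by `p` ascending then name.
#' @examples
#' pc <- PathwayCollection(list(P1 = c("TNF", "AKT1", "IL6")),
#'                         universe = sprintf("G%02d", 1:20))
#' fisherEnrichment(c("TNF", "AKT1"), pc)
#' @export
fisherEnrichment <- function(query, collection,
                             universe = geneUniverse(collection),
                             source = NA_character_,
                             correction = c("none", "BH")) {
  correction <- match.arg(correction)
  stopifnot(is(collection, "PathwayCollection"))
  universe <- unique(.normGene(universe))
  query <- unique(.normGene(query))
  out <- setdiff(query, universe)
  if (length(out)) {
    warning(sprintf("dropping %d query gene(s) outside the universe: %s",
                    length(out), paste(head(out, 5L), collapse = ", ")))
    query <- intersect(query, universe)
  }
  if (!length(query))
    stop("no query genes left after restricting to the universe")
  sets <- geneSets(collection)
  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(sets[[nm]], universe)
    ov <- intersect(query, set)
    k <- length(ov)
    if (k == 0L)
      return(NULL)
    m <- length(set)
    p <- phyper(k - 1L, m, N - m, q, lower.tail = FALSE)
    data.frame(pathway = nm, k = k, q = q, m = m, N = N, p = p,
               overlapGenes = paste(sort(ov), collapse = ","),
               source = source)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(pathway = character(), k = integer(), q = integer(),
                      m = integer(), N = integer(), p = numeric(),
                      overlapGenes = character(), source = character())
  res$negLog10P <- -log10(res$p)
  res <- res[order(res$p, res$pathway), , drop = FALSE]
  if (correction == "BH")
    res$padj <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Consolidate enrichment tables from several sources
#'
#' Merges rows from multiple components or phenotypes into a single ranked
#' table: sorted by overlap count descending, then p-value ascending (the
#' most significant first), then pathway name; the first occurrence of each
#' pathway name is retained.
#'
#' @param ... enrichment data.frames from [fisherEnrichment()] (each carrying
#'   a `source` column), or a single list of them.
#' @return one deduplicated, ranked data.frame.
#' @export
consolidate <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) &&
      !is.data.frame(args[[1L]]))
    args <- args[[1L]]
  stopifnot(length(args) >= 1L, all(vapply(args, is.data.frame, TRUE)))
  rows <- do.call(rbind, args)
  if (!NROW(rows))
    return(rows)
  rows <- rows[order(-rows$k, rows$p, rows$pathway), , drop = FALSE]
  rows <- rows[!duplicated(rows$pathway), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' First k rows of a ranked table
#'
#' @param table a data.frame (already ranked).
#' @param k number of rows to keep (default 100, the usual enriched-pathway
#'   report depth; per-phenotype summaries typically use 10).
#' @return the first `min(k, nrow)` rows, order preserved.
#' @export
topK <- function(table, k = 100L) {
  if (k < 1L)
    stop("'k' must be >= 1")
  head(table, k)
}
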