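#' Read gene sets from a GMT file
#'
#' Standard MSigDB dialect: one set per line, tab-separated as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Gene symbols are uppercased
#' and whitespace-trimmed; repeated genes within a line collapse (set
#' semantics). Duplicate set names and empty gene sets are errors.
#'
#' @param path GMT file path.
#' @param universe optional explicit gene universe; defaults to the union of
#'   all sets in the file.
#' @return a [PathwayCollection-class].
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("P1\tdesc\tTNF\tAKT1", f)
#' loadGeneSets(f)
#' @export
loadGeneSets <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- list()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop(sprintf("GMT parse error at line %d: expected name, description and >= 1 gene", i))
    nm <- trimws(f[1L])
    genes <- unique(.normGene(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop(sprintf("GMT parse error at line %d: empty gene set '%s'", i, nm))
    if (nm %in% names(sets))
      stop(sprintf("duplicate pathway name '%s' at line %d", nm, i))
    sets[[nm]] <- genes
  }
  PathwayCollection(sets, universe = universe)
}

#' Write a PathwayCollection as a GMT file
#'
#' @param x a [PathwayCollection-class].
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions
#'   (recycled; defaults to `"na"`).
#' @return `path`, invisibly.
#' @export
writeGMT <- function(x, path, descriptions = "na") {
  s <- geneSets(x)
  desc <- rep_len(descriptions, length(s))
  lines <- vapply(seq_along(s), function(i)
    paste(c(names(s)[i], desc[i], s[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
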