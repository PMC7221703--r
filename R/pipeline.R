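## End-to-end orchestration: validate a config, assemble the input graph
## (fixture, generator, or user TSV/GMT files), then run phenotype scoring,
## route exploration, enrichment, comparison and network export, writing a
## result bundle plus a reproducibility manifest.

.CONFIG_KEYS <- list(
  top = c("input", "fixture", "generator", "rw", "enrichment", "seed",
          "outdir", "compareTo"),
  input = c("edges", "gmt", "layers"),
  rw = c("alpha", "threshold", "maxIter"),
  enrichment = c("topK", "correction"))

.configError <- function(fmt, ...) {
  cond <- structure(
    class = c("herbnet_config_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1L)))
  stop(cond)
}

.checkKeys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    .configError("unknown %s key(s): %s", where, paste(bad, collapse = ", "))
}

#' Validate a pipeline configuration
#'
#' A config is a named list (or the path of a YAML file holding one) with
#' keys: exactly one of `fixture: true`, `generator: <generatorParams
#' fields>`, or `input: {edges:, gmt:, layers:}`; optional `rw` (`alpha`,
#' `threshold`, `maxIter`), `enrichment` (`topK`, `correction`), `seed`,
#' `outdir`, and `compareTo` (path to another run's shared-pathway TSV).
#' Unknown keys are rejected before any stage runs.
#'
#' @param config named list or YAML file path.
#' @return the validated config list (with defaults filled in).
#' @export
pipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config))
    .configError("config must be a named list or a YAML file path")
  .checkKeys(config, .CONFIG_KEYS$top, "config")
  modes <- c(!is.null(config$fixture) && isTRUE(config$fixture),
             !is.null(config$generator),
             !is.null(config$input))
  if (sum(modes) != 1L)
    .configError("exactly one of 'fixture', 'generator' or 'input' must be set")
  if (!is.null(config$input)) {
    .checkKeys(config$input, .CONFIG_KEYS$input, "input")
    if (is.null(config$input$edges))
      .configError("input mode requires 'input.edges' (TSV path)")
    if (is.null(config$input$gmt))
      .configError("input mode requires 'input.gmt' (GMT path)")
  }
  if (!is.null(config$rw))
    .checkKeys(config$rw, .CONFIG_KEYS$rw, "rw")
  if (!is.null(config$enrichment))
    .checkKeys(config$enrichment, .CONFIG_KEYS$enrichment, "enrichment")
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  config$rw <- utils::modifyList(
    list(alpha = 0.7, threshold = 1e-6, maxIter = 10000L),
    if (is.null(config$rw)) list() else config$rw)
  config$enrichment <- utils::modifyList(
    list(topK = 100L, correction = "none"),
    if (is.null(config$enrichment)) list() else config$enrichment)
  config
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

.slug <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))

.writeTSV <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full inference pipeline
#'
#' Loads or generates the layered knowledge graph, then: (1) scores every
#' phenotype by random walk with restart from the component-associated
#' targets; (2) enumerates, scores and ranks routes per phenotype; (3) runs
#' Fisher enrichment per phenotype on the route targets and consolidates;
#' (4) intersects the per-phenotype pathway profiles (and, when `compareTo`
#' points at another run's shared-pathway table, computes this run's
#' exclusive pathways); (5) builds and exports the T-P and C-T-P networks
#' with a target degree ranking. All outputs are TSV/SIF/GraphML files under
#' `outDir` plus `manifest.json` recording config, seed, versions and
#' summary counts. Runs are deterministic for a fixed seed.
#'
#' @param config config list or YAML path, see [pipelineConfig()].
#' @param outDir output directory (overrides `config$outdir`).
#' @return invisibly, a list with the in-memory results (`graph`,
#'   `phenotypeScores`, `routes`, `enrichment`, `profiles`, `shared`,
#'   `manifest`, ...).
#' @examples
#' \donttest{
#' res <- runPipeline(list(fixture = TRUE, outdir = tempfile()))
#' res$manifest$counts$nComponents  # 5
#' }
#' @export
runPipeline <- function(config, outDir = NULL) {
  config <- pipelineConfig(config)
  outDir <- if (is.null(outDir)) config$outdir else outDir
  if (is.null(outDir))
    .configError("no output directory: set 'outdir' or pass outDir")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  files <- character()

  data <- .stage("load", {
    if (isTRUE(config$fixture)) {
      redGinsengFixture()
    } else if (!is.null(config$generator)) {
      gp <- do.call(generatorParams,
                    utils::modifyList(config$generator,
                                      list(seed = config$seed)))
      generateGraph(gp)
    } else {
      layers <- config$input$layers
      g <- loadEdges(config$input$edges, layers = layers)
      list(graph = g, pathways = loadGeneSets(config$input$gmt))
    }
  })
  g <- data$graph
  nodes <- graphNodes(g)
  phens <- nodes$label[nodes$layer == "PHENOTYPE"]

  e <- graphEdges(g)
  ctEdges <- e[.idLayer(e$from) == "COMPONENT" & .idLayer(e$to) == "TARGET", ]
  startTargets <- sort(unique(.idLabel(ctEdges$to)))
  if (!length(startTargets))
    .stage("load", stop("graph has no component-target edges"))

  scores <- .stage("phenotype-scores", {
    s <- phenotypeScores(g, startTargets, alpha = config$rw$alpha,
                         threshold = config$rw$threshold,
                         maxIter = config$rw$maxIter)
    files <- c(files, .writeTSV(
      data.frame(node = s$label, score = s$normalized),
      file.path(outDir, "phenotype_scores.tsv")))
    s
  })

  routes <- .stage("routes", {
    out <- list()
    for (ph in phens) {
      r <- enumerateRoutes(g, ph)
      if (nrow(r)) {
        scored <- scoreRoutes(r)
        ranked <- rankRoutes(scored)
        tab <- data.frame(component = .idLabel(ranked$component),
                          target = .idLabel(ranked$target),
                          bioprocess = .idLabel(ranked$terminal),
                          score = ranked$score)
      } else {
        scored <- ranked <- r
        tab <- data.frame(component = character(), target = character(),
                          bioprocess = character(), score = numeric())
      }
      files <- c(files, .writeTSV(
        tab, file.path(outDir, sprintf("routes_%s.tsv", .slug(ph)))))
      out[[ph]] <- list(scored = scored, ranked = ranked)
    }
    out
  })

  enr <- .stage("enrichment", {
    perPhen <- list()
    for (ph in phens) {
      r <- routes[[ph]]$scored
      qry <- if (NROW(r)) unique(.idLabel(r$target)) else character()
      if (!length(qry))
        next
      tab <- fisherEnrichment(qry, data$pathways, source = ph,
                              correction = config$enrichment$correction)
      if (nrow(tab))
        perPhen[[ph]] <- topK(consolidate(tab), config$enrichment$topK)
    }
    if (!length(perPhen))
      stop("no phenotype produced any enrichment result")
    combined <- topK(consolidate(perPhen), config$enrichment$topK)
    files <- c(files, .writeTSV(combined,
                                 file.path(outDir, "enrichment.tsv")))
    list(perPhenotype = perPhen, combined = combined)
  })

  compare <- .stage("compare", {
    profile <- lapply(enr$perPhenotype, function(x) x$pathway)
    shared <- sharedPathways(profile)
    files <- c(files, .writeTSV(data.frame(pathway = shared),
                                 file.path(outDir, "shared_pathways.tsv")))
    excl <- NULL
    if (!is.null(config$compareTo)) {
      other <- read.table(config$compareTo, sep = "\t", header = TRUE,
                          quote = "")$pathway
      excl <- exclusivePathways(shared, other)
      files <- c(files, .writeTSV(
        data.frame(pathway = excl),
        file.path(outDir, "exclusive_pathways.tsv")))
    }
    list(profile = profile, shared = shared, exclusive = excl)
  })

  nets <- .stage("networks", {
    tp <- buildTPNetwork(data$pathways, startTargets)
    ctLists <- split(.idLabel(ctEdges$to), .idLabel(ctEdges$from))
    ctp <- buildCTPNetwork(ctLists, tp)
    for (nm in c("tp", "ctp")) {
      gnet <- if (nm == "tp") tp else ctp
      for (fmt in c("sif", "graphml")) {
        path <- file.path(outDir, sprintf("%s_network.%s", nm, fmt))
        exportNetwork(gnet, path, format = fmt)
        files <- c(files, path)
      }
    }
    rk <- degreeRanking(ctp, "TARGET", top = 10L)
    files <- c(files, .writeTSV(rk, file.path(outDir,
                                               "target_degree_ranking.tsv")))
    list(tp = tp, ctp = ctp, targetRanking = rk)
  })

  manifest <- list(
    package = "herbnet",
    version = as.character(packageVersion("herbnet")),
    rVersion = as.character(getRversion()),
    seed = config$seed,
    config = config[setdiff(names(config), "outdir")],
    counts = list(
      nComponents = sum(nodes$layer == "COMPONENT"),
      nTargets = length(startTargets),
      nPathways = sum(nodes$layer == "PATHWAY"),
      nPhenotypes = length(phens),
      nodes = nrow(nodes),
      edges = nrow(e)),
    files = basename(files))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(graph = g, pathways = data$pathways,
                 groundTruth = data$groundTruth,
                 phenotypeScores = scores, routes = routes,
                 enrichment = enr, profiles = compare$profile,
                 shared = compare$shared, exclusive = compare$exclusive,
                 networks = nets, manifest = manifest, files = files))
}

#' Write a synthetic dataset to disk
#'
#' Generates a graph with [generateGraph()] and writes it in the package's
#' on-disk dialect -- `edges.tsv` (with a `"SRC>TGT"` layer column),
#' `pathways.gmt`, and `ground_truth.json` -- so the directory can be run
#' through [runPipeline()] like any user dataset.
#'
#' @param params a `herbnet_params` list from [generatorParams()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
simulateDataset <- function(params = generatorParams(), dir) {
  sim <- generateGraph(params)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- graphNodes(sim$graph)
  e <- graphEdges(sim$graph)
  layer <- setNames(n$layer, n$id)
  label <- setNames(n$label, n$id)
  writeLines(paste(label[e$from], label[e$to],
                   paste0(layer[e$from], ">", layer[e$to]), sep = "\t"),
             file.path(dir, "edges.tsv"))
  writeGMT(sim$pathways, file.path(dir, "pathways.gmt"),
           descriptions = "synthetic pathway")
  gt <- sim$groundTruth
  gt$plantedPathway <- if (is.na(gt$plantedPathway)) "none planted"
                       else gt$plantedPathway
  gt$plantedPhenotype <- if (is.na(gt$plantedPhenotype)) "none planted"
                         else gt$plantedPhenotype
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
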