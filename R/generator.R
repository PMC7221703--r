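## Seeded synthetic knowledge-graph generator. Emulates the structure the
## pipeline assumes upstream: one herb, a handful of components hitting a
## bipartite target layer, pathway gene sets drawn from a wider gene universe
## with one deliberately over-enriched ("planted") pathway, and phenotype
## nodes of which one is wired to well-connected targets.

.withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters for the synthetic knowledge-graph generator
#'
#' Defaults are sized to the scale of the packaged red-ginseng fixture
#' (5 components, ~40 targets, ~10 pathways) so that simulation studies run
#' in seconds: `edgeProb = 0.3` approximates the fixture's component-target
#' density (67 of 5 x 37 possible edges), `plantedPathwayOverlap = 8` its
#' median pathway-target overlap, and `plantedPhenotypeTargets = 10` the
#' length of a reported top-target list. The gene universe adds `nDecoyGenes`
#' symbols that exist in pathway sets but are never component targets,
#' mimicking the breadth of a pathway database relative to one herb's
#' target slice.
#'
#' @param nComponents number of component nodes.
#' @param nTargets number of target genes.
#' @param nPathways number of pathway gene sets.
#' @param pathwaySizeRange integer length-2, min/max genes per pathway.
#' @param edgeProb probability an independent component-target edge exists.
#' @param plantedPathwayOverlap number of component-associated (query) genes
#'   forced into one pathway; 0 plants nothing.
#' @param plantedPhenotypeTargets number of high-connectivity targets wired
#'   to one phenotype; 0 plants nothing.
#' @param nPhenotypes number of phenotype nodes.
#' @param backgroundPhenotypeTargets random target links given to every
#'   phenotype regardless of planting.
#' @param nDecoyGenes extra universe genes that are not targets.
#' @param seed integer seed; the single root of all randomness.
#' @return validated list of class `herbnet_params`.
#' @export
generatorParams <- function(nComponents = 5L, nTargets = 40L, nPathways = 10L,
                            pathwaySizeRange = c(5L, 15L), edgeProb = 0.3,
                            plantedPathwayOverlap = 8L,
                            plantedPhenotypeTargets = 10L,
                            nPhenotypes = 4L,
                            backgroundPhenotypeTargets = 3L,
                            nDecoyGenes = 60L, seed = 1L) {
  p <- list(nComponents = as.integer(nComponents),
            nTargets = as.integer(nTargets),
            nPathways = as.integer(nPathways),
            pathwaySizeRange = as.integer(pathwaySizeRange),
            edgeProb = as.numeric(edgeProb),
            plantedPathwayOverlap = as.integer(plantedPathwayOverlap),
            plantedPhenotypeTargets = as.integer(plantedPhenotypeTargets),
            nPhenotypes = as.integer(nPhenotypes),
            backgroundPhenotypeTargets = as.integer(backgroundPhenotypeTargets),
            nDecoyGenes = as.integer(nDecoyGenes),
            seed = as.integer(seed))
  if (p$nComponents < 1L || p$nTargets < 1L || p$nPathways < 1L ||
      p$nPhenotypes < 1L)
    stop("counts must be positive")
  if (p$edgeProb < 0 || p$edgeProb > 1)
    stop("'edgeProb' must be in [0, 1]")
  if (length(p$pathwaySizeRange) != 2L || p$pathwaySizeRange[1L] < 1L ||
      p$pathwaySizeRange[1L] > p$pathwaySizeRange[2L])
    stop("'pathwaySizeRange' must be an increasing positive pair")
  if (p$plantedPathwayOverlap < 0L ||
      p$plantedPathwayOverlap > p$pathwaySizeRange[2L])
    stop("'plantedPathwayOverlap' must be between 0 and the maximum pathway size")
  if (p$plantedPhenotypeTargets < 0L ||
      p$plantedPhenotypeTargets > p$nTargets)
    stop("'plantedPhenotypeTargets' must be between 0 and nTargets")
  if (p$backgroundPhenotypeTargets < 0L ||
      p$backgroundPhenotypeTargets > p$nTargets)
    stop("'backgroundPhenotypeTargets' must be between 0 and nTargets")
  if (p$nDecoyGenes < 0L)
    stop("'nDecoyGenes' must be nonnegative")
  class(p) <- "herbnet_params"
  p
}

#' Generate a synthetic layered knowledge graph with planted signals
#'
#' Draws component-target edges independently with `edgeProb`, samples
#' pathway gene sets from the target + decoy universe, forces
#' `plantedPathwayOverlap` component-associated genes into one randomly chosen
#' pathway, wires every phenotype to a few random targets, and additionally
#' wires one randomly chosen phenotype to the `plantedPhenotypeTargets`
#' targets with the most component connections. Fully reproducible for a
#' fixed `p$seed`.
#'
#' @param p a `herbnet_params` list from [generatorParams()].
#' @return list with elements `graph` ([LayeredGraph-class]), `pathways`
#'   ([PathwayCollection-class], universe = targets + decoys), `groundTruth`
#'   (list naming `plantedPathway` and `plantedPhenotype`, `NA` when nothing
#'   was planted, plus the planted gene/target labels), and `params`.
#' @examples
#' sim <- generateGraph(generatorParams(seed = 7))
#' sim$graph
#' sim$groundTruth$plantedPathway
#' @export
generateGraph <- function(p = generatorParams()) {
  stopifnot(inherits(p, "herbnet_params"))
  .withSeed(p$seed, {
    herb <- "synthetic herb"
    comps <- sprintf("component%02d", seq_len(p$nComponents))
    targets <- sprintf("GENE%03d", seq_len(p$nTargets))
    decoys <- if (p$nDecoyGenes) sprintf("DECOY%03d", seq_len(p$nDecoyGenes))
              else character()
    universe <- c(targets, decoys)
    pwnames <- sprintf("pathway%02d", seq_len(p$nPathways))
    phens <- sprintf("phenotype%02d", seq_len(p$nPhenotypes))

    ## component-target bipartite layer, iid Bernoulli(edgeProb)
    hit <- matrix(runif(p$nComponents * p$nTargets) < p$edgeProb,
                  nrow = p$nComponents,
                  dimnames = list(comps, targets))
    idx <- which(hit, arr.ind = TRUE)
    ct <- data.frame(from = nodeId("COMPONENT", comps[idx[, 1L]]),
                     to = nodeId("TARGET", targets[idx[, 2L]]))
    query <- targets[colSums(hit) > 0L]

    ## pathway gene sets over the universe, one planted with query genes
    plantedPathway <- NA_character_
    plantedGenes <- character()
    if (p$plantedPathwayOverlap > 0L) {
      if (length(query) < p$plantedPathwayOverlap)
        stop(sprintf(
          "infeasible parameters: plantedPathwayOverlap=%d exceeds the %d available query genes",
          p$plantedPathwayOverlap, length(query)))
      plantedPathway <- sample(pwnames, 1L)
      plantedGenes <- sort(sample(query, p$plantedPathwayOverlap))
    }
    sizes <- sample(seq(p$pathwaySizeRange[1L], p$pathwaySizeRange[2L]),
                    p$nPathways, replace = TRUE)
    sets <- vector("list", p$nPathways)
    names(sets) <- pwnames
    for (i in seq_len(p$nPathways)) {
      if (identical(pwnames[i], plantedPathway)) {
        sz <- max(sizes[i], p$plantedPathwayOverlap)
        extra <- sample(setdiff(universe, plantedGenes),
                        sz - length(plantedGenes))
        sets[[i]] <- sort(c(plantedGenes, extra))
      } else {
        sets[[i]] <- sort(sample(universe, sizes[i]))
      }
    }
    member <- data.frame(
      gene = unlist(sets, use.names = FALSE),
      pw = rep(pwnames, lengths(sets)))
    member <- member[member$gene %in% targets, , drop = FALSE]
    tp <- data.frame(from = nodeId("TARGET", member$gene),
                     to = nodeId("PATHWAY", member$pw))

    ## phenotype wiring: uniform background plus one planted hub phenotype
    plantedPhenotype <- NA_character_
    plantedTargets <- character()
    tphen <- data.frame(from = character(), to = character())
    for (ph in phens) {
      if (p$backgroundPhenotypeTargets > 0L) {
        bg <- sample(targets, p$backgroundPhenotypeTargets)
        tphen <- rbind(tphen, data.frame(from = nodeId("TARGET", bg),
                                         to = nodeId("PHENOTYPE", ph)))
      }
    }
    if (p$plantedPhenotypeTargets > 0L) {
      plantedPhenotype <- sample(phens, 1L)
      cdeg <- colSums(hit)
      plantedTargets <- targets[order(-cdeg, targets)][
        seq_len(p$plantedPhenotypeTargets)]
      tphen <- rbind(tphen,
                     data.frame(from = nodeId("TARGET", plantedTargets),
                                to = nodeId("PHENOTYPE", plantedPhenotype)))
    }

    hc <- data.frame(from = nodeId("HERB", herb),
                     to = nodeId("COMPONENT", comps))
    nodes <- data.frame(
      id = c(nodeId("HERB", herb), nodeId("COMPONENT", comps),
             nodeId("TARGET", targets), nodeId("PATHWAY", pwnames),
             nodeId("PHENOTYPE", phens)),
      layer = c("HERB", rep("COMPONENT", length(comps)),
                rep("TARGET", length(targets)),
                rep("PATHWAY", length(pwnames)),
                rep("PHENOTYPE", length(phens))),
      label = c(herb, comps, targets, pwnames, phens))
    graph <- LayeredGraph(nodes = nodes, edges = rbind(hc, ct, tp, tphen))

    list(graph = graph,
         pathways = PathwayCollection(sets, universe = universe),
         groundTruth = list(plantedPathway = plantedPathway,
                            plantedPhenotype = plantedPhenotype,
                            plantedGenes = plantedGenes,
                            plantedTargets = plantedTargets),
         params = p)
  })
}
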