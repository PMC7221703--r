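## Red-ginseng desk fixture: the five signature components with their printed
## target-gene lists, the nine red-ginseng-only signalling pathways with their
## printed member lists, and the four clinical phenotypes. Gene lists are
## stored verbatim; the component lists union to 37 symbols while the pathway
## lists union to 35 (FOS and JUN occur only on the component side) -- the two
## edge families are deliberately not reconciled.

.RG_COMPONENT_TARGETS <- list(
  "ginsenoside Rg1" = c("AKT1", "APP", "BAD", "BCL2", "MAPK1", "MAPK3",
                        "MAPK8", "MAPK9", "NFKBIA", "NGF", "PLCG1", "TNF"),
  "ginsenoside Rb1" = c("AKT1", "IL6", "TNF"),
  "ginsenoside Re" = c("AKT1", "CASP3", "FAS", "FOS", "IFNG", "IL1B", "IL6",
                       "IRAK1", "IRAK4", "MAPK1", "MAPK3", "MYL9", "MYLK",
                       "NFKBIA", "NOS3", "OCLN", "PTGS2", "ROCK1", "TGFB1",
                       "TJP1", "TNF"),
  "notoginsenoside R1" = c("AKT1", "BAD", "BCL2", "CASP3", "CASP8", "FAS",
                           "FOS", "IFNG", "IL2", "IL4", "JUN", "MAPK1",
                           "MAPK3", "MAPK9", "NFKBIA", "OCLN", "PIK3R1",
                           "ROCK1", "TJP1", "TNF", "TNFRSF1A"),
  "salicylate" = c("AKT1", "EGF", "ICAM1", "IFNG", "IL4", "MAPK1", "MAPK3",
                   "NFKBIA", "TGFB1", "VCAM1"))

.RG_PATHWAY_GENES <- list(
  "Vascular Endothelial Cell Activation by Growth Factors" =
    c("PLCG1", "NFKBIA", "MAPK3", "MAPK1", "VCAM1", "EGF", "TGFB1", "AKT1",
      "ICAM1", "PTGS2", "NOS3"),
  "Natural Killer Cell Activation through ITAM-Containing Receptors" =
    c("FAS", "BAD", "BCL2", "PIK3R1", "AKT1", "CASP3", "TNF", "TNFRSF1A",
      "CASP8", "PLCG1"),
  "Peripheral T-Cell Tolerance: Overview" =
    c("FAS", "BAD", "BCL2", "PIK3R1", "AKT1", "CASP3", "TNF", "TNFRSF1A",
      "CASP8", "PLCG1"),
  "T-Cell Receptor Signaling" =
    c("MAPK9", "PLCG1", "NFKBIA", "IFNG", "IL4", "IL2", "MAPK3", "MAPK1",
      "AKT1"),
  "Th1-Cell Differentiation" =
    c("MAPK9", "PLCG1", "NFKBIA", "IFNG", "MAPK3", "MAPK1", "IRAK1", "IRAK4",
      "AKT1"),
  "Vascular Endothelial Cell Permeability Activation" =
    c("NFKBIA", "NOS3", "ROCK1", "MYL9", "TJP1", "MYLK", "OCLN", "AKT1",
      "PLCG1"),
  "Th17-Cell Differentiation" =
    c("PLCG1", "NFKBIA", "IL1B", "IL6", "IRAK1", "IRAK4", "TGFB1", "AKT1"),
  "T-Cell Central Tolerance" = c("PLCG1", "MAPK8", "AKT1", "BAD", "BCL2"),
  "GFs/TNF Ion Channels" = c("PLCG1", "NGF", "APP", "TNF"))

.RG_PHENOTYPES <- c("menopausal symptoms", "blood circulation",
                    "hyperlipidemia", "diabetes mellitus")

.RG_HERB <- "red ginseng"

## Reported per-phenotype top-10 target rankings; an expected-output table for
## documentation tests, not recomputed (its derivation needs the full upstream
## association graph).
.RG_TABLE1 <- data.frame(
  rank = 1:10,
  `menopausal symptoms` = c("TNF", "AKT1", "FOS", "JUN", "MAPK1", "MAPK3",
                            "NFKBIA", "CREB1", "IL6", "IRAK1"),
  `blood circulation` = c("MAPK1", "TNF", "MAPK3", "NFKBIA", "IL6", "AKT1",
                          "FOS", "TGFB1", "ROCK1", "BCL2"),
  `hyperlipidemia` = c("PLCG1", "IRAK4", "MAPK9", NA, NA, NA, NA, NA, NA, NA),
  `diabetes mellitus` = c("PLCG1", "IRAK4", "MAPK9", NA, NA, NA, NA, NA, NA, NA),
  check.names = FALSE)

#' The packaged red-ginseng component-target-pathway fixture
#'
#' Builds the desk-scale red-ginseng dataset bundled with the package: one
#' HERB node, the 5 signature components (ginsenoside Rg1, Rb1, Re,
#' notoginsenoside R1, salicylate) with their printed target-gene lists
#' (37 unique targets), the 9 red-ginseng-only signalling pathways with their
#' printed member lists, and the 4 clinical phenotypes (menopausal symptoms,
#' blood circulation, hyperlipidemia, diabetes mellitus). Edges: herb to each
#' component, component to each listed target, target to each pathway whose
#' printed list contains it, and -- since no per-phenotype target lists are
#' printed beyond the top-10 ranking -- every target to every phenotype.
#'
#' @return list with elements
#'   \describe{
#'     \item{graph}{the [LayeredGraph-class] described above;}
#'     \item{pathways}{a [PathwayCollection-class] of the 9 pathway gene sets;}
#'     \item{componentTargets}{named list: component label -> gene vector;}
#'     \item{phenotypes}{character vector of the 4 phenotype labels;}
#'     \item{herb}{the herb label;}
#'     \item{table1}{data.frame of the reported per-phenotype top-10 target
#'       rankings (an expected-output reference, not derived from the graph).}
#'   }
#' @examples
#' fx <- redGinsengFixture()
#' fx$graph
#' length(unique(unlist(fx$componentTargets)))  # 37 targets
#' @export
redGinsengFixture <- function() {
  comp <- names(.RG_COMPONENT_TARGETS)
  targets <- sort(unique(unlist(.RG_COMPONENT_TARGETS, use.names = FALSE)))
  ct <- data.frame(
    from = nodeId("COMPONENT", rep(comp, lengths(.RG_COMPONENT_TARGETS))),
    to = nodeId("TARGET", unlist(.RG_COMPONENT_TARGETS, use.names = FALSE)))
  tp <- data.frame(
    from = nodeId("TARGET",
                  unlist(.RG_PATHWAY_GENES, use.names = FALSE)),
    to = nodeId("PATHWAY",
                rep(names(.RG_PATHWAY_GENES), lengths(.RG_PATHWAY_GENES))))
  hc <- data.frame(from = nodeId("HERB", .RG_HERB),
                   to = nodeId("COMPONENT", comp))
  tph <- expand.grid(t = targets, p = .RG_PHENOTYPES,
                     stringsAsFactors = FALSE)
  tphen <- data.frame(from = nodeId("TARGET", tph$t),
                      to = nodeId("PHENOTYPE", tph$p))
  graph <- LayeredGraph(edges = rbind(hc, ct, tp, tphen))
  list(graph = graph,
       pathways = PathwayCollection(.RG_PATHWAY_GENES),
       componentTargets = .RG_COMPONENT_TARGETS,
       phenotypes = .RG_PHENOTYPES,
       herb = .RG_HERB,
       table1 = .RG_TABLE1)
}

#' Export the fixture as TSV + GMT files
#'
#' Writes the fixture in the package's on-disk dialect so it can be run like
#' any user dataset: `edges.tsv` (label, label, `"SRC>TGT"` layer column),
#' `pathways.gmt`, and `table1.tsv`.
#'
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
exportFixture <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- redGinsengFixture()
  e <- graphEdges(fx$graph)
  n <- graphNodes(fx$graph)
  layer <- setNames(n$layer, n$id)
  label <- setNames(n$label, n$id)
  lines <- paste(label[e$from], label[e$to],
                 paste0(layer[e$from], ">", layer[e$to]), sep = "\t")
  writeLines(lines, file.path(dir, "edges.tsv"))
  writeGMT(fx$pathways, file.path(dir, "pathways.gmt"),
           descriptions = "red-ginseng-only pathway")
  write.table(fx$table1, file.path(dir, "table1.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
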