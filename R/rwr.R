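## Random walk with restart on the layered graph. The propagation is the
## row-vector recursion F_{t+1} = alpha * F_t A + (1 - alpha) * F0 with A the
## row-normalized, direction-blind connectivity matrix, stopped when the L1
## difference of successive iterates falls below a threshold. A direct linear
## solve of the fixed point serves as an exact oracle.

#' Row-normalized connectivity matrix of a layered graph
#'
#' Edges are counted in both directions (connectivity, not flow direction);
#' isolated nodes receive a unit self-loop so that every row of the result
#' sums to 1 and the walk conserves probability mass.
#'
#' @param g a nonempty [LayeredGraph-class].
#' @return square row-stochastic matrix with node ids as dimnames.
#' @export
normalizeAdjacency <- function(g) {
  stopifnot(is(g, "LayeredGraph"))
  ids <- graphNodes(g)$id
  if (!length(ids))
    stop("cannot normalize an empty graph")
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  e <- graphEdges(g)
  if (nrow(e)) {
    A[cbind(e$from, e$to)] <- 1
    A[cbind(e$to, e$from)] <- 1
  }
  rs <- rowSums(A)
  iso <- rs == 0
  if (any(iso)) {
    diag(A)[iso] <- 1
    rs[iso] <- 1
  }
  A / rs
}

.checkStochastic <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (any(A < 0) || max(abs(rowSums(A) - 1)) > 1e-8)
    stop("'A' must be a row-stochastic (row sums 1, nonnegative) matrix")
}

.asRestart <- function(F0, A) {
  if (!is.null(names(F0)) && !is.null(rownames(A)))
    F0 <- F0[rownames(A)]
  F0 <- as.numeric(F0)
  if (length(F0) != nrow(A))
    stop("restart vector length does not match the matrix")
  if (any(F0 < 0) || sum(F0) <= 0)
    stop("restart vector must be nonnegative with nonempty support")
  F0 / sum(F0)
}

#' Iterative random walk with restart
#'
#' Iterates `F_{t+1} = alpha * F_t %*% A + (1 - alpha) * F0` from `F0` until
#' the L1 norm of `F_{t+1} - F_t` drops below `threshold`. Convergence is
#' geometric: the residual after t steps is at most `2 * alpha^t`, so any
#' `alpha < 1` converges.
#'
#' @param A row-stochastic connectivity matrix, see [normalizeAdjacency()].
#' @param F0 restart vector (normalized internally to sum 1); names, if
#'   present, are matched against `rownames(A)`.
#' @param alpha rate control factor in `[0, 1)`: the proportion of signal
#'   passed along edges each step (`1 - alpha` restarts at `F0`).
#' @param threshold L1 convergence bound.
#' @param maxIter iteration cap; exceeding it raises a non-convergence error
#'   (condition class `herbnet_nonconvergence`) carrying the last residual.
#' @return an [RWResult-class].
#' @examples
#' g <- LayeredGraph(edges = data.frame(
#'   from = nodeId("COMPONENT", "c1"), to = nodeId("TARGET", c("t1", "t2"))))
#' A <- normalizeAdjacency(g)
#' rwr(A, c(1, 0, 0), alpha = 0.5)
#' @export
rwr <- function(A, F0, alpha = 0.7, threshold = 1e-6, maxIter = 10000L) {
  .checkStochastic(A)
  if (alpha < 0 || alpha >= 1)
    stop("'alpha' must be in [0, 1)")
  if (threshold <= 0)
    stop("'threshold' must be positive")
  F0 <- .asRestart(F0, A)
  Ft <- F0
  for (t in seq_len(maxIter)) {
    Fn <- as.numeric(alpha * (Ft %*% A) + (1 - alpha) * F0)
    res <- sum(abs(Fn - Ft))
    if (res < threshold) {
      return(new("RWResult",
                 scores = setNames(Fn, rownames(A)),
                 iterations = as.integer(t), residual = res,
                 alpha = as.numeric(alpha),
                 threshold = as.numeric(threshold)))
    }
    Ft <- Fn
  }
  cond <- structure(
    class = c("herbnet_nonconvergence", "error", "condition"),
    list(message = sprintf(
           "random walk did not converge in %d iterations (last L1 residual %.3g >= %g)",
           maxIter, res, threshold),
         call = sys.call(), residual = res, iterations = maxIter))
  stop(cond)
}

#' Closed-form fixed point of the restart walk
#'
#' Solves `F (I - alpha * A) = (1 - alpha) * F0` directly. The system is
#' nonsingular for any `alpha < 1` (the spectral radius of `alpha * A` is at
#' most `alpha`), which is asserted. Used as the exact oracle for [rwr()].
#'
#' @inheritParams rwr
#' @return named numeric score vector summing to 1.
#' @export
rwrClosedForm <- function(A, F0, alpha = 0.7) {
  .checkStochastic(A)
  if (alpha < 0 || alpha >= 1)
    stop("'alpha' must be in [0, 1)")
  F0 <- .asRestart(F0, A)
  n <- nrow(A)
  M <- diag(n) - alpha * A
  stopifnot(abs(det(M)) > 0)
  Fv <- as.numeric(solve(t(M), (1 - alpha) * F0))
  setNames(Fv, rownames(A))
}

#' Phenotype association scores by random walk with restart
#'
#' Runs the restart walk from a uniform restart vector over the
#' component-associated start targets and reports, for every PHENOTYPE and
#' BIOPROCESS node, the raw converged score and a normalized score: the raw
#' score divided by the score the same node receives under a
#' degree-proportional restart vector (a standard correction for
#' hub bias; isolated nodes get baseline weight 1, matching their self-loop).
#'
#' @param g a [LayeredGraph-class].
#' @param startNodes character vector of start nodes: node ids or bare TARGET
#'   labels (gene symbols).
#' @inheritParams rwr
#' @return data.frame with columns `node` (id), `label`, `layer`, `raw`,
#'   `baseline`, `normalized`, sorted by `normalized` descending (ties by
#'   label).
#' @examples
#' fx <- redGinsengFixture()
#' head(phenotypeScores(fx$graph, c("AKT1", "TNF")))
#' @export
phenotypeScores <- function(g, startNodes, alpha = 0.7, threshold = 1e-6,
                            maxIter = 10000L) {
  stopifnot(is(g, "LayeredGraph"))
  if (!length(startNodes))
    stop("'startNodes' must be nonempty")
  ids <- graphNodes(g)$id
  resolved <- ifelse(startNodes %in% ids, startNodes,
                     nodeId("TARGET", startNodes))
  miss <- setdiff(resolved, ids)
  if (length(miss))
    stop("start node(s) not in graph: ", paste(miss, collapse = ", "))
  resolved <- unique(resolved)
  A <- normalizeAdjacency(g)
  F0 <- setNames(as.numeric(rownames(A) %in% resolved), rownames(A))
  fit <- rwr(A, F0, alpha = alpha, threshold = threshold, maxIter = maxIter)
  deg <- nodeDegree(g)[rownames(A)]
  base0 <- pmax(as.numeric(deg), 1)
  base <- rwr(A, setNames(base0, rownames(A)), alpha = alpha,
              threshold = threshold, maxIter = maxIter)
  n <- graphNodes(g)
  keep <- n$layer %in% c("PHENOTYPE", "BIOPROCESS")
  out <- data.frame(node = n$id[keep], label = n$label[keep],
                    layer = n$layer[keep])
  out$raw <- rwScores(fit)[out$node]
  out$baseline <- rwScores(base)[out$node]
  out$normalized <- out$raw / out$baseline
  out <- out[order(-out$normalized, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}
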