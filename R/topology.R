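#' Sparsity grid for proportional thresholding
#'
#' Thresholds `t_k = sMin + k * step` for all `k` with `t_k <= sMax`. The
#' defaults (0.2667 to 0.50 in steps of 0.01) give 24 thresholds,
#' 0.2667 ... 0.4967; the lower bound is the minimum sparsity keeping every
#' participant's network connected and the upper bound avoids excessive
#' density.
#'
#' @param sMin,sMax sparsity range.
#' @param step sparsity increment.
#' @return numeric vector of thresholds.
#' @examples
#' length(sparsityGrid()) # 24
#' @export
sparsityGrid <- function(sMin = 0.2667, sMax = 0.50, step = 0.01) {
  if (!(sMin > 0 && sMin <= sMax && step > 0))
    stop("need 0 < sMin <= sMax and step > 0", call. = FALSE)
  k <- 0:floor((sMax - sMin) / step + 1e-9)
  sMin + k * step
}

# Upper-triangle edge list of an n-node graph in lexicographic (i, j)
# order; the fixed tie-break order for proportional thresholding.
.edgeTable <- function(n) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# Rank edges of an FcMatrix: strongest z first, ties in lexicographic
# (i, j) order. Returns the edge table with a weight column.
.rankedEdges <- function(z) {
  n <- nrow(z)
  et <- .edgeTable(n)
  w <- z[cbind(et[, 1], et[, 2])]
  ord <- order(-w, et[, 1], et[, 2])
  cbind(et[ord, , drop = FALSE], w = w[ord])
}

.adjFromEdges <- function(n, edges) {
  a <- matrix(0L, n, n)
  if (nrow(edges)) {
    a[edges[, 1:2, drop = FALSE]] <- 1L
    a[edges[, 2:1, drop = FALSE]] <- 1L
  }
  a
}

.isConnectedAdj <- function(a) {
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  igraph::is_connected(g)
}

.asIntAdj <- function(adj) {
  storage.mode(adj) <- "integer"
  adj
}

#' Minimum sparsity keeping all networks connected
#'
#' For each supplied connectivity matrix, finds the smallest number K of
#' strongest edges whose graph is connected, then returns the maximum over
#' matrices of K / (number of possible edges). This is the group-level
#' lower bound of the sparsity sweep: every participant's network is
#' connected at and above it.
#'
#' @param fcList a single [FcMatrix-class] or a list of them.
#' @return the minimum connected sparsity (scalar in (0, 1]).
#' @export
minConnectedSparsity <- function(fcList) {
  if (is(fcList, "FcMatrix")) fcList <- list(fcList)
  if (!length(fcList)) stop("empty matrix list", call. = FALSE)
  kmax <- 0L
  for (i in seq_along(fcList)) {
    z <- as.matrix(fcList[[i]])
    n <- nrow(z)
    ranked <- .rankedEdges(z)
    npos <- sum(ranked[, "w"] > 0)
    connected <- FALSE
    if (npos < n - 1)
      stop(
        "matrix ", i,
        " cannot be connected from its positive edges", call. = FALSE
      )
    for (k in (n - 1):npos) {
      a <- .adjFromEdges(n, ranked[seq_len(k), , drop = FALSE])
      if (.isConnectedAdj(a)) {
        kmax <- max(kmax, k)
        connected <- TRUE
        break
      }
    }
    if (!connected)
      stop(
        "matrix ", i,
        " cannot be connected from its positive edges", call. = FALSE
      )
  }
  nEdges <- nrow(as.matrix(fcList[[1]]))
  kmax / (nEdges * (nEdges - 1) / 2)
}

#' Proportional thresholding to a binary graph
#'
#' Keeps the `K = floor(sparsity * E + 0.5)` strongest edges of the
#' Fisher-z matrix (E the number of possible edges; half-up rounding), with
#' ties at the cutoff broken by fixed lexicographic node-pair order so the
#' edge set is deterministic and nested across thresholds.
#'
#' @param fc an [FcMatrix-class].
#' @param sparsity fraction of edges to keep, in (0, 1].
#' @return binary symmetric adjacency matrix with zero diagonal.
#' @export
thresholdProportional <- function(fc, sparsity) {
  stopifnot(is(fc, "FcMatrix"))
  if (!(sparsity > 0 && sparsity <= 1))
    stop("sparsity must be in (0, 1]", call. = FALSE)
  z <- as.matrix(fc)
  n <- nrow(z)
  ee <- n * (n - 1) / 2
  k <- floor(sparsity * ee + 0.5)
  ranked <- .rankedEdges(z)
  if (sum(ranked[, "w"] > 0) < k)
    stop("fewer than ", k, " positive edges available", call. = FALSE)
  a <- .adjFromEdges(n, ranked[seq_len(k), , drop = FALSE])
  dimnames(a) <- dimnames(z)
  a
}

#' All-pairs shortest path lengths of a binary graph
#'
#' Unweighted breadth-first-search distances; unreachable pairs are
#' `Inf`.
#'
#' @param adj binary symmetric adjacency matrix.
#' @return numeric distance matrix.
#' @export
shortestPathLengths <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::distances(g)
}

#' Global efficiency
#'
#' `Eg = mean over ordered pairs (i != j) of 1 / d_ij`, with unreachable
#' pairs contributing 0. Equals 1 for a complete graph.
#'
#' @param adj binary symmetric adjacency matrix.
#' @return scalar in \[0, 1\].
#' @export
globalEfficiency <- function(adj) {
  if (nrow(adj) < 2) return(0)
  .cppGraphMetrics(.asIntAdj(adj))$eg
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of each node's neighbourhood
#' subgraph; nodes with fewer than two neighbours contribute 0.
#'
#' @param adj binary symmetric adjacency matrix.
#' @return scalar in \[0, 1\].
#' @export
localEfficiency <- function(adj) {
  .cppGraphMetrics(.asIntAdj(adj))$eloc
}

#' Nodal efficiency
#'
#' `Ne_i = mean over j != i of 1 / d_ij`; the communication efficiency of
#' one node with the rest of the network. An isolated node scores 0; a star
#' hub scores 1.
#'
#' @param adj binary symmetric adjacency matrix.
#' @param node optional node index; default returns all nodes.
#' @return numeric vector (or scalar if `node` given).
#' @export
nodalEfficiency <- function(adj, node = NULL) {
  ne <- .cppGraphMetrics(.asIntAdj(adj))$ne
  names(ne) <- rownames(adj)
  if (is.null(node)) ne else ne[[node]]
}

#' Mean clustering coefficient and characteristic path length
#'
#' `C` is the mean over nodes of the binary local clustering coefficient
#' (triangles through the node over possible neighbour pairs; degree < 2
#' scores 0). `L` is the mean shortest path length over connected ordered
#' pairs.
#'
#' @param adj binary symmetric adjacency matrix.
#' @return named numeric vector `c(C, L)`.
#' @export
clusteringAndPathLength <- function(adj) {
  m <- .cppGraphMetrics(.asIntAdj(adj))
  if (!is.finite(m$l)) stop("graph has no connected pair", call. = FALSE)
  c(C = m$c, L = m$l)
}

#' Degree-preserving rewiring (null network)
#'
#' Randomizes a binary graph by repeated double-edge swaps that reject
#' self-loops and multi-edges, preserving every node's degree exactly. If
#' the result is disconnected it is redrawn with a derived seed, up to
#' `retryCap` attempts (keeping path lengths finite in the null ensemble).
#'
#' @param adj binary symmetric adjacency matrix.
#' @param nSwaps number of attempted swaps; default 10x the edge count.
#' @param seed integer seed.
#' @param requireConnected redraw until connected (default `TRUE`).
#' @param retryCap maximum redraws (default 100).
#' @return binary adjacency matrix with the same degree sequence.
#' @export
rewireDegreePreserving <- function(adj, nSwaps = NULL, seed = 1,
                                   requireConnected = TRUE, retryCap = 100) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  gr <- .rewireGraph(g, nSwaps, seed, requireConnected, retryCap)
  a <- as.matrix(igraph::as_adjacency_matrix(gr, sparse = FALSE))
  storage.mode(a) <- "integer"
  dimnames(a) <- dimnames(adj)
  a
}

# igraph-level double-edge-swap null, redrawn until connected.
.rewireGraph <- function(g, nSwaps = NULL, seed = 1,
                         requireConnected = TRUE, retryCap = 100) {
  ne <- igraph::ecount(g)
  if (ne < 2) stop("need at least 2 edges to rewire", call. = FALSE)
  if (is.null(nSwaps)) nSwaps <- 10 * ne
  for (attempt in 0:retryCap) {
    gr <- withSeed(
      deriveSeed(seed, attempt),
      igraph::rewire(g, igraph::keeping_degseq(niter = nSwaps))
    )
    if (!requireConnected || igraph::is_connected(gr)) return(gr)
  }
  stop("could not draw a connected degree-preserving null within ",
    retryCap, " retries",
    call. = FALSE
  )
}

#' Small-worldness against a degree-preserving null ensemble
#'
#' `sigma = (C / <C_rand>) / (L / <L_rand>)` where the angle brackets are
#' ensemble means over `nRand` degree-preserving rewired null networks
#' (double-edge swaps rejecting self-loops and multi-edges; disconnected
#' draws are redrawn). Values above 1 indicate small-world organization
#' (clustering higher than random at comparable path length). For a
#' complete graph every null is identical and sigma is exactly 1.
#'
#' @param adj binary symmetric adjacency matrix of a connected graph.
#' @param nRand number of null networks (default 1000).
#' @param seed integer seed for the null ensemble.
#' @return scalar sigma.
#' @export
smallWorldness <- function(adj, nRand = 1000, seed = 1) {
  if (!.isConnectedAdj(adj))
    stop("graph must be connected for small-worldness", call. = FALSE)
  cl <- clusteringAndPathLength(adj)
  am <- adj
  storage.mode(am) <- "integer"
  ens <- withSeed(seed, .cppNullEnsembleCL(am, as.integer(nRand), 10L, 100L))
  if (mean(ens[, 1]) == 0)
    stop("degenerate null ensemble: mean clustering is 0", call. = FALSE)
  (cl[["C"]] / mean(ens[, 1])) / (cl[["L"]] / mean(ens[, 2]))
}

#' Area under a metric curve over the sparsity grid
#'
#' Threshold-free summary: the sum of the metric across thresholds
#' multiplied by the sparsity increment.
#'
#' @param values metric value per threshold.
#' @param step sparsity increment (default 0.01).
#' @return scalar AUC.
#' @export
metricAuc <- function(values, step = 0.01) {
  if (!length(values)) stop("empty metric curve", call. = FALSE)
  step * sum(values)
}

#' Graph metrics over the sparsity sweep, aggregated as AUC
#'
#' Thresholds the connectivity matrix at every sparsity in the grid,
#' computes global efficiency, local efficiency, small-worldness and
#' per-ROI nodal efficiency on each binary graph, and aggregates each
#' metric across thresholds as area under the curve.
#'
#' @param fc an [FcMatrix-class]; must yield a connected graph at every
#'   threshold (see [minConnectedSparsity()]).
#' @param grid sparsity thresholds from [sparsityGrid()].
#' @param nRand null networks per threshold for sigma (default 1000).
#' @param seed integer seed for the null ensembles.
#' @param keepCurves also return the per-threshold curves (default
#'   `FALSE`).
#' @return list of class `AucMetricSet` with elements `sigmaAuc`, `egAuc`,
#'   `elocAuc`, `neAuc` (named per ROI), `gridWidth`, and optionally
#'   `curves` (data.frame).
#' @export
networkMetrics <- function(fc, grid = sparsityGrid(), nRand = 1000,
                           seed = 1, keepCurves = FALSE) {
  stopifnot(is(fc, "FcMatrix"))
  step <- if (length(grid) > 1) grid[2] - grid[1] else 0.01
  nroi <- nrow(as.matrix(fc))
  eg <- numeric(length(grid))
  eloc <- numeric(length(grid))
  sig <- numeric(length(grid))
  ne <- matrix(0, length(grid), nroi)
  for (k in seq_along(grid)) {
    adj <- thresholdProportional(fc, grid[k])
    if (!.isConnectedAdj(adj))
      stop(
        "graph disconnected at sparsity ", grid[k],
        "; raise the grid minimum (see minConnectedSparsity)",
        call. = FALSE
      )
    eg[k] <- globalEfficiency(adj)
    eloc[k] <- localEfficiency(adj)
    ne[k, ] <- nodalEfficiency(adj)
    sig[k] <- smallWorldness(adj, nRand = nRand, seed = deriveSeed(seed, k))
  }
  neAuc <- apply(ne, 2, metricAuc, step = step)
  names(neAuc) <- rownames(as.matrix(fc))
  out <- list(
    sigmaAuc = metricAuc(sig, step),
    egAuc = metricAuc(eg, step),
    elocAuc = metricAuc(eloc, step),
    neAuc = neAuc,
    gridWidth = step * length(grid)
  )
  if (keepCurves) {
    out$curves <- data.frame(
      sparsity = grid, sigma = sig, eg = eg, eloc = eloc
    )
  }
  class(out) <- "AucMetricSet"
  out
}

#' @export
print.AucMetricSet <- function(x, ...) {
  cat(sprintf(
    "AucMetricSet (grid width %.2f)\n  sigma AUC %.4f | Eg AUC %.4f | Eloc AUC %.4f\n",
    x$gridWidth, x$sigmaAuc, x$egAuc, x$elocAuc
  ))
  cat("  nodal efficiency AUC:\n")
  print(round(x$neAuc, 4))
  invisible(x)
}
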