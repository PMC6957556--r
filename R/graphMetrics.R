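# Weighted graph measures on coherence matrices.
#
# The analysis is fully weighted: no thresholding or binarization is
# applied, so every measure is computed on the complete coherence matrix.
# Path lengths use edge length = 1/weight (option: -log(weight));
# clustering uses the Onnela geometric-mean-of-triangles formulation with
# weights normalized by the maximum off-diagonal weight, which reduces to
# the classic proportion-of-triangles definition on binary graphs.

asWeightMatrix <- function(matrix) {
  W <- if (is(matrix, "CoherenceMatrix")) cohValues(matrix) else as.matrix(matrix)
  stopIfNot(nrow(W) == ncol(W), "weight matrix must be square")
  stopIfNot(all(is.finite(W)), "weight matrix must be finite")
  if (min(W) < 0) stop("negative weights are not admissible")
  diag(W) <- 0  # unit diagonal ignored
  W
}

#' Global efficiency of a weighted network
#'
#' Mean over ordered node pairs of the inverse shortest weighted path
#' length, the standard integration measure: the inverse of the (harmonic)
#' average path length. Edge lengths are `1/weight` (or `-log(weight)`);
#' disconnected pairs contribute zero.
#'
#' @param matrix A [CoherenceMatrix-class] or symmetric nonnegative weight
#'   matrix (diagonal ignored).
#' @param lengthTransform Map from weight to edge length.
#' @return Scalar efficiency (equals the mean weight for a complete graph
#'   whose direct edges are the shortest paths).
#' @examples
#' globalEfficiency(matrix(1, 3, 3))  # 1
#' @export
globalEfficiency <- function(matrix, lengthTransform = c("inverse", "neglog")) {
  lengthTransform <- match.arg(lengthTransform)
  W <- asWeightMatrix(matrix)
  n <- nrow(W)
  stopIfNot(n >= 2, "need at least two nodes")
  D <- shortestPathLengths(W, lengthTransform)
  inv <- 1 / D[upper.tri(D)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

shortestPathLengths <- function(W, lengthTransform) {
  L <- W
  pos <- W > 0
  L[pos] <- switch(lengthTransform,
                   inverse = 1 / W[pos],
                   neglog = -log(W[pos] / max(W[pos])))
  L[!pos] <- 0
  g <- igraph::graph_from_adjacency_matrix(L, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::distances(g, algorithm = "dijkstra")
}

#' Weighted clustering coefficient
#'
#' Per-node clustering by the geometric mean of triangle weights
#' (normalized by the maximum off-diagonal weight) over the number of
#' neighbor pairs; the network mean (Gcc) summarizes segregation. On
#' binary graphs this is the proportion of realized edges among each
#' node's neighbors.
#'
#' @inheritParams globalEfficiency
#' @return List with `perNode` (numeric vector) and `mean` (Gcc). Nodes
#'   with fewer than two neighbors have clustering 0.
#' @examples
#' clusteringCoefficient(matrix(1, 3, 3))$mean  # 1
#' @export
clusteringCoefficient <- function(matrix) {
  W <- asWeightMatrix(matrix)
  n <- nrow(W)
  if (n < 3) stop("clustering is undefined for fewer than 3 nodes")
  mx <- max(W)
  if (mx == 0) {
    per <- rep(0, n)
  } else {
    Wn <- (W / mx)^(1 / 3)
    cyc <- diag(Wn %*% Wn %*% Wn)      # 2 * sum of triangle geometric means
    k <- rowSums(W > 0)                # binary degree
    per <- ifelse(k > 1, cyc / (k * (k - 1)), 0)
  }
  names(per) <- rownames(W)
  list(perNode = per, mean = mean(per))
}

#' Efficiency and clustering of one subnetwork
#'
#' Both measures computed on the induced subgraph restricted to the nodes
#' of the requested resting-state network: within-network edges only,
#' paths may not route through out-of-network nodes.
#'
#' @param matrix A [CoherenceMatrix-class] or weight matrix with node ids.
#' @param partition A [NetworkPartition-class] over the matrix's nodes.
#' @param label One of `"DMN"`, `"FPN"`, `"DAN"`, `"VAN"`.
#' @param lengthTransform Passed to [globalEfficiency()].
#' @return Named numeric vector `c(efficiency = , clustering = )`.
#' @export
subnetworkMetrics <- function(matrix, partition, label,
                              lengthTransform = c("inverse", "neglog")) {
  stopIfNot(label %in% RSN_NAMES,
            paste("unknown subnetwork label:", label))
  ids <- if (is(matrix, "CoherenceMatrix")) nodeIds(matrix) else rownames(matrix)
  labs <- partitionLabels(partition)[ids]
  stopIfNot(!anyNA(labs), "partition does not cover every matrix node")
  member <- which(labs == label)
  stopIfNot(length(member) >= 3,
            paste("subnetwork", label, "has fewer than 3 nodes"))
  W <- asWeightMatrix(matrix)[member, member, drop = FALSE]
  c(efficiency = globalEfficiency(W, lengthTransform),
    clustering = clusteringCoefficient(W)$mean)
}

blockIndices <- function(matrix, partition) {
  ids <- if (is(matrix, "CoherenceMatrix")) nodeIds(matrix) else rownames(matrix)
  labs <- partitionLabels(partition)[ids]
  stopIfNot(!anyNA(labs), "partition does not cover every matrix node")
  lapply(stats::setNames(RSN_NAMES, RSN_NAMES), function(l) which(labs == l))
}

#' Mean connectivity between and within subnetworks
#'
#' `betweenNetworkFC` averages matrix entries over all cross-network node
#' pairs for each of the six unordered RSN pairs; `withinNetworkFC`
#' averages over the distinct within-network pairs (diagonal excluded).
#'
#' @inheritParams subnetworkMetrics
#' @return Named numeric vector: six values `"DMN-FPN"`, ... for between;
#'   four values `"DMN"`, ... for within.
#' @export
betweenNetworkFC <- function(matrix, partition) {
  W <- if (is(matrix, "CoherenceMatrix")) cohValues(matrix) else as.matrix(matrix)
  idx <- blockIndices(matrix, partition)
  pairs <- utils::combn(RSN_NAMES, 2)
  out <- apply(pairs, 2, function(p) {
    a <- idx[[p[1]]]; b <- idx[[p[2]]]
    stopIfNot(length(a) > 0 && length(b) > 0,
              paste("empty block:", p[1], "or", p[2]))
    mean(W[a, b])
  })
  stats::setNames(out, apply(pairs, 2, paste, collapse = "-"))
}

#' @rdname betweenNetworkFC
#' @export
withinNetworkFC <- function(matrix, partition) {
  W <- if (is(matrix, "CoherenceMatrix")) cohValues(matrix) else as.matrix(matrix)
  idx <- blockIndices(matrix, partition)
  vapply(idx, function(a) {
    stopIfNot(length(a) >= 2, "within-network block needs >= 2 nodes")
    B <- W[a, a]
    mean(B[upper.tri(B)])
  }, numeric(1))
}

#' All topology measures for one subject
#'
#' One row of the analysis table: global efficiency (GE), global
#' clustering (Gcc), per-RSN efficiency and clustering, within-network and
#' the six between-network mean FC values.
#'
#' @inheritParams subnetworkMetrics
#' @return One-row data frame with columns `GE`, `Gcc`, `eff_<RSN>`,
#'   `clust_<RSN>`, `within_<RSN>`, `between_<A>_<B>`.
#' @export
topologyMetrics <- function(matrix, partition,
                            lengthTransform = c("inverse", "neglog")) {
  lengthTransform <- match.arg(lengthTransform)
  sub <- lapply(stats::setNames(RSN_NAMES, RSN_NAMES), function(l)
    subnetworkMetrics(matrix, partition, l, lengthTransform))
  btw <- betweenNetworkFC(matrix, partition)
  wth <- withinNetworkFC(matrix, partition)
  out <- data.frame(GE = globalEfficiency(matrix, lengthTransform),
                    Gcc = clusteringCoefficient(matrix)$mean)
  for (l in RSN_NAMES) {
    out[[paste0("eff_", l)]] <- sub[[l]]["efficiency"]
    out[[paste0("clust_", l)]] <- sub[[l]]["clustering"]
  }
  for (l in RSN_NAMES) out[[paste0("within_", l)]] <- wth[[l]]
  for (nm in names(btw))
    out[[paste0("between_", gsub("-", "_", nm))]] <- btw[[nm]]
  stopifnot(sum(grepl("^between_", names(out))) == 6L)
  rownames(out) <- NULL
  out
}
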