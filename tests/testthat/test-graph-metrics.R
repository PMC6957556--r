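# Weighted efficiency, clustering, subnetwork and block-mean measures.

test_that("efficiency and clustering reduce correctly on canonical graphs", {
  expect_equal(globalEfficiency(matrix(1, 3, 3)), 1)
  # two nodes joined by weight w: E = w
  W2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  expect_equal(globalEfficiency(W2), 0.4)
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  cc <- clusteringCoefficient(tri)
  expect_equal(unname(cc$perNode), rep(1, 3))
  expect_equal(cc$mean, 1)
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(clusteringCoefficient(star)$mean, 0)
  expect_error(globalEfficiency(matrix(c(0, -1, -1, 0), 2)), "negative")
  expect_error(clusteringCoefficient(matrix(0, 2, 2)), "fewer than 3")
})

test_that("weighted measures match brute-force oracles on random graphs", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    W <- randomWeightedGraph(n, density = runif(1, 0.4, 1))
    expect_equal(globalEfficiency(W), oracleEfficiency(W), tolerance = 1e-12)
    cc <- clusteringCoefficient(W)
    expect_equal(unname(cc$perNode), oracleClustering(W), tolerance = 1e-12)
  }
})

test_that("binary graphs recover the textbook unweighted definitions", {
  set.seed(7)
  A <- randomWeightedGraph(9, density = 0.5)
  A[A > 0] <- 1
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  ours <- clusteringCoefficient(A)$perNode
  ref <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  expect_equal(unname(ours), ref, tolerance = 1e-12)
  # unweighted efficiency: hop-count shortest paths
  Dh <- igraph::distances(g)
  invh <- 1 / Dh[upper.tri(Dh)]
  invh[!is.finite(invh)] <- 0
  expect_equal(globalEfficiency(A), mean(invh), tolerance = 1e-12)
})

test_that("measures are permutation invariant and efficiency is monotone in weights", {
  set.seed(15)
  W <- randomWeightedGraph(8)
  p <- sample(8)
  expect_equal(globalEfficiency(W[p, p]), globalEfficiency(W))
  expect_equal(clusteringCoefficient(W[p, p])$mean,
               clusteringCoefficient(W)$mean)
  for (k in 1:5) {
    W2 <- W
    ij <- sample(8, 2)
    W2[ij[1], ij[2]] <- W2[ij[2], ij[1]] <- min(1, W[ij[1], ij[2]] + 0.3)
    expect_gte(globalEfficiency(W2), globalEfficiency(W))
  }
})

test_that("subnetwork metrics equal global metrics on the extracted submatrix", {
  set.seed(22)
  n <- 14
  ids <- paste0("n", 1:n)
  labels <- rep(c("DMN", "FPN", "DAN", "VAN", "other"), c(4, 3, 3, 3, 1))
  part <- networkPartition(ids, labels)
  W <- randomWeightedGraph(n)
  dimnames(W) <- list(ids, ids)
  for (lab in c("DMN", "FPN", "DAN", "VAN")) {
    sub <- subnetworkMetrics(W, part, lab)
    member <- ids[labels == lab]
    Wm <- W[member, member]
    expect_equal(unname(sub["efficiency"]), oracleEfficiency(Wm))
    expect_equal(unname(sub["clustering"]), mean(oracleClustering(Wm)))
  }
  # clique subnetwork: (1, 1)
  Wc <- W
  Wc[1:4, 1:4] <- 1; diag(Wc) <- 0
  expect_equal(unname(subnetworkMetrics(Wc, part, "DMN")),
               c(1, 1))
  expect_error(subnetworkMetrics(W, part, "SMN"), "unknown")
})

test_that("between- and within-network means match hand arithmetic", {
  # 5 nodes, two blocks of sizes 2 and 3 (padded with singleton RSNs so
  # the partition is valid)
  ids <- paste0("n", 1:9)
  labels <- c("DMN", "DMN", "FPN", "FPN", "FPN", "DAN", "DAN", "VAN", "VAN")
  part <- networkPartition(ids, labels)
  W <- matrix(0.5, 9, 9); diag(W) <- 1
  W[1, 3] <- W[3, 1] <- 0.2
  W[1, 4] <- W[4, 1] <- 0.4
  W[2, 3] <- W[3, 2] <- 0.6
  W[1, 2] <- W[2, 1] <- 0.9
  W[3, 4] <- W[4, 3] <- 0.1
  W[3, 5] <- W[5, 3] <- 0.3
  dimnames(W) <- list(ids, ids)
  btw <- betweenNetworkFC(W, part)
  expect_length(btw, 6L)
  expect_equal(unname(btw["DMN-FPN"]),
               mean(c(0.2, 0.4, 0.5, 0.6, 0.5, 0.5)))
  wth <- withinNetworkFC(W, part)
  expect_equal(unname(wth["DMN"]), 0.9)
  expect_equal(unname(wth["FPN"]), mean(c(0.1, 0.3, 0.5)))
  # constant matrix: every block mean is the constant
  Wc <- matrix(0.3, 9, 9); diag(Wc) <- 1
  dimnames(Wc) <- list(ids, ids)
  expect_true(all(abs(betweenNetworkFC(Wc, part) - 0.3) < 1e-15))
  expect_true(all(abs(withinNetworkFC(Wc, part) - 0.3) < 1e-15))
  # symmetric in pair order by construction of the labels
  expect_equal(unname(btw["DMN-FPN"]),
               mean(cohValues(coherenceMatrix(W))[3:5, 1:2]))
})

test_that("the per-subject metrics row carries exactly the expected columns", {
  set.seed(3)
  ids <- paste0("n", 1:15)
  labels <- rep(c("DMN", "FPN", "DAN", "VAN", "other"), each = 3)
  part <- networkPartition(ids, labels)
  W <- randomWeightedGraph(15)
  dimnames(W) <- list(ids, ids)
  row <- topologyMetrics(coherenceMatrix(pmin(W + 0.01, 1)), part)
  expect_equal(nrow(row), 1L)
  expect_length(grep("^between_", names(row)), 6L)
  expect_length(grep("^within_", names(row)), 4L)
  expect_length(grep("^(eff|clust)_", names(row)), 8L)
  expect_true(all(is.finite(unlist(row))))
})
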