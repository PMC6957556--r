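# Independent oracles used to validate the package's implementations.
# Each is written from the definition, with no shared code paths.

# --- all-pairs shortest paths by Floyd-Warshall (edge length = 1/weight)
oracleEfficiency <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  pos <- W > 0
  D[pos] <- 1 / W[pos]
  diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  inv <- 1 / D[upper.tri(D)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

# --- weighted clustering by exhaustive triple enumeration (Onnela)
oracleClustering <- function(W) {
  n <- nrow(W)
  diag(W) <- 0
  mx <- max(W)
  if (mx == 0) return(rep(0, n))
  Wn <- W / mx
  per <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      j <- nb[a]; h <- nb[b]
      s <- s + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1 / 3)
    }
    per[i] <- 2 * s / (k * (k - 1))
  }
  per
}

randomWeightedGraph <- function(n, density = 0.7) {
  W <- matrix(0, n, n)
  up <- which(upper.tri(W))
  on <- runif(length(up)) < density
  W[up[on]] <- runif(sum(on), 0.05, 1)
  W <- W + t(W)
  W
}

# --- Tower of London: independent move generator + bidirectional BFS.
# States as list(post1, post2, post3) of bead vectors; its own rules code.
oracleTolMoves <- function(code) {
  posts <- strsplit(code, "/", fixed = TRUE)[[1]]
  length(posts) <- 3
  posts[is.na(posts)] <- ""
  caps <- c(3, 2, 1)
  out <- character()
  for (i in 1:3) {
    if (!nzchar(posts[i])) next
    bead <- substr(posts[i], nchar(posts[i]), nchar(posts[i]))
    rest <- substr(posts[i], 1, nchar(posts[i]) - 1)
    for (j in 1:3) {
      if (j == i || nchar(posts[j]) >= caps[j]) next
      np <- posts
      np[i] <- rest
      np[j] <- paste0(posts[j], bead)
      out <- c(out, paste(np, collapse = "/"))
    }
  }
  out
}

oracleTolDistance <- function(start, goal) {
  if (start == goal) return(0L)
  front <- c(start); back <- c(goal)
  dFront <- c(0L); dBack <- c(0L)
  names(dFront) <- start; names(dBack) <- goal
  repeat {
    # expand the smaller frontier
    if (length(front) <= length(back)) {
      nxt <- character()
      for (s in front) for (m in oracleTolMoves(s)) {
        if (!is.na(dBack[m])) return(unname(dFront[s] + 1L + dBack[m]))
        if (is.na(dFront[m])) {
          dFront[m] <- dFront[s] + 1L
          nxt <- c(nxt, m)
        }
      }
      front <- nxt
    } else {
      nxt <- character()
      for (s in back) for (m in oracleTolMoves(s)) {
        if (!is.na(dFront[m])) return(unname(dBack[s] + 1L + dFront[m]))
        if (is.na(dBack[m])) {
          dBack[m] <- dBack[s] + 1L
          nxt <- c(nxt, m)
        }
      }
      back <- nxt
    }
    if (!length(front) && !length(back)) stop("states not connected")
  }
}

# --- rigid-body RMS displacement by numeric integration over a solid
# ball of radius 80 mm: map points through both volumes' transforms via
# the relative transform and take the root mean square displacement.
oracleMotionRMS <- function(p1, p2, nPoints = 40000, seed = 424243) {
  rot <- function(p) {
    Rx <- rbind(c(1, 0, 0), c(0, cos(p[1]), -sin(p[1])),
                c(0, sin(p[1]), cos(p[1])))
    Ry <- rbind(c(cos(p[2]), 0, sin(p[2])), c(0, 1, 0),
                c(-sin(p[2]), 0, cos(p[2])))
    Rz <- rbind(c(cos(p[3]), -sin(p[3]), 0), c(sin(p[3]), cos(p[3]), 0),
                c(0, 0, 1))
    Rx %*% Ry %*% Rz
  }
  M1 <- rbind(cbind(rot(p1), p1[4:6]), c(0, 0, 0, 1))
  M2 <- rbind(cbind(rot(p2), p2[4:6]), c(0, 0, 0, 1))
  Mrel <- M2 %*% solve(M1)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # uniform points in the ball by rejection
  pts <- matrix(runif(3 * ceiling(nPoints * 2.2), -80, 80), ncol = 3)
  pts <- pts[rowSums(pts^2) <= 80^2, , drop = FALSE]
  moved <- t(Mrel %*% t(cbind(pts, 1)))[, 1:3]
  sqrt(mean(rowSums((moved - pts)^2)))
}

# --- Benjamini-Hochberg by exhaustive threshold scan: a test is rejected
# at FDR level q iff the step-up rule at q rejects it; the adjusted value
# is the smallest candidate level at which that happens.
oracleBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  candidates <- sort(unique(pmin(m * p[ord] / seq_len(m), 1)))
  stepUpRejected <- function(q) {
    ps <- p[ord]
    k <- which(ps <= seq_len(m) * q / m)
    if (!length(k)) return(rep(FALSE, m))
    out <- rep(FALSE, m)
    out[ord[seq_len(max(k))]] <- TRUE
    out
  }
  adj <- rep(1, m)
  for (q in rev(candidates)) {
    rej <- stepUpRejected(q)
    adj[rej] <- q
  }
  adj
}

# --- small helpers shared by tests
tinyPartitionSizes <- c(DMN = 4L, FPN = 3L, DAN = 3L, VAN = 3L, other = 2L)

tinyCohortConfig <- function(...) {
  cohortConfig(partitionSizes = tinyPartitionSizes, lowSignalNodes = 0L, ...)
}

statsCohortTable <- function(config) {
  coh <- generateCohort(config)
  tab <- cohortTable(coh)
  tab$integration <- cohortGroundTruth(coh)$coupling
  tab
}
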