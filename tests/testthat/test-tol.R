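# Tower of London state space, solver, problem generation and scoring.

test_that("state enumeration matches the combinatorial count and all states are valid and reachable", {
  states <- tolStates()
  expect_length(states, 36L)
  expect_true(all(vapply(states, tolIsValidState, TRUE)))
  # exhaustive BFS from the all-on-post-1 state covers everything
  seen <- "RGB//"
  frontier <- seen
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(lapply(frontier, tolLegalMoves))), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  expect_setequal(seen, states)
})

test_that("legal moves follow the one-bead, capacity and top-only rules", {
  expect_length(tolLegalMoves("RGB//"), 2L)   # only the top bead can move
  # occupancy (1,1,1): post-1 and post-2 tops can swap posts 1<->2, the
  # post-3 bead can go to either -> 4 successors
  expect_length(tolLegalMoves("R/G/B"), 4L)
  expect_setequal(tolLegalMoves("R/G/B"),
                  c("/GR/B", "RG//B", "RB/G/", "R/GB/"))
  expect_error(tolLegalMoves("RG//B/"), "invalid")
  # the move relation is symmetric over the whole graph
  for (s in tolStates())
    for (m in tolLegalMoves(s))
      expect_true(s %in% tolLegalMoves(m))
})

test_that("minimal move counts agree with an independent bidirectional BFS and form a metric", {
  states <- tolStates()
  D <- vapply(states, function(a)
    vapply(states, function(b) tolMinMoves(a, b), integer(1)),
    integer(length(states)))
  Do <- vapply(states, function(a)
    vapply(states, function(b) oracleTolDistance(a, b), integer(1)),
    integer(length(states)))
  expect_identical(D, Do)
  expect_identical(D, t(D))                       # symmetry
  expect_true(all(diag(D) == 0L) && all(D[upper.tri(D)] > 0L))
  expect_equal(tolMinMoves("RGB//", "BGR//"), 7L) # full reversal on post 1
  expect_gte(max(D), 5L)                          # every level 1-5 exists
  # triangle inequality over all ordered triples through a middle state
  for (k in sample(seq_along(states), 6)) {
    viaK <- outer(D[, k], D[k, ], `+`)
    expect_true(all(D <= viaK))
  }
})

test_that("problem sets are balanced, reproducible and correctly labeled", {
  ps <- tolProblemSet(1, seed = 11)
  expect_identical(sort(unique(ps$level)), 1:5)
  a <- tolProblemSet(3, seed = 7)
  b <- tolProblemSet(3, seed = 7)
  expect_identical(a, b)
  relabeled <- mapply(tolMinMoves, a$start, a$goal)
  expect_identical(unname(relabeled), a$level)
  expect_error(tolProblemSet(1000, seed = 1), "level")
})

test_that("response scoring computes accuracy and correct-trial RT, with level restriction", {
  ps <- tolProblemSet(2, seed = 3)
  ps$answer <- ps$level
  ps$rt_s <- rep(c(8, 12), length.out = nrow(ps))
  s <- tolScore(ps)
  expect_equal(s$accuracyPct, 100)
  expect_equal(s$meanRtS, 10)
  # half correct: RT averaged over the correct half only
  half <- ps
  half$answer[seq(1, nrow(half), by = 2)] <- half$level[seq(1, nrow(half), by = 2)] + 1L
  s2 <- tolScore(half)
  expect_equal(s2$accuracyPct, 50)
  expect_equal(s2$meanRtS, mean(half$rt_s[half$answer == half$level]))
  # fixed 20-trial fixture restricted to levels 4-5, against hand arithmetic
  fx <- data.frame(level = rep(1:5, each = 4),
                   answer = c(rep(1, 4), rep(2, 4), rep(3, 4),
                              4, 4, 5, 3, 5, 4, 5, 5),
                   rt_s = seq(1, 20))
  fx$start <- "RGB//"; fx$goal <- NA  # unused when `correct` supplied
  fx$correct <- fx$answer == fx$level
  s45 <- tolScore(fx, levels = 4:5)
  expect_equal(s45$accuracyPct, 100 * 5 / 8)      # 2/4 + 3/4 correct
  expect_equal(s45$meanRtS, mean(c(13, 14, 17, 19, 20)))
  # no-correct-trials subset is flagged, not silently zero
  none <- fx[fx$level == 4, ]
  none$correct <- FALSE
  expect_warning(sN <- tolScore(none, levels = 4), "no correct trials")
  expect_true(is.na(sN$meanRtS))
})

test_that("overall score equals the trial-count-weighted mean of per-level scores", {
  set.seed(41)
  ps <- tolProblemSet(4, seed = 5)
  ps$answer <- ifelse(runif(nrow(ps)) < 0.7, ps$level, pmax(1, ps$level - 1))
  ps$rt_s <- runif(nrow(ps), 5, 15)
  whole <- tolScore(ps)
  per <- lapply(1:5, function(l) tolScore(ps, levels = l))
  nTr <- vapply(per, `[[`, numeric(1), "nTrials")
  acc <- vapply(per, `[[`, numeric(1), "accuracyPct")
  expect_equal(whole$accuracyPct, sum(acc * nTr) / sum(nTr))
  nCor <- vapply(per, `[[`, numeric(1), "nCorrect")
  rt <- vapply(per, `[[`, numeric(1), "meanRtS")
  expect_equal(whole$meanRtS, sum(rt * nCor) / sum(nCor))
})

test_that("trial tables round-trip through TSV", {
  ps <- tolProblemSet(1, seed = 2)
  ps$answer <- ps$level; ps$rt_s <- c(8.5, 9, 10, 11.25, 12)
  path <- tempfile(fileext = ".tsv")
  writeTrials(ps, path)
  back <- readTrials(path)
  expect_equal(back$start, ps$start)
  expect_equal(back$rt_s, ps$rt_s)
})
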