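# Exact model of the 3-bead Tower of London task: state space, legal
# moves, minimal-move solver, problem generation, behavioral scoring.
#
# A state is serialized as "P1/P2/P3" where each post lists its beads
# bottom-to-top from {R, G, B} and the post capacities are fixed at
# (3, 2, 1); e.g. "RGB//" has all beads on the first post with B on top.

TOL_BEADS <- c("R", "G", "B")
TOL_CAPACITY <- c(3L, 2L, 1L)

.tolCache <- new.env(parent = emptyenv())

tolParseState <- function(state) {
  parts <- strsplit(state, "/", fixed = TRUE)[[1]]
  length(parts) <- 3L
  parts[is.na(parts)] <- ""
  lapply(parts, function(p) if (nzchar(p)) strsplit(p, "")[[1]] else character())
}

tolSerializeState <- function(posts) {
  paste(vapply(posts, paste, "", collapse = ""), collapse = "/")
}

#' Validate a Tower of London state
#'
#' A valid state places the three distinct beads R, G, B on posts of
#' capacities 3, 2 and 1 (left to right).
#'
#' @param state Character state code `"P1/P2/P3"` (beads bottom-to-top).
#' @return Logical.
#' @examples
#' tolIsValidState("RGB//")   # TRUE
#' tolIsValidState("RG/B/B")  # FALSE (duplicate bead)
#' @export
tolIsValidState <- function(state) {
  if (!is.character(state) || length(state) != 1L) return(FALSE)
  if (length(gregexpr("/", state, fixed = TRUE)[[1]]) != 2L &&
      !identical(state, "")) {
    nslash <- lengths(regmatches(state, gregexpr("/", state, fixed = TRUE)))
    if (nslash != 2L) return(FALSE)
  }
  posts <- tolParseState(state)
  beads <- unlist(posts)
  length(beads) == 3L && setequal(beads, TOL_BEADS) &&
    !anyDuplicated(beads) &&
    all(lengths(posts) <= TOL_CAPACITY)
}

#' Enumerate all Tower of London states
#'
#' Generates every admissible configuration of three distinct beads on
#' posts of capacities (3, 2, 1). There are 6 occupancy patterns times
#' 3! bead orderings = 36 states, all mutually reachable.
#'
#' @return Character vector of 36 canonical state codes, sorted.
#' @examples
#' length(tolStates())  # 36
#' @export
tolStates <- function() {
  if (!is.null(.tolCache$states)) return(.tolCache$states)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  occ <- list(c(3, 0, 0), c(2, 1, 0), c(2, 0, 1), c(1, 2, 0), c(1, 1, 1),
              c(0, 2, 1))
  out <- character()
  for (o in occ) for (p in perms) {
    beads <- TOL_BEADS[p]
    posts <- vector("list", 3L)
    i <- 1L
    for (j in 1:3) {
      posts[[j]] <- if (o[j] > 0) beads[i:(i + o[j] - 1L)] else character()
      i <- i + o[j]
    }
    out <- c(out, tolSerializeState(posts))
  }
  out <- sort(unique(out))
  stopifnot(all(vapply(out, tolIsValidState, TRUE)))
  .tolCache$states <- out
  out
}

#' Legal moves from a state
#'
#' One bead moves at a time; only a bead with nothing on top of it may
#' move, and only to a post with free capacity. The move relation is
#' symmetric.
#'
#' @param state Character state code.
#' @return Character vector of successor states.
#' @examples
#' tolLegalMoves("RGB//")  # two successors: top bead to post 2 or 3
#' @export
tolLegalMoves <- function(state) {
  if (!tolIsValidState(state))
    stop("invalid Tower of London state: ", state)
  posts <- tolParseState(state)
  out <- character()
  for (from in 1:3) {
    n <- length(posts[[from]])
    if (n == 0L) next
    bead <- posts[[from]][n]
    for (to in 1:3) {
      if (to == from || length(posts[[to]]) >= TOL_CAPACITY[to]) next
      np <- posts
      np[[from]] <- np[[from]][-n]
      np[[to]] <- c(np[[to]], bead)
      out <- c(out, tolSerializeState(np))
    }
  }
  out
}

# All-pairs shortest-path table over the 36-state graph, by BFS from every
# state; cached (the graph is tiny and immutable).
tolDistances <- function() {
  if (!is.null(.tolCache$dist)) return(.tolCache$dist)
  states <- tolStates()
  n <- length(states)
  adj <- lapply(states, function(s) match(tolLegalMoves(s), states))
  D <- matrix(NA_integer_, n, n, dimnames = list(states, states))
  for (i in seq_len(n)) {
    d <- rep(NA_integer_, n)
    d[i] <- 0L
    frontier <- i
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(d[nxt])]
      d[nxt] <- d[frontier[1]] + 1L
      frontier <- nxt
    }
    D[i, ] <- d
  }
  stopifnot(!anyNA(D))  # the move graph is connected
  .tolCache$dist <- D
  D
}

#' Minimum number of moves between two states
#'
#' Breadth-first-search distance on the 36-state move graph; symmetric in
#' its arguments and zero iff `start == goal`.
#'
#' @param start,goal Character state codes.
#' @return Integer minimal move count.
#' @examples
#' tolMinMoves("RGB//", "RGB//")  # 0
#' @export
tolMinMoves <- function(start, goal) {
  if (!tolIsValidState(start)) stop("invalid start state: ", start)
  if (!tolIsValidState(goal)) stop("invalid goal state: ", goal)
  D <- tolDistances()
  D[start, goal]
}

#' Generate a balanced Tower of London problem set
#'
#' Samples `nPerLevel` distinct (start, goal) pairs at every minimal-move
#' level 1-5, uniformly without replacement among all pairs at that
#' distance.
#'
#' @param nPerLevel Problems per difficulty level.
#' @param seed Integer seed (mandatory, for reproducibility).
#' @param levels Difficulty levels to include.
#' @return Data frame with columns `start`, `goal`, `level`.
#' @examples
#' ps <- tolProblemSet(1, seed = 7)
#' table(ps$level)
#' @export
tolProblemSet <- function(nPerLevel, seed, levels = 1:5) {
  stopIfNot(nPerLevel >= 1, "nPerLevel must be >= 1")
  stopIfNot(!missing(seed), "seed is required")
  D <- tolDistances()
  states <- tolStates()
  out <- withSeed(seed, {
    rows <- list()
    for (lev in levels) {
      idx <- which(D == lev, arr.ind = TRUE)
      if (nrow(idx) < nPerLevel)
        stop("only ", nrow(idx), " distinct problems exist at level ", lev,
             "; ", nPerLevel, " requested")
      pick <- idx[sample.int(nrow(idx), nPerLevel), , drop = FALSE]
      rows[[as.character(lev)]] <- data.frame(
        start = states[pick[, 1]], goal = states[pick[, 2]],
        level = as.integer(lev), stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  rownames(out) <- NULL
  out
}

#' Score Tower of London responses
#'
#' Accuracy is the percentage of trials (within the requested levels) whose
#' answered move count equals the true minimum; mean reaction time is
#' computed over correct trials only (pooled across levels by default).
#'
#' @param trials Data frame with columns `level`, `answer` (or `correct`),
#'   `rt_s`, and (unless `correct` is supplied) `start`, `goal`.
#' @param levels Levels to include; `4:5` gives the high-load re-analysis.
#' @param rtPerLevel If `TRUE`, average RT within level first, then across
#'   levels (alternative convention); default pools all correct trials.
#' @return List with `accuracyPct`, `meanRtS` (`NA` with a warning when no
#'   trial in the subset is correct), `nTrials`, `nCorrect`.
#' @examples
#' ps <- tolProblemSet(2, seed = 1)
#' ps$answer <- ps$level; ps$rt_s <- 10
#' tolScore(ps)$accuracyPct  # 100
#' @export
tolScore <- function(trials, levels = 1:5, rtPerLevel = FALSE) {
  keep <- trials$level %in% levels
  stopIfNot(any(keep), "no trials at the requested levels")
  tr <- trials[keep, , drop = FALSE]
  if (is.null(tr$correct)) {
    truth <- mapply(tolMinMoves, tr$start, tr$goal)
    stopifnot(all(truth == tr$level))
    tr$correct <- tr$answer == truth
  }
  acc <- 100 * mean(tr$correct)
  ok <- tr$correct
  if (!any(ok)) {
    warning("no correct trials in the requested level subset; mean RT undefined")
    rt <- NA_real_
  } else if (rtPerLevel) {
    rt <- mean(tapply(tr$rt_s[ok], tr$level[ok], mean))
  } else {
    rt <- mean(tr$rt_s[ok])
  }
  list(accuracyPct = acc, meanRtS = rt, nTrials = nrow(tr),
       nCorrect = sum(tr$correct))
}

#' Read or write trial tables
#'
#' Tab-separated, one row per trial: serialized start and goal states,
#' level, answered move count, reaction time in seconds.
#'
#' @param trials Data frame of trials.
#' @param path File path.
#' @return `readTrials` returns the data frame; `writeTrials` its path,
#'   invisibly.
#' @export
writeTrials <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrials
#' @export
readTrials <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
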