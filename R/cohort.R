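# Synthetic-cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes:
# band-limited (0.06-0.12 Hz) modular BOLD-like signals with tunable
# within/between-network coupling, random-walk rigid-body motion traces,
# demographics matched to the target sample, and Tower of London behavior
# with planted (standardized) age and network-integration effects. A
# hidden ground-truth table records the latent per-subject coupling and
# any planted quality-control violations.

partitionFromSizes <- function(sizes) {
  labels <- rep(names(sizes), sizes)
  ids <- unlist(lapply(names(sizes), function(l)
    sprintf("%s_%03d", l, seq_len(sizes[[l]]))))
  networkPartition(ids, labels)
}

# Band-limited unit-variance Gaussian signal via Fourier masking.
bandLimitedNoise <- function(T_, trS, band) {
  w <- stats::rnorm(T_)
  W <- stats::fft(w)
  f <- seq(0, T_ - 1) / (T_ * trS)
  f <- pmin(f, 1 / trS - f)  # two-sided frequency of each bin
  keep <- f >= band[1] & f <= band[2]
  stopIfNot(any(keep), "record too short to resolve the signal band")
  W[!keep] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / T_
  (x - mean(x)) / stats::sd(x)
}

#' Simulate one subject's parcellated time series
#'
#' Each node's signal is a `subjectCoupling`-weighted copy of its
#' subnetwork's shared band-limited component plus
#' `sqrt(1 - coupling^2)`-weighted private white noise; cross-network
#' leakage mixes a global component into every shared signal with weight
#' `sqrt(couplingBetween)`. Columns are standardized to zero mean and unit
#' variance.
#'
#' @param config A [CohortConfig-class].
#' @param subjectCoupling Subject-level shared-signal weight in \[0, 1).
#' @param seed Optional seed for reproducibility.
#' @return Numeric matrix, volumes x nodes, node ids as column names.
#' @examples
#' cfg <- cohortConfig(partitionSizes = c(DMN = 4L, FPN = 3L, DAN = 3L,
#'                                        VAN = 3L, other = 2L))
#' X <- simulateTimeseries(cfg, 0.6, seed = 1)
#' @export
simulateTimeseries <- function(config, subjectCoupling, seed = NULL) {
  stopIfNot(subjectCoupling >= 0 && subjectCoupling < 1,
            "subjectCoupling must lie in [0, 1)")
  T_ <- config@nVolumes
  trS <- config@trS
  band <- config@signalBand
  if (T_ * trS < 3 / band[1])
    stop("record too short: need at least 3 cycles of ", band[1], " Hz (",
         ceiling(3 / band[1] / trS), " volumes at TR ", trS, " s)")
  part <- partitionFromSizes(config@partitionSizes)
  labels <- partitionLabels(part)
  withSeed(seed, {
    groups <- unique(labels)
    global <- bandLimitedNoise(T_, trS, band)
    cb <- config@couplingBetween
    latents <- lapply(stats::setNames(groups, groups), function(g)
      sqrt(1 - cb) * bandLimitedNoise(T_, trS, band) + sqrt(cb) * global)
    X <- vapply(seq_along(labels), function(j) {
      lab <- labels[j]
      cw <- if (lab %in% names(config@couplingWithin))
        config@couplingWithin[[lab]] else 0
      cj <- subjectCoupling * cw
      x <- cj * latents[[lab]] +
        sqrt(1 - cj^2) * stats::rnorm(T_, sd = config@noiseSd)
      (x - mean(x)) / stats::sd(x)
    }, numeric(T_))
    colnames(X) <- names(labels)
    X
  })
}

#' Simulate a rigid-body motion trace
#'
#' Random-walk six-parameter trace (three rotations in radians, then three
#' translations in mm, one row per volume) whose mean relative RMS
#' displacement scales monotonically with `severity`; `severity = 0`
#' yields an identically zero trace. `spikes` inserts that many isolated
#' large alternating translation jumps (for planting spike-count
#' violations without raising the mean).
#'
#' @param config A [CohortConfig-class] (step sizes, volumes).
#' @param severity Nonnegative severity multiplier.
#' @param seed Optional seed.
#' @param spikes Number of planted spike transitions (default 0).
#' @param spikeMm Translation jump size per spike.
#' @return Numeric matrix, volumes x 6.
#' @export
simulateMotion <- function(config, severity, seed = NULL, spikes = 0L,
                           spikeMm = 0.45) {
  stopIfNot(severity >= 0, "severity must be >= 0")
  T_ <- config@nVolumes
  withSeed(seed, {
    if (severity == 0 && spikes == 0L) return(matrix(0, T_, 6))
    steps <- cbind(
      matrix(stats::rnorm(3 * (T_ - 1), 0, severity * config@motionStepRotRad),
             ncol = 3),
      matrix(stats::rnorm(3 * (T_ - 1), 0, severity * config@motionStepTransMm),
             ncol = 3))
    if (spikes > 0L) {
      at <- round(seq(10, T_ - 10, length.out = spikes))
      steps[at, 5] <- steps[at, 5] + spikeMm * rep_len(c(1, -1), spikes)
    }
    rbind(rep(0, 6), apply(steps, 2, cumsum))
  })
}

# Scale a trace multiplicatively so its mean relative RMS lands at
# `target` (displacement is near-linear in the parameters at these
# amplitudes; one correction step suffices for QC exactness).
rescaleMotionTo <- function(params, target) {
  m <- mean(framewiseRMS(params))
  if (m == 0) return(params)
  params * (target / m)
}

# Solve the per-level correctness offset so the level-mean probability of
# a correct response equals the target accuracy.
accuracyOffset <- function(targetPct, slope, levels = 1:5) {
  p <- min(max(targetPct / 100, 0.02), 0.995)
  f <- function(eta) mean(stats::plogis(eta + slope * (3 - levels))) - p
  stats::uniroot(f, c(-15, 15))$root
}

simulateTrialResponses <- function(problems, accTargetPct, rtBase, config,
                                   deterministic) {
  lev <- problems$level
  eta <- accuracyOffset(accTargetPct, config@accLevelSlope)
  p <- stats::plogis(eta + config@accLevelSlope * (3 - lev))
  if (deterministic) {
    correct <- logical(nrow(problems))
    for (l in unique(lev)) {
      i <- which(lev == l)
      nc <- round(p[i[1]] * length(i))
      correct[i[seq_len(nc)]] <- TRUE
    }
    rt <- rtBase + config@rtLevelSlope * (lev - 3)
  } else {
    correct <- stats::runif(nrow(problems)) < p
    rt <- rtBase + config@rtLevelSlope * (lev - 3) +
      stats::rnorm(nrow(problems), 0, config@rtTrialSd)
  }
  rt <- pmax(rt, 0.5)
  answer <- ifelse(correct, lev,
                   pmin(pmax(lev + sample(c(-1L, 1L), nrow(problems),
                                          replace = TRUE), 1L), 5L))
  # a wrong answer must differ from the truth
  fix <- !correct & answer == lev
  answer[fix] <- ifelse(lev[fix] == 5L, 4L, lev[fix] + 1L)
  data.frame(start = problems$start, goal = problems$goal, level = lev,
             answer = answer, correct = correct, rt_s = rt,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Draws demographics (age truncated to the configured range, sex,
#' Verhage education, handedness, scan-task interval), a latent
#' network-integration coupling per subject, motion traces, parcellated
#' time series (unless disabled), per-node signal-voxel counts with a
#' configured number of low-signal nodes, and trial-level Tower of London
#' behavior whose subject means follow the configured standardized age and
#' integration effects. Planted quality-control violators (motion,
#' behavior, interval) are labeled in the ground-truth table; when any
#' violator fraction is positive the generator guarantees QC exactness by
#' keeping non-violators strictly inside every threshold (truncated
#' residuals, capped motion severity, deterministic trial scoring).
#'
#' @param config A [CohortConfig-class].
#' @return A [Cohort-class].
#' @examples
#' coh <- generateCohort(cohortConfig(nSubjects = 6L,
#'                                    generateTimeseries = FALSE))
#' @export
generateCohort <- function(config) {
  n <- config@nSubjects
  exact <- (config@violatorFracMotion + config@violatorFracBehavior +
              config@violatorFracInterval) > 0
  part <- partitionFromSizes(config@partitionSizes)
  ids <- nodeIds(part)
  withSeed(config@seed, {
    age <- rnormTrunc(n, config@ageMean, config@ageSd,
                      config@ageRange[1], config@ageRange[2])
    sex <- ifelse(stats::runif(n) < config@pFemale, "F", "M")
    edu <- sample(seq_along(config@educationProbs), n, replace = TRUE,
                  prob = config@educationProbs)
    hand <- ifelse(stats::runif(n) < config@pLeftHanded, "L", "R")
    interval <- pmin(pmax(round(stats::rnorm(n, config@intervalMean,
                                             config@intervalSd)), 0L), 21L)
    cr <- config@subjectCouplingRange
    coupling <- cr[1] + diff(cr) *
      stats::rbeta(n, config@subjectCouplingShape[1],
                   config@subjectCouplingShape[2])
    severity <- stats::rlnorm(n, config@motionSeverityMeanlog,
                              config@motionSeveritySdlog)
    if (exact) severity <- pmin(severity, 2)

    # planted violators: disjoint subject sets, chosen reproducibly
    shuffled <- sample.int(n)
    nm <- floor(config@violatorFracMotion * n)
    nb <- floor(config@violatorFracBehavior * n)
    ni <- floor(config@violatorFracInterval * n)
    vMotion <- shuffled[seq_len(nm)]
    vBehavior <- shuffled[nm + seq_len(nb)]
    vInterval <- shuffled[nm + nb + seq_len(ni)]
    vMotionMean <- vMotion[seq_len(ceiling(nm / 2))]
    vMotionSpikes <- setdiff(vMotion, vMotionMean)
    interval[vInterval] <- sample(22:40, ni, replace = TRUE)

    # standardized behavioral generating model
    zAge <- (age - config@ageMean) / config@ageSd
    cMean <- cr[1] + diff(cr) * config@subjectCouplingShape[1] /
      sum(config@subjectCouplingShape)
    a <- config@subjectCouplingShape[1]; b <- config@subjectCouplingShape[2]
    cSd <- diff(cr) * sqrt(a * b / ((a + b)^2 * (a + b + 1)))
    zCoup <- (coupling - cMean) / cSd
    rtResidSd <- sqrt(1 - config@betaAgeRt^2 - config@betaIntegrationRt^2)
    accResidSd <- sqrt(1 - config@betaAgeAcc^2 - config@betaIntegrationAcc^2)
    zRt <- stats::rnorm(n)
    zAcc <- stats::rnorm(n)
    rtBase <- config@rtMean + config@rtSd *
      (config@betaAgeRt * zAge + config@betaIntegrationRt * zCoup +
         rtResidSd * zRt)
    accBase <- config@accMean + config@accSd *
      (config@betaAgeAcc * zAge + config@betaIntegrationAcc * zCoup +
         accResidSd * zAcc)
    if (exact) {
      # QC exactness: keep every non-violator's total behavioral
      # deviation strictly inside the 2 SD rule (clipped at 1.5 SD of
      # the compliant pool, leaving headroom for trial-level scoring)
      clipZ <- function(v, keep, k = 1.5) {
        m <- mean(v[keep]); s <- stats::sd(v[keep])
        v[keep] <- m + pmin(pmax(v[keep] - m, -k * s), k * s)
        v
      }
      nonViol <- !(seq_len(n) %in% vBehavior)
      rtBase <- clipZ(rtBase, nonViol)
      accBase <- clipZ(accBase, nonViol)
    }
    rtBase[vBehavior] <- config@rtMean + 6 * config@rtSd
    rtBase <- pmax(rtBase, 1)
    accBase <- pmin(pmax(accBase, 5), 100)

    problems <- tolProblemSet(config@trialsPerLevel,
                              seed = deriveSeed(config@seed, 17))

    # low-signal nodes: each is below the voxel floor in >= 1 subject
    lowNodes <- if (config@lowSignalNodes > 0L)
      sort(sample(seq_along(ids), config@lowSignalNodes)) else integer()
    voxBase <- matrix(sample(20:200, n * length(ids), replace = TRUE), n,
                      dimnames = list(NULL, ids))
    for (k in lowNodes) {
      hit <- which(stats::runif(n) < 0.15)
      if (!length(hit)) hit <- sample.int(n, 1)
      voxBase[hit, k] <- sample(0:3, length(hit), replace = TRUE)
    }

    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      sev <- severity[i]
      spikes <- 0L
      if (i %in% vMotionMean) sev <- 4.5
      if (i %in% vMotionSpikes) {
        sev <- min(sev, 1)
        spikes <- 25L
      }
      motion <- simulateMotion(config, sev, seed = deriveSeed(config@seed,
                                                              2000 + i),
                               spikes = spikes)
      if (exact && sev > 0) {
        fd <- framewiseRMS(motion)
        if (i %in% vMotionMean && mean(fd) < 0.25)
          motion <- rescaleMotionTo(motion, 0.3)
        if (!(i %in% vMotion) && (mean(fd) > 0.18 || sum(fd > 0.25) > 15))
          motion <- rescaleMotionTo(motion, 0.12)
      }
      trials <- simulateTrialResponses(problems, accBase[i], rtBase[i],
                                       config, deterministic = exact)
      all5 <- tolScore(trials)
      s45 <- tolScore(trials, levels = 4:5)
      ts <- if (config@generateTimeseries)
        simulateTimeseries(config, coupling[i],
                           seed = deriveSeed(config@seed, 1000 + i))
      else NULL
      subjects[[i]] <- new("SubjectRecord",
        subjectId = sprintf("sub-%03d", i), ageYears = age[i], sex = sex[i],
        educationVerhage = as.integer(edu[i]), handedness = hand[i],
        intervalDays = as.integer(interval[i]), motionParams = motion,
        timeseries = ts,
        voxelCounts = stats::setNames(as.integer(voxBase[i, ]), ids),
        trials = trials,
        tolAccuracyPct = all5$accuracyPct, tolRtS = all5$meanRtS,
        tolAccuracy45Pct = s45$accuracyPct, tolRt45S = s45$meanRtS)
    }
    gt <- data.frame(
      subjectId = vapply(subjects, slot, "", "subjectId"),
      coupling = coupling, severity = severity,
      violatorMotionMean = seq_len(n) %in% vMotionMean,
      violatorMotionSpikes = seq_len(n) %in% vMotionSpikes,
      violatorBehavior = seq_len(n) %in% vBehavior,
      violatorInterval = seq_len(n) %in% vInterval,
      stringsAsFactors = FALSE)
    new("Cohort", subjects = subjects, config = config, partition = part,
        nodeIds = ids, groundTruth = gt)
  })
}

#' Analysis table of a cohort
#'
#' One row per subject with demographics, behavior (overall and
#' level-4/5), and mean relative RMS motion — the covariate side of the
#' regression stage.
#'
#' @param cohort A [Cohort-class].
#' @return Data frame keyed by `subjectId`.
#' @export
cohortTable <- function(cohort) {
  subjects <- cohortSubjects(cohort)
  do.call(rbind, lapply(subjects, function(s) data.frame(
    subjectId = s@subjectId, age_years = s@ageYears, sex = s@sex,
    education = s@educationVerhage, interval_days = s@intervalDays,
    motion_mean_rms = mean(framewiseRMS(s@motionParams)),
    tol_accuracy_pct = s@tolAccuracyPct, tol_rt_s = s@tolRtS,
    tol_accuracy_45_pct = s@tolAccuracy45Pct, tol_rt_45_s = s@tolRt45S,
    stringsAsFactors = FALSE)))
}

configAsList <- function(config) {
  out <- lapply(slotNames(config), function(s) {
    v <- slot(config, s)
    if (!is.null(names(v))) as.list(v) else v  # keep names through JSON
  })
  names(out) <- slotNames(config)
  out
}

#' Write / read a cohort directory
#'
#' The directory holds `manifest.json` (configuration, seed, ground
#' truth), `demographics.tsv`, and per subject a time-series TSV (volumes
#' x nodes, header = node ids), an MCFLIRT-style six-column motion file
#' (rotations rad then translations mm) and a trials TSV.
#'
#' @param cohort A [Cohort-class].
#' @param dir Directory path.
#' @return `writeCohort` returns `dir` invisibly; `readCohort` is not
#'   provided — the manifest plus [generateCohort()] reproduces the cohort
#'   bit-identically.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(config = configAsList(cohort@config),
         ground_truth = cohortGroundTruth(cohort),
         node_ids = cohort@nodeIds,
         partition = as.list(partitionLabels(cohort@partition))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  tab <- cohortTable(cohort)
  utils::write.table(tab, file.path(dir, "demographics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  vox <- do.call(rbind, lapply(cohortSubjects(cohort), slot, "voxelCounts"))
  utils::write.table(data.frame(subjectId = tab$subjectId, vox,
                                check.names = FALSE),
                     file.path(dir, "voxel_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (s in cohortSubjects(cohort)) {
    if (is.matrix(s@timeseries)) {
      ts <- as.data.frame(s@timeseries)
      utils::write.table(ts, file.path(dir, paste0(s@subjectId,
                                                   "_timeseries.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(format(s@motionParams, digits = 10),
                       file.path(dir, paste0(s@subjectId, "_motion.par")),
                       sep = " ", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    writeTrials(s@trials, file.path(dir, paste0(s@subjectId, "_trials.tsv")))
  }
  invisible(dir)
}
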