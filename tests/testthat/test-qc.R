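# Motion metrics, exclusion rules and node harmonization.

test_that("framewise RMS reduces to the translation norm and matches the point-cloud oracle", {
  expect_equal(framewiseRMS(matrix(0, 10, 6)), rep(0, 9))
  # pure 0.5 mm translation on one axis between two volumes
  M <- rbind(rep(0, 6), c(0, 0, 0, 0.5, 0, 0))
  expect_equal(framewiseRMS(M), 0.5)
  # random small motions against numeric integration over the 80 mm ball
  set.seed(55)
  for (i in 1:6) {
    p1 <- c(rnorm(3, 0, 0.002), rnorm(3, 0, 0.2))
    p2 <- c(rnorm(3, 0, 0.002), rnorm(3, 0, 0.2))
    ours <- framewiseRMS(rbind(p1, p2))
    expect_equal(ours, oracleMotionRMS(p1, p2), tolerance = 0.01)
  }
  expect_error(framewiseRMS(rbind(rep(0, 6), c(NA, 0, 0, 0, 0, 0))),
               "row")
  expect_error(framewiseRMS(matrix(0, 5, 4)), "6 columns")
})

makeSubject <- function(id, motion, rt = 10, acc = 88, interval = 5L) {
  new("SubjectRecord", subjectId = id, ageYears = 50, sex = "F",
      educationVerhage = 5L, handedness = "R", intervalDays = interval,
      motionParams = motion, timeseries = NULL,
      voxelCounts = c(a = 10L, b = 10L), trials = data.frame(),
      tolAccuracyPct = acc, tolRtS = rt, tolAccuracy45Pct = acc,
      tolRt45S = rt)
}

test_that("motion exclusion applies the printed thresholds with strict boundaries", {
  cfg <- tinyCohortConfig(nVolumes = 192L)
  quiet <- simulateMotion(cfg, 1, seed = 1)          # cohort-typical ~0.07
  loud <- simulateMotion(cfg, 1, seed = 1) * 3.7     # mean > 0.2
  # exactly 21 spikes above 0.25 mm but mean below 0.2: alternate jumps
  spiky <- matrix(0, 192, 6)
  at <- seq(10, 178, by = 8)[1:21]
  spiky[, 4] <- cumsum(replace(rep(0, 192), at, 0.3 * rep_len(c(1, -1), 21)))
  subs <- list(makeSubject("typ", quiet), makeSubject("bad", loud),
               makeSubject("spk", spiky))
  rep <- applyMotionExclusion(subs)
  expect_equal(rep$kept, c(TRUE, FALSE, FALSE))
  expect_match(rep$reasons[2], "motion_mean")
  expect_equal(rep$reasons[3], "motion_spikes")
  expect_equal(rep$nSpikeVolumes[3], 21L)           # strict "> 20"
  expect_lt(rep$meanRelRmsMm[1], 0.2)
  # exactly 20 spikes is kept
  spiky20 <- matrix(0, 192, 6)
  spiky20[, 4] <- cumsum(replace(rep(0, 192), at[1:20],
                                 0.3 * rep_len(c(1, -1), 20)))
  expect_true(applyMotionExclusion(list(makeSubject("s20", spiky20)))$kept)
})

test_that("behavioral and interval rules use inclusive 2 SD and exclusive 21 days", {
  z <- matrix(0, 5, 6)
  subs <- list(
    makeSubject("s1", z, rt = 10), makeSubject("s2", z, rt = 11),
    makeSubject("s3", z, rt = 9), makeSubject("s4", z, rt = 10.5),
    makeSubject("s5", z, rt = 9.5, interval = 21L),
    makeSubject("s6", z, rt = 10.2, interval = 22L),
    makeSubject("out", z, rt = 16))  # far outlier
  rep <- behavioralExclusion(subs, outcomes = "tolRtS")
  expect_true(rep$kept[rep$subjectId == "s5"])       # 21 days admissible
  expect_false(rep$kept[rep$subjectId == "s6"])
  expect_equal(rep$reasons[rep$subjectId == "s6"], "interval")
  expect_false(rep$kept[rep$subjectId == "out"])
  expect_equal(rep$reasons[rep$subjectId == "out"], "behavior_outlier")
  # subject exactly at the mean is kept
  expect_true(rep$kept[rep$subjectId == "s1"] ||
                rep$kept[rep$subjectId == "s4"])
  expect_error(behavioralExclusion(subs[1:2], outcomes = "tolRtS"), ">= 3")
})

test_that("harmonization drops any node below the voxel floor in any subject", {
  v1 <- c(a = 10L, b = 5L, c = 4L)
  v2 <- c(a = 9L, b = 3L, c = 20L)
  expect_equal(harmonizeNodes(list(v1, v1)), c("a", "b", "c"))
  expect_equal(harmonizeNodes(list(v1, v2)), c("a", "c"))  # b < 4 once
  expect_equal(harmonizeNodes(list(v1, v2), minVoxels = 3L),
               c("a", "b", "c"))
  expect_error(harmonizeNodes(list(c(a = 0L), c(a = 1L))), "no common")
  expect_error(harmonizeNodes(list(v1, v2[c(2, 1, 3)])), "universe")
})

test_that("the generator's 225-node cohort harmonizes to exactly 194 common nodes", {
  coh <- generateCohort(cohortConfig(nSubjects = 12L,
                                     generateTimeseries = FALSE, seed = 8L))
  expect_length(coh@nodeIds, 225L)
  common <- harmonizeNodes(coh)
  expect_length(common, 194L)
  # order-preserving intersection
  expect_identical(common, intersect(coh@nodeIds, common))
})

test_that("QC excludes exactly the planted violators with matching reasons", {
  cfg <- cohortConfig(nSubjects = 40L, generateTimeseries = FALSE,
                      violatorFracMotion = 0.1, violatorFracBehavior = 0.05,
                      violatorFracInterval = 0.075, seed = 21L)
  coh <- generateCohort(cfg)
  rep <- qcReport(coh)
  gt <- cohortGroundTruth(coh)
  planted <- gt$violatorMotionMean | gt$violatorMotionSpikes |
    gt$violatorBehavior | gt$violatorInterval
  expect_identical(!rep$kept, planted)
  has <- function(r, what) grepl(what, r)
  expect_true(all(has(rep$reasons[gt$violatorMotionMean], "motion_mean")))
  expect_true(all(rep$reasons[gt$violatorMotionSpikes] == "motion_spikes"))
  expect_true(all(has(rep$reasons[gt$violatorBehavior], "behavior_outlier")))
  expect_true(all(has(rep$reasons[gt$violatorInterval], "interval")))
  # flow summary reconciles with the report
  flow <- attr(rep, "flow")
  expect_equal(flow$n_excluded, sum(!rep$kept))
  expect_equal(flow$interval, sum(gt$violatorInterval))
  # QC is a single pass: re-applying the pool-independent rules (motion,
  # interval) to the kept subjects changes nothing (behavioral z-scores
  # are deliberately not recomputed on the reduced pool, where they could
  # cascade)
  kept <- cohortSubjects(coh)[rep$kept]
  rep2 <- applyMotionExclusion(kept)
  expect_true(all(rep2$kept))
  expect_true(all(vapply(kept, slot, 1L, "intervalDays") <= 21L))
})

test_that("the QC report writes its TSV and exclusion-flow JSON", {
  coh <- generateCohort(cohortConfig(nSubjects = 8L,
                                     generateTimeseries = FALSE, seed = 2L))
  rep <- qcReport(coh)
  d <- file.path(tempdir(), "qcout")
  writeQcReport(rep, d)
  expect_true(file.exists(file.path(d, "qc_report.tsv")))
  flow <- jsonlite::read_json(file.path(d, "exclusion_flow.json"))
  expect_equal(flow$n_total, 8L)
})
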