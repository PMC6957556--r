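# Quality control: motion metrics and cut-offs, behavioral outlier and
# scan-task interval rules, and common-node harmonization.
#
# Frame-wise motion is summarized with the rigid-body root-mean-square
# displacement over a sphere of radius 80 mm (the mean head size used by
# the FSL motion literature): for the relative transform between
# consecutive volumes with rotation part R and translation b,
# RMS = sqrt(r^2/5 * tr(A'A) + b'b) with A = R - I, which is the exact
# root-mean-square displacement of a uniform solid ball of radius r.

MOTION_RADIUS_MM <- 80

rigidTransform <- function(p) {
  # p: c(rx, ry, rz, tx, ty, tz), rotations rad, translations mm
  cx <- cos(p[1]); sx <- sin(p[1])
  cy <- cos(p[2]); sy <- sin(p[2])
  cz <- cos(p[3]); sz <- sin(p[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  list(R = Rx %*% Ry %*% Rz, t = p[4:6])
}

#' Frame-wise relative RMS displacement
#'
#' Volume-to-volume rigid-body displacement in millimetres: for each
#' transition, the RMS displacement of a solid sphere of radius 80 mm
#' under the relative transform between consecutive volumes.
#'
#' @param motionParams Numeric matrix, volumes x 6: three rotations
#'   (radians) then three translations (mm), per volume.
#' @param radiusMm Reference sphere radius.
#' @return Numeric vector of length `nrow(motionParams) - 1`.
#' @examples
#' framewiseRMS(matrix(0, 10, 6))  # all zeros
#' @export
framewiseRMS <- function(motionParams, radiusMm = MOTION_RADIUS_MM) {
  motionParams <- as.matrix(motionParams)
  stopIfNot(ncol(motionParams) == 6,
            "motion parameters must have 6 columns (3 rot rad, 3 trans mm)")
  stopIfNot(nrow(motionParams) >= 2, "need at least two volumes")
  bad <- which(!apply(motionParams, 1, function(r) all(is.finite(r))))
  if (length(bad))
    stop("malformed motion-parameter row(s): ", paste(bad, collapse = ", "))
  T_ <- nrow(motionParams)
  out <- numeric(T_ - 1)
  prev <- rigidTransform(motionParams[1, ])
  for (t in 2:T_) {
    cur <- rigidTransform(motionParams[t, ])
    Rrel <- cur$R %*% t(prev$R)
    brel <- cur$t - Rrel %*% prev$t
    A <- Rrel - diag(3)
    out[t - 1] <- sqrt(radiusMm^2 / 5 * sum(A * A) + sum(brel^2))
    prev <- cur
  }
  out
}

emptyReasons <- function(n) vector("list", n)

#' Motion-based subject exclusion
#'
#' Flags subjects whose mean relative RMS displacement exceeds
#' `meanThreshMm` (default 0.2 mm) or who have more than `maxSpikes`
#' (default 20) transitions with frame-wise relative RMS above
#' `spikeThreshMm` (default 0.25 mm).
#'
#' @param cohort A [Cohort-class] (or list of subject records).
#' @param meanThreshMm,spikeThreshMm,maxSpikes Thresholds; defaults as
#'   printed above.
#' @return Data frame: `subjectId`, `meanRelRmsMm`, `nSpikeVolumes`,
#'   `kept`, `reasons` (comma-joined machine-readable codes).
#' @export
applyMotionExclusion <- function(cohort, meanThreshMm = 0.2,
                                 spikeThreshMm = 0.25, maxSpikes = 20L) {
  subjects <- if (is(cohort, "Cohort")) cohortSubjects(cohort) else cohort
  rows <- lapply(subjects, function(s) {
    fd <- framewiseRMS(s@motionParams)
    m <- mean(fd)
    k <- sum(fd > spikeThreshMm)
    reasons <- character()
    if (m > meanThreshMm) reasons <- c(reasons, "motion_mean")
    if (k > maxSpikes) reasons <- c(reasons, "motion_spikes")
    data.frame(subjectId = s@subjectId, meanRelRmsMm = m, nSpikeVolumes = k,
               kept = length(reasons) == 0L,
               reasons = paste(reasons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Behavioral and interval exclusion
#'
#' Flags subjects with extreme behavioral scores (|z| >= `zThreshold` on
#' any listed outcome, z computed once over the candidate pool), an
#' interval between scan and task of more than `maxIntervalDays` days, or
#' missing task scores. The z-scores are computed in a single pass: no
#' iterative re-exclusion.
#'
#' @param cohort A [Cohort-class] or list of subject records.
#' @param outcomes Outcome slots checked for outliers (accuracy and RT by
#'   default).
#' @param zThreshold Inclusive z cut-off (`>= 2` excludes).
#' @param maxIntervalDays Exclusive cut-off (`> 21` days excludes).
#' @return Data frame: `subjectId`, `kept`, `reasons`.
#' @export
behavioralExclusion <- function(cohort,
                                outcomes = c("tolAccuracyPct", "tolRtS"),
                                zThreshold = 2, maxIntervalDays = 21L) {
  subjects <- if (is(cohort, "Cohort")) cohortSubjects(cohort) else cohort
  stopIfNot(length(subjects) >= 3, "need >= 3 subjects to estimate SDs")
  vals <- lapply(outcomes, function(o)
    vapply(subjects, function(s) slot(s, o), numeric(1)))
  names(vals) <- outcomes
  z <- lapply(vals, function(v) {
    sdv <- stats::sd(v, na.rm = TRUE)
    if (!is.na(sdv) && sdv == 0)
      stop("zero-variance behavioral outcome; z-scores undefined")
    (v - mean(v, na.rm = TRUE)) / sdv
  })
  rows <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    reasons <- character()
    if (anyNA(vapply(vals, `[`, numeric(1), i)))
      reasons <- c(reasons, "missing_tol")
    else if (any(vapply(z, function(x) abs(x[i]) >= zThreshold, logical(1))))
      reasons <- c(reasons, "behavior_outlier")
    if (s@intervalDays > maxIntervalDays) reasons <- c(reasons, "interval")
    data.frame(subjectId = s@subjectId, kept = length(reasons) == 0L,
               reasons = paste(reasons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Harmonize nodes across subjects
#'
#' Per subject, nodes with fewer than `minVoxels` signal-containing voxels
#' are discarded; the common node set is the order-preserving intersection
#' across all subjects.
#'
#' @param voxelCounts Integer matrix (subjects x nodes, column names =
#'   node ids), or a [Cohort-class], or a list of per-subject named
#'   integer vectors.
#' @param minVoxels Minimum signal-voxel count (default 4; "< 4" drops).
#' @return Character vector of common node ids.
#' @export
harmonizeNodes <- function(voxelCounts, minVoxels = 4L) {
  if (is(voxelCounts, "Cohort"))
    voxelCounts <- lapply(cohortSubjects(voxelCounts), slot, "voxelCounts")
  if (is.list(voxelCounts)) {
    ids <- names(voxelCounts[[1]])
    stopIfNot(!is.null(ids), "voxel counts must be named by node id")
    stopIfNot(all(vapply(voxelCounts, function(v)
      identical(names(v), ids), logical(1))),
      "all subjects must share one node universe")
    voxelCounts <- do.call(rbind, voxelCounts)
  }
  ids <- colnames(voxelCounts)
  keep <- apply(voxelCounts >= minVoxels, 2, all)
  common <- ids[keep]
  if (!length(common))
    stop("node harmonization left no common nodes")
  common
}

#' Full single-pass QC report
#'
#' Combines motion, behavioral and interval rules into one report, with an
#' exclusion-flow summary (counts per reason) attached as
#' `attr(., "flow")`. Each excluded subject carries every reason that
#' applies.
#'
#' @inheritParams applyMotionExclusion
#' @inheritParams behavioralExclusion
#' @return Data frame with one row per subject: `subjectId`,
#'   `meanRelRmsMm`, `nSpikeVolumes`, `kept`, `reasons`.
#' @export
qcReport <- function(cohort, meanThreshMm = 0.2, spikeThreshMm = 0.25,
                     maxSpikes = 20L,
                     outcomes = c("tolAccuracyPct", "tolRtS"),
                     zThreshold = 2, maxIntervalDays = 21L) {
  mot <- applyMotionExclusion(cohort, meanThreshMm, spikeThreshMm, maxSpikes)
  beh <- behavioralExclusion(cohort, outcomes, zThreshold, maxIntervalDays)
  reasons <- mapply(function(a, b) {
    r <- c(strsplit(a, ",")[[1]], strsplit(b, ",")[[1]])
    paste(r[nzchar(r)], collapse = ",")
  }, mot$reasons, beh$reasons, USE.NAMES = FALSE)
  out <- data.frame(subjectId = mot$subjectId,
                    meanRelRmsMm = mot$meanRelRmsMm,
                    nSpikeVolumes = mot$nSpikeVolumes,
                    kept = !nzchar(reasons), reasons = reasons,
                    stringsAsFactors = FALSE)
  allReasons <- c("motion_mean", "motion_spikes", "behavior_outlier",
                  "interval", "missing_tol")
  flow <- vapply(allReasons, function(r)
    sum(vapply(strsplit(out$reasons, ","), function(x) r %in% x, logical(1))),
    numeric(1))
  attr(out, "flow") <- c(list(n_total = nrow(out),
                              n_excluded = sum(!out$kept),
                              n_kept = sum(out$kept)), as.list(flow))
  out
}

#' Write the QC report and exclusion-flow summary
#'
#' @param report Output of [qcReport()].
#' @param dir Output directory; writes `qc_report.tsv` and
#'   `exclusion_flow.json`.
#' @return The directory, invisibly.
#' @export
writeQcReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report, file.path(dir, "qc_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  flow <- attr(report, "flow")
  if (!is.null(flow))
    jsonlite::write_json(flow, file.path(dir, "exclusion_flow.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
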