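#' @import methods
NULL

RSN_NAMES <- c("DMN", "FPN", "DAN", "VAN")
NODE_LABELS <- c(RSN_NAMES, "other")

## ------------------------------------------------------------------------
## WaveletSpec

#' Wavelet-coherence specification
#'
#' Parameters of the continuous wavelet transform and of the coherence
#' smoothing used to build functional-connectivity matrices: a complex
#' Morlet mother wavelet (centre frequency `omega0`), a logarithmic grid of
#' analysis frequencies bracketing the band of interest, Gaussian time
#' smoothing with standard deviation equal to the scale, boxcar smoothing
#' over `scaleSmoothHalfWidth` adjacent scales on each side, and a
#' cone-of-influence policy for edge-affected coefficients.
#'
#' @slot omega0 Morlet centre frequency (dimensionless; default 6).
#' @slot freqs Analysis frequencies in Hz (log-spaced grid).
#' @slot band Length-2 numeric, the averaging band in Hz.
#' @slot coiPolicy `"exclude"` drops edge-affected times from band means;
#'   `"keep"` retains them (for short series).
#' @slot squared Logical; store magnitude-squared coherence (default) or
#'   its square root.
#' @slot scaleSmoothHalfWidth Integer; boxcar half-width in scales.
#' @export
setClass("WaveletSpec",
  representation(omega0 = "numeric", freqs = "numeric", band = "numeric",
                 coiPolicy = "character", squared = "logical",
                 scaleSmoothHalfWidth = "integer"))

setValidity("WaveletSpec", function(object) {
  msg <- character()
  if (length(object@omega0) != 1L || object@omega0 < 4)
    msg <- c(msg, "omega0 must be a single value >= 4 (admissibility)")
  if (length(object@band) != 2L || diff(object@band) <= 0)
    msg <- c(msg, "band must be (low, high) with low < high")
  if (any(diff(object@freqs) <= 0))
    msg <- c(msg, "freqs must be strictly increasing")
  inBand <- object@freqs >= object@band[1] & object@freqs <= object@band[2]
  if (length(object@freqs) < 8L || sum(inBand) < 2L)
    msg <- c(msg, "frequency grid must have >= 8 scales and cover the band")
  if (object@freqs[1] >= object@band[1] || object@freqs[length(object@freqs)] <= object@band[2])
    msg <- c(msg, "band must be interior to the frequency grid")
  if (!object@coiPolicy %in% c("exclude", "keep"))
    msg <- c(msg, "coiPolicy must be 'exclude' or 'keep'")
  if (length(msg)) msg else TRUE
})

#' Construct a WaveletSpec
#'
#' @param omega0 Morlet centre frequency.
#' @param nScales Number of log-spaced analysis frequencies.
#' @param freqRange Range (Hz) spanned by the scale grid; the default
#'   0.04-0.18 Hz leaves the 0.06-0.12 Hz band interior.
#' @param band Averaging band (Hz).
#' @param coiPolicy Cone-of-influence handling, `"exclude"` or `"keep"`.
#' @param squared Store squared coherence?
#' @param scaleSmoothHalfWidth Boxcar half-width (scales).
#' @return A [WaveletSpec-class] object.
#' @examples
#' waveletSpec()
#' @export
waveletSpec <- function(omega0 = 6, nScales = 12L, freqRange = c(0.04, 0.18),
                        band = c(0.06, 0.12),
                        coiPolicy = c("exclude", "keep"), squared = TRUE,
                        scaleSmoothHalfWidth = 1L) {
  coiPolicy <- match.arg(coiPolicy)
  freqs <- exp(seq(log(freqRange[1]), log(freqRange[2]),
                   length.out = as.integer(nScales)))
  new("WaveletSpec", omega0 = omega0, freqs = freqs, band = as.numeric(band),
      coiPolicy = coiPolicy, squared = squared,
      scaleSmoothHalfWidth = as.integer(scaleSmoothHalfWidth))
}

setMethod("show", "WaveletSpec", function(object) {
  cat("WaveletSpec (complex Morlet, omega0 =", object@omega0, ")\n",
      " ", length(object@freqs), "scales,",
      sprintf("%.3f-%.3f Hz; band %.2f-%.2f Hz\n", min(object@freqs),
              max(object@freqs), object@band[1], object@band[2]),
      "  COI:", object@coiPolicy, "; squared coherence:", object@squared, "\n")
})

## ------------------------------------------------------------------------
## CoherenceMatrix

#' Band-averaged wavelet-coherence connectivity matrix
#'
#' Symmetric node-by-node matrix of band-averaged wavelet coherence values
#' in \[0, 1\] with unit diagonal. The diagonal is excluded from all
#' downstream summaries.
#'
#' @slot values Numeric matrix (nodes x nodes).
#' @slot nodeIds Character node labels (row/column order).
#' @slot band Length-2 numeric averaging band in Hz.
#' @export
setClass("CoherenceMatrix",
  representation(values = "matrix", nodeIds = "character", band = "numeric"))

setValidity("CoherenceMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (length(object@nodeIds) != nrow(v))
    msg <- c(msg, "nodeIds length must match matrix dimension")
  if (anyNA(v) || any(!is.finite(v))) msg <- c(msg, "values must be finite")
  else {
    if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "values must be symmetric")
    if (min(v) < -1e-12 || max(v) > 1 + 1e-12)
      msg <- c(msg, "values must lie in [0, 1]")
    if (max(abs(diag(v) - 1)) > 1e-12)
      msg <- c(msg, "diagonal must be fixed to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CoherenceMatrix
#'
#' @param values Symmetric numeric matrix in \[0, 1\].
#' @param nodeIds Node labels; defaults to the matrix dimnames.
#' @param band Averaging band in Hz.
#' @return A [CoherenceMatrix-class].
#' @export
coherenceMatrix <- function(values, nodeIds = rownames(values),
                            band = c(0.06, 0.12)) {
  if (is.null(nodeIds)) nodeIds <- paste0("n", seq_len(nrow(values)))
  diag(values) <- 1
  dimnames(values) <- list(nodeIds, nodeIds)
  new("CoherenceMatrix", values = values, nodeIds = as.character(nodeIds),
      band = as.numeric(band))
}

setMethod("show", "CoherenceMatrix", function(object) {
  off <- object@values[upper.tri(object@values)]
  cat("CoherenceMatrix:", nrow(object@values), "nodes, band",
      sprintf("%.2f-%.2f Hz\n", object@band[1], object@band[2]),
      sprintf("  off-diagonal coherence: mean %.3f, range [%.3f, %.3f]\n",
              mean(off), min(off), max(off)))
})

#' Accessors for CoherenceMatrix
#'
#' `cohValues` returns the numeric matrix; `nodeIds` the node labels.
#'
#' @param x A [CoherenceMatrix-class] or [NetworkPartition-class].
#' @return A matrix or character vector.
#' @export
setGeneric("cohValues", function(x) standardGeneric("cohValues"))

#' @rdname cohValues
#' @export
setMethod("cohValues", "CoherenceMatrix", function(x) x@values)

#' @rdname cohValues
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname cohValues
#' @export
setMethod("nodeIds", "CoherenceMatrix", function(x) x@nodeIds)

## ------------------------------------------------------------------------
## NetworkPartition

#' Node-to-subnetwork partition
#'
#' Assigns every node to one of the four resting-state networks (DMN, FPN,
#' DAN, VAN) or to `"other"` (unassigned cortical, subcortical and
#' cerebellar nodes). The four named networks must each be non-empty.
#'
#' @slot nodeIds Character node labels.
#' @slot labels Character labels, one per node, in
#'   `c("DMN","FPN","DAN","VAN","other")`.
#' @export
setClass("NetworkPartition",
  representation(nodeIds = "character", labels = "character"))

setValidity("NetworkPartition", function(object) {
  msg <- character()
  if (length(object@nodeIds) != length(object@labels))
    msg <- c(msg, "nodeIds and labels must have equal length")
  if (anyDuplicated(object@nodeIds)) msg <- c(msg, "duplicate node ids")
  if (!all(object@labels %in% NODE_LABELS))
    msg <- c(msg, "labels must be DMN/FPN/DAN/VAN/other")
  missing <- setdiff(RSN_NAMES, object@labels)
  if (length(missing))
    msg <- c(msg, paste("empty subnetwork(s):", paste(missing, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a NetworkPartition
#'
#' @param nodeIds Character node labels.
#' @param labels Subnetwork label per node.
#' @return A [NetworkPartition-class].
#' @examples
#' networkPartition(paste0("n", 1:9),
#'                  rep(c("DMN", "FPN", "DAN", "VAN", "other"), c(2, 2, 2, 2, 1)))
#' @export
networkPartition <- function(nodeIds, labels) {
  new("NetworkPartition", nodeIds = as.character(nodeIds),
      labels = as.character(labels))
}

#' @rdname cohValues
#' @export
setMethod("nodeIds", "NetworkPartition", function(x) x@nodeIds)

#' Subnetwork labels of a partition
#'
#' @param x A [NetworkPartition-class].
#' @return Named character vector of labels, names = node ids.
#' @export
setGeneric("partitionLabels", function(x) standardGeneric("partitionLabels"))

#' @rdname partitionLabels
#' @export
setMethod("partitionLabels", "NetworkPartition", function(x) {
  stats::setNames(x@labels, x@nodeIds)
})

#' Restrict a partition to a node subset
#'
#' @param partition A [NetworkPartition-class].
#' @param keep Character node ids to retain (order preserved).
#' @return A [NetworkPartition-class] on the subset.
#' @export
subsetPartition <- function(partition, keep) {
  idx <- match(keep, partition@nodeIds)
  if (anyNA(idx)) stop("unknown node id(s): ",
                       paste(keep[is.na(idx)], collapse = ", "))
  networkPartition(partition@nodeIds[idx], partition@labels[idx])
}

setMethod("show", "NetworkPartition", function(object) {
  tab <- table(factor(object@labels, levels = NODE_LABELS))
  cat("NetworkPartition:", length(object@nodeIds), "nodes\n  ")
  cat(paste(names(tab), tab, sep = "="), sep = "  ")
  cat("\n")
})

## ------------------------------------------------------------------------
## Cohort configuration

#' Synthetic-cohort configuration
#'
#' Holds every tunable of the generator: scan geometry (volumes, TR), the
#' node partition, signal coupling, demographics, the behavioral generating
#' model (expressed through standardized effect sizes), motion severity,
#' planted quality-control violators and the root seed. Defaults emulate the
#' study conditions the analysis assumes: 62 subjects, 192 volumes at
#' TR = 1.8 s, 225 nodes of which 31 fail the voxel-count rule (194 common),
#' age 48.1 +/- 13.9 limited to 21-74 years, Tower of London accuracy
#' 87.7 +/- 7.5 % and reaction time 10.1 +/- 2.1 s with a positive age-RT
#' correlation (standardized 0.5) and a positive network-integration effect
#' on RT (standardized 0.22).
#'
#' @export
setClass("CohortConfig", representation(
  nSubjects = "integer", nVolumes = "integer", trS = "numeric",
  partitionSizes = "integer", couplingWithin = "numeric",
  couplingBetween = "numeric", subjectCouplingShape = "numeric",
  subjectCouplingRange = "numeric", noiseSd = "numeric",
  signalBand = "numeric",
  ageMean = "numeric", ageSd = "numeric", ageRange = "numeric",
  pFemale = "numeric", educationProbs = "numeric", pLeftHanded = "numeric",
  intervalMean = "numeric", intervalSd = "numeric",
  rtMean = "numeric", rtSd = "numeric", betaAgeRt = "numeric",
  betaIntegrationRt = "numeric",
  accMean = "numeric", accSd = "numeric", betaAgeAcc = "numeric",
  betaIntegrationAcc = "numeric",
  trialsPerLevel = "integer", rtLevelSlope = "numeric", rtTrialSd = "numeric",
  accLevelSlope = "numeric",
  motionSeverityMeanlog = "numeric", motionSeveritySdlog = "numeric",
  motionStepTransMm = "numeric", motionStepRotRad = "numeric",
  violatorFracMotion = "numeric", violatorFracBehavior = "numeric",
  violatorFracInterval = "numeric",
  lowSignalNodes = "integer", generateTimeseries = "logical",
  seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (object@trS <= 0) msg <- c(msg, "trS must be > 0")
  if (is.null(names(object@partitionSizes)) ||
      !all(NODE_LABELS %in% names(object@partitionSizes)))
    msg <- c(msg, "partitionSizes must be named DMN/FPN/DAN/VAN/other")
  if (any(object@couplingWithin < 0) || any(object@couplingWithin > 1) ||
      object@couplingBetween < 0 || object@couplingBetween >= 1)
    msg <- c(msg, "coupling parameters must lie in [0, 1]")
  if (max(object@subjectCouplingRange) * max(object@couplingWithin) >= 1)
    msg <- c(msg, "effective node coupling must stay below 1")
  if (object@noiseSd <= 0 || object@rtSd <= 0 || object@accSd <= 0 ||
      object@ageSd <= 0)
    msg <- c(msg, "all spread parameters must be > 0")
  if (object@betaAgeRt^2 + object@betaIntegrationRt^2 >= 1 ||
      object@betaAgeAcc^2 + object@betaIntegrationAcc^2 >= 1)
    msg <- c(msg, "standardized effects must satisfy sum of squares < 1")
  fr <- object@violatorFracMotion + object@violatorFracBehavior +
    object@violatorFracInterval
  if (any(c(object@violatorFracMotion, object@violatorFracBehavior,
            object@violatorFracInterval) < 0) || fr > 1)
    msg <- c(msg, "violator fractions must be >= 0 and sum to <= 1")
  if (object@lowSignalNodes < 0L ||
      object@lowSignalNodes >= sum(object@partitionSizes))
    msg <- c(msg, "lowSignalNodes must leave at least one common node")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortConfig
#'
#' See [CohortConfig-class] for the semantics of each parameter. All
#' behavioral effects are standardized (outcome SDs per predictor SD), so
#' `betaIntegrationRt = 0` yields a null network effect and 0.4 a strong
#' planted one.
#'
#' @param nSubjects Number of subjects.
#' @param nVolumes Time-series length (volumes).
#' @param trS Repetition time in seconds.
#' @param partitionSizes Named integer vector of node counts per label
#'   (DMN, FPN, DAN, VAN, other).
#' @param couplingWithin Named per-RSN multiplier on the subject coupling
#'   (1 = full, 0 = none) for nodes of that label.
#' @param couplingBetween Fraction of shared-signal variance common to all
#'   RSNs (cross-network leakage), in \[0, 1).
#' @param subjectCouplingShape,subjectCouplingRange Beta shape parameters
#'   and range into which the per-subject coupling is mapped.
#' @param noiseSd Private-noise standard deviation before standardization.
#' @param signalBand Band (Hz) of the shared network signals.
#' @param ageMean,ageSd,ageRange Age distribution (years), truncated.
#' @param pFemale,educationProbs,pLeftHanded Demographic distributions
#'   (education on the 7-level Verhage scale).
#' @param intervalMean,intervalSd Days between scan and task.
#' @param rtMean,rtSd,betaAgeRt,betaIntegrationRt Reaction-time model.
#' @param accMean,accSd,betaAgeAcc,betaIntegrationAcc Accuracy model.
#' @param trialsPerLevel Tower of London trials per difficulty level.
#' @param rtLevelSlope,rtTrialSd,accLevelSlope Trial-level behavior.
#' @param motionSeverityMeanlog,motionSeveritySdlog Lognormal subject
#'   motion-severity distribution.
#' @param motionStepTransMm,motionStepRotRad Random-walk step SDs at
#'   severity 1.
#' @param violatorFracMotion,violatorFracBehavior,violatorFracInterval
#'   Fractions of subjects planted to violate each QC rule.
#' @param lowSignalNodes Number of nodes given < 4 signal voxels in at
#'   least one subject (dropped by harmonization).
#' @param generateTimeseries If `FALSE`, skip BOLD simulation (for fast
#'   statistical validation at the regression stage).
#' @param seed Root seed; every draw derives from it.
#' @return A [CohortConfig-class].
#' @examples
#' cfg <- cohortConfig(nSubjects = 10L, generateTimeseries = FALSE)
#' @export
cohortConfig <- function(nSubjects = 62L, nVolumes = 192L, trS = 1.8,
                         partitionSizes = c(DMN = 48L, FPN = 36L, DAN = 30L,
                                            VAN = 26L, other = 85L),
                         couplingWithin = c(DMN = 1, FPN = 1, DAN = 1,
                                            VAN = 1, other = 0),
                         couplingBetween = 0.2,
                         subjectCouplingShape = c(2, 2),
                         subjectCouplingRange = c(0.35, 0.8),
                         noiseSd = 1, signalBand = c(0.06, 0.12),
                         ageMean = 48.1, ageSd = 13.9, ageRange = c(21, 74),
                         pFemale = 0.468,
                         educationProbs = c(0, 0, 1.6, 8, 29, 43.5, 17.7),
                         pLeftHanded = 7 / 61,
                         intervalMean = 6.2, intervalSd = 4.6,
                         rtMean = 10.1, rtSd = 2.1, betaAgeRt = 0.5,
                         betaIntegrationRt = 0.22,
                         accMean = 87.7, accSd = 7.5, betaAgeAcc = -0.24,
                         betaIntegrationAcc = 0,
                         trialsPerLevel = 10L, rtLevelSlope = 1.5,
                         rtTrialSd = 2, accLevelSlope = 0.7,
                         motionSeverityMeanlog = 0,
                         motionSeveritySdlog = 0.35,
                         motionStepTransMm = 0.04,
                         motionStepRotRad = 2.5e-4,
                         violatorFracMotion = 0, violatorFracBehavior = 0,
                         violatorFracInterval = 0,
                         lowSignalNodes = 31L, generateTimeseries = TRUE,
                         seed = 1L) {
  new("CohortConfig",
      nSubjects = as.integer(nSubjects), nVolumes = as.integer(nVolumes),
      trS = trS,
      partitionSizes = stats::setNames(as.integer(partitionSizes),
                                       names(partitionSizes)),
      couplingWithin = couplingWithin, couplingBetween = couplingBetween,
      subjectCouplingShape = subjectCouplingShape,
      subjectCouplingRange = subjectCouplingRange,
      noiseSd = noiseSd, signalBand = signalBand,
      ageMean = ageMean, ageSd = ageSd, ageRange = ageRange,
      pFemale = pFemale, educationProbs = educationProbs,
      pLeftHanded = pLeftHanded,
      intervalMean = intervalMean, intervalSd = intervalSd,
      rtMean = rtMean, rtSd = rtSd, betaAgeRt = betaAgeRt,
      betaIntegrationRt = betaIntegrationRt,
      accMean = accMean, accSd = accSd, betaAgeAcc = betaAgeAcc,
      betaIntegrationAcc = betaIntegrationAcc,
      trialsPerLevel = as.integer(trialsPerLevel),
      rtLevelSlope = rtLevelSlope, rtTrialSd = rtTrialSd,
      accLevelSlope = accLevelSlope,
      motionSeverityMeanlog = motionSeverityMeanlog,
      motionSeveritySdlog = motionSeveritySdlog,
      motionStepTransMm = motionStepTransMm,
      motionStepRotRad = motionStepRotRad,
      violatorFracMotion = violatorFracMotion,
      violatorFracBehavior = violatorFracBehavior,
      violatorFracInterval = violatorFracInterval,
      lowSignalNodes = as.integer(lowSignalNodes),
      generateTimeseries = generateTimeseries, seed = as.integer(seed))
}

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nSubjects, "subjects,",
      object@nVolumes, "volumes @ TR", object@trS, "s,",
      sum(object@partitionSizes), "nodes",
      sprintf("(%d low-signal)\n", object@lowSignalNodes))
  cat("  behavioral effects (standardized): age->RT",
      object@betaAgeRt, "; integration->RT", object@betaIntegrationRt, "\n")
})

## ------------------------------------------------------------------------
## SubjectRecord and Cohort

#' One synthetic participant
#'
#' Demographics, motion trace, parcellated ROI time series, per-node
#' signal-voxel counts, trial-level Tower of London responses and derived
#' behavioral scores.
#'
#' @export
setClass("SubjectRecord", representation(
  subjectId = "character", ageYears = "numeric", sex = "character",
  educationVerhage = "integer", handedness = "character",
  intervalDays = "integer", motionParams = "matrix", timeseries = "ANY",
  voxelCounts = "integer", trials = "data.frame",
  tolAccuracyPct = "numeric", tolRtS = "numeric",
  tolAccuracy45Pct = "numeric", tolRt45S = "numeric"))

setValidity("SubjectRecord", function(object) {
  msg <- character()
  if (object@intervalDays < 0L) msg <- c(msg, "intervalDays must be >= 0")
  if (!object@educationVerhage %in% 1:7)
    msg <- c(msg, "educationVerhage must be in 1..7")
  if (any(object@voxelCounts < 0L)) msg <- c(msg, "voxelCounts must be >= 0")
  if (ncol(object@motionParams) != 6L)
    msg <- c(msg, "motionParams must have six columns")
  if (is.matrix(object@timeseries) &&
      nrow(object@timeseries) != nrow(object@motionParams))
    msg <- c(msg, "timeseries and motionParams must have equal volumes")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SubjectRecord", function(object) {
  cat("SubjectRecord", object@subjectId, ":", object@sex,
      sprintf("%.0f y,", object@ageYears),
      sprintf("ToL acc %.1f%%, RT %.2f s\n", object@tolAccuracyPct,
              object@tolRtS))
})

#' A synthetic cohort
#'
#' List of [SubjectRecord-class]s plus the generating configuration, the
#' node partition and a hidden ground-truth table (per-subject coupling and
#' planted quality-control violations) used only by tests and validation.
#'
#' @slot subjects List of subject records.
#' @slot config The generating [CohortConfig-class].
#' @slot partition Node partition over the full (pre-harmonization) set.
#' @slot nodeIds Full node-id vector.
#' @slot groundTruth Data frame: subject id, latent coupling, severity,
#'   planted violator flags.
#' @export
setClass("Cohort", representation(
  subjects = "list", config = "CohortConfig", partition = "NetworkPartition",
  nodeIds = "character", groundTruth = "data.frame"))

setMethod("show", "Cohort", function(object) {
  cat("Cohort:", length(object@subjects), "subjects,",
      length(object@nodeIds), "nodes",
      if (isTRUE(object@config@generateTimeseries)) "(with time series)\n"
      else "(demographics/behavior only)\n")
})

#' Cohort accessors
#'
#' `cohortSubjects` returns the list of subject records,
#' `cohortGroundTruth` the hidden generator truth, `cohortPartition` the
#' node partition.
#'
#' @param x A [Cohort-class].
#' @return A list, data frame, or [NetworkPartition-class].
#' @export
setGeneric("cohortSubjects", function(x) standardGeneric("cohortSubjects"))

#' @rdname cohortSubjects
#' @export
setMethod("cohortSubjects", "Cohort", function(x) x@subjects)

#' @rdname cohortSubjects
#' @export
setGeneric("cohortGroundTruth", function(x) standardGeneric("cohortGroundTruth"))

#' @rdname cohortSubjects
#' @export
setMethod("cohortGroundTruth", "Cohort", function(x) x@groundTruth)

#' @rdname cohortSubjects
#' @export
setGeneric("cohortPartition", function(x) standardGeneric("cohortPartition"))

#' @rdname cohortSubjects
#' @export
setMethod("cohortPartition", "Cohort", function(x) x@partition)

## ------------------------------------------------------------------------
## BootstrapRegressionResult

#' Result of a bootstrapped hierarchical regression
#'
#' Final-model coefficients with standard errors, standardized betas, BCa
#' 95% confidence intervals and inversion-based bootstrap P values, plus
#' the R-squared of every nested model.
#'
#' @slot outcome Outcome variable name.
#' @slot coefficients Data frame: term, block, B, SE, beta, ciLow, ciHigh,
#'   pBca.
#' @slot r2 Numeric vector of nested-model R-squared values.
#' @slot nBoot Number of bootstrap replicates.
#' @slot nObs Number of observations used (after listwise deletion).
#' @slot seed Seed used for resampling.
#' @slot notes Character warnings (e.g. clamped bias correction).
#' @export
setClass("BootstrapRegressionResult", representation(
  outcome = "character", coefficients = "data.frame", r2 = "numeric",
  nBoot = "integer", nObs = "integer", seed = "integer",
  notes = "character"))

setMethod("show", "BootstrapRegressionResult", function(object) {
  cat("Bootstrapped hierarchical regression of", object@outcome,
      sprintf("(n = %d, %d replicates)\n", object@nObs, object@nBoot))
  co <- object@coefficients
  cat(sprintf("  %-22s %9s (%8s) [%8s, %8s] %7s %7s\n", "term", "B", "SE",
              "CI low", "CI high", "Beta", "P_bca"))
  for (i in seq_len(nrow(co)))
    cat(sprintf("  %-22s %9.3f (%8.3f) [%8.3f, %8.3f] %7.3f %7.3f\n",
                co$term[i], co$B[i], co$SE[i], co$ciLow[i], co$ciHigh[i],
                co$beta[i], co$pBca[i]))
  cat("  nested-model R2:", paste(sprintf("%.3f", object@r2), collapse = " -> "),
      "\n")
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "),
                                "\n")
})

#' Coefficient table of a bootstrap regression
#'
#' @param x A [BootstrapRegressionResult-class].
#' @return Data frame with columns term, block, B, SE, beta, ciLow, ciHigh,
#'   pBca.
#' @export
setGeneric("regressionCoefficients",
           function(x) standardGeneric("regressionCoefficients"))

#' @rdname regressionCoefficients
#' @export
setMethod("regressionCoefficients", "BootstrapRegressionResult",
          function(x) x@coefficients)

#' @rdname regressionCoefficients
#' @export
setGeneric("modelR2", function(x) standardGeneric("modelR2"))

#' @rdname regressionCoefficients
#' @export
setMethod("modelR2", "BootstrapRegressionResult", function(x) x@r2)
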