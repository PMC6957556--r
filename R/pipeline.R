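# End-to-end orchestration: simulate (or ingest) -> QC -> harmonize ->
# connectivity -> graph metrics -> bootstrapped regression, with one root
# seed, per-stage outputs and a machine-readable provenance trail. All
# outputs are deterministic functions of the configuration, so re-running
# from the same config reproduces the result tree bit-identically (no
# timestamps are written).

#' Pipeline configuration
#'
#' Bundles the cohort generator configuration, the wavelet spec, the
#' quality-control thresholds, the regression setup and the root seed.
#' The default emulates the target study design at a tractable node
#' count: 62 subjects, 192 volumes at TR = 1.8 s, 60 nodes across
#' DMN/FPN/DAN/VAN plus unassigned nodes.
#'
#' @export
setClass("PipelineConfig", representation(
  cohort = "CohortConfig", wavelet = "WaveletSpec", measures = "character",
  outcomes = "character", sensitivity = "character", nBoot = "integer",
  lengthTransform = "character", qc = "list", seed = "integer"))

ALL_MEASURES <- function() {
  c("GE", "Gcc", paste0("eff_", RSN_NAMES), paste0("clust_", RSN_NAMES),
    paste0("within_", RSN_NAMES),
    paste0("between_", apply(utils::combn(RSN_NAMES, 2), 2, paste,
                             collapse = "_")))
}

#' Construct a PipelineConfig
#'
#' @param cohort A [CohortConfig-class]; the default is the 60-node,
#'   62-subject emulation.
#' @param wavelet A [WaveletSpec-class].
#' @param measures Network measures to model (default: all 20 — global,
#'   per-subnetwork, within- and between-network).
#' @param outcomes `"all_levels"`, `"steps_4_5"`, or `"both"`.
#' @param sensitivity Optional fourth regression block (`"none"`,
#'   `"sex"`, `"education"`).
#' @param nBoot Bootstrap replicates per model.
#' @param lengthTransform Edge-length convention for efficiency.
#' @param qc Named list of QC thresholds (`meanThreshMm`,
#'   `spikeThreshMm`, `maxSpikes`, `zThreshold`, `maxIntervalDays`).
#' @param seed Root seed; stage substreams derive from it.
#' @return A [PipelineConfig-class].
#' @export
pipelineConfig <- function(cohort = cohortConfig(
                             partitionSizes = c(DMN = 16L, FPN = 14L,
                                                DAN = 12L, VAN = 10L,
                                                other = 8L),
                             lowSignalNodes = 0L),
                           wavelet = waveletSpec(),
                           measures = ALL_MEASURES(),
                           outcomes = c("all_levels", "steps_4_5", "both"),
                           sensitivity = c("none", "sex", "education"),
                           nBoot = 2000L,
                           lengthTransform = c("inverse", "neglog"),
                           qc = list(), seed = 1L) {
  outcomes <- match.arg(outcomes)
  sensitivity <- match.arg(sensitivity)
  lengthTransform <- match.arg(lengthTransform)
  qcDefaults <- list(meanThreshMm = 0.2, spikeThreshMm = 0.25,
                     maxSpikes = 20L, zThreshold = 2, maxIntervalDays = 21L)
  qc <- utils::modifyList(qcDefaults, qc)
  cohort@seed <- as.integer(seed)
  new("PipelineConfig", cohort = cohort, wavelet = wavelet,
      measures = measures, outcomes = outcomes, sensitivity = sensitivity,
      nBoot = as.integer(nBoot), lengthTransform = lengthTransform,
      qc = qc, seed = as.integer(seed))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig: seed", object@seed, "\n")
  show(object@cohort)
  show(object@wavelet)
  cat("  outcomes:", object@outcomes, "; measures:",
      length(object@measures), "; nBoot:", object@nBoot, "\n")
})

pipelineConfigAsList <- function(config) {
  list(cohort = configAsList(config@cohort),
       wavelet = list(omega0 = config@wavelet@omega0,
                      freqs = config@wavelet@freqs,
                      band = config@wavelet@band,
                      coiPolicy = config@wavelet@coiPolicy,
                      squared = config@wavelet@squared,
                      scaleSmoothHalfWidth =
                        config@wavelet@scaleSmoothHalfWidth),
       measures = config@measures, outcomes = config@outcomes,
       sensitivity = config@sensitivity, nBoot = config@nBoot,
       lengthTransform = config@lengthTransform, qc = config@qc,
       seed = config@seed)
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config A [PipelineConfig-class].
#' @param path JSON path.
#' @return The path, or the reconstructed [PipelineConfig-class].
#' @export
writePipelineConfig <- function(config, path) {
  jsonlite::write_json(pipelineConfigAsList(config), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  cc <- l$cohort
  cohort <- cohortConfig(
    nSubjects = cc$nSubjects, nVolumes = cc$nVolumes, trS = cc$trS,
    partitionSizes = unlist(cc$partitionSizes),
    couplingWithin = unlist(cc$couplingWithin),
    couplingBetween = cc$couplingBetween,
    subjectCouplingShape = cc$subjectCouplingShape,
    subjectCouplingRange = cc$subjectCouplingRange, noiseSd = cc$noiseSd,
    signalBand = cc$signalBand, ageMean = cc$ageMean, ageSd = cc$ageSd,
    ageRange = cc$ageRange, pFemale = cc$pFemale,
    educationProbs = cc$educationProbs, pLeftHanded = cc$pLeftHanded,
    intervalMean = cc$intervalMean, intervalSd = cc$intervalSd,
    rtMean = cc$rtMean, rtSd = cc$rtSd, betaAgeRt = cc$betaAgeRt,
    betaIntegrationRt = cc$betaIntegrationRt, accMean = cc$accMean,
    accSd = cc$accSd, betaAgeAcc = cc$betaAgeAcc,
    betaIntegrationAcc = cc$betaIntegrationAcc,
    trialsPerLevel = cc$trialsPerLevel, rtLevelSlope = cc$rtLevelSlope,
    rtTrialSd = cc$rtTrialSd, accLevelSlope = cc$accLevelSlope,
    motionSeverityMeanlog = cc$motionSeverityMeanlog,
    motionSeveritySdlog = cc$motionSeveritySdlog,
    motionStepTransMm = cc$motionStepTransMm,
    motionStepRotRad = cc$motionStepRotRad,
    violatorFracMotion = cc$violatorFracMotion,
    violatorFracBehavior = cc$violatorFracBehavior,
    violatorFracInterval = cc$violatorFracInterval,
    lowSignalNodes = cc$lowSignalNodes,
    generateTimeseries = cc$generateTimeseries, seed = cc$seed)
  wl <- l$wavelet
  wavelet <- new("WaveletSpec", omega0 = wl$omega0, freqs = wl$freqs,
                 band = wl$band, coiPolicy = wl$coiPolicy,
                 squared = wl$squared,
                 scaleSmoothHalfWidth = as.integer(wl$scaleSmoothHalfWidth))
  pipelineConfig(cohort = cohort, wavelet = wavelet,
                 measures = l$measures, outcomes = l$outcomes,
                 sensitivity = l$sensitivity, nBoot = l$nBoot,
                 lengthTransform = l$lengthTransform, qc = l$qc,
                 seed = l$seed)
}

outcomeColumns <- function(outcomes) {
  cols <- list(all_levels = c(rt = "tol_rt_s", acc = "tol_accuracy_pct"),
               steps_4_5 = c(rt = "tol_rt_45_s", acc = "tol_accuracy_45_pct"))
  switch(outcomes, all_levels = cols["all_levels"],
         steps_4_5 = cols["steps_4_5"], both = cols)
}

## --- stages ------------------------------------------------------------

#' Pipeline stages
#'
#' Each stage mirrors one analysis step, reads its inputs from the
#' preceding stage and writes the documented TSV/JSON outputs into
#' `outDir`. `runPipeline` composes them; calling the stages manually
#' yields byte-identical results.
#'
#' @param config A [PipelineConfig-class].
#' @param outDir Result directory.
#' @param cohort A [Cohort-class] (from [stageSimulate()]).
#' @param keptIds Subject ids retained by QC.
#' @param commonNodes Harmonized node ids.
#' @param matrices Named list of [CoherenceMatrix-class] per subject.
#' @param metricsTable Analysis table from [stageMetrics()].
#' @return Each stage returns its primary product (see details);
#'   `stageStats` returns a named list of
#'   [BootstrapRegressionResult-class] objects.
#' @export
stageSimulate <- function(config, outDir) {
  cohort <- generateCohort(config@cohort)
  writeCohort(cohort, file.path(outDir, "cohort"))
  cohort
}

#' @rdname stageSimulate
#' @export
stageQc <- function(config, cohort, outDir) {
  q <- config@qc
  rep <- qcReport(cohort, meanThreshMm = q$meanThreshMm,
                  spikeThreshMm = q$spikeThreshMm, maxSpikes = q$maxSpikes,
                  zThreshold = q$zThreshold,
                  maxIntervalDays = q$maxIntervalDays)
  writeQcReport(rep, file.path(outDir, "qc"))
  rep
}

#' @rdname stageSimulate
#' @export
stageConnect <- function(config, cohort, keptIds, outDir) {
  common <- harmonizeNodes(cohort)
  dir.create(file.path(outDir, "connectivity"), recursive = TRUE,
             showWarnings = FALSE)
  jsonlite::write_json(list(common_nodes = common),
                       file.path(outDir, "connectivity",
                                 "common_nodes.json"),
                       auto_unbox = FALSE, digits = NA)
  subjects <- cohortSubjects(cohort)
  names(subjects) <- vapply(subjects, slot, "", "subjectId")
  mats <- list()
  for (id in keptIds) {
    s <- subjects[[id]]
    stopIfNot(is.matrix(s@timeseries),
              paste("subject", id, "has no time series"))
    X <- s@timeseries[, common, drop = FALSE]
    m <- connectivityMatrix(X, config@cohort@trS, config@wavelet)
    writeCoherenceMatrix(m, file.path(outDir, "connectivity",
                                      paste0(id, "_fc.tsv")),
                         spec = config@wavelet)
    mats[[id]] <- m
  }
  mats
}

#' @rdname stageSimulate
#' @export
stageMetrics <- function(config, cohort, matrices, outDir) {
  common <- nodeIds(matrices[[1]])
  part <- subsetPartition(cohortPartition(cohort), common)
  rows <- lapply(names(matrices), function(id)
    cbind(subjectId = id,
          topologyMetrics(matrices[[id]], part, config@lengthTransform)))
  met <- do.call(rbind, rows)
  tab <- merge(cohortTable(cohort), met, by = "subjectId", sort = FALSE)
  tab <- tab[match(names(matrices), tab$subjectId), ]
  dir.create(file.path(outDir, "metrics"), showWarnings = FALSE)
  utils::write.table(tab, file.path(outDir, "metrics", "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}

# FDR families: the global measures are uncorrected; subnetwork topology
# (8 tests), within-network FC (4) and between-network FC (6) each form
# their own family, per outcome.
fdrFamilies <- function(measures) {
  list(subnetwork = grep("^(eff|clust)_", measures, value = TRUE),
       within = grep("^within_", measures, value = TRUE),
       between = grep("^between_", measures, value = TRUE))
}

#' @rdname stageSimulate
#' @export
stageStats <- function(config, metricsTable, outDir) {
  dir.create(file.path(outDir, "stats"), showWarnings = FALSE)
  outs <- outcomeColumns(config@outcomes)
  results <- list()
  pJson <- list()
  k <- 0L
  for (ocSet in names(outs)) for (oc in outs[[ocSet]]) {
    rows <- list()
    praw <- stats::setNames(numeric(length(config@measures)),
                            config@measures)
    for (ms in config@measures) {
      k <- k + 1L
      br <- bootstrapRegression(metricsTable, oc,
                                regressionBlocks(ms, config@sensitivity),
                                nBoot = config@nBoot,
                                seed = deriveSeed(config@seed, 5000 + k))
      results[[paste(oc, ms, sep = ".")]] <- br
      co <- regressionCoefficients(br)
      co <- cbind(measure = ms, co,
                  R2 = modelR2(br)[length(modelR2(br))])
      rows[[ms]] <- co
      praw[ms] <- co$pBca[co$term == ms]
    }
    tab <- do.call(rbind, rows)
    utils::write.table(tab, file.path(outDir, "stats",
                                      paste0("model_", oc, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fam <- fdrFamilies(config@measures)
    adj <- list(global = as.list(praw[intersect(c("GE", "Gcc"),
                                                names(praw))]))
    for (f in names(fam)) if (length(fam[[f]])) {
      fd <- fdrBH(praw[fam[[f]]], labels = fam[[f]])
      adj[[f]] <- stats::setNames(as.list(fd$pAdj), fd$label)
    }
    pJson[[oc]] <- list(raw = as.list(praw), fdr_adjusted = adj)
  }
  jsonlite::write_json(pJson, file.path(outDir, "stats", "pvalues.json"),
                       auto_unbox = TRUE, digits = NA)
  results
}

#' Run the full analysis pipeline
#'
#' Simulate -> QC -> harmonize -> connectivity -> network measures ->
#' bootstrapped hierarchical regression with FDR control, writing
#' per-stage outputs, the serialized configuration and an exclusion-flow
#' summary under `outDir`. Deterministic: the result tree depends only on
#' the configuration.
#'
#' @param config A [PipelineConfig-class].
#' @param outDir Output directory (created if needed).
#' @return Invisibly, a list: `cohort`, `qc`, `matrices`, `metrics`,
#'   `regressions`, `outDir`.
#' @export
runPipeline <- function(config, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writePipelineConfig(config, file.path(outDir, "config.json"))
  log <- character()
  logStage <- function(...) log <<- c(log, paste0(...))
  logStage("pipeline seed=", config@seed)
  cohort <- stageSimulate(config, outDir)
  logStage("simulate: n=", length(cohortSubjects(cohort)), " nodes=",
           length(cohort@nodeIds))
  qc <- stageQc(config, cohort, outDir)
  keptIds <- qc$subjectId[qc$kept]
  logStage("qc: kept ", length(keptIds), "/", nrow(qc))
  stopIfNot(length(keptIds) >= 8, "too few subjects survive QC")
  mats <- stageConnect(config, cohort, keptIds, outDir)
  logStage("connectivity: ", length(mats), " matrices, ",
           length(nodeIds(mats[[1]])), " common nodes")
  met <- stageMetrics(config, cohort, mats, outDir)
  logStage("metrics: ", nrow(met), " rows, ", ncol(met), " columns")
  reg <- stageStats(config, met, outDir)
  logStage("stats: ", length(reg), " models, nBoot=", config@nBoot)
  writeLines(log, file.path(outDir, "log.txt"))
  invisible(list(cohort = cohort, qc = qc, matrices = mats, metrics = met,
                 regressions = reg, outDir = outDir))
}
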