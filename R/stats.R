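# Inferential machinery: distribution-aware correlations, bootstrapped
# hierarchical multiple regression with BCa confidence intervals and
# inversion-based bootstrap P values, standardized betas, nested-model
# R-squared, partial-correlation residualization, and Benjamini-Hochberg
# FDR control.

#' Correlation with distribution-aware method choice
#'
#' Pearson's r, Spearman's rho, or automatic selection: `"auto"` uses
#' Spearman whenever either variable fails a Shapiro-Wilk normality check
#' at alpha = 0.05.
#'
#' @param x,y Numeric vectors (n >= 4, finite, non-constant).
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @return List: `estimate`, `p`, `method`.
#' @examples
#' correlate(1:10, (1:10)^3, method = "spearman")$estimate  # 1
#' @export
correlate <- function(x, y, method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  stopIfNot(length(x) == length(y) && length(x) >= 4,
            "need paired vectors of length >= 4")
  stopIfNot(all(is.finite(x)) && all(is.finite(y)), "inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input; correlation undefined")
  if (method == "auto") {
    normal <- function(v) stats::shapiro.test(v)$p.value >= 0.05
    method <- if (normal(x) && normal(y)) "pearson" else "spearman"
  }
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(estimate = unname(ct$estimate), p = ct$p.value, method = method)
}

#' Predictor blocks for the hierarchical regression
#'
#' The default ordering enters age first, the network measure of interest
#' second and mean RMS motion third; a sensitivity block adds sex or
#' education fourth.
#'
#' @param measure Column name of the network measure.
#' @param sensitivity `"none"`, `"sex"` or `"education"`.
#' @return List of character vectors, one per block.
#' @export
regressionBlocks <- function(measure, sensitivity = c("none", "sex",
                                                      "education")) {
  sensitivity <- match.arg(sensitivity)
  blocks <- list("age_years", measure, "motion_mean_rms")
  if (sensitivity != "none") blocks <- c(blocks, list(sensitivity))
  blocks
}

checkBlocks <- function(blocks) {
  stopIfNot(length(blocks) >= 1 && all(lengths(blocks) > 0),
            "blocks must be non-empty")
  preds <- unlist(blocks)
  if (anyDuplicated(preds))
    stop("predictor repeated across blocks: ",
         paste(unique(preds[duplicated(preds)]), collapse = ", "))
  preds
}

buildModelFrame <- function(data, outcome, blocks) {
  preds <- checkBlocks(blocks)
  cols <- c(outcome, preds)
  missing <- setdiff(cols, names(data))
  if (length(missing)) stop("missing column(s): ",
                            paste(missing, collapse = ", "))
  df <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
             drop = FALSE]
  # character covariates (e.g. sex) become 0/1 indicators
  for (cl in names(df)) if (is.character(df[[cl]]) || is.factor(df[[cl]]))
    df[[cl]] <- as.numeric(factor(df[[cl]])) - 1
  stopIfNot(nrow(df) > length(preds) + 1,
            "need more observations than predictors")
  df
}

#' Hierarchical (nested-block) OLS fits
#'
#' Fits the sequence block 1, blocks 1-2, blocks 1-3, ... by ordinary
#' least squares after listwise deletion, reporting unstandardized
#' coefficients, standard errors, standardized betas and R-squared per
#' model; the final model's coefficients are the headline outputs.
#'
#' @param data Data frame.
#' @param outcome Outcome column name.
#' @param blocks List of character vectors of predictor names, entered
#'   cumulatively.
#' @return List: `models` (one coefficient data frame per nested model),
#'   `r2` (numeric vector), `finalFit` (the `lm` object), `data` (the
#'   model frame used).
#' @export
hierarchicalFit <- function(data, outcome, blocks) {
  df <- buildModelFrame(data, outcome, blocks)
  ySd <- stats::sd(df[[outcome]])
  models <- list()
  r2 <- numeric(length(blocks))
  fit <- NULL
  for (m in seq_along(blocks)) {
    preds <- unlist(blocks[seq_len(m)])
    fo <- stats::reformulate(preds, response = outcome)
    fit <- stats::lm(fo, data = df)
    if (anyNA(stats::coef(fit)))
      stop("rank-deficient design; collinear column(s): ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                 collapse = ", "))
    sm <- summary(fit)
    co <- sm$coefficients
    terms <- rownames(co)[-1]
    models[[m]] <- data.frame(
      term = terms, block = match(terms, unlist(blocks)),
      B = co[-1, 1], SE = co[-1, 2],
      beta = vapply(terms, function(tm)
        standardizedBeta(co[tm, 1], stats::sd(df[[tm]]), ySd), numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
    r2[m] <- sm$r.squared
  }
  list(models = models, r2 = r2, finalFit = fit, data = df)
}

#' Standardized regression coefficient
#'
#' `beta = B * sd(x) / sd(y)`, computed on the original (non-bootstrap)
#' sample.
#'
#' @param B Unstandardized coefficient.
#' @param xSd,ySd Predictor and outcome standard deviations (> 0).
#' @return Scalar beta.
#' @export
standardizedBeta <- function(B, xSd, ySd) {
  stopIfNot(xSd > 0 && ySd > 0, "standard deviations must be > 0")
  B * xSd / ySd
}

# Bias-correction and acceleration constants.
bcaConstants <- function(estimate, replicates, jackknife) {
  B <- length(replicates)
  # ties with the estimate split evenly so exact symmetry gives z0 = 0
  propBelow <- (sum(replicates < estimate) +
                  0.5 * sum(replicates == estimate)) / B
  clamped <- FALSE
  if (propBelow <= 0 || propBelow >= 1) {
    propBelow <- min(max(propBelow, 1 / (2 * B)), 1 - 1 / (2 * B))
    clamped <- TRUE
  }
  z0 <- stats::qnorm(propBelow)
  jm <- mean(jackknife)
  d <- jm - jackknife
  denom <- sum(d^2)^1.5
  a <- if (denom == 0) 0 else sum(d^3) / (6 * denom)
  list(z0 = z0, a = a, clamped = clamped)
}

bcaProbs <- function(z0, a, alphas) {
  z <- z0 + stats::qnorm(alphas)
  stats::pnorm(z0 + z / (1 - a * z))
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Endpoints at the BCa-adjusted percentiles of the bootstrap
#' distribution, with bias correction `z0` from the fraction of
#' replicates below the point estimate and acceleration `a` from the
#' jackknife skewness. When every replicate falls on one side of the
#' estimate, `z0` is clamped to the value implied by half a replicate
#' (reported via `attr(., "clamped")`).
#'
#' @param estimate Point estimate on the full sample.
#' @param replicates Numeric bootstrap replicates (>= 1000 recommended).
#' @param jackknife Leave-one-out estimates.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lower, upper)` with attributes `z0`, `a`,
#'   `clamped`.
#' @examples
#' set.seed(1)
#' x <- rnorm(30)
#' reps <- replicate(2000, mean(sample(x, replace = TRUE)))
#' jack <- vapply(seq_along(x), function(i) mean(x[-i]), numeric(1))
#' bcaInterval(mean(x), reps, jack)
#' @export
bcaInterval <- function(estimate, replicates, jackknife, level = 0.95) {
  stopIfNot(all(is.finite(replicates)), "replicates must be finite")
  if (stats::sd(replicates) == 0)
    stop("zero-variance bootstrap replicates; interval undefined")
  k <- bcaConstants(estimate, replicates, jackknife)
  alphas <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- stats::quantile(replicates, bcaProbs(k$z0, k$a, alphas),
                        names = FALSE, type = 7)
  structure(qs, z0 = k$z0, a = k$a, clamped = k$clamped)
}

# Bootstrap P by confidence-interval inversion: the smallest alpha (on a
# grid of step 0.001, floored at 1/nBoot) at which the 1 - alpha BCa
# interval excludes zero.
bcaPvalue <- function(estimate, replicates, jackknife) {
  if (stats::sd(replicates) == 0)
    stop("zero-variance bootstrap replicates; P value undefined")
  B <- length(replicates)
  k <- bcaConstants(estimate, replicates, jackknife)
  floorP <- max(1 / B, 0.001)
  alphas <- seq(ceiling(floorP * 1000) / 1000, 0.999, by = 0.001)
  lo <- stats::quantile(replicates, bcaProbs(k$z0, k$a, alphas / 2),
                        names = FALSE, type = 7)
  hi <- stats::quantile(replicates, bcaProbs(k$z0, k$a, 1 - alphas / 2),
                        names = FALSE, type = 7)
  excl <- lo > 0 | hi < 0
  if (!any(excl)) return(1)
  p <- alphas[which(excl)[1]]
  if (p <= alphas[1] && 1 / B >= p) attr(p, "belowFloor") <- TRUE
  p
}

#' Bootstrapped hierarchical regression
#'
#' Case-resampling bootstrap (whole rows) of the final nested model:
#' every coefficient gets a 95% BCa confidence interval and an
#' inversion-based bootstrap P value (`pBca`); standardized betas and
#' per-block R-squared come from the original sample. Deterministic given
#' `seed`.
#'
#' @inheritParams hierarchicalFit
#' @param nBoot Bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return A [BootstrapRegressionResult-class].
#' @examples
#' d <- data.frame(age_years = rnorm(50), GE = rnorm(50),
#'                 motion_mean_rms = rnorm(50))
#' d$tol_rt_s <- 10 + 0.1 * d$age_years + rnorm(50)
#' bootstrapRegression(d, "tol_rt_s", regressionBlocks("GE"),
#'                     nBoot = 200, seed = 1)
#' @export
bootstrapRegression <- function(data, outcome, blocks, nBoot = 2000L,
                                seed = 1L, level = 0.95) {
  hf <- hierarchicalFit(data, outcome, blocks)
  df <- hf$data
  n <- nrow(df)
  preds <- unlist(blocks)
  X <- cbind(`(Intercept)` = 1, as.matrix(df[, preds, drop = FALSE]))
  y <- df[[outcome]]
  p <- ncol(X)
  boots <- withSeed(seed, {
    out <- matrix(NA_real_, nBoot, p, dimnames = list(NULL, colnames(X)))
    singular <- 0L
    for (b in seq_len(nBoot)) {
      idx <- sample.int(n, n, replace = TRUE)
      fit <- stats::.lm.fit(X[idx, , drop = FALSE], y[idx])
      if (fit$rank < p) { singular <- singular + 1L; next }
      out[b, ] <- fit$coefficients
    }
    if (singular > 0.01 * nBoot)
      stop(singular, " of ", nBoot, " bootstrap fits were rank-deficient; ",
           "design too unstable to bootstrap")
    out[stats::complete.cases(out), , drop = FALSE]
  })
  jack <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(X)))
  for (i in seq_len(n))
    jack[i, ] <- stats::.lm.fit(X[-i, , drop = FALSE], y[-i])$coefficients
  final <- hf$models[[length(hf$models)]]
  notes <- character()
  ciLow <- ciHigh <- pB <- numeric(nrow(final))
  for (r in seq_len(nrow(final))) {
    tm <- final$term[r]
    est <- final$B[r]
    ci <- bcaInterval(est, boots[, tm], jack[, tm], level = level)
    if (isTRUE(attr(ci, "clamped")))
      notes <- c(notes, paste0("clamped z0 for ", tm))
    ciLow[r] <- ci[1]
    ciHigh[r] <- ci[2]
    pB[r] <- as.numeric(bcaPvalue(est, boots[, tm], jack[, tm]))
  }
  co <- cbind(final, ciLow = ciLow, ciHigh = ciHigh, pBca = pB)
  new("BootstrapRegressionResult", outcome = outcome, coefficients = co,
      r2 = hf$r2, nBoot = as.integer(nBoot), nObs = as.integer(n),
      seed = as.integer(seed), notes = notes)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up adjusted P values via `stats::p.adjust(method = "BH")`, with
#' rejection flags at the target false-discovery rate.
#'
#' @param pvalues Numeric P values in \[0, 1\].
#' @param labels Optional test labels.
#' @param q Target FDR (default 0.05).
#' @return Data frame: `label`, `p`, `pAdj`, `reject`.
#' @examples
#' fdrBH(c(0.001, 0.02, 0.8), c("a", "b", "c"))
#' @export
fdrBH <- function(pvalues, labels = names(pvalues), q = 0.05) {
  stopIfNot(all(is.finite(pvalues)) && all(pvalues >= 0 & pvalues <= 1),
            "P values must lie in [0, 1]")
  if (is.null(labels)) labels <- paste0("test", seq_along(pvalues))
  adj <- stats::p.adjust(pvalues, method = "BH")
  data.frame(label = labels, p = pvalues, pAdj = adj, reject = adj <= q,
             stringsAsFactors = FALSE)
}

#' Residualize an outcome/predictor pair on covariates
#'
#' OLS residuals of `y` and of `x` after regression on the covariates;
#' their Pearson correlation is the partial correlation (the quantity
#' behind a partial-correlation plot).
#'
#' @param data Data frame.
#' @param y,x Column names.
#' @param covariates Character vector of covariate columns.
#' @return List: `table` (data frame `yRes`, `xRes`), `partialR` (`NA`
#'   with a warning when a residual vector is essentially zero).
#' @export
residualizePair <- function(data, y, x, covariates) {
  df <- buildModelFrame(data, y, list(c(x, covariates)))
  ry <- stats::resid(stats::lm(stats::reformulate(covariates, y), data = df))
  rx <- stats::resid(stats::lm(stats::reformulate(covariates, x), data = df))
  if (stats::sd(ry) < 1e-10 * max(1, stats::sd(df[[y]])) ||
      stats::sd(rx) < 1e-10 * max(1, stats::sd(df[[x]]))) {
    warning("residual vector is essentially zero; partial correlation ",
            "undefined")
    pr <- NA_real_
  } else pr <- stats::cor(ry, rx)
  list(table = data.frame(yRes = ry, xRes = rx), partialR = pr)
}
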