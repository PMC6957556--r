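# Wavelet-coherence functional connectivity.
#
# The transform is a complex Morlet continuous wavelet transform computed
# in the frequency domain (zero-padded FFT). Coherence is the
# magnitude-squared cross-spectrum normalized by the smoothed
# auto-spectra:
#
#   C(s,t) = |S(Wx Wy*)|^2 / ( S(|Wx|^2) S(|Wy|^2) )
#
# with S a Gaussian smoother in time (SD equal to the scale) followed by a
# boxcar over adjacent scales. Smoothing is mandatory: without it the
# magnitude coherence is identically 1 at every point. Band-averaged
# values over 0.06-0.12 Hz, with cone-of-influence exclusion, are the
# stored connectivity weights.

morletFourierFactor <- function(omega0) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

morletScales <- function(spec) {
  1 / (spec@freqs * morletFourierFactor(spec@omega0))  # seconds
}

# CWT of every column of X (T x nodes) at all scales of the spec.
# Returns a list (one complex T x nodes matrix per scale).
cwtAll <- function(X, trS, spec) {
  T_ <- nrow(X)
  stopIfNot(T_ >= 64, "time series must have at least 64 volumes")
  stopIfNot(all(is.finite(X)), "non-finite samples in input time series")
  nyq <- 1 / (2 * trS)
  stopIfNot(max(spec@freqs) < nyq,
            sprintf("scale grid exceeds the Nyquist frequency (%.3f Hz)", nyq))
  scales <- morletScales(spec)
  npad <- 2^ceiling(log2(T_))
  Xp <- rbind(X, matrix(0, npad - T_, ncol(X)))
  FX <- stats::mvfft(Xp)
  k <- c(0:(npad / 2), -((npad / 2 - 1):1)) * (2 * pi / (npad * trS))
  pos <- k > 0
  lapply(scales, function(sc) {
    psi <- numeric(npad)
    psi[pos] <- pi^(-0.25) * sqrt(2 * pi * sc / trS) *
      exp(-(sc * k[pos] - spec@omega0)^2 / 2)
    W <- stats::mvfft(FX * psi, inverse = TRUE) / npad
    W[seq_len(T_), , drop = FALSE]
  })
}

#' Continuous wavelet transform of one series
#'
#' Complex Morlet coefficients at the spec's scale grid; linear in the
#' input.
#'
#' @param x Numeric series (length >= 64).
#' @param trS Sampling interval in seconds (the fMRI repetition time).
#' @param spec A [WaveletSpec-class].
#' @return Complex matrix, scales x time; `attr(., "freqsHz")` gives the
#'   per-row analysis frequencies.
#' @examples
#' W <- waveletTransform(sin(2 * pi * 0.09 * (0:127) * 1.8), 1.8, waveletSpec())
#' dim(W)
#' @export
waveletTransform <- function(x, trS, spec = waveletSpec()) {
  W <- cwtAll(cbind(as.numeric(x)), trS, spec)
  out <- t(vapply(W, function(m) m[, 1], complex(length(x))))
  attr(out, "freqsHz") <- spec@freqs
  out
}

# Gaussian time smoother per scale, FFT convolution with edge
# renormalization so that the kernel integrates to 1 inside the record.
makeTimeSmoother <- function(T_, trS, sc) {
  half <- min(T_ - 1L, ceiling(4 * sc / trS))
  t <- (-half:half) * trS
  ker <- exp(-t^2 / (2 * sc^2))
  ker <- ker / sum(ker)
  L <- length(ker)
  npad <- 2^ceiling(log2(T_ + L))
  K <- stats::fft(c(ker, rep(0, npad - L)))
  idx <- (half + 1L):(half + T_)
  ones <- c(rep(1, T_), rep(0, npad - T_))
  nrm <- Re(stats::fft(stats::fft(ones) * K, inverse = TRUE) / npad)[idx]
  list(K = K, npad = npad, idx = idx, nrm = nrm, T_ = T_)
}

applyTimeSmoother <- function(M, sm) {
  Mp <- rbind(M, matrix(0, sm$npad - sm$T_, ncol(M)))
  out <- stats::mvfft(stats::mvfft(Mp) * sm$K,
                      inverse = TRUE)[sm$idx, , drop = FALSE] / sm$npad
  out / sm$nrm
}

# Boxcar over adjacent scales (half-width from the spec), list in, list out.
scaleSmooth <- function(L, halfWidth) {
  ns <- length(L)
  out <- vector("list", ns)
  for (s in seq_len(ns)) {
    lo <- max(1L, s - halfWidth)
    hi <- min(ns, s + halfWidth)
    A <- L[[lo]]
    j <- lo + 1L
    while (j <= hi) {
      A <- A + L[[j]]
      j <- j + 1L
    }
    out[[s]] <- A / (hi - lo + 1L)
  }
  out
}

# Cone-of-influence: volumes within sqrt(2)*scale (the Morlet e-folding
# time) of either record edge are edge-affected at that scale.
coiKeep <- function(T_, trS, sc) {
  e <- sqrt(2) * sc / trS
  idx <- seq_len(T_)
  idx > e & idx <= T_ - e
}

# Shared engine: smoothed coherence surfaces for a set of column pairs.
# X: T x nodes. pairs: 2-column index matrix. Returns list over scales of
# T x npairs coherence matrices (clipped to [0, 1]).
coherenceEngine <- function(X, trS, spec, pairs) {
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant (zero-variance) input series at column(s): ",
         paste(which(sds == 0), collapse = ", "),
         "; coherence is undefined")
  T_ <- nrow(X)
  scales <- morletScales(spec)
  W <- cwtAll(X, trS, spec)
  ns <- length(scales)
  SP <- vector("list", ns)
  SC <- vector("list", ns)
  for (s in seq_len(ns)) {
    sm <- makeTimeSmoother(T_, trS, scales[s])
    Ws <- W[[s]]
    SP[[s]] <- Re(applyTimeSmoother(Ws * Conj(Ws), sm))
    SC[[s]] <- applyTimeSmoother(
      Ws[, pairs[, 1], drop = FALSE] * Conj(Ws[, pairs[, 2], drop = FALSE]),
      sm)
  }
  SP <- scaleSmooth(SP, spec@scaleSmoothHalfWidth)
  SC <- scaleSmooth(SC, spec@scaleSmoothHalfWidth)
  lapply(seq_len(ns), function(s) {
    num <- Mod(SC[[s]])^2
    den <- SP[[s]][, pairs[, 1], drop = FALSE] *
      SP[[s]][, pairs[, 2], drop = FALSE]
    coh <- num / den
    if (!spec@squared) coh <- sqrt(coh)
    pmin(pmax(coh, 0), 1)
  })
}

#' Wavelet coherence of two series
#'
#' Smoothed magnitude-squared coherence surface; symmetric in `(x, y)`,
#' invariant to rescaling of either input, and identically 1 for `y = x`.
#'
#' @param x,y Numeric series of equal length.
#' @param trS Sampling interval (s).
#' @param spec A [WaveletSpec-class].
#' @return Numeric matrix (scales x time) in \[0, 1\];
#'   `attr(., "freqsHz")` gives the per-row frequencies.
#' @export
waveletCoherence <- function(x, y, trS, spec = waveletSpec()) {
  stopIfNot(length(x) == length(y), "x and y must have equal length")
  surf <- coherenceEngine(cbind(as.numeric(x), as.numeric(y)), trS, spec,
                          pairs = cbind(1L, 2L))
  out <- t(vapply(surf, function(m) m[, 1], numeric(length(x))))
  attr(out, "freqsHz") <- spec@freqs
  out
}

# Band+time mean of per-scale coherence columns (T x m each).
bandTimeMean <- function(surfList, T_, trS, spec) {
  scales <- morletScales(spec)
  inBand <- which(spec@freqs >= spec@band[1] & spec@freqs <= spec@band[2])
  stopIfNot(length(inBand) > 0, "no scales inside the averaging band")
  acc <- NULL
  for (s in inBand) {
    keep <- if (spec@coiPolicy == "exclude") coiKeep(T_, trS, scales[s])
            else rep(TRUE, T_)
    if (!any(keep))
      stop("cone-of-influence masking removed every volume at ",
           sprintf("%.3f Hz; use coiPolicy = 'keep' for short series",
                   spec@freqs[s]))
    m <- colMeans(surfList[[s]][keep, , drop = FALSE])
    acc <- if (is.null(acc)) m else acc + m
  }
  acc / length(inBand)
}

#' Band-averaged wavelet coherence of two series
#'
#' Mean of the coherence surface over the scales inside the band and over
#' all volumes retained by the cone-of-influence policy, for the entire
#' record.
#'
#' @inheritParams waveletCoherence
#' @return Scalar in \[0, 1\].
#' @export
bandMeanCoherence <- function(x, y, trS, spec = waveletSpec()) {
  stopIfNot(length(x) == length(y), "x and y must have equal length")
  surf <- coherenceEngine(cbind(as.numeric(x), as.numeric(y)), trS, spec,
                          pairs = cbind(1L, 2L))
  as.numeric(bandTimeMean(surf, length(x), trS, spec))
}

#' Connectivity matrix by band-averaged wavelet coherence
#'
#' Computes `bandMeanCoherence` for every pair of columns (node pairs) of a
#' parcellated time-series matrix, sharing one transform per node.
#'
#' @param timeseries Numeric matrix, volumes x nodes, with node ids as
#'   column names.
#' @param trS Repetition time (s).
#' @param spec A [WaveletSpec-class].
#' @return A [CoherenceMatrix-class].
#' @examples
#' X <- matrix(rnorm(128 * 4), 128, 4,
#'             dimnames = list(NULL, paste0("n", 1:4)))
#' connectivityMatrix(X, 1.8)
#' @export
connectivityMatrix <- function(timeseries, trS, spec = waveletSpec()) {
  n <- ncol(timeseries)
  stopIfNot(n >= 2, "need at least two nodes")
  ids <- colnames(timeseries)
  if (is.null(ids)) ids <- paste0("n", seq_len(n))
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  surf <- tryCatch(
    coherenceEngine(timeseries, trS, spec, pairs),
    error = function(e) {
      bad <- regmatches(conditionMessage(e),
                        regexpr("column\\(s\\): [0-9, ]+", conditionMessage(e)))
      if (length(bad))
        stop("connectivityMatrix: ", conditionMessage(e), " (node ids: ",
             paste(ids[as.integer(strsplit(sub(".*: ", "", bad),
                                           ", ")[[1]])], collapse = ", "),
             ")", call. = FALSE)
      stop(e)
    })
  vals <- bandTimeMean(surf, nrow(timeseries), trS, spec)
  M <- diag(1, n)
  M[pairs] <- vals
  M[pairs[, c(2, 1), drop = FALSE]] <- vals
  coherenceMatrix(M, nodeIds = ids, band = spec@band)
}

#' Write / read a coherence matrix as TSV with a JSON sidecar
#'
#' The TSV carries node ids as header row and first column; the sidecar
#' records the band and wavelet parameters for provenance.
#'
#' @param x A [CoherenceMatrix-class].
#' @param path TSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param spec Optional [WaveletSpec-class] recorded in the sidecar.
#' @return The path (write) or a [CoherenceMatrix-class] (read).
#' @export
writeCoherenceMatrix <- function(x, path, spec = NULL) {
  df <- data.frame(node = x@nodeIds, x@values, check.names = FALSE)
  colnames(df) <- c("node", x@nodeIds)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(band_hz = x@band)
  if (!is.null(spec))
    side <- c(side, list(omega0 = spec@omega0, freqs_hz = spec@freqs,
                         coi_policy = spec@coiPolicy, squared = spec@squared,
                         scale_smooth_half_width = spec@scaleSmoothHalfWidth))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeCoherenceMatrix
#' @export
readCoherenceMatrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  ids <- df[[1]]
  M <- as.matrix(df[, -1, drop = FALSE])
  band <- c(0.06, 0.12)
  side <- paste0(path, ".json")
  if (file.exists(side))
    band <- as.numeric(jsonlite::read_json(side,
                                           simplifyVector = TRUE)$band_hz)
  coherenceMatrix(M, nodeIds = ids, band = band)
}
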