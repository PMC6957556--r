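# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' that seeded helpers do not perturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seed derived from a root seed and a stage/subject
# offset; kept within the 32-bit integer range.
deriveSeed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + as.double(offset) * 104729) %%
               2147483647)
}

# Truncated-normal draws by rejection; used for bounded demographics.
rnormTrunc <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
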