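# Correlations, hierarchical regression, BCa bootstrap, FDR.

test_that("correlate selects methods sensibly and matches a permutation oracle", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x + 1, method = "pearson")$estimate, 1)
  r <- correlate(seq(-5, 5), seq(-5, 5)^3, method = "spearman")
  expect_equal(r$estimate, 1)
  expect_lt(correlate(seq(-5, 5), seq(-5, 5)^3,
                      method = "pearson")$estimate, 1)
  # auto falls back to Spearman for a clearly non-normal variable
  set.seed(2)
  skewed <- rexp(40)^3
  normal <- rnorm(40)
  expect_equal(correlate(skewed, normal)$method, "spearman")
  expect_equal(correlate(normal, rnorm(40))$method, "pearson")
  expect_error(correlate(rep(1, 10), rnorm(10)), "constant")
  # permutation oracle on a fixed n = 30 fixture
  set.seed(30)
  x30 <- rnorm(30)
  y30 <- 0.3 * x30 + rnorm(30)
  ct <- correlate(x30, y30, method = "pearson")
  robs <- abs(cor(x30, y30))
  set.seed(31)
  perm <- mean(replicate(10000, abs(cor(x30, sample(y30))) >= robs))
  expect_lt(abs(ct$p - perm), 0.02)
})

test_that("nested fits report monotone R2 and exact fits saturate in block one", {
  d <- data.frame(age_years = rnorm(40), x2 = rnorm(40), x3 = rnorm(40))
  d$y <- 3 + 2 * d$age_years
  hf <- suppressWarnings(hierarchicalFit(d, "y", list("age_years", "x2", "x3")))
  expect_equal(hf$r2[1], 1)
  expect_equal(diff(hf$r2), c(0, 0), tolerance = 1e-12)
  set.seed(9)
  for (i in 1:20) {
    n <- 40
    dd <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n),
                     y = rnorm(n))
    r2 <- hierarchicalFit(dd, "y", list("a", "b", "c"))$r2
    expect_true(all(diff(r2) >= -1e-12))
  }
  dd <- data.frame(a = rnorm(20))
  dd$b <- 2 * dd$a
  dd$y <- rnorm(20)
  expect_error(hierarchicalFit(dd, "y", list("a", "b")), "collinear")
  expect_error(hierarchicalFit(dd, "y", list("a", "a")), "repeated")
})

test_that("the generating coefficients of a large simulated sample are recovered", {
  set.seed(14)
  n <- 5000
  d <- data.frame(age_years = rnorm(n, 48, 14),
                  GE = rnorm(n, 0.44, 0.05),
                  motion_mean_rms = rnorm(n, 0.07, 0.03))
  d$tol_rt_s <- 2 + 0.09 * d$age_years + 9.79 * d$GE -
    16.46 * d$motion_mean_rms + rnorm(n, 0, 0.8)
  hf <- hierarchicalFit(d, "tol_rt_s", regressionBlocks("GE"))
  fin <- hf$models[[3]]
  truth <- c(age_years = 0.09, GE = 9.79, motion_mean_rms = -16.46)
  for (tm in names(truth)) {
    row <- fin[fin$term == tm, ]
    expect_lt(abs(row$B - truth[[tm]]), 2 * row$SE)
  }
})

test_that("standardized betas equal the slope on standardized variables", {
  set.seed(4)
  d <- data.frame(x = rnorm(50, 0, 3))
  d$y <- 1 + 0.5 * d$x + rnorm(50)
  B <- coef(lm(y ~ x, d))["x"]
  beta <- standardizedBeta(B, sd(d$x), sd(d$y))
  zfit <- coef(lm(scale(y) ~ scale(x), d))[2]
  expect_equal(unname(beta), unname(zfit), tolerance = 1e-10)
  # invariant to rescaling of x's units
  d$xkm <- d$x / 1000
  B2 <- coef(lm(y ~ xkm, d))["xkm"]
  expect_equal(unname(standardizedBeta(B2, sd(d$xkm), sd(d$y))),
               unname(beta))
  expect_error(standardizedBeta(1, 0, 1), "> 0")
})

test_that("BCa reduces to the percentile interval under symmetry and zero constants", {
  # symmetric replicate distribution centred on the estimate -> z0 = 0
  reps <- c(seq(-1, 1, length.out = 1001))
  jack <- seq(-0.5, 0.5, length.out = 30)  # symmetric jackknife -> a = 0
  ci <- bcaInterval(0, reps, jack)
  expect_equal(attr(ci, "z0"), 0, tolerance = 1e-12)
  expect_equal(attr(ci, "a"), 0, tolerance = 1e-12)
  expect_equal(as.numeric(ci),
               unname(quantile(reps, c(0.025, 0.975), type = 7)),
               tolerance = 1e-12)
  expect_error(bcaInterval(0, rep(1, 100), jack), "zero-variance")
})

test_that("BCa agrees with the reference implementation on a mean", {
  skip_if_not_installed("boot")
  set.seed(77)
  x <- rexp(40)  # skewed, so z0 and a both matter
  bo <- boot::boot(x, function(d, i) mean(d[i]), R = 4000)
  ref <- boot::boot.ci(bo, type = "bca")$bca[4:5]
  jack <- vapply(seq_along(x), function(i) mean(x[-i]), numeric(1))
  ours <- bcaInterval(mean(x), as.numeric(bo$t), jack)
  # different interpolation conventions; agreement to a few percent of
  # the interval width
  width <- diff(ref)
  expect_lt(max(abs(as.numeric(ours) - ref)), 0.05 * width)
})

test_that("bootstrap regression is seed-deterministic with consistent P/CI inversion", {
  set.seed(6)
  n <- 62
  d <- data.frame(age_years = rnorm(n, 48, 14), integration = rnorm(n),
                  motion_mean_rms = rnorm(n, 0.07, 0.03))
  d$tol_rt_s <- 10 + 0.05 * d$age_years + 0.5 * d$integration + rnorm(n)
  b1 <- bootstrapRegression(d, "tol_rt_s", regressionBlocks("integration"),
                            nBoot = 400, seed = 5)
  b2 <- bootstrapRegression(d, "tol_rt_s", regressionBlocks("integration"),
                            nBoot = 400, seed = 5)
  expect_identical(regressionCoefficients(b1), regressionCoefficients(b2))
  expect_true(all(diff(modelR2(b1)) >= -1e-12))
  co <- regressionCoefficients(b1)
  # CI excludes zero <=> pBca < 0.05 (up to the alpha grid step)
  for (i in seq_len(nrow(co))) {
    excl <- co$ciLow[i] > 0 || co$ciHigh[i] < 0
    if (co$pBca[i] < 0.045) expect_true(excl)
    if (co$pBca[i] > 0.055) expect_false(excl)
    expect_true(co$ciLow[i] <= co$B[i] && co$B[i] <= co$ciHigh[i])
  }
})

test_that("BH adjustment matches the threshold-scan oracle and controls edge cases", {
  expect_true(all(fdrBH(rep(1, 5))$pAdj == 1))
  expect_true(all(!fdrBH(rep(1, 5))$reject))
  set.seed(10)
  for (i in 1:30) {
    p <- runif(sample(3:12, 1))
    expect_equal(fdrBH(p)$pAdj, oracleBH(p), tolerance = 1e-12)
  }
  # adjusted values are monotone in raw-P order and >= raw
  p <- runif(10)
  f <- fdrBH(p)
  expect_true(all(f$pAdj >= f$p))
  expect_true(all(diff(f$pAdj[order(f$p)]) >= -1e-15))
  expect_error(fdrBH(c(0.5, 1.2)), "\\[0, 1\\]")
  # two small P values among 8 subnetwork tests fail the step-up bound,
  # mirroring the DMN efficiency/clustering pattern
  p8 <- c(0.018, 0.039, 0.31, 0.45, 0.52, 0.61, 0.72, 0.9)
  f8 <- fdrBH(p8)
  expect_equal(f8$pAdj[1], 8 * 0.018 / 1, tolerance = 1e-12)  # 0.144
  expect_true(all(!f8$reject))
  expect_gt(min(f8$pAdj), 0.05)
})

test_that("residualization yields the closed-form partial correlation", {
  set.seed(8)
  n <- 80
  d <- data.frame(z = rnorm(n))
  d$x <- 0.6 * d$z + rnorm(n)
  d$y <- 0.4 * d$z + 0.3 * d$x + rnorm(n)
  rp <- residualizePair(d, "y", "x", "z")
  rxy <- cor(d$x, d$y); rxz <- cor(d$x, d$z); ryz <- cor(d$y, d$z)
  closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(rp$partialR, closed, tolerance = 1e-10)
  # orthogonal covariate: partial equals raw correlation
  d2 <- data.frame(x = rnorm(n), y = rnorm(n))
  d2$w <- residuals(lm(rnorm(n) ~ d2$x + d2$y))
  rp2 <- residualizePair(d2, "y", "x", "w")
  expect_equal(rp2$partialR, cor(d2$x, d2$y), tolerance = 1e-10)
  # outcome fully explained by covariates -> flagged
  d3 <- data.frame(y = 1:20 + 0, c1 = 1:20, x = rnorm(20))
  expect_warning(rp3 <- residualizePair(d3, "y", "x", "c1"), "zero")
  expect_true(is.na(rp3$partialR))
})
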