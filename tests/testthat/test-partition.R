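# Variance-partition statistics, HPD intervals, WAIC and PSIS-LOO.

drawsFor <- function(spec, values, n = 1) {
  cols <- unlist(values)
  M <- matrix(rep(as.numeric(cols), each = n), nrow = n)
  colnames(M) <- names(cols)
  M
}

test_that("partition fractions reproduce worked examples", {
  # symmetric LM1 draw: all three variances equal -> thirds
  D <- drawsFor("LM1", c(sigma2_P = 1, sigma2_G = 1, sigma2_E = 1))
  ps <- varianceFractions(D, spec = "LM1")
  expect_equal(unname(ps@perDraw[1, ]), rep(1 / 3, 3))
  # reduced interaction draw: (3, 3, 1/3) -> (3/7, 3/7, 1/7)
  D2 <- drawsFor("IM1", c(sigma2_P = 0, sigma2_G = 3, sigma2_E = 3,
                          k_GE = 1 / 3))
  ps2 <- varianceFractions(D2, spec = "IM1")
  expect_equal(ps2@perDraw[1, c("h2", "e2", "he2")],
               c(h2 = 3 / 7, e2 = 3 / 7, he2 = 1 / 7))
  # equal variances under LM0 -> h2 = 0.5
  D3 <- drawsFor("LM0", c(sigma2_G = 2.2, sigma2_E = 2.2))
  expect_equal(unname(varianceFractions(D3, spec = "LM0")@perDraw[1, ]),
               c(0.5, 0.5))
})

test_that("per-draw fractions sum to one for all five models", {
  set.seed(14)
  n <- 200
  for (nm in c("LM0", "LM1", "IM1", "LM2", "IM2")) {
    spec <- modelSpec(nm)
    cols <- c(if (spec@includeGeo) "sigma2_P", "sigma2_G",
              paste0("sigma2_", spec@environments),
              if (length(spec@interactions))
                paste0("k_", spec@interactions))
    D <- matrix(abs(rnorm(n * length(cols), sd = 2)), n,
                dimnames = list(NULL, cols))
    if (length(spec@interactions))
      D[, paste0("k_", spec@interactions)] <-
        rnorm(n * length(spec@interactions))
    ps <- varianceFractions(D, spec = spec)
    expect_lt(max(abs(rowSums(ps@perDraw) - 1)), 1e-12)
    expect_true(all(ps@perDraw >= 0 & ps@perDraw <= 1))
  }
})

test_that("interaction fractions are invariant to sign flips", {
  base <- c(sigma2_P = 0.5, sigma2_G = 2, sigma2_E = 1, k_GE = 0.7)
  fPos <- varianceFractions(drawsFor("IM1", base), spec = "IM1")@perDraw
  base["k_GE"] <- -0.7
  fNeg <- varianceFractions(drawsFor("IM1", base), spec = "IM1")@perDraw
  expect_equal(fPos, fNeg)
})

test_that("a vanishing extra component leaves fractions unchanged", {
  full <- c(sigma2_P = 1e-8, sigma2_G = 2, sigma2_E = 1)
  f1 <- varianceFractions(drawsFor("LM1", full), spec = "LM1")@perDraw
  red <- varianceFractions(drawsFor("LM0",
           c(sigma2_G = 2, sigma2_E = 1)), spec = "LM0")@perDraw
  expect_equal(f1[1, c("h2", "e2")], red[1, c("h2", "e2")],
               tolerance = 1e-7)
})

test_that("zero-variance draws are excluded and counted", {
  D <- rbind(c(sigma2_G = 1, sigma2_E = 1),
             c(sigma2_G = 0, sigma2_E = 0))
  ps <- varianceFractions(D, spec = "LM0")
  expect_identical(ps@excluded, 1L)
  expect_identical(nrow(ps@perDraw), 1L)
})

test_that("HPD intervals behave on analytic cases", {
  set.seed(15)
  u <- runif(20000)
  h <- hpdInterval(u, 0.95)
  expect_equal(h[2] - h[1], 0.95, tolerance = 0.01)
  z <- rnorm(20000)
  hz <- hpdInterval(z, 0.95)
  et <- quantile(z, c(0.025, 0.975))
  expect_equal(unname(hz), unname(et), tolerance = 0.05)
  expect_equal(hpdInterval(rep(3.2, 10)), c(3.2, 3.2))
  expect_error(hpdInterval(u, 1.2), "mass")
  # own minimal-width-window oracle (same gap convention)
  x <- sort(rbeta(5000, 2, 8))
  gap <- max(1, min(length(x) - 1, round(0.95 * length(x))))
  widths <- x[(gap + 1):length(x)] - x[1:(length(x) - gap)]
  j <- which.min(widths)
  expect_equal(hpdInterval(x, 0.95), c(x[j], x[j + gap]),
               tolerance = 1e-6)
})

test_that("WAIC matches hand computation and additivity", {
  # degenerate posterior, single observation at p = 0.5
  ll <- matrix(log(0.5), 4, 1)
  w <- waic(ll)
  expect_equal(w$waic, -2 * log(0.5), tolerance = 1e-12)
  expect_equal(w$p_waic, 0)
  # 3 draws x 2 observations against direct formula
  M <- matrix(log(c(0.3, 0.5, 0.4, 0.8, 0.6, 0.7)), 3, 2)
  w2 <- waic(M)
  lppd <- sum(log(colMeans(exp(M))))
  pw <- sum(apply(M, 2, var))
  expect_equal(w2$waic, -2 * (lppd - pw), tolerance = 1e-10)
  # duplicating every observation doubles the total
  w3 <- waic(cbind(M, M))
  expect_equal(w3$waic, 2 * w2$waic, tolerance = 1e-10)
  expect_error(waic(matrix(c(0, -Inf), 1)), "non-finite")
})

test_that("degenerate posteriors collapse PSIS-LOO onto WAIC", {
  p <- c(0.3, 0.8, 0.6, 0.9)
  ll <- matrix(rep(log(p), each = 150), 150)
  l <- psisLoo(ll)
  expect_equal(l$loo, -2 * sum(log(p)), tolerance = 1e-10)
  expect_equal(l$loo, waic(ll)$waic, tolerance = 1e-10)
})

test_that("LOO and WAIC agree within error on a well-specified toy", {
  set.seed(16)
  n <- 60
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.8 * x))
  lg <- function(th) {
    eta <- th * x
    list(lp = sum(y * eta - log(1 + exp(eta))) - th^2 / 8,
         grad = sum(x * (y - plogis(eta))) - th / 4)
  }
  res <- nutsGeneric(lg, init = 0, warmup = 400, draws = 1000)
  eta <- res$draws[, 1] %o% x
  ll <- t(t(eta) * y) - log(1 + exp(eta))
  w <- waic(ll); l <- psisLoo(ll)
  expect_lt(abs(w$waic - l$loo), 2 * w$se)
  expect_true(all(l$pareto_k < 0.7, na.rm = TRUE))
})

test_that("an outlying observation earns the largest Pareto k", {
  set.seed(17)
  S <- 600; n <- 20
  ll <- matrix(rnorm(S * n, -0.7, 0.05), S, n)
  # an outlier whose likelihood varies wildly across draws
  ll[, 7] <- -exp(rnorm(S, 1.2, 1.2))
  l <- psisLoo(ll)
  expect_identical(which.max(l$pareto_k), 7L)
})

test_that("the generalized Pareto fit recovers known tails", {
  set.seed(18)
  x <- rexp(800, 2)          # shape 0, scale 0.5
  f <- famGxE:::.gpdFit(x)
  expect_lt(abs(f$k), 0.12)
  expect_equal(f$sigma, 0.5, tolerance = 0.1)
  u <- runif(800)
  xg <- 0.7 / 0.3 * ((1 - u)^(-0.3) - 1)   # shape 0.3, scale 0.7
  f2 <- famGxE:::.gpdFit(xg)
  expect_lt(abs(f2$k - 0.3), 0.12)
  expect_lt(abs(f2$sigma - 0.7), 0.15)
})

test_that("selection traces flag the best model and ties honestly", {
  rep1 <- new("ModelFitReport", model = "LM0", waic = 500, waicSE = 5,
              waicCI = c(490.2, 509.8), loo = 510, looSE = 5,
              looCI = c(500.2, 519.8), paretoK = rep(0.1, 10), n = 10L)
  rep2 <- new("ModelFitReport", model = "LM1", waic = 450, waicSE = 5,
              waicCI = c(440.2, 459.8), loo = 460, looSE = 5,
              looCI = c(450.2, 469.8), paretoK = rep(0.1, 10), n = 10L)
  rep3 <- new("ModelFitReport", model = "IM1", waic = 400, waicSE = 5,
              waicCI = c(390.2, 409.8), loo = 410, looSE = 5,
              looCI = c(400.2, 419.8), paretoK = rep(0.1, 10), n = 10L)
  tr <- selectionTrace(list(rep1, rep2, rep3))
  expect_identical(tr$model[tr$best_waic], "IM1")
  expect_identical(tr$model[tr$best_loo], "IM1")
  expect_equal(tr$delta_waic, c(100, 50, 0))
  # overlapping intervals are annotated, not resolved
  rep4 <- new("ModelFitReport", model = "IM2", waic = 402, waicSE = 5,
              waicCI = c(392.2, 411.8), loo = 412, looSE = 5,
              looCI = c(402.2, 421.8), paretoK = rep(0.1, 10), n = 10L)
  tr2 <- selectionTrace(list(rep3, rep4))
  expect_identical(tr2$note[tr2$model == "IM2"], "indistinguishable")
  # single report is trivially best
  tr3 <- selectionTrace(list(rep1))
  expect_true(tr3$best_waic)
  # mismatched cohorts are refused
  rep5 <- rep1; rep5@n <- 99L
  expect_error(selectionTrace(list(rep1, rep5)), "different cohorts")
})
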