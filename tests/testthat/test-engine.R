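# The NUTS sampler, variational initialization and convergence
# diagnostics, validated on targets with known posteriors.

test_that("NUTS recovers an analytic Beta posterior through the logit", {
  # y: 30 of 50 successes, uniform prior on p -> posterior Beta(31, 21)
  s <- 30; n <- 50
  lg <- function(th) {
    p <- plogis(th)
    list(lp = (s + 1) * th - (n + 2) * log(1 + exp(th)),
         grad = (s + 1) - (n + 2) * p)
  }
  set.seed(42)
  res <- nutsGeneric(lg, init = 0, warmup = 500, draws = 2000)
  p <- plogis(res$draws[, 1])
  aMean <- 31 / 52
  aSd <- sqrt(31 * 21 / (52^2 * 53))
  expect_lt(abs(mean(p) - aMean), 4 * aSd / sqrt(200))  # generous MC error
  expect_lt(abs(sd(p) - aSd) / aSd, 0.1)
  expect_equal(sum(res$divergent), 0)
})

test_that("NUTS reproduces a correlated Gaussian target", {
  Sig <- matrix(c(1, 0.9, 0.9, 1), 2)
  Si <- solve(Sig)
  lg <- function(th) list(lp = -0.5 * sum(th * (Si %*% th)),
                          grad = as.numeric(-Si %*% th))
  set.seed(7)
  res <- nutsGeneric(lg, init = c(0, 0), warmup = 500, draws = 2000)
  expect_equal(cov(res$draws), Sig, tolerance = 0.12, ignore_attr = TRUE)
})

test_that("sampler effective size is comparable to iid sampling", {
  lg <- function(th) list(lp = -0.5 * sum(th^2), grad = -th)
  set.seed(12)
  res <- nutsGeneric(lg, init = rep(0, 3), warmup = 400, draws = 1200)
  ess <- as.numeric(coda::effectiveSize(res$draws[, 1]))
  expect_gt(ess, 1200 / 3)   # within 3x of the iid ESS
})

test_that("sampling is deterministic under the seed contract", {
  co <- smallCohort(nFamilies = 6, seed = 50)
  m <- assembleModel("LM0", co)
  cfg <- samplerConfig(nChains = 2, warmup = 100, draws = 100, seed = 99)
  d1 <- sampleModel(m, cfg)
  d2 <- sampleModel(m, cfg)
  expect_identical(posteriorMatrix(d1), posteriorMatrix(d2))
  d3 <- sampleModel(m, samplerConfig(nChains = 2, warmup = 100,
                                     draws = 100, seed = 100))
  expect_false(identical(posteriorMatrix(d1), posteriorMatrix(d3)))
})

test_that("chain initialization respects the configured method", {
  co <- smallCohort(nFamilies = 6, seed = 51)
  m <- assembleModel("LM0", co)
  set.seed(1)
  ini <- initializeChains(m, samplerConfig(nChains = 3, init = "random"))
  expect_identical(ini$method, "random")
  expect_length(ini$inits, 3)
  expect_false(identical(ini$inits[[1]], ini$inits[[2]]))
  set.seed(1)
  ini2 <- initializeChains(m, samplerConfig(nChains = 3, init = "random"))
  expect_identical(ini$inits, ini2$inits)   # seeded RNG contract
  set.seed(2)
  iniV <- initializeChains(m, samplerConfig(nChains = 2,
                                            init = "variational",
                                            adviIters = 150L))
  expect_identical(iniV$method, "variational")
  expect_true(all(vapply(iniV$inits, function(v) all(is.finite(v)),
                         logical(1))))
})

test_that("variational initialization gives an optimized start", {
  co <- smallCohort(nFamilies = 10, seed = 52)
  m <- assembleModel("LM0", co)
  set.seed(33)
  fit <- famGxE:::fg_advi(famGxE:::.modelPtr(m), 300L, 1L, 0.05)
  expect_true(fit$converged)
  lpMu <- logPosterior(m, fit$mu)$lp
  set.seed(34)
  rand <- replicate(20, logPosterior(m, 0.1 * rnorm(length(fit$mu)))$lp)
  # the variational mean beats every typical random start on log-density
  expect_gt(lpMu, max(rand))
  # and the chain starts drawn from it are finite and distinct
  set.seed(35)
  ini <- initializeChains(m, samplerConfig(nChains = 4, adviIters = 200L))
  expect_identical(ini$method, "variational")
  expect_false(identical(ini$inits[[1]], ini$inits[[2]]))
})

test_that("split R-hat flags disagreeing chains and passes identical ones", {
  set.seed(90)
  v <- rnorm(200)                # stationary, well-mixed chain, copied
  x <- rep(v, 2)
  chain <- rep(1:2, each = 200)
  expect_lt(abs(famGxE:::.splitRhat(x, chain) - 1), 0.05)
  y <- c(rep(0, 200), rep(5, 200))  # chains stuck at different constants
  expect_gt(famGxE:::.splitRhat(y, chain), 10)
})

test_that("diagnostics report R-hat, ESS and divergences per chain", {
  co <- smallCohort(nFamilies = 8, seed = 53)
  m <- assembleModel("IM0", co)
  dr <- sampleModel(m, samplerConfig(nChains = 2, warmup = 200,
                                     draws = 200, seed = 5))
  dg <- samplerDiagnostics(dr)
  expect_true(all(c("sigma2_G", "sigma2_E", "k_GE") %in%
                  dg$summary$parameter))
  expect_true(all(is.finite(dg$summary$ess)))
  expect_length(dg$divergences, 2)
  # well-behaved scalar parameters should show reasonable mixing
  betaRows <- grepl("^beta\\.", dg$summary$parameter)
  expect_lt(median(dg$summary$rhat[betaRows]), 1.1)
})

test_that("simulation-based calibration ranks are near uniform (LM0)", {
  # scaled-down SBC: truth drawn from the variance priors, data simulated
  # from it, rank of the true sigma2_G within the posterior draws
  set.seed(61)
  nSBC <- 32L
  L <- 60L
  ranks <- integer(nSBC)
  co0 <- generateCohort(cohortConfig(nFamilies = 12, nLocations = 4))
  X <- buildDesign(co0)
  grm <- buildGRM(pedigree(co0))
  for (r in seq_len(nSBC)) {
    s2G <- rgamma(1, 2, 0.5); s2E <- rgamma(1, 2, 0.5)
    truth <- generativeTruth("LM0", sigma_g_sq = s2G, sigma_e_sq = s2E,
                             k_ge = 0)
    eff <- sampleLatentEffects(co0, truth, grm = grm)
    y <- simulatePhenotype(X, eff, truth)
    coy <- setPhenotype(co0, as.integer(y))
    mdl <- assembleModel("LM0", coy, X = X, grm = grm)
    dr <- sampleModel(mdl, samplerConfig(nChains = 2, warmup = 150,
                                         draws = 150, seed = 1000 + r,
                                         init = "random"))
    post <- posteriorMatrix(dr)[, "sigma2_G"]
    post <- post[seq(1, length(post), length.out = L)]  # thin
    ranks[r] <- sum(post < s2G)
  }
  bins <- cut(ranks, breaks = seq(0, L, length.out = 5),
              include.lowest = TRUE)
  chi <- suppressWarnings(chisq.test(table(bins)))
  expect_gt(chi$p.value, 0.01)
})
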