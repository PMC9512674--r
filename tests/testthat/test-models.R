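# Model specifications, assembled posteriors, variance arithmetic and the
# pointwise log-likelihood.

test_that("the five specs encode the model ledger and its nesting", {
  lm0 <- modelSpec("LM0")
  expect_false(lm0@includeGeo)
  expect_identical(lm0@environments, "E")
  expect_length(lm0@interactions, 0)
  lm1 <- modelSpec("LM1")
  expect_true(lm1@includeGeo)
  im1 <- modelSpec("IM1")
  expect_identical(im1@interactions, "GE")
  lm2 <- modelSpec("LM2")
  expect_setequal(lm2@environments, c("F", "C", "S", "E"))
  expect_length(lm2@interactions, 0)
  im2 <- modelSpec("IM2")
  expect_setequal(im2@interactions, c("GF", "GC", "GS", "GE"))
  # forward traces: each later model extends the earlier one
  expect_true(all(lm0@environments %in% lm1@environments))
  expect_true(all(lm1@environments %in% im1@environments))
  expect_true(all(lm2@environments %in% im2@environments))
  expect_true(all(lm2@interactions %in% im2@interactions))
  # an interaction without its environment is rejected
  expect_error(new("ModelSpec", name = "bad", includeGeo = FALSE,
                   environments = "E", interactions = "GF"),
               "requires environment")
})

test_that("totalVariance reproduces worked contributions", {
  lm0 <- totalVariance(list(sigma_g_sq = 1, sigma_e_sq = 1), "LM0")
  expect_equal(unname(lm0$contributions), c(1, 1))
  expect_equal(lm0$total, 2)
  im1 <- totalVariance(list(sigma_p_sq = 0, sigma_g_sq = 3,
                            sigma_e_sq = 3, k_ge = 1 / 3), "IM1")
  expect_equal(im1$contributions[["he2"]], 1)
  expect_equal(im1$total, 7)
  im2 <- totalVariance(list(sigma_p_sq = 0.5, sigma_g_sq = 2,
                            sigma_f_sq = 1, sigma_c_sq = 0.7,
                            sigma_s_sq = 0.3, sigma_e_sq = 1.5,
                            k_gf = 0.2, k_gc = 0.3, k_gs = 0.1,
                            k_ge = 0.4), "IM2")
  expect_length(im2$contributions, 10)
  expect_equal(im2$contributions[["hf2"]], 0.2^2 * 2 * 1)
  expect_equal(im2$contributions[["hc2"]], 0.3^2 * 2 * 0.7)
  expect_equal(im2$contributions[["hs2"]], 0.1^2 * 2 * 0.3)
  expect_equal(im2$contributions[["he2"]], 0.4^2 * 2 * 1.5)
  expect_equal(im2$total, sum(im2$contributions))
})

test_that("compiled gradients match finite differences for every model", {
  co <- simulateCohort(
    cohortConfig(nFamilies = 5, nLocations = 3),
    generativeTruth("IM2", sigma_p_sq = 1, sigma_f_sq = 0.5,
                    sigma_c_sq = 0.5, sigma_s_sq = 0.5, k_gf = 0.2,
                    k_gc = 0.2, k_gs = 0.2, length_scale = 8),
    seed = 71)
  for (nm in c("LM0", "LM1", "IM1", "LM2", "IM2")) {
    m <- assembleModel(nm, co)
    d <- modelDimension(m)
    set.seed(72)
    th <- rnorm(d) * 0.4
    lg <- logPosterior(m, th)
    num <- vapply(seq_len(d), function(j) {
      e <- rep(0, d); e[j] <- 1e-5
      (logPosterior(m, th + e)$lp - logPosterior(m, th - e)$lp) / 2e-5
    }, numeric(1))
    expect_lt(max(abs(num - lg$grad)), 1e-5)
  }
})

test_that("non-centered density agrees with a centered R oracle (LM0)", {
  co <- smallCohort(nFamilies = 4, seed = 77)
  m <- assembleModel("LM0", co)
  st <- m@structures
  n <- length(m@y)
  p <- ncol(m@X)
  idx <- m@paramIndex
  # centered oracle: the same joint density expressed through (G, E) with
  # multivariate-normal densities plus the change-of-variables terms; the
  # compiled density drops additive constants, so compare differences
  # between two points.
  centered <- function(th) {
    z <- th[idx$z_beta]; lam <- exp(th[idx$log_lambda])
    tau <- exp(th[idx$log_tau])
    beta <- c(st$priors$beta0_sd * z[1], tau * lam * z[-1])
    s2G <- exp(th[idx$log_sigma2_G]); s2E <- exp(th[idx$log_sigma2_E])
    G <- sqrt(s2G) * as.numeric(st$LG %*% th[idx$u_G])
    E <- sqrt(s2E) * th[idx$u_E]
    l <- as.numeric(st$X %*% beta) + G + E
    SigG <- s2G * as.matrix(Matrix::tcrossprod(st$LG))
    lpC <- sum(m@y * l - log1p(exp(l))) +
      mvtnorm::dmvnorm(G, sigma = SigG, log = TRUE) +
      sum(dnorm(E, 0, sqrt(s2E), log = TRUE)) +
      sum(dnorm(z, log = TRUE)) +
      sum(dcauchy(lam, log = TRUE) + log(2) + log(lam)) +
      dcauchy(tau, log = TRUE) + log(2) + log(tau) +
      dgamma(s2G, 2, 0.5, log = TRUE) + log(s2G) +
      dgamma(s2E, 2, 0.5, log = TRUE) + log(s2E)
    jac <- 0.5 * n * log(s2G) + sum(log(diag(as.matrix(st$LG)))) +
      0.5 * n * log(s2E)
    lpC + jac
  }
  set.seed(78)
  th1 <- rnorm(modelDimension(m)) * 0.5
  th2 <- rnorm(modelDimension(m)) * 0.5
  dNC <- logPosterior(m, th1)$lp - logPosterior(m, th2)$lp
  dC <- centered(th1) - centered(th2)
  expect_equal(dNC, dC, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("prior-predictive liability covariance matches the closed form", {
  # 12-person cohort (3 families), reduced interaction model truth
  truth <- generativeTruth("IM0", sigma_g_sq = 3, sigma_e_sq = 3,
                           k_ge = 1 / 3)
  co <- generateCohort(cohortConfig(nFamilies = 3,
                                    childrenRange = c(2L, 2L),
                                    nLocations = 2), seed = 90)
  X <- buildDesign(co)
  n <- nIndividuals(co)
  grm <- buildGRM(pedigree(co))
  set.seed(91)
  reps <- 20000
  L <- matrix(0, reps, n)
  for (r in seq_len(reps)) {
    eff <- sampleLatentEffects(co, truth, grm = grm)
    L[r, ] <- liabilityFromEffects(X, eff, truth)
  }
  emp <- cov(L)
  SigG <- matrixValues(grm)
  closed <- truth$sigma_g_sq * SigG +
    truth$sigma_e_sq * diag(n) +
    truth$k_ge^2 * truth$sigma_g_sq * truth$sigma_e_sq * (SigG * diag(n))
  relFrob <- function(a, b) norm(a - b, "F") / norm(b, "F")
  expect_lt(relFrob(emp, closed), 0.05)
  expect_lt(mean(abs(diag(emp) - diag(closed)) / diag(closed)), 0.05)
})

test_that("pointwise log-likelihood matches hand computation", {
  co <- smallCohort(nFamilies = 3, seed = 80)
  m <- assembleModel("IM0", co)
  # degenerate draws with everything zero: p = 0.5 for every individual
  n <- length(m@y)
  cols <- c(paste0("beta.", colnames(m@X)), "tau", "sigma2_G",
            paste0("G.", m@labels), "sigma2_E", paste0("E.", m@labels),
            "k_GE")
  D <- matrix(0, 2, length(cols), dimnames = list(NULL, cols))
  ll <- pointwiseLogLik(m, D)
  expect_equal(unname(ll), matrix(log(0.5), 2, n))
  # strong positive liability on a case approaches perfect fit
  D2 <- D
  i1 <- which(m@y == 1)[1]
  D2[, paste0("G.", m@labels[i1])] <- 40
  ll2 <- pointwiseLogLik(m, D2)
  expect_gt(ll2[1, i1], -1e-10)
  # hand-computed three-individual check with nonzero effects
  D3 <- D
  D3[1, "beta.(Intercept)"] <- 0.3   # draws store constrained coefficients
  D3[1, paste0("G.", m@labels[1:3])] <- c(0.5, -0.2, 0.1)
  D3[1, paste0("E.", m@labels[1:3])] <- c(-1, 0.4, 0)
  D3[1, "k_GE"] <- 2
  lhand <- 0.3 + c(0.5, -0.2, 0.1) + c(-1, 0.4, 0) +
    2 * c(0.5, -0.2, 0.1) * c(-1, 0.4, 0)
  ll3 <- pointwiseLogLik(m, D3)
  yh <- m@y[1:3]
  expect_equal(unname(ll3[1, 1:3]),
               yh * lhand - log(1 + exp(lhand)), tolerance = 1e-12)
})

test_that("interaction term covariance follows the Hadamard structure", {
  truth <- generativeTruth("IM0", sigma_g_sq = 2, sigma_e_sq = 1.5,
                           k_ge = 0.6)
  co <- generateCohort(cohortConfig(nFamilies = 2,
                                    childrenRange = c(2L, 2L),
                                    nLocations = 1), seed = 95)
  grm <- buildGRM(pedigree(co))
  n <- nIndividuals(co)
  set.seed(96)
  reps <- 20000
  P <- matrix(0, reps, n)
  for (r in seq_len(reps)) {
    eff <- sampleLatentEffects(co, truth, grm = grm)
    P[r, ] <- truth$k_ge * eff$G * eff$E
  }
  emp <- cov(P)
  closed <- truth$k_ge^2 * truth$sigma_g_sq * truth$sigma_e_sq *
    (matrixValues(grm) * diag(n))
  # only diagonal entries are nonzero; off-diagonals vanish
  expect_lt(norm(emp - closed, "F") / norm(closed, "F"), 0.05)
  expect_lt(max(abs(emp[upper.tri(emp)])), 0.12)
})
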