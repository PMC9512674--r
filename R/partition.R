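# Posterior variance-partition statistics and model-comparison criteria
# (WAIC, PSIS-LOO-CV) on the deviance scale.

.STAT_ORDER <- c("p2", "h2", "f2", "c2", "s2", "e2",
                 "hf2", "hc2", "hs2", "he2")

#' Posterior variance-partition statistics
#'
#' For every posterior draw, computes the liability-scale variance
#' contribution of each component the model includes (see
#' [totalVariance()]) and divides by their sum, giving per-draw fractions
#' p2, h2, f2, c2, s2, e2 and interaction fractions hf2, hc2, hs2, he2.
#' Fractions are then summarized by the posterior mean and the 95%
#' highest-posterior-density interval (fraction first, summary second,
#' because the reported intervals are intervals of the statistics
#' themselves). Draws with zero total variance are excluded and counted.
#'
#' @param draws a [PosteriorDraws-class], or a data.frame/matrix with
#'   columns `sigma2_*` / `k_*` for arbitrary (e.g. hand-constructed)
#'   draws.
#' @param spec the [ModelSpec-class]; defaults to the spec stored in
#'   `draws`.
#' @param mass credible mass of the HPD intervals.
#' @return a [PartitionStatistics-class].
#' @export
varianceFractions <- function(draws, spec = NULL, mass = 0.95) {
  if (is(draws, "PosteriorDraws")) {
    if (is.null(spec)) spec <- draws@spec
    D <- draws@draws
  } else {
    D <- as.matrix(draws)
    if (is.null(spec)) stop("spec is required for plain draw matrices")
  }
  if (is.character(spec)) spec <- modelSpec(spec)
  gcol <- function(nm) {
    if (!nm %in% colnames(D)) stop("draws lack column ", nm)
    as.numeric(D[, nm])
  }
  contrib <- list()
  if (spec@includeGeo) contrib$p2 <- gcol("sigma2_P")
  contrib$h2 <- gcol("sigma2_G")
  envMap <- c(F = "f2", C = "c2", S = "s2", E = "e2")
  for (e in c("F", "C", "S", "E")) {
    if (e %in% spec@environments)
      contrib[[envMap[[e]]]] <- gcol(paste0("sigma2_", e))
  }
  iaMap <- c(GF = "hf2", GC = "hc2", GS = "hs2", GE = "he2")
  for (ia in c("GF", "GC", "GS", "GE")) {
    if (ia %in% spec@interactions) {
      e <- substr(ia, 2, 2)
      contrib[[iaMap[[ia]]]] <- gcol(paste0("k_", ia))^2 *
        gcol("sigma2_G") * gcol(paste0("sigma2_", e))
    }
  }
  M <- do.call(cbind, contrib)
  tot <- rowSums(M)
  keep <- tot > 0
  frac <- M[keep, , drop = FALSE] / tot[keep]
  ord <- .STAT_ORDER[.STAT_ORDER %in% colnames(frac)]
  frac <- frac[, ord, drop = FALSE]
  sm <- data.frame(statistic = ord,
                   mean = colMeans(frac),
                   lower = NA_real_, upper = NA_real_,
                   row.names = NULL)
  for (i in seq_along(ord)) {
    h <- if (nrow(frac) < 2L) rep(frac[1, i], 2)
         else hpdInterval(frac[, i], mass = mass)
    sm$lower[i] <- h[1]; sm$upper[i] <- h[2]
  }
  new("PartitionStatistics", summary = sm, perDraw = frac,
      excluded = as.integer(sum(!keep)))
}

#' Highest-posterior-density interval
#'
#' The shortest interval containing the requested posterior mass,
#' computed as the minimal-width window over the sorted samples
#' (via [coda::HPDinterval()]).
#'
#' @param samples numeric vector of posterior samples (>= 2 finite
#'   values).
#' @param mass credible mass in (0, 1).
#' @return numeric `c(lower, upper)`.
#' @export
hpdInterval <- function(samples, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)")
  samples <- samples[is.finite(samples)]
  if (length(samples) < 2L) stop("need at least two finite samples")
  h <- coda::HPDinterval(coda::as.mcmc(as.numeric(samples)), prob = mass)
  c(h[1, "lower"], h[1, "upper"])
}

.logMeanExp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Widely applicable information criterion (deviance scale)
#'
#' `WAIC = -2 (lppd - p_waic)` with
#' `lppd = sum_i log mean_s exp(ll_si)` and
#' `p_waic = sum_i var_s(ll_si)`. The 95% confidence interval is the
#' normal approximation `value +/- 1.96 * SE`,
#' `SE = sqrt(n * var_i(pointwise))` over the pointwise deviance-scale
#' contributions. Lower is better.
#'
#' @param loglik draws-by-observations matrix of pointwise
#'   log-likelihoods (see [pointwiseLogLik()]).
#' @return list: `waic`, `se`, `ci`, `lppd`, `p_waic`, `pointwise`
#'   (deviance-scale per-observation contributions).
#' @export
waic <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (any(!is.finite(loglik))) {
    bad <- unique(which(!is.finite(loglik), arr.ind = TRUE)[, 2])
    stop("non-finite log-likelihood for observation(s): ",
         paste(head(bad, 10), collapse = ", "))
  }
  lppd_i <- apply(loglik, 2, .logMeanExp)
  p_i <- apply(loglik, 2, var)
  pointwise <- -2 * (lppd_i - p_i)
  n <- ncol(loglik)
  se <- sqrt(n * var(pointwise))
  value <- sum(pointwise)
  list(waic = value, se = se, ci = value + c(-1.96, 1.96) * se,
       lppd = sum(lppd_i), p_waic = sum(p_i), pointwise = pointwise)
}

# Zhang-Stephens (2009) posterior-mean fit of the generalized Pareto
# shape/scale to exceedances x > 0 (sorted or not).
.gpdFit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior <- 3
  M <- 30 + floor(sqrt(n))
  jj <- seq_len(M)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  bs <- 1 / x[n] + (1 - sqrt(M / (jj - 0.5))) / (prior * xstar * sqrt(M))
  ks <- vapply(bs, function(b) -mean(log1p(-b * x)), numeric(1))
  L <- n * (log(bs / ks) + ks - 1)
  w <- vapply(seq_len(M), function(j) 1 / sum(exp(L - L[j])), numeric(1))
  b <- sum(bs * w)
  # report the shape in the heavy-tail-positive convention (xi)
  k <- mean(log1p(-b * x))
  list(k = k, sigma = -k / b)
}

# quantile of the generalized Pareto (location 0) in (k, sigma)
.gpdQuantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

#' PSIS-LOO cross-validation (deviance scale)
#'
#' Leave-one-out predictive density estimated by Pareto-smoothed
#' importance sampling: per observation, the largest 20% of the raw
#' importance ratios are replaced by expected order statistics of a
#' generalized Pareto distribution fitted to them (Zhang-Stephens
#' posterior-mean estimator), truncated at the raw maximum. Observations
#' with shape diagnostic `k > 0.7` are unreliable and flagged. With too
#' few draws for a tail fit (< 100), falls back to truncated importance
#' sampling with a warning.
#'
#' @param loglik draws-by-observations matrix of pointwise
#'   log-likelihoods.
#' @return list: `loo`, `se`, `ci`, `pareto_k` (per observation),
#'   `pointwise` (deviance-scale contributions).
#' @export
psisLoo <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (any(!is.finite(loglik))) {
    bad <- unique(which(!is.finite(loglik), arr.ind = TRUE)[, 2])
    stop("non-finite log-likelihood for observation(s): ",
         paste(head(bad, 10), collapse = ", "))
  }
  S <- nrow(loglik); n <- ncol(loglik)
  smooth <- S >= 100L
  if (!smooth)
    warning("fewer than 100 draws; using truncated importance sampling ",
            "without Pareto smoothing")
  elpd_i <- numeric(n)
  pareto_k <- numeric(n)
  for (i in seq_len(n)) {
    ll <- loglik[, i]
    lw <- -ll                      # log raw importance ratios
    lw <- lw - max(lw)
    if (sd(lw) < 1e-12) {
      # degenerate posterior: uniform weights, LOO reduces to lppd
      pareto_k[i] <- -Inf
      elpd_i[i] <- .logMeanExp(ll)
      next
    }
    M <- floor(0.2 * S)
    if (smooth && M >= 5L) {
      ord <- order(lw)
      tailIdx <- ord[(S - M + 1):S]
      cutoff <- lw[ord[S - M]]
      exceed <- exp(lw[tailIdx]) - exp(cutoff)
      # ties (repeated draws) may produce zero exceedances; fit the tail
      # to the strictly positive ones
      pos <- exceed[exceed > 0]
      if (length(pos) >= 5L) {
        fit <- .gpdFit(pos)
        pareto_k[i] <- fit$k
        pq <- (seq_len(M) - 0.5) / M
        sm <- exp(cutoff) + vapply(pq, .gpdQuantile, numeric(1),
                                   k = fit$k, sigma = fit$sigma)
        sm <- pmin(sm, exp(max(lw)))
        lw[tailIdx[order(lw[tailIdx])]] <- log(sm)
      } else {
        pareto_k[i] <- NA_real_
      }
    } else {
      # truncated IS: cap weights at mean * S^(3/4)
      lw <- pmin(lw, .logMeanExp(lw) + 0.75 * log(S))
      pareto_k[i] <- NA_real_
    }
    lw <- lw - .logMeanExp(lw) - log(S)   # normalized log weights
    elpd_i[i] <- .logMeanExp(ll + lw + log(S))
  }
  pointwise <- -2 * elpd_i
  se <- sqrt(n * var(pointwise))
  value <- sum(pointwise)
  list(loo = value, se = se, ci = value + c(-1.96, 1.96) * se,
       pareto_k = pareto_k, pointwise = pointwise)
}

#' Model-fit report (WAIC + PSIS-LOO) for one fitted model
#'
#' @param model the fitted [LiabilityModel-class].
#' @param draws its [PosteriorDraws-class].
#' @return a [ModelFitReport-class].
#' @export
fitReport <- function(model, draws) {
  ll <- pointwiseLogLik(model, draws)
  w <- waic(ll)
  l <- psisLoo(ll)
  new("ModelFitReport", model = model@spec@name,
      waic = w$waic, waicSE = w$se, waicCI = w$ci,
      loo = l$loo, looSE = l$se, looCI = l$ci,
      paretoK = l$pareto_k, n = ncol(ll))
}

#' Forward-selection comparison of fitted models
#'
#' Orders a list of [ModelFitReport-class] objects (one forward-selection
#' trace) and tabulates WAIC and PSIS-LOO with deltas to the best model
#' per criterion. WAIC is the headline criterion; PSIS-LOO is
#' confirmatory. When the criteria disagree, or when the best two models'
#' confidence intervals overlap, the table says so rather than silently
#' resolving the tie.
#'
#' @param reports list of [ModelFitReport-class] on the same cohort and
#'   phenotype.
#' @return data.frame with one row per model: criteria values, standard
#'   errors, deltas, `best_waic` / `best_loo` flags and a `note` column
#'   (`"indistinguishable"` where the best models' CIs overlap).
#' @export
selectionTrace <- function(reports) {
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, is, logical(1), "ModelFitReport")))
  ns <- vapply(reports, function(r) r@n, integer(1))
  if (length(unique(ns)) != 1L)
    stop("reports cover different cohorts (observation counts differ)")
  tab <- data.frame(
    model = vapply(reports, function(r) r@model, character(1)),
    waic = vapply(reports, function(r) r@waic, numeric(1)),
    waic_se = vapply(reports, function(r) r@waicSE, numeric(1)),
    loo = vapply(reports, function(r) r@loo, numeric(1)),
    loo_se = vapply(reports, function(r) r@looSE, numeric(1)))
  tab$delta_waic <- tab$waic - min(tab$waic)
  tab$delta_loo <- tab$loo - min(tab$loo)
  tab$best_waic <- tab$waic == min(tab$waic)
  tab$best_loo <- tab$loo == min(tab$loo)
  tab$note <- ""
  bw <- which.min(tab$waic)
  for (i in seq_len(nrow(tab))) {
    if (i == bw) next
    lo_i <- tab$waic[i] - 1.96 * tab$waic_se[i]
    hi_b <- tab$waic[bw] + 1.96 * tab$waic_se[bw]
    if (lo_i <= hi_b) tab$note[i] <- "indistinguishable"
  }
  if (which.min(tab$waic) != which.min(tab$loo))
    attr(tab, "criterion_disagreement") <- TRUE
  tab
}
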