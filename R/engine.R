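# Posterior computation: ADVI-initialized NUTS over four independent
# chains, pooling by concatenation, and convergence diagnostics.

#' Sampler configuration
#'
#' Defaults: 4 chains, 1000 warmup + 1000 kept draws per chain, target
#' acceptance 0.9 (the interaction models are ill-conditioned; a high
#' target acceptance reduces divergences), variational initialization.
#' All randomness of a run flows from `seed` through R's RNG: the ADVI
#' fit, per-chain jittered starts and every NUTS trajectory are drawn from
#' one seeded stream, so reruns are bit-identical on a platform.
#'
#' @param nChains,warmup,draws,targetAccept,maxTreedepth,seed,init,adviIters
#'   see [SamplerConfig-class].
#' @return a [SamplerConfig-class].
#' @export
samplerConfig <- function(nChains = 4L, warmup = 1000L, draws = 1000L,
                          targetAccept = 0.9, maxTreedepth = 10L,
                          seed = 1L, init = c("variational", "random"),
                          adviIters = 250L) {
  new("SamplerConfig", nChains = as.integer(nChains),
      warmup = as.integer(warmup), draws = as.integer(draws),
      targetAccept = targetAccept, maxTreedepth = as.integer(maxTreedepth),
      seed = as.integer(seed), init = match.arg(init),
      adviIters = as.integer(adviIters))
}

#' Initial values for each chain
#'
#' With `init = "variational"`, fits a mean-field ADVI approximation to the
#' posterior and draws each chain's start from it (an optimized,
#' independently jittered start). If the variational objective diverges,
#' falls back to random initialization with a warning. With
#' `init = "random"`, starts are scaled unit Gaussians on the
#' unconstrained scale.
#'
#' @param model a [LiabilityModel-class].
#' @param config a [SamplerConfig-class].
#' @return list with `inits` (list of numeric vectors, one per chain) and
#'   `method` actually used.
#' @export
initializeChains <- function(model, config) {
  d <- modelDimension(model)
  method <- config@init
  inits <- NULL
  if (method == "variational") {
    fit <- fg_advi(.modelPtr(model), config@adviIters, 1L, 0.05)
    if (isTRUE(fit$converged) && all(is.finite(fit$mu))) {
      inits <- lapply(seq_len(config@nChains), function(ch)
        fit$mu + exp(fit$omega) * rnorm(d))
    } else {
      warning("variational initialization diverged; falling back to random inits")
      method <- "random"
    }
  }
  if (is.null(inits))
    inits <- lapply(seq_len(config@nChains), function(ch) 0.1 * rnorm(d))
  list(inits = inits, method = method)
}

#' Draw from the posterior of a liability model
#'
#' Runs `nChains` independent NUTS chains (dual-averaging step-size
#' adaptation, diagonal mass-matrix adaptation during warmup), discards
#' warmup, pools the kept draws by concatenation, and transforms them to
#' the constrained scale: fixed-effect coefficients (`beta.*`), variance
#' scales (`sigma2_*`), the spatial length scale (`ell`), interaction
#' factors (`k_*`), the horseshoe global scale (`tau`) and the latent
#' effect vectors (`G.*`, `F.*`, `C.*`, `S.*`, `E.*`, `fp.*`).
#'
#' @param model a [LiabilityModel-class].
#' @param config a [SamplerConfig-class].
#' @return a [PosteriorDraws-class].
#' @export
sampleModel <- function(model, config = samplerConfig()) {
  set.seed(config@seed)
  ptr <- .modelPtr(model)
  ini <- initializeChains(model, config)
  rawAll <- vector("list", config@nChains)
  diag <- list(divergences = integer(config@nChains),
               treedepth = vector("list", config@nChains),
               stepsize = numeric(config@nChains),
               acceptStat = numeric(config@nChains),
               energy = vector("list", config@nChains),
               init = ini$method)
  for (ch in seq_len(config@nChains)) {
    res <- fg_nuts(ptr, ini$inits[[ch]], config@warmup, config@draws,
                   config@targetAccept, config@maxTreedepth)
    rawAll[[ch]] <- res$draws
    diag$divergences[ch] <- sum(res$divergent)
    diag$treedepth[[ch]] <- res$treedepth
    diag$stepsize[ch] <- res$stepsize
    diag$acceptStat[ch] <- mean(res$accept_stat)
    diag$energy[[ch]] <- res$energy
  }
  raw <- do.call(rbind, rawAll)
  chain <- rep(seq_len(config@nChains), each = config@draws)
  D <- .constrainDraws(model, raw)
  new("PosteriorDraws", draws = D, chain = as.integer(chain),
      spec = model@spec, diagnostics = diag)
}

# map raw unconstrained draws to named constrained parameters + effects
.constrainDraws <- function(model, raw) {
  idx <- model@paramIndex
  st <- model@structures
  spec <- model@spec
  n <- length(model@y)
  p <- ncol(model@X)
  iters <- nrow(raw)
  ids <- model@labels

  z <- raw[, idx$z_beta, drop = FALSE]
  lam <- exp(raw[, idx$log_lambda, drop = FALSE])
  tau <- exp(raw[, idx$log_tau])
  B <- matrix(0, iters, p)
  B[, 1] <- st$priors$beta0_sd * z[, 1]
  for (j in 2:p)
    B[, j] <- st$priors$hs_scale * tau * lam[, j - 1] * z[, j]
  colnames(B) <- paste0("beta.", colnames(model@X))

  out <- list(B, matrix(tau, ncol = 1, dimnames = list(NULL, "tau")))

  s2G <- exp(raw[, idx$log_sigma2_G])
  UG <- raw[, idx$u_G, drop = FALSE]
  G <- as.matrix(Matrix::tcrossprod(UG, st$LG)) * sqrt(s2G)
  colnames(G) <- paste0("G.", ids)
  out <- c(out, list(
    matrix(s2G, ncol = 1, dimnames = list(NULL, "sigma2_G")), G))

  for (e in spec@environments) {
    ei <- match(e, st$env_codes)
    s2 <- exp(raw[, idx[[paste0("log_sigma2_", e)]]])
    U <- raw[, idx[[paste0("u_", e)]], drop = FALSE]
    comp <- U[, st$groups[[ei]], drop = FALSE] * sqrt(s2)
    colnames(comp) <- paste0(e, ".", ids)
    out <- c(out, list(
      matrix(s2, ncol = 1,
             dimnames = list(NULL, paste0("sigma2_", e))), comp))
  }
  for (ia in spec@interactions) {
    k <- raw[, idx[[paste0("k_", ia)]]]
    out <- c(out, list(
      matrix(k, ncol = 1, dimnames = list(NULL, paste0("k_", ia)))))
  }
  if (spec@includeGeo) {
    s2P <- exp(raw[, idx$log_sigma2_P])
    ell <- exp(raw[, idx$log_ell])
    UP <- raw[, idx$u_P, drop = FALSE]
    m <- ncol(UP)
    W <- matrix(0, iters, m)
    for (s in seq_len(iters)) {
      K0 <- exp(-st$D2 / (2 * ell[s]^2)) + diag(st$priors$jitter, m)
      W[s, ] <- as.numeric(t(chol(K0)) %*% UP[s, ])
    }
    fp <- W[, st$loc, drop = FALSE] * sqrt(s2P)
    colnames(fp) <- paste0("fp.", ids)
    out <- c(out, list(
      matrix(s2P, ncol = 1, dimnames = list(NULL, "sigma2_P")),
      matrix(ell, ncol = 1, dimnames = list(NULL, "ell")), fp))
  }
  do.call(cbind, out)
}

#' Convergence diagnostics for pooled draws
#'
#' Split R-hat (each chain halved) and effective sample size for the
#' scalar model parameters (fixed effects, variance scales, interaction
#' factors, spatial length scale), plus divergence counts per chain. With
#' a single chain, R-hat is unavailable and flagged `NA`.
#'
#' @param draws a [PosteriorDraws-class].
#' @param parameters optional character vector of draw columns to
#'   diagnose; default: all scalar model parameters.
#' @return list with `summary` (data.frame: parameter, rhat, ess) and
#'   `divergences` (per chain).
#' @export
samplerDiagnostics <- function(draws, parameters = NULL) {
  stopifnot(is(draws, "PosteriorDraws"))
  D <- draws@draws
  if (is.null(parameters)) {
    parameters <- grep("^(beta\\.|sigma2_|k_|ell$|tau$)",
                       colnames(D), value = TRUE)
  }
  chains <- sort(unique(draws@chain))
  rhat <- vapply(parameters, function(pn) {
    .splitRhat(D[, pn], draws@chain)
  }, numeric(1))
  ess <- vapply(parameters, function(pn) {
    sum(vapply(chains, function(ch)
      as.numeric(coda::effectiveSize(D[draws@chain == ch, pn])),
      numeric(1)))
  }, numeric(1))
  list(summary = data.frame(parameter = parameters, rhat = rhat, ess = ess,
                            row.names = NULL),
       divergences = draws@diagnostics$divergences)
}

# split R-hat: each chain split in half, potential scale reduction factor
.splitRhat <- function(x, chain) {
  chains <- sort(unique(chain))
  if (length(chains) < 2L && sum(chain == chains[1]) < 4L) return(NA_real_)
  halves <- list()
  for (ch in chains) {
    v <- x[chain == ch]
    h <- length(v) %/% 2L
    if (h < 2L) return(NA_real_)
    halves <- c(halves, list(v[seq_len(h)], v[(h + 1L):(2L * h)]))
  }
  m <- length(halves)
  nn <- min(lengths(halves))
  halves <- lapply(halves, function(v) v[seq_len(nn)])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- nn * var(means)
  if (!is.finite(W) || W <= 0) {
    return(if (isTRUE(all.equal(B, 0))) 1 else Inf)
  }
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' NUTS on an arbitrary log-density
#'
#' Runs the package's No-U-Turn sampler against a user-supplied
#' log-density-with-gradient function. Used to validate the sampler on
#' targets with known posteriors; the liability models go through the
#' compiled path in [sampleModel()].
#'
#' @param logpGrad function taking a numeric vector and returning
#'   `list(lp = , grad = )`.
#' @param init numeric starting vector (its length fixes the dimension).
#' @param warmup,draws,targetAccept,maxTreedepth sampler settings.
#' @return list with `draws` (matrix), `divergent`, `treedepth`,
#'   `accept_stat`, `stepsize`.
#' @export
nutsGeneric <- function(logpGrad, init, warmup = 500L, draws = 500L,
                        targetAccept = 0.9, maxTreedepth = 10L) {
  fg_nuts_generic(logpGrad, as.numeric(init), as.integer(warmup),
                  as.integer(draws), targetAccept, as.integer(maxTreedepth))
}
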