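# The five nested liability models (plus the reduced interaction model used
# by the coverage simulation study), assembled into a compiled
# Bernoulli-logit posterior with horseshoe priors on fixed effects,
# zero-avoiding Gamma priors on variance scales, and non-centered latent
# effects.

.TABLE1 <- list(
  LM0 = list(geo = FALSE, env = "E",                  ia = character()),
  LM1 = list(geo = TRUE,  env = "E",                  ia = character()),
  IM1 = list(geo = TRUE,  env = "E",                  ia = "GE"),
  LM2 = list(geo = TRUE,  env = c("F", "C", "S", "E"), ia = character()),
  IM2 = list(geo = TRUE,  env = c("F", "C", "S", "E"),
             ia = c("GF", "GC", "GS", "GE")),
  # reduced interaction model of the simulation study: G + E + k.G.E, no GP
  IM0 = list(geo = FALSE, env = "E",                  ia = "GE")
)

#' Construct a model specification
#'
#' The five models of the two forward-selection traces, by name:
#' \describe{
#'   \item{LM0}{genetics G + independent environment E.}
#'   \item{LM1}{LM0 + Gaussian-process term over residence coordinates.}
#'   \item{IM1}{LM1 + gene-environment interaction `k_GE * G * E`.}
#'   \item{LM2}{geo + G + family F + couple C + sibling S + E.}
#'   \item{IM2}{LM2 + all four interaction terms (GF, GC, GS, GE).}
#' }
#' The additional name `"IM0"` denotes the reduced interaction model
#' (G + E + `k_GE * G * E`, no spatial term) under which the coverage
#' simulation study simulates and fits.
#'
#' @param name one of `"LM0"`, `"LM1"`, `"IM1"`, `"LM2"`, `"IM2"`, `"IM0"`.
#' @return a [ModelSpec-class].
#' @export
modelSpec <- function(name = c("LM0", "LM1", "IM1", "LM2", "IM2", "IM0")) {
  name <- match.arg(name)
  def <- .TABLE1[[name]]
  new("ModelSpec", name = name, includeGeo = def$geo,
      environments = def$env, interactions = def$ia)
}

.ENV_ORDER <- c("F", "C", "S", "E")
.IA_ORDER <- c("GF", "GC", "GS", "GE")

.defaultPriors <- function() {
  list(hs_scale = 1, beta0_sd = 5, gam_shape = 2, gam_rate = 0.5,
       k_sd = 2, ell_a = 3, ell_b = NA_real_, jitter = 1e-6)
}

# group index vectors (1-based) of the shared-environment structures
.envGroups <- function(ped, env) {
  n <- nrow(ped)
  fam <- as.character(ped$family_id)
  key <- switch(env,
    F = fam,
    C = ifelse(ped$role == "parent", paste0("cp.", fam),
               paste0("i.", seq_len(n))),
    S = ifelse(ped$role == "child", paste0("sb.", fam),
               paste0("i.", seq_len(n))),
    E = as.character(seq_len(n)))
  match(key, unique(key))
}

#' Assemble a liability model for sampling
#'
#' Binds together the fixed-effect design, the phenotype, the structure
#' factors of every random effect the specification requests (the sparse
#' Cholesky factor of the genetic relationship matrix, shared-environment
#' group indicators, squared distances between unique residence locations)
#' and the prior configuration. Liability is
#' `X beta + f_p(x) + G + F + C + S + E + sum_k k * G * component` with the
#' terms the specification includes; the phenotype is Bernoulli with a
#' logit link. Latent effects use the non-centered parameterization
#' (unit-normal innovations transformed by structure factors).
#'
#' Priors: horseshoe (global scale 1) on all fixed-effect coefficients
#' except the intercept, which gets Normal(0, 5); zero-avoiding
#' Gamma(shape 2, rate 0.5) on every variance scale; on each interaction
#' factor, `k | sigmas ~ Normal(0, k_sd^2 / (sigma_G^2 sigma_comp^2))`,
#' so the implied interaction variance `k^2 sigma_G^2 sigma_comp^2` is a
#' priori on the scale of a single variance component (with the default
#' `k_sd = 2`, its prior mean equals the Gamma prior mean of the other
#' components); inverse-Gamma on the spatial length scale with
#' prior mean at half the maximum inter-location distance. All are
#' overridable through `priors`. The age column is centered at the cohort
#' mean before sampling (a pure reparameterization of the intercept).
#'
#' @param spec a [ModelSpec-class] (or model name).
#' @param cohort a [FamilyCohort-class] with a phenotype attached.
#' @param X optional design matrix; default [buildDesign()] of the cohort.
#' @param grm optional precomputed genetic [RelationshipMatrix-class]
#'   (labels must equal the cohort's canonical individual order).
#' @param priors named list overriding individual prior hyperparameters.
#' @return a [LiabilityModel-class].
#' @export
assembleModel <- function(spec, cohort, X = NULL, grm = NULL,
                          priors = list()) {
  if (is.character(spec)) spec <- modelSpec(spec)
  stopifnot(is(spec, "ModelSpec"), is(cohort, "FamilyCohort"))
  if (!length(cohort@phenotype))
    stop("cohort has no phenotype attached")
  ped <- cohort@pedigree
  n <- nrow(ped)
  ids <- as.character(ped$individual_id)
  if (is.null(X)) X <- buildDesign(cohort)
  if (!identical(rownames(X), ids))
    stop("design rows must follow the cohort's canonical individual order")
  if (is.null(grm)) grm <- buildGRM(ped)
  if (!identical(individualIds(grm), ids))
    stop("genetic relationship matrix labels must match the cohort order")
  pr <- utils::modifyList(.defaultPriors(), priors)

  Xs <- X
  ageCenter <- 0
  if ("age" %in% colnames(Xs)) {
    ageCenter <- mean(Xs[, "age"])
    Xs[, "age"] <- Xs[, "age"] - ageCenter
  }

  LG <- .structureFactor(grm, ped)
  envs <- .ENV_ORDER[.ENV_ORDER %in% spec@environments]
  groups <- lapply(envs, function(e) .envGroups(ped, e))
  ias <- .IA_ORDER[.IA_ORDER %in% spec@interactions]

  structures <- list(
    X = Xs, y = as.numeric(cohort@phenotype),
    LG = methods::as(methods::as(LG, "generalMatrix"), "CsparseMatrix"),
    use_geo = spec@includeGeo,
    env_codes = envs, groups = groups, interactions = ias,
    ageCenter = ageCenter)

  if (spec@includeGeo) {
    if (!nrow(cohort@coordinates))
      stop("model includes a spatial term but the cohort has no coordinates")
    co <- cohort@coordinates
    D2 <- .sqDistMatrix(as.matrix(co[, c("latitude", "longitude")]))
    locId <- as.character(co$location_id)
    locOf <- match(cohort@familyLocation[as.character(ped$family_id)], locId)
    structures$D2 <- D2
    structures$loc <- as.integer(locOf)
    structures$locationIds <- locId
    if (is.na(pr$ell_b)) {
      maxd <- sqrt(max(D2))
      if (maxd <= 0) maxd <- 1
      pr$ell_b <- (pr$ell_a - 1) * maxd / 2
    }
  } else {
    pr$ell_b <- if (is.na(pr$ell_b)) 1 else pr$ell_b
  }
  structures$priors <- pr

  model <- new("LiabilityModel", spec = spec, X = Xs,
               y = as.integer(cohort@phenotype), structures = structures,
               priors = pr, paramIndex = list(), labels = ids,
               cache = new.env(parent = emptyenv()))
  model@paramIndex <- .modelLayout(model)
  model
}

# build (or fetch cached) external pointer to the compiled model
.modelPtr <- function(model) {
  ptr <- model@cache$ptr
  if (is.null(ptr) ||
      isTRUE(tryCatch(fg_dim(ptr) < 0, error = function(e) TRUE))) {
    st <- model@structures
    dat <- list(X = st$X, y = st$y, LG = st$LG, use_geo = st$use_geo,
                env_codes = st$env_codes, groups = st$groups,
                interactions = st$interactions, priors = st$priors)
    if (st$use_geo) { dat$D2 <- st$D2; dat$loc <- st$loc }
    else { dat$D2 <- matrix(0, 0, 0); dat$loc <- integer() }
    ptr <- fg_build(dat)
    model@cache$ptr <- ptr
  }
  ptr
}

.modelLayout <- function(model) {
  lay <- fg_layout(.modelPtr(model))
  idx <- mapply(function(s, l) seq.int(s, length.out = l),
                lay$start, lay$length, SIMPLIFY = FALSE)
  names(idx) <- lay$block
  idx
}

#' Unnormalized log-posterior and gradient of a liability model
#'
#' Evaluates the model's joint log-density (up to a constant) and its
#' gradient at a point of the unconstrained parameter space. Exposed for
#' validation (finite-difference gradient checks, parameterization
#' equivalence) and generic use.
#'
#' @param model a [LiabilityModel-class].
#' @param theta numeric vector of length `modelDimension(model)`.
#' @return list with elements `lp` and `grad`.
#' @export
logPosterior <- function(model, theta) {
  stopifnot(length(theta) == modelDimension(model))
  fg_logp_grad(.modelPtr(model), as.numeric(theta))
}

#' @rdname logPosterior
#' @export
modelDimension <- function(model) fg_dim(.modelPtr(model))

#' Per-component liability variance contributions
#'
#' Given variance scales and interaction factors, returns the contribution
#' of every component the specification includes to the total liability
#' variance: `sigma_P^2`, `sigma_G^2`, `sigma_F^2`, `sigma_C^2`,
#' `sigma_S^2`, `sigma_E^2` and the interaction terms
#' `k^2 sigma_G^2 sigma_comp^2`, plus their sum. Contribution names follow
#' the partition statistics they feed (`p2`, `h2`, `f2`, `c2`, `s2`, `e2`,
#' `hf2`, `hc2`, `hs2`, `he2`).
#'
#' @param components named list or vector: `sigma_p_sq`, `sigma_g_sq`,
#'   `sigma_f_sq`, `sigma_c_sq`, `sigma_s_sq`, `sigma_e_sq`, `k_gf`,
#'   `k_gc`, `k_gs`, `k_ge` (only those the spec includes are read).
#' @param spec a [ModelSpec-class] (or model name).
#' @return list with `contributions` (named numeric) and `total`.
#' @export
totalVariance <- function(components, spec) {
  if (is.character(spec)) spec <- modelSpec(spec)
  cmp <- as.list(components)
  g <- function(nm) {
    v <- cmp[[nm]]
    if (is.null(v)) stop("component missing: ", nm)
    as.numeric(v)
  }
  out <- c()
  if (spec@includeGeo) out["p2"] <- g("sigma_p_sq")
  out["h2"] <- g("sigma_g_sq")
  envMap <- c(F = "f2", C = "c2", S = "s2", E = "e2")
  sigEnv <- c(F = "sigma_f_sq", C = "sigma_c_sq", S = "sigma_s_sq",
              E = "sigma_e_sq")
  for (e in .ENV_ORDER) {
    if (e %in% spec@environments) out[envMap[[e]]] <- g(sigEnv[[e]])
  }
  iaMap <- c(GF = "hf2", GC = "hc2", GS = "hs2", GE = "he2")
  kName <- c(GF = "k_gf", GC = "k_gc", GS = "k_gs", GE = "k_ge")
  for (ia in .IA_ORDER) {
    if (ia %in% spec@interactions) {
      e <- substr(ia, 2, 2)
      out[iaMap[[ia]]] <- g(kName[[ia]])^2 * g("sigma_g_sq") *
        g(sigEnv[[e]])
    }
  }
  list(contributions = out, total = sum(out))
}

.log1pexp <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

#' Pointwise log-likelihood matrix
#'
#' Computes the draws-by-individuals matrix of Bernoulli log-likelihoods
#' `log p(y_i | logistic(l_i^(s)))`, the input of [waic()] and [psisLoo()].
#' The liability of each draw is rebuilt from the stored fixed effects and
#' latent effect vectors.
#'
#' @param model the [LiabilityModel-class] the draws came from.
#' @param draws a [PosteriorDraws-class] (or its constrained draw matrix).
#' @return numeric matrix, rows = draws, columns = individuals.
#' @export
pointwiseLogLik <- function(model, draws) {
  D <- if (is(draws, "PosteriorDraws")) draws@draws else draws
  l <- .liabilityFromDraws(model, D)
  y <- as.numeric(model@y)
  ll <- t(t(l) * y) - .log1pexp(l)
  colnames(ll) <- model@labels
  ll
}

# draws x n liability matrix from constrained draws
.liabilityFromDraws <- function(model, D) {
  spec <- model@spec
  n <- length(model@y)
  cols <- colnames(D)
  pick <- function(prefix) {
    idx <- match(paste0(prefix, ".", model@labels), cols)
    if (anyNA(idx)) stop("draws lack columns for ", prefix)
    D[, idx, drop = FALSE]
  }
  B <- D[, paste0("beta.", colnames(model@X)), drop = FALSE]
  l <- B %*% t(model@X)
  G <- pick("G")
  l <- l + G
  for (e in spec@environments) {
    comp <- pick(e)
    l <- l + comp
    ia <- paste0("G", e)
    if (ia %in% spec@interactions)
      l <- l + D[, paste0("k_", ia)] * (G * comp)
  }
  if (spec@includeGeo) l <- l + pick("fp")
  unname(l)
}
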