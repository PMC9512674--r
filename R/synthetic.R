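# Synthetic cohorts with the statistical structure the analysis assumes:
# nuclear families (two parents, children aged >= 16), one residence
# coordinate per family, five EQI domain scores per location, and binary
# phenotypes generated from the liability models.

#' Construct a FamilyCohort from its parts
#'
#' Validates and canonically orders the pedigree (by family, parents before
#' children, ties by individual id). All matrices and designs built from
#' the cohort follow this single ordering.
#'
#' @param pedigree data.frame, see [FamilyCohort-class].
#' @param coordinates data.frame with `location_id`, `latitude`,
#'   `longitude`; may be empty for models without a spatial term.
#' @param familyLocation named vector mapping family ids to location ids.
#' @param eqiScores data.frame of standardized per-location domain scores.
#' @param phenotype optional 0/1 vector named by individual id (any order)
#'   or aligned with `pedigree` rows.
#' @return a [FamilyCohort-class].
#' @export
familyCohort <- function(pedigree, coordinates = data.frame(),
                         familyLocation = character(),
                         eqiScores = data.frame(), phenotype = NULL) {
  ped <- as.data.frame(pedigree)
  ord <- order(as.character(ped$family_id), ped$role != "parent",
               as.character(ped$individual_id))
  ped <- ped[ord, , drop = FALSE]
  rownames(ped) <- NULL
  y <- integer(0)
  if (!is.null(phenotype)) {
    if (!is.null(names(phenotype))) {
      idx <- match(as.character(ped$individual_id), names(phenotype))
      if (anyNA(idx))
        stop("phenotype missing for individuals: ",
             paste(ped$individual_id[is.na(idx)], collapse = ", "))
      y <- as.integer(phenotype[idx])
    } else {
      if (length(phenotype) != nrow(ped))
        stop("unnamed phenotype must match pedigree length")
      y <- as.integer(phenotype[ord])
    }
  }
  fl <- character()
  if (length(familyLocation))
    fl <- setNames(as.character(familyLocation), names(familyLocation))
  new("FamilyCohort", pedigree = ped,
      coordinates = as.data.frame(coordinates), familyLocation = fl,
      eqiScores = as.data.frame(eqiScores), phenotype = y)
}

#' Replace or attach the phenotype of a cohort
#'
#' @param cohort a [FamilyCohort-class].
#' @param phenotype 0/1 vector aligned with the cohort's canonical order
#'   (or named by individual id).
#' @return the updated cohort.
#' @export
setPhenotype <- function(cohort, phenotype) {
  stopifnot(is(cohort, "FamilyCohort"))
  if (!is.null(names(phenotype))) {
    idx <- match(individualIds(cohort), names(phenotype))
    if (anyNA(idx)) stop("phenotype names do not cover the cohort")
    phenotype <- phenotype[idx]
  }
  cohort@phenotype <- as.integer(phenotype)
  validObject(cohort)
  cohort
}

#' Cohort generator configuration
#'
#' Defaults describe the emulated study population: nuclear families of
#' two parents (ages 35-70) and one to three children aged 16-45, all
#' sharing one residence; locations drawn uniformly over the continental
#' US bounding box; three correlated raw variables per EQI domain
#' (cross-variable correlation 0.6) at each location.
#'
#' @param nFamilies number of families.
#' @param childrenRange integer range of children per family (uniform).
#' @param parentAgeRange,childAgeRange age ranges in years (children are
#'   never younger than 16).
#' @param nLocations number of distinct residence locations.
#' @param boundingBox named vector `latMin`, `latMax`, `lonMin`, `lonMax`.
#' @param eqiVarsPerDomain raw variables generated per EQI domain.
#' @param eqiCorrelation cross-variable correlation within a domain.
#' @return a named list of settings for [generateCohort()].
#' @export
cohortConfig <- function(nFamilies = 100L, childrenRange = c(1L, 3L),
                         parentAgeRange = c(35, 70),
                         childAgeRange = c(16, 45),
                         nLocations = 30L,
                         boundingBox = c(latMin = 25, latMax = 49,
                                         lonMin = -124, lonMax = -67),
                         eqiVarsPerDomain = 3L, eqiCorrelation = 0.6) {
  stopifnot(nFamilies >= 1L, all(childrenRange >= 0L),
            childAgeRange[1] >= 16, nLocations >= 1L,
            eqiCorrelation >= 0, eqiCorrelation <= 1)
  list(nFamilies = as.integer(nFamilies),
       childrenRange = as.integer(childrenRange),
       parentAgeRange = parentAgeRange, childAgeRange = childAgeRange,
       nLocations = as.integer(nLocations), boundingBox = boundingBox,
       eqiVarsPerDomain = as.integer(eqiVarsPerDomain),
       eqiCorrelation = eqiCorrelation)
}

#' Generate a synthetic cohort (pedigrees, residences, EQI scores)
#'
#' Families are two parents (one of each sex) plus a uniformly sampled
#' number of children with Bernoulli(0.5) sexes; ages are uniform within
#' the configured ranges. Each family is assigned one location uniformly;
#' per location, each EQI domain gets `eqiVarsPerDomain` raw Gaussian
#' variables sharing a latent factor (correlation `eqiCorrelation`),
#' summarized into one standardized score by [eqiPcaScore()]. Phenotypes
#' are not generated here; see [simulatePhenotype()] /
#' [simulateCohort()]. Deterministic given the R RNG state.
#'
#' @param config a [cohortConfig()] list.
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first.
#' @return a [FamilyCohort-class] without a phenotype.
#' @export
generateCohort <- function(config = cohortConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nf <- config$nFamilies
  nkids <- if (config$childrenRange[1] == config$childrenRange[2])
    rep(config$childrenRange[1], nf)
  else sample(seq(config$childrenRange[1], config$childrenRange[2]),
              nf, replace = TRUE)
  rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    fid <- sprintf("fam%04d", f)
    dad <- sprintf("%s.p1", fid); mom <- sprintf("%s.p2", fid)
    pAges <- round(runif(2, config$parentAgeRange[1],
                         config$parentAgeRange[2]), 1)
    kk <- nkids[f]
    kidIds <- if (kk > 0) sprintf("%s.c%d", fid, seq_len(kk)) else character()
    rows[[f]] <- data.frame(
      family_id = fid,
      individual_id = c(dad, mom, kidIds),
      father_id = c(NA, NA, rep(dad, kk)),
      mother_id = c(NA, NA, rep(mom, kk)),
      sex = c(1L, 0L, if (kk > 0) rbinom(kk, 1, 0.5) else integer()),
      age = c(pAges, if (kk > 0)
        round(runif(kk, config$childAgeRange[1],
                    config$childAgeRange[2]), 1) else numeric()),
      role = c("parent", "parent", rep("child", kk)))
  }
  ped <- do.call(rbind, rows)
  bb <- config$boundingBox
  nl <- config$nLocations
  coords <- data.frame(
    location_id = sprintf("loc%03d", seq_len(nl)),
    latitude = runif(nl, bb["latMin"], bb["latMax"]),
    longitude = runif(nl, bb["lonMin"], bb["lonMax"]))
  famLoc <- setNames(sample(coords$location_id, nf, replace = TRUE),
                     unique(ped$family_id))
  # correlated raw EQI variables per domain, then PCA-summarized
  eqi <- data.frame(location_id = coords$location_id)
  rho <- config$eqiCorrelation
  for (dom in .EQI_DOMAINS) {
    latent <- rnorm(nl)
    block <- matrix(vapply(seq_len(config$eqiVarsPerDomain), function(v)
      sqrt(rho) * latent + sqrt(1 - rho) * rnorm(nl), numeric(nl)),
      nrow = nl)
    colnames(block) <- sprintf("%s_v%d", dom, seq_len(ncol(block)))
    eqi[[dom]] <- if (nl >= 2) eqiPcaScore(block) else 0
  }
  familyCohort(ped, coords, famLoc, eqi)
}

#' Generative truth for simulation
#'
#' Bundles the variance scales, interaction factors and fixed-effect
#' coefficients under which liabilities are simulated. Components absent
#' from the spec are held at zero; fixed-effect coefficients default to
#' zero (so variance-partition recovery is not confounded by fixed-effect
#' misfit) but may be set freely.
#'
#' @param spec a [ModelSpec-class] or model name (default the reduced
#'   interaction model `"IM0"` of the coverage study).
#' @param sigma_p_sq,sigma_g_sq,sigma_f_sq,sigma_c_sq,sigma_s_sq,sigma_e_sq
#'   variance scales.
#' @param k_gf,k_gc,k_gs,k_ge interaction scale factors.
#' @param length_scale spatial length scale (degrees).
#' @param beta named or plain numeric vector of fixed-effect coefficients
#'   matching the design columns; default all zero.
#' @return a named list (class `"GenerativeTruth"`).
#' @export
generativeTruth <- function(spec = "IM0", sigma_g_sq = 3, sigma_e_sq = 3,
                            k_ge = 1 / 3, sigma_p_sq = 0, sigma_f_sq = 0,
                            sigma_c_sq = 0, sigma_s_sq = 0, k_gf = 0,
                            k_gc = 0, k_gs = 0, length_scale = 5,
                            beta = NULL) {
  if (is.character(spec)) spec <- modelSpec(spec)
  tr <- list(spec = spec, sigma_p_sq = sigma_p_sq, sigma_g_sq = sigma_g_sq,
             sigma_f_sq = sigma_f_sq, sigma_c_sq = sigma_c_sq,
             sigma_s_sq = sigma_s_sq, sigma_e_sq = sigma_e_sq,
             k_gf = k_gf, k_gc = k_gc, k_gs = k_gs, k_ge = k_ge,
             length_scale = length_scale, beta = beta)
  class(tr) <- "GenerativeTruth"
  tr
}

#' Draw latent effect vectors under a generative truth
#'
#' Each component the truth's spec includes is drawn multivariate normal
#' with covariance `sigma^2 * Sigma` via its structure factor; the spatial
#' effect is drawn at unique locations from the exponentiated-quadratic
#' covariance and expanded to individuals. Components are independent of
#' one another.
#'
#' @param cohort a [FamilyCohort-class].
#' @param truth a [generativeTruth()] object.
#' @param grm optional precomputed genetic [RelationshipMatrix-class].
#' @return named list of per-individual effect vectors (`G`, and `F`,
#'   `C`, `S`, `E`, `fp` as included; absent components are zero
#'   vectors).
#' @export
sampleLatentEffects <- function(cohort, truth, grm = NULL) {
  stopifnot(is(cohort, "FamilyCohort"))
  ped <- cohort@pedigree
  n <- nrow(ped)
  spec <- truth$spec
  zero <- rep(0, n)
  eff <- list(G = zero, F = zero, C = zero, S = zero, E = zero, fp = zero)
  if (is.null(grm)) grm <- buildGRM(ped)
  LG <- .structureFactor(grm, ped)
  eff$G <- sqrt(truth$sigma_g_sq) * as.numeric(LG %*% rnorm(n))
  sig <- c(F = truth$sigma_f_sq, C = truth$sigma_c_sq,
           S = truth$sigma_s_sq, E = truth$sigma_e_sq)
  for (e in spec@environments) {
    g <- .envGroups(ped, e)
    eff[[e]] <- sqrt(sig[[e]]) * rnorm(max(g))[g]
  }
  if (spec@includeGeo && truth$sigma_p_sq > 0) {
    co <- cohort@coordinates
    K <- matrixValues(buildGeoCovariance(co, truth$sigma_p_sq,
                                         truth$length_scale))
    L <- t(chol(K))
    w <- as.numeric(L %*% rnorm(nrow(co)))
    locOf <- match(cohort@familyLocation[as.character(ped$family_id)],
                   as.character(co$location_id))
    eff$fp <- w[locOf]
  }
  eff
}

#' Simulate a binary phenotype from liabilities
#'
#' Assembles the liability `X beta + effects + interaction products` under
#' the truth's spec and draws `y_i ~ Bernoulli(logistic(l_i))`. The
#' liability vector is attached as attribute `"liability"`.
#'
#' @param design fixed-effect design matrix ([buildDesign()]).
#' @param effects latent effects from [sampleLatentEffects()].
#' @param truth a [generativeTruth()] object.
#' @return integer 0/1 vector with attribute `liability`.
#' @export
simulatePhenotype <- function(design, effects, truth) {
  l <- liabilityFromEffects(design, effects, truth)
  y <- rbinom(length(l), 1, plogis(l))
  attr(y, "liability") <- l
  y
}

#' @rdname simulatePhenotype
#' @export
liabilityFromEffects <- function(design, effects, truth) {
  spec <- truth$spec
  beta <- truth$beta
  if (is.null(beta)) beta <- rep(0, ncol(design))
  if (!is.null(names(beta))) {
    beta <- beta[colnames(design)]
    if (anyNA(beta))
      stop("named beta must cover every design column")
  }
  if (length(beta) != ncol(design))
    stop("beta length must match the design columns")
  l <- as.numeric(design %*% beta) + effects$G
  kv <- c(F = truth$k_gf, C = truth$k_gc, S = truth$k_gs, E = truth$k_ge)
  for (e in spec@environments) {
    l <- l + effects[[e]]
    if (paste0("G", e) %in% spec@interactions)
      l <- l + kv[[e]] * effects$G * effects[[e]]
  }
  if (spec@includeGeo) l <- l + effects$fp
  l
}

#' One-call synthetic cohort with phenotype
#'
#' [generateCohort()] + [sampleLatentEffects()] + [simulatePhenotype()].
#'
#' @param config a [cohortConfig()] list.
#' @param truth a [generativeTruth()] object.
#' @param seed optional integer seed.
#' @return a [FamilyCohort-class] with phenotype attached; the latent
#'   effects and liability are attached as attributes `effects` and
#'   `liability` for validation use.
#' @export
simulateCohort <- function(config = cohortConfig(),
                           truth = generativeTruth(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cohort <- generateCohort(config)
  X <- buildDesign(cohort)
  eff <- sampleLatentEffects(cohort, truth)
  y <- simulatePhenotype(X, eff, truth)
  out <- setPhenotype(cohort, as.integer(y))
  attr(out, "effects") <- eff
  attr(out, "liability") <- attr(y, "liability")
  out
}
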