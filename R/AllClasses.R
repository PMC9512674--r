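#' @import methods
#' @importFrom stats var sd rnorm runif rbinom plogis qlogis quantile setNames
#'   prcomp rgamma rcauchy median cor dist aggregate complete.cases
#' @importFrom utils head read.csv write.csv read.table write.table
#' @useDynLib famGxE, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.EQI_DOMAINS <- c("air", "water", "land", "sociodemographic", "built")

.MATRIX_KINDS <- c("genetic", "family", "couple", "sibling", "geographic",
                   "identity", "product")

#' RelationshipMatrix: a labelled structure matrix over individuals
#'
#' Symmetric covariance-structure matrices used by the liability models:
#' the pedigree-derived additive genetic relationship matrix, the 0/1
#' shared-environment structures (family, couple, sibling), the Gaussian
#' process covariance over residence coordinates, and the identity.
#'
#' @slot values numeric matrix with identical row/column labels
#'   (individual ids, or location ids for the geographic kind).
#' @slot kind one of `"genetic"`, `"family"`, `"couple"`, `"sibling"`,
#'   `"geographic"`, `"identity"`.
#'
#' @seealso [buildGRM()], [buildFamilyMatrix()], [buildCoupleMatrix()],
#'   [buildSiblingMatrix()], [buildGeoCovariance()], [hadamard()]
#' @export
setClass("RelationshipMatrix",
         slots = c(values = "matrix", kind = "character"))

setValidity("RelationshipMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (length(object@kind) != 1L || !object@kind %in% .MATRIX_KINDS)
    msgs <- c(msgs, sprintf("kind must be one of: %s",
                            paste(.MATRIX_KINDS, collapse = ", ")))
  if (nrow(v) != ncol(v))
    msgs <- c(msgs, "matrix must be square")
  if (is.null(rownames(v)) || is.null(colnames(v)) ||
      !identical(rownames(v), colnames(v)))
    msgs <- c(msgs, "row and column labels must be present and identical")
  if (anyDuplicated(rownames(v)))
    msgs <- c(msgs, "labels must be unique")
  if (nrow(v) > 0L && max(abs(v - t(v))) > 1e-10)
    msgs <- c(msgs, "matrix must be symmetric")
  if (length(msgs)) msgs else TRUE
})

#' FamilyCohort: pedigree, residence, environmental scores and phenotype
#'
#' The unit of analysis: a set of nuclear families (two parents plus their
#' children aged 16 or older), one residence coordinate per family, one
#' standardized environmental-quality score per domain per location, and a
#' binary phenotype per individual. Individuals are stored in the canonical
#' order (by family, parents before children, ties broken by id); every
#' design matrix and relationship matrix built from a cohort uses this
#' single ordering.
#'
#' @slot pedigree data.frame with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id` (NA for founders), `sex` (0 = female,
#'   1 = male), `age` (years), `role` (`"parent"` or `"child"`).
#' @slot coordinates data.frame with columns `location_id`, `latitude`,
#'   `longitude` (degrees), one row per distinct location.
#' @slot familyLocation named character vector mapping `family_id` to
#'   `location_id`.
#' @slot eqiScores data.frame with column `location_id` plus one
#'   standardized score column per environmental-quality domain
#'   (`air`, `water`, `land`, `sociodemographic`, `built`).
#' @slot phenotype integer vector of 0/1 disease indicators aligned with
#'   `pedigree` rows (may be length 0 before a phenotype is attached).
#'
#' @seealso [simulateCohort()], [readCohort()], [buildDesign()]
#' @export
setClass("FamilyCohort",
         slots = c(pedigree = "data.frame",
                   coordinates = "data.frame",
                   familyLocation = "character",
                   eqiScores = "data.frame",
                   phenotype = "integer"))

setValidity("FamilyCohort", function(object) {
  ped <- object@pedigree
  msgs <- character()
  need <- c("family_id", "individual_id", "father_id", "mother_id",
            "sex", "age", "role")
  if (!all(need %in% names(ped)))
    return(sprintf("pedigree must have columns: %s",
                   paste(need, collapse = ", ")))
  if (anyDuplicated(ped$individual_id))
    msgs <- c(msgs, "individual_id must be unique")
  if (!all(ped$role %in% c("parent", "child")))
    msgs <- c(msgs, "role must be 'parent' or 'child'")
  if (!all(ped$sex %in% c(0L, 1L)))
    msgs <- c(msgs, "sex must be coded 0 (female) / 1 (male)")
  kid <- ped$role == "child"
  if (any(kid & ped$age < 16))
    msgs <- c(msgs, "children must be aged 16 or older")
  if (any(!is.na(ped$father_id[!kid])) || any(!is.na(ped$mother_id[!kid])))
    msgs <- c(msgs, "parent-role members must have absent parent links")
  if (length(object@phenotype) &&
      length(object@phenotype) != nrow(ped))
    msgs <- c(msgs, "phenotype length must match pedigree rows")
  if (length(object@phenotype) &&
      !all(object@phenotype %in% c(0L, 1L)))
    msgs <- c(msgs, "phenotype must be binary 0/1")
  if (nrow(object@coordinates)) {
    if (!all(c("location_id", "latitude", "longitude") %in%
             names(object@coordinates)))
      msgs <- c(msgs, "coordinates need location_id, latitude, longitude")
    else {
      if (any(abs(object@coordinates$latitude) > 90))
        msgs <- c(msgs, "latitude must lie in [-90, 90]")
      if (any(abs(object@coordinates$longitude) > 180))
        msgs <- c(msgs, "longitude must lie in [-180, 180]")
      fams <- unique(as.character(ped$family_id))
      if (!all(fams %in% names(object@familyLocation)))
        msgs <- c(msgs, "every family must be mapped to a location")
      else if (!all(object@familyLocation[fams] %in%
                    as.character(object@coordinates$location_id)))
        msgs <- c(msgs, "familyLocation refers to unknown location_id")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' ModelSpec: which liability model to fit
#'
#' Encodes the five nested models of the two forward-selection traces
#' (LM0 -> LM1 -> IM1 and LM2 -> IM2), plus the reduced interaction model
#' `"IM0"` (genetics, independent environment and their interaction, no
#' spatial term) that the coverage simulation study fits.
#'
#' @slot name model name.
#' @slot includeGeo logical; Gaussian-process term over residence
#'   coordinates.
#' @slot environments subset of `c("F","C","S","E")`: family-, couple-,
#'   sibling-shared and individually independent environmental effects.
#' @slot interactions subset of `c("GF","GC","GS","GE")`: gene-environment
#'   interaction random effects (per-individual products).
#' @export
setClass("ModelSpec",
         slots = c(name = "character", includeGeo = "logical",
                   environments = "character", interactions = "character"))

setValidity("ModelSpec", function(object) {
  msgs <- character()
  if (!all(object@environments %in% c("F", "C", "S", "E")))
    msgs <- c(msgs, "environments must be a subset of F, C, S, E")
  if (!"E" %in% object@environments)
    msgs <- c(msgs, "the individually independent environment E is always present")
  if (!all(object@interactions %in% c("GF", "GC", "GS", "GE")))
    msgs <- c(msgs, "interactions must be a subset of GF, GC, GS, GE")
  for (ia in object@interactions) {
    env <- substr(ia, 2, 2)
    if (!env %in% object@environments)
      msgs <- c(msgs, sprintf(
        "interaction %s requires environment %s in the model", ia, env))
  }
  if (length(msgs)) msgs else TRUE
})

#' SamplerConfig: NUTS/ADVI sampling configuration
#'
#' @slot nChains number of independent chains (default 4).
#' @slot warmup warmup (adaptation) iterations per chain.
#' @slot draws kept posterior draws per chain.
#' @slot targetAccept dual-averaging target acceptance statistic.
#' @slot maxTreedepth NUTS maximum tree depth.
#' @slot seed integer seed governing all randomness of the run.
#' @slot init `"variational"` (ADVI-optimized start, jittered per chain,
#'   falling back to random on failure) or `"random"` (unit Gaussian on the
#'   unconstrained scale).
#' @slot adviIters ADVI optimization steps used when `init="variational"`.
#' @export
setClass("SamplerConfig",
         slots = c(nChains = "integer", warmup = "integer", draws = "integer",
                   targetAccept = "numeric", maxTreedepth = "integer",
                   seed = "integer", init = "character",
                   adviIters = "integer"))

setValidity("SamplerConfig", function(object) {
  msgs <- character()
  if (object@nChains < 1L) msgs <- c(msgs, "nChains must be >= 1")
  if (object@draws < 1L) msgs <- c(msgs, "draws must be >= 1")
  if (object@targetAccept <= 0 || object@targetAccept >= 1)
    msgs <- c(msgs, "targetAccept must lie in (0, 1)")
  if (!object@init %in% c("variational", "random"))
    msgs <- c(msgs, "init must be 'variational' or 'random'")
  if (length(msgs)) msgs else TRUE
})

#' LiabilityModel: an assembled Bernoulli-logit mixed model
#'
#' Produced by [assembleModel()]; bundles the fixed-effect design, the
#' phenotype, the structure factors of all requested random effects and the
#' prior configuration, ready for [sampleModel()].
#'
#' @slot spec the [ModelSpec-class].
#' @slot X fixed-effect design matrix (canonical individual order).
#' @slot y integer phenotype vector.
#' @slot structures list handed to the compiled log-posterior: sparse
#'   Cholesky factor of the genetic relationship matrix, group index
#'   vectors of the shared-environment structures, squared-distance matrix
#'   and per-individual index of unique residence locations.
#' @slot priors list of prior hyperparameters.
#' @slot paramIndex named list mapping parameter blocks to positions in the
#'   unconstrained parameter vector.
#' @slot labels individual ids in model order.
#' @slot cache environment caching the external pointer to the compiled
#'   model (rebuilt lazily; never serialized).
#' @export
setClass("LiabilityModel",
         slots = c(spec = "ModelSpec", X = "matrix", y = "integer",
                   structures = "list", priors = "list",
                   paramIndex = "list", labels = "character",
                   cache = "environment"))

#' PosteriorDraws: pooled NUTS draws with diagnostics
#'
#' Draws from all chains are pooled by concatenation after warmup; per-chain
#' identity is retained in `chain` for split R-hat and ESS.
#'
#' @slot draws numeric matrix, (chains x kept draws) rows, one column per
#'   model parameter on the constrained scale (variances as sigma2_*,
#'   interaction factors k_*, fixed effects beta_*, latent effect vectors).
#' @slot chain integer chain index per row.
#' @slot spec the [ModelSpec-class] the draws belong to.
#' @slot diagnostics list: divergence counts, tree depths, step sizes,
#'   acceptance statistics, energies per chain; init method used.
#' @export
setClass("PosteriorDraws",
         slots = c(draws = "matrix", chain = "integer", spec = "ModelSpec",
                   diagnostics = "list"))

#' PartitionStatistics: posterior variance-partition fractions
#'
#' Per-draw liability-scale variance fractions (p2, h2, f2, c2, s2, e2 and
#' the interaction fractions hf2, hc2, hs2, he2 as present in the model),
#' summarized by posterior mean and 95% highest-posterior-density interval.
#'
#' @slot summary data.frame: statistic, mean, lower, upper.
#' @slot perDraw numeric matrix of per-draw fractions (rows = draws).
#' @slot excluded number of draws dropped for zero total variance.
#' @export
setClass("PartitionStatistics",
         slots = c(summary = "data.frame", perDraw = "matrix",
                   excluded = "integer"))

#' ModelFitReport: WAIC and PSIS-LOO for one fitted model
#'
#' Both criteria are reported on the deviance scale (-2 * elpd); lower is
#' better. Confidence intervals are the normal approximation from the
#' pointwise standard error.
#'
#' @slot model model name.
#' @slot waic,waicSE,waicCI WAIC, its standard error, and 95% CI.
#' @slot loo,looSE,looCI PSIS-LOO-CV, its standard error, and 95% CI.
#' @slot paretoK per-observation generalized-Pareto shape diagnostics.
#' @slot n number of observations.
#' @export
setClass("ModelFitReport",
         slots = c(model = "character", waic = "numeric", waicSE = "numeric",
                   waicCI = "numeric", loo = "numeric", looSE = "numeric",
                   looCI = "numeric", paretoK = "numeric", n = "integer"))
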