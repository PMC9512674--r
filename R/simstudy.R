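# Coverage simulation study: five canonical variance settings, repeated
# simulate-and-fit under the reduced interaction model, coverage of the
# 95% HPD intervals of h2, e2 and he2.

.CANONICAL_SETS <- data.frame(
  set = 1:5,
  sigma_g_sq = c(1, 2, 3, 4, 5),
  sigma_e_sq = c(5, 4, 3, 2, 1))

#' A simulation-study variance setting
#'
#' The five canonical settings pair genetic and environmental variance
#' scales `(1,5), (2,4), (3,3), (4,2), (5,1)` with interaction factor
#' `k_GE = 1/3`, spanning dominantly environmental to dominantly genetic
#' traits.
#'
#' @param set canonical set number 1-5, or `NULL` to give scales
#'   explicitly.
#' @param sigma_g_sq,sigma_e_sq,k_ge variance scales and interaction
#'   factor (overridden by `set` when given).
#' @return named list with the setting.
#' @export
simulationSet <- function(set = NULL, sigma_g_sq = 3, sigma_e_sq = 3,
                          k_ge = 1 / 3) {
  if (!is.null(set)) {
    stopifnot(set %in% 1:5)
    sigma_g_sq <- .CANONICAL_SETS$sigma_g_sq[set]
    sigma_e_sq <- .CANONICAL_SETS$sigma_e_sq[set]
    k_ge <- 1 / 3
  }
  list(sigma_g_sq = sigma_g_sq, sigma_e_sq = sigma_e_sq, k_ge = k_ge)
}

#' True variance-partition statistics of a simulation setting
#'
#' `h2 = sigma_G^2 / D`, `e2 = sigma_E^2 / D`,
#' `he2 = k^2 sigma_G^2 sigma_E^2 / D` with
#' `D = sigma_G^2 + sigma_E^2 + k^2 sigma_G^2 sigma_E^2`; the three always
#' sum to one.
#'
#' @param set a [simulationSet()] list.
#' @return named numeric `c(h2, e2, he2)`.
#' @export
trueStatistics <- function(set) {
  ia <- set$k_ge^2 * set$sigma_g_sq * set$sigma_e_sq
  D <- set$sigma_g_sq + set$sigma_e_sq + ia
  c(h2 = set$sigma_g_sq / D, e2 = set$sigma_e_sq / D, he2 = ia / D)
}

#' One simulate-and-fit replicate of the coverage study
#'
#' Simulates a cohort under the reduced interaction model
#' (`X beta + f_q(q) + G + E + k_GE G E`) with the setting's variance
#' scales, fits the same model by [sampleModel()], and returns the 95%
#' HPD intervals and posterior means of h2, e2 and he2.
#'
#' @param set a [simulationSet()] list.
#' @param cohortConf a [cohortConfig()] list.
#' @param samplerConf a [SamplerConfig-class]; its seed is offset by
#'   `replicate` so replicates are independent but reproducible.
#' @param replicate replicate index (>= 1).
#' @return data.frame with one row per statistic: mean, lower, upper,
#'   true value, covered flag.
#' @export
runReplicate <- function(set, cohortConf = cohortConfig(nFamilies = 200L),
                         samplerConf = samplerConfig(warmup = 500L,
                                                     draws = 500L),
                         replicate = 1L) {
  truth <- generativeTruth("IM0", sigma_g_sq = set$sigma_g_sq,
                           sigma_e_sq = set$sigma_e_sq, k_ge = set$k_ge)
  seed <- samplerConf@seed + 1000L * (replicate - 1L)
  cohort <- simulateCohort(cohortConf, truth, seed = seed)
  model <- assembleModel("IM0", cohort)
  sc <- samplerConf
  sc@seed <- seed + 1L
  draws <- sampleModel(model, sc)
  ps <- varianceFractions(draws)
  sm <- partitionSummary(ps)
  tv <- trueStatistics(set)
  sm <- sm[match(names(tv), sm$statistic), ]
  data.frame(statistic = names(tv), mean = sm$mean, lower = sm$lower,
             upper = sm$upper, true = as.numeric(tv),
             covered = sm$lower <= tv & tv <= sm$upper,
             divergences = sum(draws@diagnostics$divergences),
             row.names = NULL)
}

#' Coverage probability over replicates
#'
#' Fraction of successful replicates whose credible interval contains the
#' true generating value, per statistic, with a binomial standard error.
#'
#' @param replicates list of [runReplicate()] results (failed replicates
#'   may be `NULL`; they are excluded and counted).
#' @return data.frame: statistic, true value, coverage, binomial SE,
#'   successes, failures.
#' @export
coverageReport <- function(replicates) {
  ok <- !vapply(replicates, is.null, logical(1))
  if (!any(ok)) stop("no successful replicates; coverage undefined")
  reps <- replicates[ok]
  stats <- reps[[1]]$statistic
  out <- lapply(stats, function(s) {
    cov <- vapply(reps, function(r) r$covered[r$statistic == s],
                  logical(1))
    p <- mean(cov)
    data.frame(statistic = s, true = reps[[1]]$true[reps[[1]]$statistic == s],
               coverage = p,
               se = sqrt(p * (1 - p) / length(cov)),
               n_success = length(cov), n_failed = sum(!ok))
  })
  do.call(rbind, out)
}

#' Run the coverage simulation study
#'
#' For each requested variance setting, repeats simulate-and-fit
#' `nReplicates` times and tabulates the coverage of the 95% HPD
#' intervals of h2, e2 and he2. Replicates whose sampler fails are
#' excluded from the denominator and counted.
#'
#' @param sets integer vector of canonical set numbers (default all
#'   five).
#' @param nReplicates replicates per set.
#' @param cohortConf,samplerConf see [runReplicate()].
#' @param seed base seed; each set and replicate derives its own.
#' @return data.frame of per-set [coverageReport()] rows.
#' @export
runSimulationStudy <- function(sets = 1:5, nReplicates = 20L,
                               cohortConf = cohortConfig(nFamilies = 200L),
                               samplerConf = samplerConfig(warmup = 500L,
                                                           draws = 500L),
                               seed = 1L) {
  out <- list()
  for (s in sets) {
    st <- simulationSet(s)
    reps <- vector("list", nReplicates)
    for (r in seq_len(nReplicates)) {
      sc <- samplerConf
      sc@seed <- as.integer(seed + 100000L * s)
      reps[[r]] <- tryCatch(
        runReplicate(st, cohortConf, sc, replicate = r),
        error = function(e) {
          warning(sprintf("set %d replicate %d failed: %s", s, r,
                          conditionMessage(e)))
          NULL
        })
    }
    cr <- coverageReport(reps)
    cr$set <- s
    cr$sigma_g_sq <- st$sigma_g_sq
    cr$sigma_e_sq <- st$sigma_e_sq
    out[[length(out) + 1L]] <- cr
  }
  do.call(rbind, out)
}
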