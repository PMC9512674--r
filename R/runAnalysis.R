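# End-to-end orchestration: assemble -> sample -> partition -> compare for
# a list of models on one cohort and phenotype.

.TRACES <- list(trace1 = c("LM0", "LM1", "IM1"), trace2 = c("LM2", "IM2"))

#' Fit a set of liability models and compare them
#'
#' For each requested model: assembles the model on the cohort, samples
#' the posterior, computes the variance-partition statistics with 95% HPD
#' intervals and a WAIC/PSIS-LOO fit report, then tabulates the two
#' forward-selection traces (LM0 -> LM1 -> IM1 and LM2 -> IM2) for the
#' models present. One phenotype per run.
#'
#' @param cohort a [FamilyCohort-class] with phenotype, or a list of file
#'   paths `list(ped=, coords=, covar=)` passed to [readCohort()].
#' @param models character vector of model names.
#' @param samplerConf a [SamplerConfig-class]; model fits derive their
#'   seeds from it.
#' @param outDir optional directory; when given, partition summaries and
#'   the comparison table are written as CSV.
#' @return list with `partitions` (named list of
#'   [PartitionStatistics-class]), `reports` (named list of
#'   [ModelFitReport-class]), `draws` (named list of
#'   [PosteriorDraws-class]), and `traces` (named list of
#'   [selectionTrace()] tables).
#' @export
runAnalysis <- function(cohort, models = c("LM0", "LM1", "IM1"),
                        samplerConf = samplerConfig(), outDir = NULL) {
  if (is.list(cohort) && !is(cohort, "FamilyCohort"))
    cohort <- readCohort(cohort$ped, cohort$coords, cohort$covar)
  stopifnot(is(cohort, "FamilyCohort"))
  if (!length(models)) {
    warning("empty model list; nothing to do")
    return(list(partitions = list(), reports = list(), draws = list(),
                traces = list()))
  }
  X <- buildDesign(cohort)
  grm <- buildGRM(cohort@pedigree)
  partitions <- reports <- drawsList <- list()
  for (i in seq_along(models)) {
    mn <- models[i]
    model <- assembleModel(mn, cohort, X = X, grm = grm)
    sc <- samplerConf
    sc@seed <- as.integer(samplerConf@seed + 97L * (i - 1L))
    dr <- sampleModel(model, sc)
    partitions[[mn]] <- varianceFractions(dr)
    reports[[mn]] <- fitReport(model, dr)
    drawsList[[mn]] <- dr
  }
  traces <- list()
  for (tn in names(.TRACES)) {
    present <- intersect(.TRACES[[tn]], models)
    if (length(present) >= 1L)
      traces[[tn]] <- selectionTrace(reports[present])
  }
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (mn in names(partitions))
      write.csv(partitionSummary(partitions[[mn]]),
                file.path(outDir, paste0("partition_", mn, ".csv")),
                row.names = FALSE)
    cmp <- do.call(rbind, traces)
    if (!is.null(cmp))
      write.csv(cmp, file.path(outDir, "model_comparison.csv"),
                row.names = FALSE)
  }
  list(partitions = partitions, reports = reports, draws = drawsList,
       traces = traces)
}
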