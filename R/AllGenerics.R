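#' @name famGxE-accessors
#' @title Accessors for famGxE classes
#'
#' @description Small accessor generics: `matrixValues()` and `matrixKind()`
#' for [RelationshipMatrix-class]; `individualIds()`, `nIndividuals()`,
#' `nFamilies()`, `pedigree()`, `phenotype()` for [FamilyCohort-class] (and
#' where meaningful for other classes); `modelName()` for
#' [ModelSpec-class]/[ModelFitReport-class]; `posteriorMatrix()` and
#' `chainIndex()` for [PosteriorDraws-class]; `partitionSummary()` for
#' [PartitionStatistics-class].
#'
#' @param x an object of the documented class.
#' @return the corresponding slot content (matrices, data.frames or
#'   vectors); see Description.
NULL

#' @rdname famGxE-accessors
#' @export
setGeneric("matrixValues", function(x) standardGeneric("matrixValues"))
#' @rdname famGxE-accessors
#' @export
setGeneric("matrixKind", function(x) standardGeneric("matrixKind"))
#' @rdname famGxE-accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))
#' @rdname famGxE-accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))
#' @rdname famGxE-accessors
#' @export
setGeneric("nFamilies", function(x) standardGeneric("nFamilies"))
#' @rdname famGxE-accessors
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))
#' @rdname famGxE-accessors
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))
#' @rdname famGxE-accessors
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))
#' @rdname famGxE-accessors
#' @export
setGeneric("posteriorMatrix", function(x) standardGeneric("posteriorMatrix"))
#' @rdname famGxE-accessors
#' @export
setGeneric("chainIndex", function(x) standardGeneric("chainIndex"))
#' @rdname famGxE-accessors
#' @export
setGeneric("partitionSummary", function(x) standardGeneric("partitionSummary"))

#' @rdname famGxE-accessors
setMethod("matrixValues", "RelationshipMatrix", function(x) x@values)
#' @rdname famGxE-accessors
setMethod("matrixKind", "RelationshipMatrix", function(x) x@kind)
#' @rdname famGxE-accessors
setMethod("individualIds", "RelationshipMatrix",
          function(x) rownames(x@values))
#' @rdname famGxE-accessors
setMethod("individualIds", "FamilyCohort",
          function(x) as.character(x@pedigree$individual_id))
#' @rdname famGxE-accessors
setMethod("individualIds", "LiabilityModel", function(x) x@labels)
#' @rdname famGxE-accessors
setMethod("nIndividuals", "FamilyCohort", function(x) nrow(x@pedigree))
#' @rdname famGxE-accessors
setMethod("nIndividuals", "RelationshipMatrix", function(x) nrow(x@values))
#' @rdname famGxE-accessors
setMethod("nIndividuals", "LiabilityModel", function(x) length(x@y))
#' @rdname famGxE-accessors
setMethod("nFamilies", "FamilyCohort",
          function(x) length(unique(x@pedigree$family_id)))
#' @rdname famGxE-accessors
setMethod("pedigree", "FamilyCohort", function(x) x@pedigree)
#' @rdname famGxE-accessors
setMethod("phenotype", "FamilyCohort", function(x) x@phenotype)
#' @rdname famGxE-accessors
setMethod("modelName", "ModelSpec", function(x) x@name)
#' @rdname famGxE-accessors
setMethod("modelName", "LiabilityModel", function(x) x@spec@name)
#' @rdname famGxE-accessors
setMethod("modelName", "ModelFitReport", function(x) x@model)
#' @rdname famGxE-accessors
setMethod("posteriorMatrix", "PosteriorDraws", function(x) x@draws)
#' @rdname famGxE-accessors
setMethod("chainIndex", "PosteriorDraws", function(x) x@chain)
#' @rdname famGxE-accessors
setMethod("partitionSummary", "PartitionStatistics", function(x) x@summary)

setMethod("show", "RelationshipMatrix", function(object) {
  cat(sprintf("RelationshipMatrix (kind=%s) over %d individuals\n",
              object@kind, nrow(object@values)))
  if (nrow(object@values) <= 8L) {
    print(round(object@values, 3))
  } else {
    cat("  [use matrixValues() for the full matrix]\n")
  }
})

setMethod("show", "FamilyCohort", function(object) {
  cat(sprintf(
    "FamilyCohort: %d individuals in %d families, %d locations\n",
    nrow(object@pedigree), length(unique(object@pedigree$family_id)),
    nrow(object@coordinates)))
  if (length(object@phenotype))
    cat(sprintf("  phenotype prevalence: %.3f\n", mean(object@phenotype)))
  else cat("  no phenotype attached\n")
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec %s: geo=%s, environments={%s}, interactions={%s}\n",
              object@name, object@includeGeo,
              paste(object@environments, collapse = ","),
              if (length(object@interactions))
                paste(object@interactions, collapse = ",") else ""))
})

setMethod("show", "SamplerConfig", function(object) {
  cat(sprintf(
    "SamplerConfig: %d chains x (%d warmup + %d draws), accept=%.2f, init=%s, seed=%d\n",
    object@nChains, object@warmup, object@draws, object@targetAccept,
    object@init, object@seed))
})

setMethod("show", "LiabilityModel", function(object) {
  cat(sprintf("LiabilityModel %s: n=%d individuals, %d fixed-effect columns\n",
              object@spec@name, length(object@y), ncol(object@X)))
})

setMethod("show", "PosteriorDraws", function(object) {
  cat(sprintf("PosteriorDraws (%s): %d draws x %d parameters, %d chains\n",
              object@spec@name, nrow(object@draws), ncol(object@draws),
              length(unique(object@chain))))
  dv <- object@diagnostics$divergences
  if (!is.null(dv))
    cat(sprintf("  divergent transitions: %d\n", sum(dv)))
})

setMethod("show", "PartitionStatistics", function(object) {
  cat("Posterior variance-partition statistics (mean [95% HPD]):\n")
  s <- object@summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-4s %6.2f%% [%6.2f, %6.2f]%%\n", s$statistic[i],
                100 * s$mean[i], 100 * s$lower[i], 100 * s$upper[i]))
  if (object@excluded > 0L)
    cat(sprintf("  (%d draws excluded for zero total variance)\n",
                object@excluded))
})

setMethod("show", "ModelFitReport", function(object) {
  cat(sprintf("ModelFitReport %s (n=%d)\n", object@model, object@n))
  cat(sprintf("  WAIC     %10.2f (%.2f, %.2f)\n", object@waic,
              object@waicCI[1], object@waicCI[2]))
  cat(sprintf("  PSIS-LOO %10.2f (%.2f, %.2f)\n", object@loo,
              object@looCI[1], object@looCI[2]))
  cat(sprintf("  Pareto k > 0.7: %d of %d observations\n",
              sum(object@paretoK > 0.7, na.rm = TRUE),
              length(object@paretoK)))
})
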