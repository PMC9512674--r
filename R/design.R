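# Fixed-effect design: demographics plus cubic polynomial bases of five
# PCA-summarized environmental-quality (EQI) domain scores.

#' Summarize an EQI domain block into one standardized PCA score
#'
#' Standardizes every variable of a location-level block to zero mean and
#' unit variance, takes the first principal component, restandardizes the
#' score, and aligns its sign so that a higher score correlates positively
#' with the designated "worse-quality" anchor variable (by convention,
#' higher scores mean worse environmental quality). Constant variables are
#' dropped with a warning; a single-variable block passes through
#' standardized.
#'
#' @param block numeric matrix or data.frame, one row per location, one
#'   column per raw EQI variable of one domain.
#' @param anchor name or index of the anchor variable (default: first
#'   column).
#' @return numeric vector of standardized scores, one per location.
#' @export
eqiPcaScore <- function(block, anchor = 1L) {
  block <- as.matrix(block)
  if (nrow(block) < 2L) stop("at least two locations are required")
  if (is.character(anchor)) anchor <- match(anchor, colnames(block))
  anchorCol <- block[, anchor]
  sds <- apply(block, 2, sd)
  if (any(sds == 0)) {
    warning("dropping constant EQI variable(s): ",
            paste(colnames(block)[sds == 0], collapse = ", "))
    block <- block[, sds > 0, drop = FALSE]
    if (ncol(block) == 0L)
      stop("all variables in the block are constant")
  }
  z <- scale(block)
  if (ncol(z) == 1L) {
    score <- z[, 1]
  } else {
    score <- prcomp(z, center = FALSE, scale. = FALSE)$x[, 1]
  }
  score <- as.numeric(scale(score))
  if (sd(anchorCol) > 0 && cor(score, anchorCol) < 0) score <- -score
  score
}

#' Cubic polynomial basis of a standardized score
#'
#' Returns the three design columns `q`, `q^2`, `q^3` of the per-domain
#' cubic fixed-effect function; the global intercept lives in the design
#' matrix, so no per-domain intercept column is emitted.
#'
#' @param score numeric vector of (standardized) scores.
#' @return numeric matrix with columns `1`, `2`, `3` (powers).
#' @export
cubicBasis <- function(score) {
  if (any(!is.finite(score))) stop("scores must be finite")
  cbind(`1` = score, `2` = score^2, `3` = score^3)
}

#' Fixed-effect design matrix for a cohort
#'
#' Assembles the design with one global intercept, sex (0 = female,
#' 1 = male), numeric age in years, and a cubic basis (`q`, `q^2`, `q^3`)
#' of the standardized score of each of the five EQI domains, expanded
#' from locations to individuals. Rows follow the cohort's canonical
#' individual order, the same ordering all relationship matrices use.
#'
#' @param cohort a [FamilyCohort-class] with coordinates and EQI scores.
#' @return numeric matrix with `3 + 5*3` columns.
#' @export
buildDesign <- function(cohort) {
  stopifnot(is(cohort, "FamilyCohort"))
  ped <- cohort@pedigree
  if (!nrow(cohort@eqiScores))
    stop("cohort carries no EQI scores")
  miss <- !complete.cases(ped[, c("sex", "age")])
  if (any(miss))
    stop("missing sex/age for individuals: ",
         paste(ped$individual_id[miss], collapse = ", "))
  loc <- cohort@familyLocation[as.character(ped$family_id)]
  eqi <- cohort@eqiScores
  rowOf <- match(loc, as.character(eqi$location_id))
  if (any(is.na(rowOf)))
    stop("no EQI scores for individuals: ",
         paste(ped$individual_id[is.na(rowOf)], collapse = ", "))
  X <- cbind(`(Intercept)` = 1, sex = as.numeric(ped$sex),
             age = as.numeric(ped$age))
  for (dom in .EQI_DOMAINS) {
    if (!dom %in% names(eqi))
      stop("EQI domain score missing: ", dom)
    b <- cubicBasis(eqi[[dom]][rowOf])
    colnames(b) <- paste(dom, 1:3, sep = ".")
    X <- cbind(X, b)
  }
  rownames(X) <- as.character(ped$individual_id)
  X
}
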