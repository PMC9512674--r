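# Readers and writers for the plain-text cohort formats: a PED-like
# pedigree table, a per-family coordinates CSV and an EQI covariates CSV.

#' Read a PED-like pedigree file
#'
#' Whitespace- or comma-delimited table with columns
#' `FID IID PAT MAT SEX AGE ROLE PHENO`; `"0"`, `""` or `NA` denote an
#' absent parent. Note the sex coding: 0 = female, 1 = male (differing
#' from PLINK's 1/2 convention). `ROLE` is `parent`/`child`; `PHENO` is
#' the 0/1 disease indicator (optional column, `NA` allowed when the
#' phenotype is supplied elsewhere).
#'
#' @param file path.
#' @return data.frame in [FamilyCohort-class] pedigree layout, with a
#'   `phenotype` column when present.
#' @export
readPedigree <- function(file) {
  first <- readLines(file, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  hasHeader <- grepl("FID|family", first, ignore.case = TRUE)
  tab <- read.table(file, header = hasHeader, sep = sep,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!hasHeader) {
    names(tab) <- c("FID", "IID", "PAT", "MAT", "SEX", "AGE",
                    "ROLE", "PHENO")[seq_len(ncol(tab))]
  }
  ped <- data.frame(
    family_id = as.character(tab$FID),
    individual_id = as.character(tab$IID),
    father_id = ifelse(is.na(tab$PAT) | tab$PAT == "0", NA_character_,
                       as.character(tab$PAT)),
    mother_id = ifelse(is.na(tab$MAT) | tab$MAT == "0", NA_character_,
                       as.character(tab$MAT)),
    sex = as.integer(tab$SEX),
    age = as.numeric(tab$AGE),
    role = as.character(tab$ROLE))
  if ("PHENO" %in% names(tab)) ped$phenotype <- as.integer(tab$PHENO)
  ped
}

# summarize a covariates table into per-location standardized scores
.covariatesToScores <- function(covar, key) {
  out <- data.frame(location_id = as.character(covar[[key]]))
  for (dom in .EQI_DOMAINS) {
    if (dom %in% names(covar)) {
      # precomputed standardized score: pass through unchanged
      out[[dom]] <- as.numeric(covar[[dom]])
      next
    }
    vars <- grep(paste0("^", dom, "[_.]"), names(covar), value = TRUE)
    if (!length(vars))
      stop("no covariate columns found for EQI domain ", dom)
    out[[dom]] <- eqiPcaScore(covar[, vars, drop = FALSE])
  }
  out
}

#' Read a cohort from its plain-text files
#'
#' Reconciles identifiers across the pedigree, coordinates and covariates
#' files, canonicalizes the individual ordering, and validates the
#' result; orphan or duplicate ids and missing phenotypes are reported by
#' name. Row order of the input files does not matter.
#'
#' @param pedFile PED-like pedigree file, see [readPedigree()].
#' @param coordFile CSV with columns `family_id`, `latitude`,
#'   `longitude` (one shared residence per family); families at
#'   identical coordinates are merged into one location.
#' @param covarFile CSV keyed by `family_id` or `location_id` with either
#'   precomputed domain scores (columns `air`, `water`, `land`,
#'   `sociodemographic`, `built`) or raw variables named
#'   `<domain>_<name>`, which are PCA-summarized per domain.
#' @param phenotype optional named 0/1 vector overriding the PED file's
#'   `PHENO` column.
#' @return a [FamilyCohort-class].
#' @export
readCohort <- function(pedFile, coordFile = NULL, covarFile = NULL,
                       phenotype = NULL) {
  ped <- readPedigree(pedFile)
  phen <- phenotype
  if (is.null(phen) && "phenotype" %in% names(ped) &&
      !anyNA(ped$phenotype))
    phen <- setNames(ped$phenotype, ped$individual_id)
  ped$phenotype <- NULL

  coords <- data.frame(); famLoc <- character(); eqi <- data.frame()
  if (!is.null(coordFile)) {
    fc <- read.csv(coordFile, stringsAsFactors = FALSE)
    need <- c("family_id", "latitude", "longitude")
    if (!all(need %in% names(fc)))
      stop("coordinates file needs columns: ", paste(need, collapse = ", "))
    fams <- unique(as.character(ped$family_id))
    miss <- setdiff(fams, as.character(fc$family_id))
    if (length(miss))
      stop("no coordinates for families: ", paste(miss, collapse = ", "))
    key <- paste(fc$latitude, fc$longitude)
    locId <- sprintf("loc%03d", match(key, unique(key)))
    coords <- unique(data.frame(location_id = locId,
                                latitude = fc$latitude,
                                longitude = fc$longitude))
    famLoc <- setNames(locId, as.character(fc$family_id))
  }
  if (!is.null(covarFile)) {
    cv <- read.csv(covarFile, stringsAsFactors = FALSE)
    if ("location_id" %in% names(cv)) {
      eqi <- .covariatesToScores(cv, "location_id")
    } else if ("family_id" %in% names(cv)) {
      sc <- .covariatesToScores(cv, "family_id")
      # collapse family-keyed rows to locations
      loc <- famLoc[sc$location_id]
      sc$location_id <- loc
      eqi <- sc[!duplicated(sc$location_id), , drop = FALSE]
      rownames(eqi) <- NULL
    } else stop("covariates file needs a family_id or location_id column")
  }
  familyCohort(ped, coords, famLoc, eqi, phenotype = phen)
}

#' Write a cohort to plain-text files
#'
#' Inverse of [readCohort()]: a PED-like pedigree (with PHENO column), a
#' per-family coordinates CSV and a per-location covariates CSV of the
#' standardized domain scores.
#'
#' @param cohort a [FamilyCohort-class].
#' @param pedFile,coordFile,covarFile output paths (`NULL` skips a file).
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, pedFile, coordFile = NULL,
                        covarFile = NULL) {
  stopifnot(is(cohort, "FamilyCohort"))
  ped <- cohort@pedigree
  tab <- data.frame(FID = ped$family_id, IID = ped$individual_id,
                    PAT = ifelse(is.na(ped$father_id), "0", ped$father_id),
                    MAT = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                    SEX = ped$sex, AGE = ped$age, ROLE = ped$role,
                    PHENO = if (length(cohort@phenotype))
                      cohort@phenotype else NA_integer_)
  write.table(tab, pedFile, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(coordFile) && nrow(cohort@coordinates)) {
    fams <- unique(as.character(ped$family_id))
    loc <- cohort@familyLocation[fams]
    co <- cohort@coordinates[match(loc, cohort@coordinates$location_id), ]
    write.csv(data.frame(family_id = fams, latitude = co$latitude,
                         longitude = co$longitude),
              coordFile, row.names = FALSE)
  }
  if (!is.null(covarFile) && nrow(cohort@eqiScores)) {
    # keyed by family so the reader can reconstruct locations from the
    # coordinates file alone
    fams <- unique(as.character(ped$family_id))
    loc <- cohort@familyLocation[fams]
    sc <- cohort@eqiScores[match(loc, cohort@eqiScores$location_id), ]
    sc$location_id <- NULL
    write.csv(cbind(family_id = fams, sc), covarFile, row.names = FALSE)
  }
  invisible(c(pedFile, coordFile, covarFile))
}
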