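# Pedigree relationship matrices: the additive genetic relationship matrix by
# the recursive tabular method, and the 0/1 shared-environment structures
# (family / couple / sibling), plus elementwise (Hadamard) combinations.

.asPedigreeFrame <- function(pedigree) {
  if (is(pedigree, "FamilyCohort")) return(pedigree@pedigree)
  if (!is.data.frame(pedigree))
    stop("pedigree must be a data.frame or FamilyCohort")
  pedigree
}

# Structural validation shared by the matrix builders. `requireRoles` demands
# the nuclear-family role column (parent/child); the GRM builder accepts
# arbitrary multi-generation pedigrees and only needs parent links.
.checkPedigree <- function(ped, requireRoles = FALSE) {
  need <- c("individual_id", "father_id", "mother_id")
  if (!all(need %in% names(ped)))
    stop("pedigree needs columns individual_id, father_id, mother_id")
  ids <- as.character(ped$individual_id)
  if (anyDuplicated(ids))
    stop("duplicate individual_id in pedigree: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (col in c("father_id", "mother_id")) {
    p <- as.character(ped[[col]])
    bad <- !is.na(p) & !(p %in% ids)
    if (any(bad))
      stop("unknown ", col, " referenced: ",
           paste(unique(p[bad]), collapse = ", "))
    if (any(!is.na(p) & p == ids))
      stop("individual listed as its own ", col)
  }
  if (requireRoles) {
    if (!"role" %in% names(ped) || !"family_id" %in% names(ped))
      stop("pedigree needs family_id and role columns for this structure")
    if (!all(ped$role %in% c("parent", "child")))
      stop("role must be 'parent' or 'child'")
  }
  invisible(ids)
}

# Kahn topological order, parents before offspring; cycle -> error.
.topoOrder <- function(ids, father, mother) {
  n <- length(ids)
  idx <- seq_len(n)
  names(idx) <- ids
  fi <- ifelse(is.na(father), NA_integer_, idx[as.character(father)])
  mi <- ifelse(is.na(mother), NA_integer_, idx[as.character(mother)])
  indeg <- (!is.na(fi)) + (!is.na(mi))
  children <- vector("list", n)
  for (i in idx) {
    for (p in c(fi[i], mi[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- idx[indeg == 0L]
  out <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != n)
    stop("cyclic parent links in pedigree")
  list(order = out, father = fi, mother = mi)
}

.newRelMatrix <- function(values, labels, kind) {
  dimnames(values) <- list(labels, labels)
  new("RelationshipMatrix", values = values, kind = kind)
}

#' Additive genetic relationship matrix from a pedigree
#'
#' Computes the expected additive (numerator) relationship matrix by the
#' standard recursive tabular method, processing individuals in an order
#' that places parents before their offspring. Founders are treated as
#' unrelated and non-inbred, so the diagonal is exactly 1 and parent-child
#' and full-sibling entries are 0.5. Multi-generation pedigrees are
#' supported (grandparent-grandchild relatedness 0.25, and so on).
#'
#' @param pedigree a data.frame with columns `individual_id`, `father_id`,
#'   `mother_id` (`NA` for founders), or a [FamilyCohort-class].
#' @return a [RelationshipMatrix-class] of kind `"genetic"`, rows/columns
#'   in the input order of `pedigree`.
#' @examples
#' trio <- data.frame(individual_id = c("dad", "mom", "kid"),
#'                    father_id = c(NA, NA, "dad"),
#'                    mother_id = c(NA, NA, "mom"))
#' matrixValues(buildGRM(trio))
#' @export
buildGRM <- function(pedigree) {
  ped <- .asPedigreeFrame(pedigree)
  ids <- .checkPedigree(ped)
  topo <- .topoOrder(ids, ped$father_id, ped$mother_id)
  n <- length(ids)
  A <- matrix(0, n, n)
  for (i in topo$order) {
    f <- topo$father[i]; m <- topo$mother[i]
    # off-diagonals with already-processed individuals
    done <- topo$order[seq_len(which(topo$order == i) - 1L)]
    if (length(done)) {
      af <- if (!is.na(f)) A[done, f] else rep(0, length(done))
      am <- if (!is.na(m)) A[done, m] else rep(0, length(done))
      A[done, i] <- 0.5 * (af + am)
      A[i, done] <- A[done, i]
    }
    A[i, i] <- 1 + if (!is.na(f) && !is.na(m)) 0.5 * A[f, m] else 0
  }
  .newRelMatrix(A, ids, "genetic")
}

#' Shared-environment structure matrices
#'
#' `buildFamilyMatrix()` marks pairs belonging to the same family (entry 1,
#' else 0). `buildCoupleMatrix()` marks the two parent-role members of each
#' family as a couple; every other individual carries only its diagonal
#' entry. `buildSiblingMatrix()` marks child-role members of the same
#' family as a sibling group; parents carry only their diagonal. All three
#' have unit diagonal, are block-diagonal by family, symmetric and positive
#' semidefinite.
#'
#' @param pedigree a data.frame with columns `family_id`, `individual_id`,
#'   `role` (plus parent links), or a [FamilyCohort-class].
#' @return a [RelationshipMatrix-class] of the corresponding kind, ordered
#'   as the input pedigree.
#' @examples
#' fam <- data.frame(family_id = 1, individual_id = c("p1","p2","c1","c2"),
#'                   father_id = c(NA, NA, "p1", "p1"),
#'                   mother_id = c(NA, NA, "p2", "p2"),
#'                   role = c("parent","parent","child","child"))
#' matrixValues(buildCoupleMatrix(fam))
#' @export
buildFamilyMatrix <- function(pedigree) {
  ped <- .asPedigreeFrame(pedigree)
  ids <- .checkPedigree(ped, requireRoles = TRUE)
  fam <- as.character(ped$family_id)
  A <- outer(fam, fam, "==") * 1
  .newRelMatrix(A, ids, "family")
}

#' @rdname buildFamilyMatrix
#' @export
buildCoupleMatrix <- function(pedigree) {
  ped <- .asPedigreeFrame(pedigree)
  ids <- .checkPedigree(ped, requireRoles = TRUE)
  fam <- as.character(ped$family_id)
  parents <- ped$role == "parent"
  nPar <- table(fam[parents])
  if (any(nPar > 2L))
    stop("family with more than two parent-role members: ",
         paste(names(nPar)[nPar > 2L], collapse = ", "))
  A <- diag(length(ids))
  couple <- outer(fam, fam, "==") & outer(parents, parents, "&")
  A[couple] <- 1
  .newRelMatrix(A, ids, "couple")
}

#' @rdname buildFamilyMatrix
#' @export
buildSiblingMatrix <- function(pedigree) {
  ped <- .asPedigreeFrame(pedigree)
  ids <- .checkPedigree(ped, requireRoles = TRUE)
  fam <- as.character(ped$family_id)
  kids <- ped$role == "child"
  A <- diag(length(ids))
  sib <- outer(fam, fam, "==") & outer(kids, kids, "&")
  A[sib] <- 1
  .newRelMatrix(A, ids, "sibling")
}

#' Elementwise (Hadamard) product of relationship matrices
#'
#' The covariance structure of a product of two independent zero-mean
#' latent effect vectors is the elementwise product of their structures
#' (Schur product theorem guarantees positive semidefiniteness). Labels
#' must match exactly.
#'
#' @param a,b [RelationshipMatrix-class] objects with identical labels.
#' @return a [RelationshipMatrix-class]; its kind is the common kind when
#'   `a` and `b` agree, otherwise `"product"`.
#' @export
hadamard <- function(a, b) {
  stopifnot(is(a, "RelationshipMatrix"), is(b, "RelationshipMatrix"))
  if (!identical(individualIds(a), individualIds(b)))
    stop("label mismatch between relationship matrices")
  kind <- if (identical(a@kind, b@kind)) a@kind else "product"
  .newRelMatrix(a@values * b@values, individualIds(a), kind)
}

#' Identity structure over a set of individuals
#'
#' Covariance structure of the individually independent environmental
#' effect: the identity matrix labelled by individual id.
#'
#' @param labels character vector of individual ids (or a
#'   [FamilyCohort-class], whose canonical ordering is used).
#' @return a [RelationshipMatrix-class] of kind `"identity"`.
#' @export
identityMatrixFor <- function(labels) {
  if (is(labels, "FamilyCohort")) labels <- individualIds(labels)
  .newRelMatrix(diag(length(labels)), as.character(labels), "identity")
}

# Sparse factor A with A %*% t(A) == structure matrix, used by both the
# non-centered model parameterization and the synthetic-effect sampler.
# genetic: per-family (block) Cholesky, n x n; family/couple/sibling:
# 0/1 group-indicator factors, n x (number of groups).
.structureFactor <- function(rel, ped = NULL) {
  kind <- rel@kind
  V <- rel@values
  n <- nrow(V)
  if (kind %in% c("genetic", "geographic", "product")) {
    # block-aware dense Cholesky with tiny jitter fallback
    L <- tryCatch(t(chol(V)), error = function(e)
      t(chol(V + diag(1e-8, n))))
    return(Matrix::Matrix(L, sparse = TRUE))
  }
  if (kind == "identity") return(Matrix::Diagonal(n))
  stopifnot(!is.null(ped))
  fam <- as.character(ped$family_id)
  group <- switch(kind,
    family = fam,
    couple = ifelse(ped$role == "parent", paste0("cp.", fam),
                    paste0("i.", seq_len(n))),
    sibling = ifelse(ped$role == "child", paste0("sb.", fam),
                     paste0("i.", seq_len(n))),
    stop("no factor rule for kind ", kind))
  g <- match(group, unique(group))
  Matrix::sparseMatrix(i = seq_len(n), j = g, x = 1,
                       dims = c(n, max(g)))
}

#' Export a relationship matrix as labelled CSV
#'
#' @param x a [RelationshipMatrix-class].
#' @param file path of the CSV to write; first column holds the row labels.
#' @return invisibly, `file`.
#' @export
writeRelationshipMatrix <- function(x, file) {
  stopifnot(is(x, "RelationshipMatrix"))
  write.csv(as.data.frame(x@values), file, row.names = TRUE)
  invisible(file)
}
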