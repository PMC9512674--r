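# Pedigree relationship matrices: worked examples, the path-counting
# oracle, structural invariants and error handling.

test_that("trio GRM reproduces the worked parent-parent-child matrix", {
  A <- matrixValues(buildGRM(trioPedigree()))
  expect_identical(dim(A), c(3L, 3L))
  expected <- matrix(c(1, 0, 0.5,
                       0, 1, 0.5,
                       0.5, 0.5, 1), 3, 3,
                     dimnames = list(c("p1", "p2", "c1"),
                                     c("p1", "p2", "c1")))
  expect_equal(A, expected)
})

test_that("full siblings are related 0.5 and grandparents 0.25", {
  A <- matrixValues(buildGRM(quadPedigree()))
  expect_equal(A["c1", "c2"], 0.5)
  threeGen <- data.frame(
    individual_id = c("g1", "g2", "d", "m", "k"),
    father_id = c(NA, NA, "g1", NA, "d"),
    mother_id = c(NA, NA, "g2", NA, "m"))
  B <- matrixValues(buildGRM(threeGen))
  expect_equal(B["g1", "k"], 0.25)
  expect_equal(B["g1", "d"], 0.5)
  expect_equal(unname(diag(B)), rep(1, 5))
})

test_that("GRM equals the path-counting oracle on random pedigrees", {
  set.seed(11)
  for (rep in 1:25) {
    ped <- randomTreePedigree(sample(6:20, 1))
    A <- matrixValues(buildGRM(ped))
    expect_equal(A, pathCountingGRM(ped), tolerance = 1e-12)
  }
})

test_that("family, couple and sibling matrices match the worked examples", {
  quad <- quadPedigree()
  Fm <- matrixValues(buildFamilyMatrix(quad))
  expect_equal(unname(Fm), matrix(1, 4, 4))
  Cm <- matrixValues(buildCoupleMatrix(quad))
  expect_equal(unname(Cm),
               matrix(c(1, 1, 0, 0,
                        1, 1, 0, 0,
                        0, 0, 1, 0,
                        0, 0, 0, 1), 4, 4))
  Sm <- matrixValues(buildSiblingMatrix(quad))
  expect_equal(unname(Sm),
               matrix(c(1, 0, 0, 0,
                        0, 1, 0, 0,
                        0, 0, 1, 1,
                        0, 0, 1, 1), 4, 4))
})

test_that("two families give block-diagonal structures with no coupling", {
  two <- rbind(quadPedigree(),
               within(quadPedigree(), {
                 family_id <- "f2"
                 individual_id <- paste0("b.", individual_id)
                 father_id <- ifelse(is.na(father_id), NA,
                                     paste0("b.", father_id))
                 mother_id <- ifelse(is.na(mother_id), NA,
                                     paste0("b.", mother_id))
               }))
  for (build in list(buildFamilyMatrix, buildCoupleMatrix,
                     buildSiblingMatrix, buildGRM)) {
    M <- matrixValues(build(two))
    expect_equal(M[1:4, 5:8], matrix(0, 4, 4), ignore_attr = TRUE)
  }
})

test_that("degenerate families give identity blocks", {
  single <- data.frame(family_id = "f1", individual_id = "solo",
                       father_id = NA, mother_id = NA, sex = 0L,
                       age = 40, role = "parent")
  expect_equal(unname(matrixValues(buildFamilyMatrix(single))),
               matrix(1, 1, 1))
  oneParent <- quadPedigree()[-1, ]
  oneParent$father_id <- NA
  Cm <- matrixValues(buildCoupleMatrix(oneParent))
  expect_equal(unname(Cm), diag(3))
  oneChild <- quadPedigree()[-4, ]
  Sm <- matrixValues(buildSiblingMatrix(oneChild))
  expect_equal(unname(Sm), diag(3))
})

test_that("all four structures are symmetric and positive semidefinite", {
  for (rep in 1:5) {
    ped <- pedigree(generateCohort(cohortConfig(nFamilies = 4),
                                   seed = 20 + rep))
    for (build in list(buildGRM, buildFamilyMatrix, buildCoupleMatrix,
                       buildSiblingMatrix)) {
      M <- matrixValues(build(ped))
      expect_equal(M, t(M))
      expect_gte(min(eigen(M, symmetric = TRUE,
                           only.values = TRUE)$values), -1e-8)
    }
  }
  # GRM stays PSD on deeper, non-nuclear pedigrees too
  set.seed(21)
  for (rep in 1:5) {
    A <- matrixValues(buildGRM(randomTreePedigree(15)))
    expect_gte(min(eigen(A, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
  }
})

test_that("family sharing dominates couple and sibling sharing", {
  ped <- pedigree(generateCohort(cohortConfig(nFamilies = 5), seed = 31))
  Fm <- matrixValues(buildFamilyMatrix(ped))
  expect_true(all(Fm >= matrixValues(buildCoupleMatrix(ped))))
  expect_true(all(Fm >= matrixValues(buildSiblingMatrix(ped))))
})

test_that("permuting pedigree rows permutes matrices consistently", {
  set.seed(41)
  ped <- randomTreePedigree(12)
  A <- matrixValues(buildGRM(ped))
  perm <- sample(nrow(ped))
  B <- matrixValues(buildGRM(ped[perm, ]))
  expect_equal(B, A[rownames(B), colnames(B)])
})

test_that("structural pedigree errors are caught", {
  cyc <- data.frame(individual_id = c("a", "b"),
                    father_id = c("b", "a"), mother_id = c(NA, NA))
  expect_error(buildGRM(cyc), "cyclic")
  orphan <- data.frame(individual_id = "a", father_id = "ghost",
                       mother_id = NA)
  expect_error(buildGRM(orphan), "unknown")
  dup <- data.frame(individual_id = c("a", "a"),
                    father_id = c(NA, NA), mother_id = c(NA, NA))
  expect_error(buildGRM(dup), "duplicate")
  triple <- quadPedigree()
  triple$role <- c("parent", "parent", "parent", "child")
  expect_error(buildCoupleMatrix(triple), "more than two parent")
})

test_that("hadamard products obey the identity and annihilation rules", {
  quad <- quadPedigree()
  G <- buildGRM(quad)
  S <- buildSiblingMatrix(quad)
  ones <- famGxE:::.newRelMatrix(matrix(1, 4, 4), individualIds(G),
                                 "product")
  expect_equal(matrixValues(hadamard(G, ones)), matrixValues(G))
  GS <- hadamard(G, S)
  expect_equal(matrixValues(GS), matrixValues(G) * matrixValues(S))
  expect_true(all(matrixValues(GS)[matrixValues(S) == 0] == 0))
  # elementwise product with the identity keeps only the (unit) diagonal
  I <- identityMatrixFor(individualIds(G))
  expect_equal(matrixValues(hadamard(G, I)), diag(4), ignore_attr = TRUE)
  mismatch <- buildGRM(trioPedigree())
  expect_error(hadamard(G, mismatch), "label mismatch")
})
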