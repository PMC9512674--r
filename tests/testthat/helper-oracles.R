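# Shared fixtures and independent oracles, built in code.

# canonical worked pedigrees ------------------------------------------------

trioPedigree <- function() {
  data.frame(family_id = "f1",
             individual_id = c("p1", "p2", "c1"),
             father_id = c(NA, NA, "p1"),
             mother_id = c(NA, NA, "p2"),
             sex = c(1L, 0L, 1L), age = c(45, 43, 18),
             role = c("parent", "parent", "child"))
}

quadPedigree <- function() {
  data.frame(family_id = "f1",
             individual_id = c("p1", "p2", "c1", "c2"),
             father_id = c(NA, NA, "p1", "p1"),
             mother_id = c(NA, NA, "p2", "p2"),
             sex = c(1L, 0L, 1L, 0L), age = c(45, 43, 18, 20),
             role = c("parent", "parent", "child", "child"))
}

# random loop-free pedigrees: members mate only with fresh founders, so each
# pair of individuals is connected by unique up-down paths and Wright's
# path-counting formula is exact.
randomTreePedigree <- function(maxSize = 20) {
  ids <- c("A1", "A2")
  father <- c(NA, NA)
  mother <- c(NA, NA)
  counter <- 2L
  newId <- function() {
    counter <<- counter + 1L
    sprintf("I%02d", counter)
  }
  # seed family
  kids <- sample(1:3, 1)
  for (k in seq_len(kids)) {
    ids <- c(ids, newId()); father <- c(father, "A1"); mother <- c(mother, "A2")
  }
  while (length(ids) < maxSize - 2) {
    # pick any existing member, mate with a fresh founder
    mate1 <- sample(ids, 1)
    mate2 <- newId()
    ids <- c(ids, mate2); father <- c(father, NA); mother <- c(mother, NA)
    kids <- sample(1:2, 1)
    for (k in seq_len(kids)) {
      if (length(ids) >= maxSize) break
      ids <- c(ids, newId())
      father <- c(father, mate1); mother <- c(mother, mate2)
    }
    if (runif(1) < 0.25) break
  }
  data.frame(individual_id = ids, father_id = father, mother_id = mother)
}

# Wright path-counting oracle for the additive relationship matrix:
# a_ij = sum over common ancestors A and pairs of up-paths meeting only at A
# of (1/2)^(total path edges); founders non-inbred, so diagonal is 1.
pathCountingGRM <- function(ped) {
  ids <- as.character(ped$individual_id)
  fa <- setNames(as.character(ped$father_id), ids)
  mo <- setNames(as.character(ped$mother_id), ids)
  # all paths from an individual up to each ancestor (inclusive), as id chains
  upPaths <- function(id) {
    paths <- list(id)           # trivial path of length 0
    for (p in c(fa[[id]], mo[[id]])) {
      if (!is.na(p)) {
        for (pp in upPaths(p)) paths <- c(paths, list(c(id, pp)))
      }
    }
    paths
  }
  allPaths <- lapply(ids, upPaths)
  names(allPaths) <- ids
  n <- length(ids)
  A <- diag(n)
  dimnames(A) <- list(ids, ids)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      tot <- 0
      for (pi in allPaths[[i]]) {
        for (pj in allPaths[[j]]) {
          a <- pi[length(pi)]
          if (a != pj[length(pj)]) next
          shared <- intersect(pi[-length(pi)], pj[-length(pj)])
          if (length(shared)) next
          tot <- tot + 0.5^(length(pi) - 1 + length(pj) - 1)
        }
      }
      A[i, j] <- tot
    }
  }
  A
}

# small ready-made cohort with phenotype for model-level tests
smallCohort <- function(nFamilies = 12, seed = 424,
                        truth = generativeTruth("IM0")) {
  simulateCohort(cohortConfig(nFamilies = nFamilies, nLocations = 6),
                 truth, seed = seed)
}
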