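test_that("coexpressionProfiles matches a brute-force pairwise loop", {
  set.seed(5)
  m <- exp(matrix(rnorm(20), 4, 5))
  e <- mkExpr(m)
  C <- coexpressionProfiles(e)
  X <- log(m)
  for (i in 1:4) for (j in 1:4)
    expect_equal(unname(C[i, j]),
                 if (i == j) 1 else cor(X[i, ], X[j, ]), tolerance = 1e-12)
})

test_that("coexpressionProfiles handles identical and constant genes", {
  m <- rbind(g1 = c(1, 2, 4, 8), g2 = c(2, 4, 8, 16), g3 = rep(3, 4))
  colnames(m) <- sprintf("mc%d", 1:4)
  C <- coexpressionProfiles(mkExpr(m))
  expect_equal(unname(C["g1", "g2"]), 1)          # identical profiles
  expect_equal(unname(C["g3", c("g1", "g2")]), c(0, 0))  # zero variance
  expect_equal(unname(C["g3", "g3"]), 1)
  expect_error(coexpressionProfiles(mkExpr(m[, 1:2])), "3 metacells")
})

test_that("self-comparison yields EC = 1 and convergence", {
  set.seed(8)
  e <- mkExpr(exp(matrix(rnorm(60), 10, 6)))
  hom <- identityHomology(rownames(fcMatrix(e)))
  ec <- computeEC(e, e, hom)
  expect_true(all(abs(ecScores(ec) - 1) < 1e-12))
  expect_true(ec@converged)
})

test_that("a constant gene gets EC 0 at every iteration", {
  set.seed(9)
  m <- exp(matrix(rnorm(50), 10, 5))
  m[3, ] <- 2                                     # constant gene
  e1 <- mkExpr(m, "a"); e2 <- mkExpr(exp(matrix(rnorm(50), 10, 5)), "b")
  hom <- identityHomology(rownames(fcMatrix(e1)))
  for (iters in c(0L, 3L)) {
    ec <- computeEC(e1, e2, hom, maxIterations = iters)
    expect_equal(unname(ecScores(ec)[3]), 0)
  }
})

test_that("iteration-0 EC equals the correlation-of-correlations oracle
           and a shuffled pair scores the minimum", {
  sim <- generateAtlases(nGenes = 40, nModules = 0, conservedFraction = 1,
                         noiseSd = 0, seed = 13)
  a <- sim$atlases$spA; b <- sim$atlases$spB
  # shuffle one gene's profile in species B to break its conservation
  fcB <- fcMatrix(b)
  set.seed(1)
  fcB["spB_g0005", ] <- sample(fcB["spB_g0005", ])
  b2 <- MetacellExpression("spB", fcB, metacellToCelltype = metacellTypes(b))
  ec <- computeEC(a, b2, sim$homology, maxIterations = 0L)
  oracle <- ecOracle(a, b2, homologyPairs(sim$homology))
  expect_lt(max(abs(unname(ecScores(ec)) - oracle)), 1e-10)
  shuffledIdx <- which(homologyPairs(sim$homology)$geneB == "spB_g0005")
  expect_equal(unname(which.min(ecScores(ec))), shuffledIdx)
})

test_that("EC is symmetric in species order and invariant to metacell
           permutations", {
  sim <- generateAtlases(nGenes = 30, nModules = 0, seed = 17)
  a <- sim$atlases$spA; b <- sim$atlases$spB
  hp <- homologyPairs(sim$homology)
  ecAB <- ecScores(computeEC(a, b, sim$homology))
  swapped <- HomologyMap(data.frame(geneA = hp$geneB, geneB = hp$geneA,
                                    relation = "one2one",
                                    setId = NA_character_))
  ecBA <- ecScores(computeEC(b, a, swapped))
  expect_equal(unname(ecAB), unname(ecBA), tolerance = 1e-12)

  fcA <- fcMatrix(a)
  perm <- sample(ncol(fcA))
  aPerm <- MetacellExpression("spA", fcA[, perm],
                              metacellToCelltype = metacellTypes(a)[perm])
  ecPerm <- ecScores(computeEC(aPerm, b, sim$homology))
  expect_equal(unname(ecAB), unname(ecPerm), tolerance = 1e-10)
})

test_that("mean EC separates conserved from diverged genes at
           increasing noise", {
  for (sd in c(0, 0.3, 0.6)) {
    sim <- generateAtlases(nGenes = 120, nModules = 0,
                           conservedFraction = 0.5, noiseSd = sd,
                           seed = 100 + round(10 * sd))
    ec <- computeEC(sim$atlases$spA, sim$atlases$spB, sim$homology)
    p <- ecPairs(ec)
    cls <- unlist(sim$truth$conservationClass)[sub("^spA_", "", p$geneA)]
    expect_gt(mean(p$ec[cls == "conserved"]), mean(p$ec[cls == "diverged"]))
  }
})

test_that("computeEC validates its inputs", {
  sim <- generateAtlases(nGenes = 20, nModules = 0, seed = 2)
  hp <- homologyPairs(sim$homology)
  bad <- HomologyMap(data.frame(geneA = c(hp$geneA[1:3], "nope"),
                                geneB = c(hp$geneB[1:3], "nope"),
                                relation = "one2one",
                                setId = NA_character_))
  expect_error(computeEC(sim$atlases$spA, sim$atlases$spB, bad), "unmatched")
  expect_error(computeEC(sim$atlases$spA, sim$atlases$spB, sim$homology,
                         tol = 0), "tol")
})

test_that("paralog resolution prefers the exact-profile candidate and
           breaks ties lexicographically", {
  sim <- generateAtlases(nGenes = 40, nModules = 0, conservedFraction = 1,
                         noiseSd = 0.1, nParalogSets = 1, seed = 31)
  # candidate duplicating the true ortholog profile must win
  res <- selectBestParalogs(sim$atlases$spA, sim$atlases$spB,
                            sim$homology, nReference = 30, seed = 1)
  tr <- sim$truth$paralogs[[1]]
  expect_identical(homologyPairs(res)$geneB, tr$trueGeneB)

  # identical candidates tie; the lexicographically smaller pair wins
  b <- sim$atlases$spB
  fcB <- fcMatrix(b)
  hp <- homologyPairs(sim$homology)
  cand <- hp[hp$relation == "candidate_paralog", ]
  dupFc <- rbind(fcB, zzz_dup = fcB[cand$geneB[1], ])
  rownames(dupFc)[nrow(dupFc)] <- "spB_zzz_dup"
  b2 <- MetacellExpression("spB", dupFc,
                           metacellToCelltype = metacellTypes(b))
  hom2 <- HomologyMap(rbind(
    hp[hp$relation == "one2one", ],
    data.frame(geneA = cand$geneA[1],
               geneB = c(cand$geneB[1], "spB_zzz_dup"),
               relation = "candidate_paralog", setId = "TIE")))
  res2 <- selectBestParalogs(sim$atlases$spA, b2, hom2,
                             nReference = 30, seed = 1)
  win <- homologyPairs(res2)
  expect_identical(win$geneB[win$setId == "TIE"],
                   min(cand$geneB[1], "spB_zzz_dup"))
})

test_that("planted paralog sets resolve to the expression-retaining
           member", {
  sim <- generateAtlases(nGenes = 200, nModules = 0, conservedFraction = 1,
                         noiseSd = 0.2, nParalogSets = 20,
                         paralogJitterSd = 0.2, seed = 51)
  res <- selectBestParalogs(sim$atlases$spA, sim$atlases$spB,
                            sim$homology, nReference = 150, seed = 3)
  rp <- homologyPairs(res)
  hits <- vapply(names(sim$truth$paralogs), function(s)
    rp$geneB[rp$setId == s] == sim$truth$paralogs[[s]]$trueGeneB,
    logical(1))
  expect_gte(mean(hits), 0.9)
})
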