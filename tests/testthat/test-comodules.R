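test_that("eigengene of a single shared profile is that profile,
           z-scored", {
  set.seed(1)
  v <- rnorm(12)
  fc <- exp(t(vapply(1:5, function(i) v, numeric(12))))
  rownames(fc) <- sprintf("g%d", 1:5)
  colnames(fc) <- sprintf("mc%02d", 1:12)
  e <- mkExpr(fc)
  eg <- moduleEigengene(rownames(fc), e)
  for (g in rownames(fc))
    expect_equal(abs(cor(eg, log(fc[g, ]))), 1, tolerance = 1e-9)
  expect_gt(cor(eg, v), 0)        # orientation: positive with the mean
})

test_that("eigengene matches an SVD oracle up to sign and explains at
           least any single gene's variance", {
  set.seed(2)
  fc <- exp(matrix(rnorm(200), 10, 20,
                   dimnames = list(sprintf("g%02d", 1:10),
                                   sprintf("mc%02d", 1:20))))
  e <- mkExpr(fc)
  eg <- moduleEigengene(rownames(fc), e)
  Z <- t(scale(t(log(fc))))
  sv <- svd(Z)
  oracle <- sv$v[, 1] * sv$d[1]
  expect_equal(abs(cor(eg, oracle)), 1, tolerance = 1e-9)
  # variance explained by the first PC bounds any single standardized gene
  proj <- function(v) sum((Z %*% v / sqrt(sum(v^2)))^2)
  for (g in 1:10) expect_gte(proj(oracle) + 1e-9, proj(Z[g, ]))
  expect_error(moduleEigengene(c("g01", "g02"),
                               mkExpr(matrix(1, 2, 5,
                                 dimnames = list(c("g01", "g02"), NULL)))),
               "zero-variance")
})

test_that("two orthogonal planted blocks give exactly two modules and an
           uncorrelated gene stays unassigned", {
  set.seed(3)
  nmc <- 12
  blockA <- rep(c(2, -2), each = nmc / 2)
  blockB <- rep(c(-2, 2, -2, 2), each = nmc / 4)
  mkRow <- function(base) base + rnorm(nmc, sd = 0.05)
  fc <- exp(rbind(
    t(vapply(1:12, function(i) mkRow(blockA), numeric(nmc))),
    t(vapply(1:12, function(i) mkRow(blockB), numeric(nmc))),
    lone = rnorm(nmc, sd = 2)))
  rownames(fc) <- c(sprintf("a%02d", 1:12), sprintf("b%02d", 1:12), "lone")
  colnames(fc) <- sprintf("mc%02d", 1:nmc)
  ms <- detectModules(mkExpr(fc), minSize = 10)
  memb <- moduleMembership(ms)
  expect_length(unique(memb), 2L)
  expect_false("lone" %in% names(memb))
  expect_length(unique(memb[sprintf("a%02d", 1:12)]), 1L)
  expect_length(unique(memb[sprintf("b%02d", 1:12)]), 1L)
})

test_that("module detection is invariant to gene and metacell order", {
  sim <- generateAtlases(nGenes = 150, nModules = 3, moduleSize = 20,
                         conservedFraction = 0.9, noiseSd = 0.3, seed = 4)
  e <- sim$atlases$spA
  fc <- fcMatrix(e)
  set.seed(5)
  gOrd <- sample(nrow(fc)); mOrd <- sample(ncol(fc))
  ePerm <- MetacellExpression("spA", fc[gOrd, mOrd],
    metacellToCelltype = metacellTypes(e)[mOrd])
  m1 <- moduleMembership(detectModules(e))
  m2 <- moduleMembership(detectModules(ePerm))
  expect_setequal(names(m1), names(m2))
  # same partition (module ids may differ)
  tab <- table(m1[names(m2)], m2)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("planted module structure is recovered with high agreement", {
  skip_if_not_installed("mclust")
  sim <- generateAtlases(nGenes = 300, nModules = 5, moduleSize = 25,
                         conservedFraction = 0.9, noiseSd = 0.3, seed = 4)
  ms <- detectModules(sim$atlases$spA)
  truthMod <- unlist(sim$truth$modules)
  memb <- moduleMembership(ms)
  common <- intersect(paste0("spA_", names(truthMod)), names(memb))
  expect_gte(length(common), 100)
  ari <- mclust::adjustedRandIndex(truthMod[sub("spA_", "", common)],
                                   memb[common])
  expect_gte(ari, 0.8)
})

test_that("cross-species module clustering follows Jaccard set
           arithmetic and transitive closure", {
  mkSet <- function(sp, mods) {
    memb <- unlist(lapply(names(mods), function(m)
      setNames(rep(m, length(mods[[m]])), mods[[m]])))
    new("GeneModuleSet", species = sp, membership = memb,
        eigengenes = matrix(0, 0, 0), kme = setNames(numeric(), character()))
  }
  og <- setNames(sub("_.$", "", c(paste0("og", 1:15, "_a"),
                                  paste0("og", 1:15, "_b"))),
                 c(paste0("og", 1:15, "_a"), paste0("og", 1:15, "_b")))
  # module pair sharing 5 of 15 pooled orthogroups -> J = 1/3
  a <- mkSet("A", list(M1 = paste0("og", 1:10, "_a")))
  b <- mkSet("B", list(M1 = paste0("og", 6:15, "_b")))
  msm <- clusterModulesAcrossSpecies(list(a, b), og, jaccardMin = 0.1)
  expect_length(msm@components, 1L)
  expect_equal(msm@edges$jaccard, 1 / 3, tolerance = 1e-12)

  # disjoint orthogroup sets stay apart
  b2 <- mkSet("B", list(M1 = paste0("og", 11:15, "_b")))
  a2 <- mkSet("A", list(M1 = paste0("og", 1:5, "_a")))
  msm2 <- clusterModulesAcrossSpecies(list(a2, b2), og)
  expect_length(msm2@components, 2L)

  # random bipartite inputs: components equal the transitive closure of
  # the thresholded edge relation (igraph-free oracle by flood fill)
  set.seed(6)
  ogAll <- paste0("og", 1:40)
  names(ogAll) <- ogAll
  sets <- lapply(c("A", "B", "C"), function(sp) {
    mods <- lapply(1:3, function(i) {
      genes <- sample(ogAll, 8)
      setNames(genes, genes)   # gene label == orthogroup label
    })
    names(mods) <- paste0("M", 1:3)
    mkSet(sp, mods)
  })
  msm3 <- clusterModulesAcrossSpecies(sets, ogAll, jaccardMin = 0.1)
  # flood-fill oracle over the edge list
  ids <- unlist(lapply(msm3@components, identity))
  adj <- rbind(msm3@edges[, c("moduleA", "moduleB")],
               setNames(msm3@edges[, c("moduleB", "moduleA")],
                        c("moduleA", "moduleB")))
  reach <- function(start) {
    seen <- start
    repeat {
      nxt <- unique(adj$moduleB[adj$moduleA %in% seen])
      new <- setdiff(nxt, seen)
      if (!length(new)) break
      seen <- c(seen, new)
    }
    sort(seen)
  }
  for (comp in msm3@components)
    expect_setequal(comp, reach(comp[1]))
})

test_that("module activity scoring equals a counting oracle", {
  set.seed(7)
  genes <- sprintf("g%02d", 1:20)
  memb <- setNames(rep("M01", 20), genes)
  ms <- new("GeneModuleSet", species = "A", membership = memb,
            eigengenes = matrix(0, 0, 0),
            kme = setNames(numeric(), character()))
  tab <- matrix(runif(20 * 4, 0.3, 3), 20, 4,
                dimnames = list(genes, sprintf("T%d", 1:4)))
  act <- scoreModuleActivity("A|M01", list(A = ms), list(A = tab),
                             activeFc = 1.5)
  oracle <- colMeans(tab >= 1.5)
  expect_equal(act, oracle, tolerance = 1e-12)

  tabHigh <- tab; tabHigh[, "T1"] <- 2
  expect_equal(unname(scoreModuleActivity("A|M01", list(A = ms),
                                          list(A = tabHigh))["T1"]), 1)
  tabLow <- tab; tabLow[] <- 1.2
  expect_true(all(scoreModuleActivity("A|M01", list(A = ms),
                                      list(A = tabLow)) == 0))
})
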