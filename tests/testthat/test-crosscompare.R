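test_that("self-similarity with full EC weights has unit diagonal", {
  set.seed(2)
  fc <- exp(matrix(rnorm(120), 20, 6,
                   dimnames = list(sprintf("g%02d", 1:20),
                                   sprintf("T%d", 1:6))))
  ec <- new("ECWeights",
            pairs = data.frame(geneA = rownames(fc), geneB = rownames(fc)),
            ec = rep(1, 20), iterations = 0L, converged = TRUE)
  sm <- celltypeSimilarity(fc, fc, ec)
  expect_equal(unname(diag(sm@similarity)), rep(1, 6), tolerance = 1e-12)
})

test_that("similarity is undefined below the gene-support floor and
           invariant to gene order", {
  set.seed(3)
  fc <- exp(matrix(rnorm(120), 20, 6,
                   dimnames = list(sprintf("g%02d", 1:20),
                                   sprintf("T%d", 1:6))))
  ecv <- rep(0, 20); ecv[1] <- 1
  ecLow <- new("ECWeights",
               pairs = data.frame(geneA = rownames(fc),
                                  geneB = rownames(fc)),
               ec = ecv, iterations = 0L, converged = TRUE)
  sm <- celltypeSimilarity(fc, fc, ecLow)
  expect_true(all(is.na(sm@similarity)))

  ecFull <- new("ECWeights",
                pairs = data.frame(geneA = rownames(fc),
                                   geneB = rownames(fc)),
                ec = runif(20), iterations = 0L, converged = TRUE)
  s1 <- celltypeSimilarity(fc, fc, ecFull)@similarity
  ord <- sample(20)
  ecPerm <- new("ECWeights",
                pairs = data.frame(geneA = rownames(fc)[ord],
                                   geneB = rownames(fc)[ord]),
                ec = ecFull@ec[ord], iterations = 0L, converged = TRUE)
  s2 <- celltypeSimilarity(fc, fc, ecPerm)@similarity
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("binarization is boundary-inclusive and matches the
           elementwise oracle", {
  set.seed(4)
  fc <- matrix(runif(40, 0.5, 4), 10, 4,
               dimnames = list(sprintf("g%02d", 1:10), sprintf("T%d", 1:4)))
  fc[1, ] <- c(2, 1, 1, 1)              # exact boundary
  fc[2, ] <- 1                          # constant -> dropped
  bin <- binarizeExpression(fc, fcThreshold = 2, minPresenceFraction = 0.7)
  expect_identical(unname(bin["g01", 1]), 1L)
  expect_false("g02" %in% rownames(bin))
  oracle <- (fc >= 2) * 1L
  for (g in rownames(bin))
    expect_identical(unname(bin[g, ]), unname(oracle[g, ]))
})

test_that("Log-Det distance matches its closed form", {
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  y <- c(1, 1, 1, 0, 0, 0, 0, 1)
  expect_equal(logdetDistance(x, y), -0.5 * log(0.5), tolerance = 1e-12)
  expect_equal(logdetDistance(x, x), 0, tolerance = 1e-12)
  expect_equal(logdetDistance(x, y), logdetDistance(y, x))
  # complementary balanced vectors saturate at the cap, strictly above
  # any single-mismatch distance
  xm <- x; xm[4] <- 0
  expect_gt(suppressWarnings(logdetDistance(x, 1 - x)),
            logdetDistance(x, xm))
  expect_error(logdetDistance(x, y[1:4]), "length")
  expect_warning(logdetDistance(c(1, 1, 1, 1), c(1, 0, 1, 0)),
                 "degenerate")
})

test_that("Log-Det equals the closed-form oracle on random vectors", {
  set.seed(6)
  for (rep in 1:25) {
    x <- rbinom(30, 1, 0.5); y <- rbinom(30, 1, 0.5)
    expect_equal(suppressWarnings(logdetDistance(x, y)),
                 logdetOracle(x, y), tolerance = 1e-12)
  }
})

test_that("UPGMA recovers simple topologies and ultrametric inputs
           exactly", {
  D <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgmaTree(D)@tree
  expect_true(ape::is.monophyletic(tr, c("A", "B")))

  # an ultrametric matrix is a fixed point (cophenetic distances equal it)
  D4 <- matrix(c(0, 2, 6, 6,
                 2, 0, 6, 6,
                 6, 6, 0, 4,
                 6, 6, 4, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr4 <- upgmaTree(D4)@tree
  co <- ape::cophenetic.phylo(tr4)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(co, D4, tolerance = 1e-9)
  expect_error(upgmaTree(matrix(c(0, NA, NA, 0), 2, 2)), "distances")
})

test_that("UPGMA matches a naive agglomeration oracle on perturbed
           ultrametric matrices", {
  set.seed(8)
  for (rep in 1:5) {
    base <- matrix(0, 6, 6, dimnames = list(LETTERS[1:6], LETTERS[1:6]))
    # random ultrametric via a random dendrogram of merge heights
    hts <- sort(runif(5, 1, 10))
    hc <- hclust(dist(cbind(rnorm(6), rnorm(6))), method = "average")
    hc$height <- hts
    co <- stats::cophenetic(hc)
    D <- as.matrix(co) + matrix(runif(36, 0, 0.01), 6, 6)
    D <- (D + t(D)) / 2; diag(D) <- 0
    dimnames(D) <- dimnames(base)
    tr <- upgmaTree(D)@tree
    expect_setequal(lapply(phyloClades(tr), paste, collapse = ","),
                    lapply(upgmaOracleClades(D), paste, collapse = ","))
  }
})

test_that("UPGMA trees are ultrametric", {
  set.seed(9)
  m <- matrix(rbinom(200, 1, 0.4), 50, 4,
              dimnames = list(NULL, sprintf("T%d", 1:4)))
  D <- crosscell:::.logdetMatrix(m)
  tr <- upgmaTree(D)@tree
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  expect_lt(diff(range(depths)), 1e-9)
})

test_that("bootstrap supports behave at the extremes and favor a clade
           with exclusive characters", {
  set.seed(10)
  taxa <- sprintf("X%d", 1:6)
  m <- matrix(rbinom(50 * 6, 1, 0.5), 50, 6, dimnames = list(NULL, taxa))
  bs1 <- suppressMessages(felsensteinBootstrap(m, nReps = 1L, seed = 1))
  expect_true(all(bs1@supports %in% c(0, 100)))

  excl <- matrix(0L, 50, 6, dimnames = list(NULL, taxa))
  excl[, 1:2] <- 1L
  m2 <- rbind(excl, matrix(rbinom(100 * 6, 1, 0.4), 100, 6,
                           dimnames = list(NULL, taxa)))
  bs <- suppressMessages(felsensteinBootstrap(m2, nReps = 100L, seed = 2))
  tr <- bs@tree
  cladeNode <- ape::getMRCA(tr, c("X1", "X2"))
  expect_true(ape::is.monophyletic(tr, c("X1", "X2")))
  expect_gte(bs@supports[as.character(cladeNode)], 95)
})

test_that("planted cell-type topology is recovered through binarize +
           Log-Det + UPGMA", {
  skip_if_not_installed("phangorn")
  sim <- generateAtlases(nGenes = 300, nModules = 0, markersPerClade = 8,
                         noiseSd = 0.2, seed = 11)
  bin <- binarizeExpression(celltypeFc(sim$atlases$spA), 2, 0.7)
  tr <- upgmaTree(crosscell:::.logdetMatrix(bin))@tree
  planted <- ape::read.tree(text = sim$truth$celltypeTree)
  expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(planted)), 0)
})
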