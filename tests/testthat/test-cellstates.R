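test_that("AUC scores hit the extremes and the step-curve oracle", {
  set.seed(1)
  n <- 100
  fc <- matrix(runif(n), n, 1,
               dimnames = list(sprintf("g%03d", 1:n), "mc1"))
  # put a 5-gene set at the very top ranks -> score 1 at k = 20
  fc[1:5, 1] <- 10:6
  e <- mkExpr(fc)
  expect_equal(unname(aucScores(e, sprintf("g%03d", 1:5),
                                topFraction = 0.2)), 1)
  # a set entirely below rank k -> 0
  ord <- order(-fc[, 1])
  bottom <- rownames(fc)[ord[81:90]]
  expect_equal(unname(aucScores(e, bottom, topFraction = 0.2)), 0)

  # |S| = 10 at ranks 1,3,...,19 with k = 20: discrete summation oracle
  fc2 <- matrix(0, n, 1, dimnames = list(sprintf("g%03d", 1:n), "mc1"))
  fc2[, 1] <- seq(n, 1) / 10          # rank i = gene i
  e2 <- mkExpr(exp(fc2))
  setGenes <- sprintf("g%03d", seq(1, 19, 2))
  k <- 20
  inSet <- seq_len(k) %in% seq(1, 19, 2)
  oracle <- sum(cumsum(inSet)) / (10 * k - 10 * 9 / 2)
  expect_equal(unname(aucScores(e2, setGenes, topFraction = 0.2)), oracle,
               tolerance = 1e-12)
  expect_error(aucScores(e, character(0)), "empty")
})

test_that("AUC scores are invariant to positive rescaling per metacell", {
  set.seed(2)
  fc <- matrix(runif(200, 0.1, 5), 100, 2,
               dimnames = list(sprintf("g%03d", 1:100), c("m1", "m2")))
  e1 <- mkExpr(fc)
  e2 <- mkExpr(sweep(fc, 2, c(3, 0.5), "*"))
  gs <- sample(rownames(fc), 10)
  expect_equal(aucScores(e1, gs), aucScores(e2, gs), tolerance = 1e-12)
})

test_that("intermediate calls require both marker programs", {
  set.seed(3)
  genes <- sprintf("g%03d", 1:60)
  mA <- new("MarkerSet", celltype = "A", genes = genes[1:10],
            fcThreshold = 2)
  mB <- new("MarkerSet", celltype = "B", genes = genes[11:20],
            fcThreshold = 2)
  mkCell <- function(wA, wB, bg = 1) {
    p <- rep(bg, 60); p[1:10] <- wA; p[11:20] <- wB
    rmultinom(1, 1000, p / sum(p))[, 1]
  }
  # terminals: 30/70 of UMIs in their own markers; dual-program cells
  # keep both programs at full mass by squeezing the background
  cnt <- cbind(vapply(1:20, function(i) mkCell(3, 0), numeric(60)),
               vapply(1:20, function(i) mkCell(0, 3), numeric(60)),
               vapply(1:5, function(i) mkCell(3, 3, bg = 0.1),
                      numeric(60)))
  dimnames(cnt) <- list(genes, sprintf("c%02d", 1:45))
  types <- setNames(c(rep("A", 20), rep("B", 20), rep(NA, 5)),
                    colnames(cnt))
  res <- classifyIntermediates(UmiMatrix(cnt), mA, mB, cellTypes = types)
  expect_false(any(res$intermediate[1:40]))       # pure terminals
  expect_true(all(res$intermediate[41:45]))       # dual-program cells
})

test_that("fully overlapping marker sets cannot produce intermediate
           calls", {
  genes <- sprintf("g%03d", 1:30)
  cnt <- matrix(rpois(30 * 10, 5), 30, 10,
                dimnames = list(genes, sprintf("c%02d", 1:10)))
  mA <- new("MarkerSet", celltype = "A", genes = genes[1:10],
            fcThreshold = 2)
  mB <- new("MarkerSet", celltype = "B", genes = genes[1:10],
            fcThreshold = 2)
  expect_warning(
    expect_error(classifyIntermediates(UmiMatrix(cnt), mA, mB,
                                       tauA = 0.1, tauB = 0.1),
                 "empty"),
    "overlapping")
})

test_that("two-tailed doublet test matches pmf summation and binom.test", {
  # modal outcome -> p = 1
  expect_equal(doubletBinomialTest(round(1000 * 0.02), 1000, 0.1, 0.2), 1,
               tolerance = 1e-12)
  # worked case: n = 1000, p0 = 0.02, k = 40
  p <- doubletBinomialTest(40, 1000, 0.10, 0.20)
  pmf <- dbinom(0:1000, 1000, 0.02)
  oracle <- sum(pmf[pmf <= dbinom(40, 1000, 0.02) * (1 + 1e-7)])
  expect_equal(p, oracle, tolerance = 1e-12)
  expect_lt(p, 0.01)
  # k = 0, n = 10, p0 = 0.5: both tails tie at 2^-10
  expect_equal(doubletBinomialTest(0, 10, 0.5, 0.999999) /
                 (2 * 2^-10), 1, tolerance = 1e-3)
  # independent cross-check against stats::binom.test over a grid
  for (n in c(50, 500, 5000)) {
    for (k in c(0, 1, round(n * 0.02), round(n * 0.1))) {
      expect_equal(doubletBinomialTest(k, n, 0.1, 0.2),
                   binom.test(k, n, 0.02)$p.value, tolerance = 1e-12)
    }
  }
})

test_that("marker conservation test has the stated closed forms", {
  expect_gt(markerConservationTest(5, 10, 50, 100), 0.5)
  expect_equal(markerConservationTest(0, 20, 50, 100), 2^-20,
               tolerance = 1e-15)
  expect_equal(markerConservationTest(20, 20, 50, 100), 1)
  expect_error(markerConservationTest(1, 2, 0, 0), "nTerm")
  # pmf summation oracle
  for (n in c(100, 1000)) {
    k <- round(n / 4)
    expect_equal(markerConservationTest(k, n, 30, 100),
                 sum(dbinom(0:k, n, 0.3)), tolerance = 1e-12)
  }
})

test_that("cycling calls respect the sd = 0 convention and recover a
           planted cycling population", {
  genes <- sprintf("g%03d", 1:50)
  cnt0 <- matrix(4L, 50, 20, dimnames = list(genes, sprintf("c%02d", 1:20)))
  expect_false(any(callCyclingCells(UmiMatrix(cnt0), genes[1:5])))

  set.seed(5)
  cyc <- genes[1:10]
  base <- rep(1, 50)
  pNorm <- base / sum(base)
  pCyc <- base; pCyc[1:10] <- 5; pCyc <- pCyc / sum(pCyc)
  cnt <- cbind(
    vapply(1:950, function(i) rmultinom(1, 1000, pNorm)[, 1], numeric(50)),
    vapply(1:50, function(i) rmultinom(1, 1000, pCyc)[, 1], numeric(50)))
  dimnames(cnt) <- list(genes, sprintf("cell%04d", 1:1000))
  calls <- callCyclingCells(UmiMatrix(cnt), cyc)
  expect_gte(sum(calls[951:1000]), 45)
  expect_lte(sum(calls[1:950]), 20)

  # doubling depth uniformly leaves calls unchanged
  calls2 <- callCyclingCells(UmiMatrix(cnt * 2L), cyc)
  expect_identical(calls, calls2)
})

test_that("metacell quality filtering applies every rule and records
           reasons", {
  set.seed(6)
  n <- 40
  stats <- data.frame(
    metacell = sprintf("mc%02d", 1:n),
    totalUmi = round(10^rnorm(n, 5, 0.1)),
    medianUmiPerCell = round(10^rnorm(n, 3, 0.1)),
    nMarkers = rep(30L, n), nTfMarkers = rep(3L, n))
  stats$nMarkers[1] <- 9L                      # boundary: < 10 markers
  stats$nTfMarkers[2] <- 0L
  stats$totalUmi[3] <- 10                      # extreme low outlier
  out <- filterMetacells(stats)
  expect_false(out$keep[1]); expect_match(out$reasons[1], "markers")
  expect_false(out$keep[2]); expect_match(out$reasons[2], "no_tf")
  expect_false(out$keep[3]); expect_match(out$reasons[3], "low_total_umi")
  # boundary-inclusive: exactly 10 markers and 1 TF is kept
  stats2 <- stats[4:10, ]
  stats2$nMarkers <- 10L; stats2$nTfMarkers <- 1L
  out2 <- filterMetacells(stats2)
  expect_true(all(out2$keep))

  # rule-by-rule oracle on a random table
  zcut <- qnorm(0.01)
  z <- function(v) { x <- log10(v); (x - mean(x)) / sd(x) }
  oracleKeep <- !(z(stats$totalUmi) < zcut |
                  z(stats$medianUmiPerCell) < zcut |
                  stats$nMarkers < 10 | stats$nTfMarkers == 0)
  expect_identical(out$keep, oracleKeep)
})
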