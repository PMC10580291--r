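# EC-weighted cell-type comparison across species and cell-type trees from
# binarized marker expression.

#' Pairwise cell-type similarity between two species
#'
#' @slot similarity numeric matrix (cell types of species A x cell types of
#'   species B) of EC-weighted Pearson coefficients; `NA` marks undefined
#'   entries (insufficient gene support).
#' @slot support integer matrix of supporting gene-pair counts.
#' @export
setClass("CellTypeSimilarity",
  representation(similarity = "matrix", support = "matrix"))

setMethod("show", "CellTypeSimilarity", function(object) {
  cat("CellTypeSimilarity: ", nrow(object@similarity), " x ",
      ncol(object@similarity), " cell types; ",
      sum(is.na(object@similarity)), " undefined entries\n", sep = "")
})

#' Cell-type tree with bootstrap supports
#'
#' @slot tree an `ape::phylo` over species-prefixed cell-type leaves.
#' @slot supports named numeric, per-internal-node bootstrap support in
#'   \[0,100\] (empty until [felsensteinBootstrap()] is run).
#' @slot distances the Log-Det distance matrix the tree was built from.
#' @export
setClass("CellTypeTree",
  representation(tree = "ANY", supports = "numeric", distances = "matrix"))

setMethod("show", "CellTypeTree", function(object) {
  cat("CellTypeTree: ", length(object@tree$tip.label), " cell types",
      if (length(object@supports)) sprintf(", bootstrap supports %g-%g",
        min(object@supports), max(object@supports)) else "", "\n", sep = "")
})

#' EC-weighted similarity between the cell types of two species
#'
#' For every pair of cell types, the matched ortholog-pair fold changes of
#' the two species are quantile-normalized against each other and
#' correlated with a weighted Pearson coefficient, weights being the
#' expression-conservation (EC) scores. Entries with fewer than
#' `minSupport` supporting gene pairs (EC > 0) are undefined (`NA`).
#'
#' @param fcA,fcB genes x cell-types fold-change tables (cell-type level).
#' @param ec an [ECWeights-class] whose pairs link `fcA` rows to `fcB`
#'   rows.
#' @param minSupport minimum supporting gene pairs (default 10).
#' @return a [CellTypeSimilarity-class].
#' @export
celltypeSimilarity <- function(fcA, fcB, ec, minSupport = 10L) {
  stopifnot(is(ec, "ECWeights"))
  p <- ecPairs(ec)
  keep <- p$geneA %in% rownames(fcA) & p$geneB %in% rownames(fcB)
  p <- p[keep, , drop = FALSE]
  if (!nrow(p)) stop("no matched genes between the tables and the EC pairs")
  support <- sum(p$ec > 0)
  sim <- matrix(NA_real_, ncol(fcA), ncol(fcB),
                dimnames = list(colnames(fcA), colnames(fcB)))
  supp <- matrix(as.integer(support), ncol(fcA), ncol(fcB),
                 dimnames = dimnames(sim))
  if (support >= minSupport && sum(p$ec) > 0) {
    A <- fcA[p$geneA, , drop = FALSE]
    B <- fcB[p$geneB, , drop = FALSE]
    for (i in seq_len(ncol(A))) {
      for (j in seq_len(ncol(B))) {
        qn <- quantileNormalize(A[, i], B[, j])
        sim[i, j] <- weightedPearson(qn$a, qn$b, p$ec)
      }
    }
  }
  new("CellTypeSimilarity", similarity = sim, support = supp)
}

#' Binarize a fold-change table into marker characters
#'
#' An entry is 1 when the fold change reaches `fcThreshold` (boundary
#' inclusive), 0 otherwise, and `NA` where the input is missing (no
#' measurable ortholog). Genes are retained only if they carry usable data
#' in at least `minPresenceFraction` of the cell types, and constant rows
#' (all 0 or all 1 among non-missing entries) are dropped as uninformative.
#'
#' @param fc genes x cell-types numeric matrix, possibly with `NA`.
#' @param fcThreshold minimum fold change (> 1; default 2).
#' @param minPresenceFraction minimum fraction of cell types with
#'   non-missing data (default 0.7).
#' @return integer 0/1/NA matrix; error if nothing survives filtering.
#' @export
binarizeExpression <- function(fc, fcThreshold = 2, minPresenceFraction = 0.7) {
  stopifnot(fcThreshold > 1)
  bin <- ifelse(is.na(fc), NA_integer_, ifelse(fc >= fcThreshold, 1L, 0L))
  dimnames(bin) <- dimnames(fc)
  presence <- rowMeans(!is.na(bin))
  ones <- rowSums(bin == 1L, na.rm = TRUE)
  usable <- rowSums(!is.na(bin))
  keep <- presence >= minPresenceFraction & ones > 0 & ones < usable
  bin <- bin[keep, , drop = FALSE]
  if (!nrow(bin)) stop("empty matrix after binarization filtering")
  bin
}

# joint 2x2 relative-frequency table over non-missing shared positions
.logdetPair <- function(x, y, cap = 10) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("vectors must share at least 4 characters")
  n <- length(x)
  F <- matrix(c(sum(x == 1 & y == 1), sum(x == 1 & y == 0),
                sum(x == 0 & y == 1), sum(x == 0 & y == 0)),
              2, 2, byrow = TRUE) / n
  rowm <- rowSums(F); colm <- colSums(F)
  dF <- det(F)
  if (any(rowm == 0) || any(colm == 0))
    return(list(d = cap, degenerate = TRUE, capped = TRUE))
  if (dF <= 0)   # negative association: paralinear distance saturates
    return(list(d = cap, degenerate = FALSE, capped = TRUE))
  d <- -0.5 * (log(dF) - 0.5 * (sum(log(rowm)) + sum(log(colm))))
  list(d = d, degenerate = FALSE, capped = FALSE)
}

#' Log-Det (paralinear) distance between two binary profiles
#'
#' With `F` the 2x2 joint relative-frequency table of the two binary
#' vectors over their shared (non-missing) characters,
#' `d = -(1/2) (ln det F - (1/2)(sum ln row marginals + sum ln col
#' marginals))`. Identical vectors with both states present give 0.
#' Degenerate tables -- a zero marginal or a non-positive determinant --
#' return a capped distance of `cap` with a warning, since binarized data
#' can be constant per taxon.
#'
#' @param x,y binary vectors of equal length (>= 4 shared characters),
#'   `NA` allowed for missing.
#' @param cap value returned for degenerate tables (default 10).
#' @return non-negative distance.
#' @examples
#' logdetDistance(c(1, 1, 1, 1, 0, 0, 0, 0),
#'                c(1, 1, 1, 0, 0, 0, 0, 1))   # -(1/2) ln(0.5)
#' @export
logdetDistance <- function(x, y, cap = 10) {
  if (length(x) != length(y)) stop("length mismatch")
  r <- .logdetPair(x, y, cap)
  if (r$capped)
    warning("degenerate joint frequency table; returning capped distance")
  r$d
}

# all-pairs Log-Det distances between the columns (taxa) of a binary matrix
.logdetMatrix <- function(bin, cap = 10) {
  k <- ncol(bin)
  D <- matrix(0, k, k, dimnames = list(colnames(bin), colnames(bin)))
  degenerate <- FALSE
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r <- .logdetPair(bin[, i], bin[, j], cap)
      if (r$degenerate) degenerate <- TRUE
      D[i, j] <- D[j, i] <- r$d
    }
  }
  attr(D, "degenerate") <- degenerate
  D
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration with cluster-size weighting (the standard
#' UPGMA), with deterministic tie-breaking by lexicographic label order.
#' The returned tree is ultrametric.
#'
#' @param D symmetric distance matrix with zero diagonal and labels.
#' @return a [CellTypeTree-class] (supports empty).
#' @export
upgmaTree <- function(D) {
  D <- as.matrix(D)
  if (anyNA(D)) stop("NaN/NA distances not allowed")
  ord <- order(rownames(D))
  D <- D[ord, ord]
  hc <- hclust(as.dist(D), method = "average")
  tree <- ape::as.phylo(hc)
  new("CellTypeTree", tree = tree, supports = numeric(),
      distances = D)
}

#' Felsenstein bootstrap supports for a binarized cell-type tree
#'
#' Characters (genes; matrix rows) are resampled with replacement
#' `nReps` times; each replicate's Log-Det + UPGMA tree votes for the
#' bipartitions of the full-data tree. Replicates producing a degenerate
#' distance table are skipped and counted; supports are percentages of the
#' completed replicates.
#'
#' @param bin genes x cell-types binary matrix (>= 10 characters).
#' @param nReps bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param cap degenerate-distance cap forwarded to the distance step.
#' @return a [CellTypeTree-class]; `@supports` holds one percentage per
#'   internal node (ordered as ape node ids), also written into the tree's
#'   `node.label`. The attribute `"completed"` records usable replicates.
#' @export
felsensteinBootstrap <- function(bin, nReps = 1000L, seed = 1L, cap = 10) {
  if (nrow(bin) < 10L) stop("at least 10 characters required")
  D <- .logdetMatrix(bin, cap)
  main <- upgmaTree(D)
  set.seed(seed)
  reps <- vector("list", nReps)
  skipped <- 0L
  for (r in seq_len(nReps)) {
    rows <- sample(nrow(bin), nrow(bin), replace = TRUE)
    Dr <- .logdetMatrix(bin[rows, , drop = FALSE], cap)
    if (attr(Dr, "degenerate")) { skipped <- skipped + 1L; next }
    reps[[r]] <- upgmaTree(Dr)@tree
  }
  reps <- reps[!vapply(reps, is.null, logical(1))]
  if (skipped) message(skipped, " bootstrap replicate(s) skipped (degenerate distances)")
  if (!length(reps)) stop("all bootstrap replicates degenerate")
  counts <- ape::prop.clades(main@tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  supports <- 100 * counts / length(reps)
  tree <- main@tree
  tree$node.label <- round(supports, 1)
  out <- new("CellTypeTree", tree = tree,
             supports = setNames(supports, seq_along(supports) +
                                 length(tree$tip.label)),
             distances = D)
  attr(out@tree, "completed") <- length(reps)
  out
}

#' Export a similarity matrix as an edge list
#'
#' A plain data.frame of cell-type pairs and similarities, convenient for
#' graph tools; `NA` (undefined) entries are omitted.
#'
#' @param sim a [CellTypeSimilarity-class].
#' @param minSimilarity keep edges at or above this value (default -1,
#'   i.e. all defined edges).
#' @return data.frame with columns `celltypeA`, `celltypeB`, `similarity`.
#' @export
similarityEdges <- function(sim, minSimilarity = -1) {
  stopifnot(is(sim, "CellTypeSimilarity"))
  m <- sim@similarity
  idx <- which(!is.na(m) & m >= minSimilarity, arr.ind = TRUE)
  data.frame(celltypeA = rownames(m)[idx[, 1]],
             celltypeB = colnames(m)[idx[, 2]],
             similarity = m[idx])
}
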