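# Iterative comparison of co-expression (ICC).
#
# Cross-species expression comparison without matching cell states: each
# gene is represented by its within-species co-expression profile (its
# correlation with every other matched gene), a representation that is
# comparable across species even when the two atlases have different
# numbers of metacells. The correlation between the two species' profiles
# of an ortholog pair is its expression-conservation (EC) score; iterating
# with EC as weights focuses the comparison on the pairs that are already
# conserved.

#' Within-species co-expression profile matrix
#'
#' Pairwise Pearson correlations of genes across the metacells of one
#' species, computed on log-transformed fold changes. Undefined entries
#' (zero-variance genes) are set to 0; the diagonal is 1.
#'
#' @param expr a [MetacellExpression-class] with at least 3 metacells.
#' @param geneSubset ordered gene labels to use (all must be present).
#' @return an n x n correlation matrix ordered as `geneSubset` (duplicated
#'   labels allowed; rows repeat accordingly).
#' @export
coexpressionProfiles <- function(expr, geneSubset = rownames(fcMatrix(expr))) {
  stopifnot(is(expr, "MetacellExpression"))
  fc <- expr@fc
  if (ncol(fc) < 3L) stop("at least 3 metacells required")
  miss <- setdiff(unique(geneSubset), rownames(fc))
  if (length(miss)) stop("genes not present: ", paste(head(miss), collapse = ", "))
  uniq <- unique(geneSubset)
  X <- t(log(fc[uniq, , drop = FALSE]))
  C <- suppressWarnings(cor(X))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  C[geneSubset, geneSubset, drop = FALSE]
}

# Row-wise weighted Pearson between matched rows of A and B; NA -> 0 and
# negatives clamped to 0 happen in the caller.
.rowWeightedCor <- function(A, B, w) {
  sw <- sum(w)
  am <- as.vector(A %*% w) / sw
  bm <- as.vector(B %*% w) / sw
  Ac <- A - am
  Bc <- B - bm
  num <- as.vector((Ac * Bc) %*% w)
  va <- as.vector((Ac * Ac) %*% w)
  vb <- as.vector((Bc * Bc) %*% w)
  r <- num / sqrt(va * vb)
  r[va <= 0 | vb <= 0] <- NA_real_
  pmin(1, pmax(-1, r))
}

# ICC iteration on two pre-matched profile matrices (rows = pairs).
# forceZero marks pairs with a zero-variance (constant) gene on either
# side: their co-expression profile is undefined, so EC stays 0 at every
# iteration.
.iccIterate <- function(Pa, Pb, maxIterations, tol,
                        forceZero = rep(FALSE, nrow(Pa))) {
  n <- nrow(Pa)
  ec <- .rowWeightedCor(Pa, Pb, rep(1, n))
  ec[is.na(ec)] <- 0
  ec <- pmax(ec, 0)
  ec[forceZero] <- 0
  iter <- 0L
  converged <- FALSE
  while (iter < maxIterations) {
    if (sum(ec) <= 0) { converged <- TRUE; break }  # nothing left to weight
    newEc <- .rowWeightedCor(Pa, Pb, ec)
    newEc[is.na(newEc)] <- 0
    newEc <- pmax(newEc, 0)
    newEc[forceZero] <- 0
    iter <- iter + 1L
    delta <- sum((newEc - ec)^2)
    ec <- newEc
    if (delta < tol) { converged <- TRUE; break }
  }
  list(ec = ec, iterations = iter, converged = converged)
}

# genes with no variance on the ln(FC) scale (their correlation profile
# is undefined)
.zeroVarGenes <- function(expr, genes) {
  X <- log(fcMatrix(expr)[unique(genes), , drop = FALSE])
  zv <- rownames(X)[apply(X, 1L, function(v) sd(v) == 0)]
  genes %in% zv
}

#' Expression-conservation scores by iterative comparison of co-expression
#'
#' Computes EC weights for one-to-one ortholog pairs between two species.
#' Iteration 0 correlates the two species' co-expression profiles for each
#' pair (rows matched by orthology) and clamps negatives to 0; every
#' subsequent iteration recomputes the between-species correlation as a
#' weighted Pearson over the n gene-pair dimensions, using the previous EC
#' vector as weights. Iteration stops when
#' `sum((EC_i - EC_{i-1})^2) < tol` or at `maxIterations`. The result is
#' symmetric under swapping species.
#'
#' @param exprA,exprB [MetacellExpression-class] objects for the two
#'   species.
#' @param one2one a [HomologyMap-class]; only its `one2one` pairs are
#'   used (at least 3 required). Genes absent from either atlas are an
#'   error.
#' @param maxIterations iteration cap (default 20).
#' @param tol convergence threshold on the squared EC change (default
#'   0.05; must be > 0).
#' @return an [ECWeights-class].
#' @export
computeEC <- function(exprA, exprB, one2one, maxIterations = 20L,
                      tol = 0.05) {
  stopifnot(is(exprA, "MetacellExpression"), is(exprB, "MetacellExpression"),
            is(one2one, "HomologyMap"))
  if (tol <= 0) stop("tol must be > 0")
  p <- one2one@pairs
  p <- p[p$relation == "one2one", , drop = FALSE]
  if (nrow(p) < 3L) stop("at least 3 one-to-one ortholog pairs required")
  missA <- setdiff(p$geneA, rownames(exprA@fc))
  missB <- setdiff(p$geneB, rownames(exprB@fc))
  if (length(missA) || length(missB))
    stop("unmatched genes in homology map: ",
         paste(head(c(missA, missB)), collapse = ", "))
  Pa <- coexpressionProfiles(exprA, p$geneA)
  Pb <- coexpressionProfiles(exprB, p$geneB)
  forceZero <- .zeroVarGenes(exprA, p$geneA) | .zeroVarGenes(exprB, p$geneB)
  res <- .iccIterate(Pa, Pb, maxIterations, tol, forceZero)
  new("ECWeights", pairs = p[, c("geneA", "geneB")], ec = res$ec,
      iterations = res$iterations, converged = res$converged)
}

#' Resolve paralog sets to their most expression-conserved pair
#'
#' For each set of candidate paralog pairs, the candidates are appended to
#' a reference panel of randomly chosen one-to-one ortholog pairs
#' (duplicating gene rows as needed so every candidate has its own row),
#' EC is recomputed to convergence on the extended panel, and the candidate
#' with the highest EC is retained. Ties break by lexicographic
#' `(geneA, geneB)` order.
#'
#' @param exprA,exprB [MetacellExpression-class] objects.
#' @param homology a [HomologyMap-class] with one2one pairs and
#'   candidate_paralog pairs grouped by `setId`.
#' @param nReference size of the random one-to-one reference panel
#'   (default 1000; capped at availability).
#' @param seed integer seed for the panel draw.
#' @param maxIterations,tol ICC controls, as in [computeEC()].
#' @return a [HomologyMap-class] of resolved pairs (relation
#'   `"one2one"`), one per paralog set, with the winning EC in an `ec`
#'   column of `homologyPairs()`.
#' @export
selectBestParalogs <- function(exprA, exprB, homology, nReference = 1000L,
                               seed = 1L, maxIterations = 20L, tol = 0.05) {
  stopifnot(is(homology, "HomologyMap"))
  p <- homology@pairs
  o2o <- p[p$relation == "one2one", , drop = FALSE]
  par <- p[p$relation == "candidate_paralog", , drop = FALSE]
  if (!nrow(o2o)) stop("empty reference panel: no one-to-one pairs")
  if (!nrow(par)) return(HomologyMap(o2o[0, ]))
  set.seed(seed)
  refIdx <- sample(nrow(o2o), min(nReference, nrow(o2o)))
  ref <- o2o[refIdx, , drop = FALSE]
  # one master profile-correlation per species over all genes involved
  genesA <- unique(c(ref$geneA, par$geneA))
  genesB <- unique(c(ref$geneB, par$geneB))
  Ca <- coexpressionProfiles(exprA, genesA)
  Cb <- coexpressionProfiles(exprB, genesB)
  out <- lapply(split(par, par$setId), function(set) {
    a <- c(ref$geneA, set$geneA)
    b <- c(ref$geneB, set$geneB)
    fz <- .zeroVarGenes(exprA, a) | .zeroVarGenes(exprB, b)
    res <- .iccIterate(Ca[a, a, drop = FALSE], Cb[b, b, drop = FALSE],
                       maxIterations, tol, fz)
    k <- nrow(set)
    candEc <- res$ec[(length(a) - k + 1):length(a)]
    ord <- order(-candEc, set$geneA, set$geneB)
    win <- set[ord[1L], , drop = FALSE]
    win$relation <- "one2one"
    win$ec <- candEc[ord[1L]]
    win
  })
  resolved <- do.call(rbind, out)
  resolved <- resolved[order(resolved$setId), , drop = FALSE]
  HomologyMap(resolved)
}
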