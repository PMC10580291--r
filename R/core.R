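# Numeric primitives shared by every downstream stage.

#' Metacell fold changes from UMI counts
#'
#' Summarizes per-cell UMI counts into metacell-level normalized expression:
#' cells are scaled to a common library size, a regularized geometric mean
#' `E(g,m) = exp(mean over cells of ln(u' + epsilon))` is taken within each
#' metacell, and each gene is normalized by its median across metacells.
#' The regularization pseudocount is retained in both numerator and
#' denominator, which keeps every fold change finite and strictly positive.
#'
#' @param umi a [UmiMatrix-class].
#' @param assignment named character cell -> metacell; defaults to the
#'   assignment stored in `umi`. Every retained cell must be assigned.
#' @param epsilon positive regularization pseudocount (default 1).
#' @param librarySize common per-cell scaling target (default 10000).
#' @param species species label for the result.
#' @param metacellToCelltype optional metacell -> cell-type map.
#' @return a [MetacellExpression-class]. Genes whose unregularized
#'   geometric-mean median is zero in every metacell would be flagged in
#'   the `"flagged"` attribute of the FC matrix (with FC set to 1); under
#'   the regularized form this cannot occur for valid input.
#' @examples
#' cnt <- matrix(c(4, 1, 4, 1, 0, 1, 0, 1), 2, 4,
#'               dimnames = list(c("g1", "g2"), paste0("c", 1:4)))
#' u <- UmiMatrix(cnt, setNames(c("m1", "m1", "m2", "m2"), paste0("c", 1:4)))
#' fcMatrix(fcFromUmi(u, epsilon = 1, librarySize = 4))
#' @export
fcFromUmi <- function(umi, assignment = NULL, epsilon = 1,
                      librarySize = 1e4, species = "species",
                      metacellToCelltype = NULL) {
  stopifnot(is(umi, "UmiMatrix"), epsilon > 0)
  cnt <- umi@counts
  if (is.null(assignment)) assignment <- umi@cellToMetacell
  if (!length(assignment)) stop("no cell-to-metacell assignment available")
  cells <- intersect(colnames(cnt), names(assignment))
  if (!length(cells)) stop("no assigned cells present in the matrix")
  cnt <- cnt[, cells, drop = FALSE]
  assignment <- assignment[cells]
  mcs <- sort(unique(assignment))
  if (length(mcs) < 2L) stop("at least 2 metacells required")
  ls <- colSums(cnt)
  if (any(ls == 0)) stop("retained cells must have positive library size")
  up <- sweep(cnt, 2L, librarySize / ls, "*")
  E <- vapply(mcs, function(m) {
    sub <- up[, assignment == m, drop = FALSE]
    if (ncol(sub) == 0L) stop("metacell with 0 cells: ", m)
    exp(rowMeans(log(sub + epsilon)))
  }, numeric(nrow(cnt)))
  dimnames(E) <- list(rownames(cnt), mcs)
  med <- apply(E, 1L, median)
  flagged <- med <= 0          # unreachable for E >= epsilon; kept defensively
  fc <- E / med
  if (any(flagged)) {
    warning(sum(flagged), " gene(s) with zero median flagged; fc set to 1")
    fc[flagged, ] <- 1
  }
  out <- MetacellExpression(species, fc,
                            metacellToCelltype = metacellToCelltype)
  attr(out@fc, "flagged") <- rownames(cnt)[flagged]
  out
}

#' Quantile-normalize two vectors against each other
#'
#' Both outputs share the same sorted values -- the mean of the two sorted
#' inputs -- while each keeps its own rank order. Tied values within an
#' input receive the average of the target values over the tied block.
#'
#' @param a,b numeric vectors of equal length, no missing values.
#' @return a list with elements `a` and `b`, the normalized vectors in the
#'   original input orders.
#' @examples
#' quantileNormalize(c(1, 2, 3), c(2, 4, 6))   # both -> 1.5, 3, 4.5
#' @export
quantileNormalize <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (anyNA(a) || anyNA(b)) stop("missing values not allowed")
  target <- (sort(a) + sort(b)) / 2
  remap <- function(x) {
    out <- numeric(length(x))
    out[order(x)] <- target
    ave(out, factor(x), FUN = mean)
  }
  list(a = remap(a), b = remap(b))
}

#' Weighted Pearson correlation
#'
#' `r = sum(w (x - xw)(y - yw)) / sqrt(sum(w (x - xw)^2) sum(w (y - yw)^2))`
#' with weighted means `xw`, `yw`. When either weighted variance is zero
#' the correlation is undefined and `NA` is returned (consumers state how
#' they treat it; most map it to 0).
#'
#' @param x,y numeric vectors of equal length.
#' @param w non-negative weights, sum > 0.
#' @return correlation in \[-1,1\], or `NA` if undefined.
#' @examples
#' weightedPearson(c(1, 2, 4), c(1, 3, 2), c(1, 2, 1))
#' @export
weightedPearson <- function(x, y, w = rep(1, length(x))) {
  n <- length(x)
  if (length(y) != n || length(w) != n) stop("length mismatch")
  if (any(w < 0)) stop("weights must be non-negative")
  sw <- sum(w)
  if (sw <= 0) stop("sum of weights must be > 0")
  xw <- sum(w * x) / sw
  yw <- sum(w * y) / sw
  vx <- sum(w * (x - xw)^2)
  vy <- sum(w * (y - yw)^2)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  r <- sum(w * (x - xw) * (y - yw)) / sqrt(vx * vy)
  min(1, max(-1, r))
}

#' Aggregate metacell fold changes to cell-type level
#'
#' Geometric mean of the metacell FC values within each cell type,
#' renormalized by the per-gene median across cell types so the result is
#' again a fold-change table.
#'
#' @param expr a [MetacellExpression-class].
#' @param renormalize divide by the per-gene median across cell types
#'   (default TRUE).
#' @return genes x cell-types numeric matrix.
#' @export
celltypeFc <- function(expr, renormalize = TRUE) {
  stopifnot(is(expr, "MetacellExpression"))
  fc <- expr@fc
  ct <- expr@metacellToCelltype[colnames(fc)]
  types <- sort(unique(ct))
  out <- vapply(types, function(tt)
    exp(rowMeans(log(fc[, ct == tt, drop = FALSE]))), numeric(nrow(fc)))
  dimnames(out) <- list(rownames(fc), types)
  if (renormalize && length(types) > 1L) {
    med <- apply(out, 1L, median)
    med[med <= 0] <- 1
    out <- out / med
  }
  out
}
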