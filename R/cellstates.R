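# Statistics on intermediate, doublet, cycling and low-quality cell
# populations.

#' AUC recovery score of a gene set per metacell
#'
#' Genes are ranked per metacell by fold change (descending; ties by gene
#' label). The score is the area under the step curve of cumulative
#' gene-set recovery over the top `k = ceil(topFraction * n)` ranks,
#' normalized by the maximum achievable area for that set size and `k`:
#' a set occupying the very top ranks scores 1, a set entirely below
#' rank `k` scores 0.
#'
#' @param expr a [MetacellExpression-class].
#' @param geneSet a [MarkerSet-class] or character vector of genes
#'   (subset of the atlas genes; nonempty).
#' @param topFraction fraction of top-ranked genes considered (default
#'   0.05, in (0,1\]).
#' @return named numeric in \[0,1\], one score per metacell.
#' @export
aucScores <- function(expr, geneSet, topFraction = 0.05) {
  stopifnot(is(expr, "MetacellExpression"),
            topFraction > 0, topFraction <= 1)
  genes <- if (is(geneSet, "MarkerSet")) geneSet@genes else geneSet
  if (!length(genes)) stop("empty gene set")
  fc <- expr@fc
  miss <- setdiff(genes, rownames(fc))
  if (length(miss)) stop("gene set not in atlas: ", paste(head(miss), collapse = ", "))
  n <- nrow(fc)
  k <- ceiling(topFraction * n)
  s <- length(genes)
  maxArea <- if (s >= k) k * (k + 1) / 2 else s * k - s * (s - 1) / 2
  apply(fc, 2L, function(col) {
    ord <- order(-col, rownames(fc))
    inSet <- rownames(fc)[ord] %in% genes
    sum(cumsum(inSet)[seq_len(k)]) / maxArea
  })
}

#' Classify intermediate cells from dual marker-program load
#'
#' A cell is called intermediate between cell types A and B when the
#' fraction of its total UMIs falling in each type's marker set reaches
#' the respective threshold. Genes shared by both marker sets are excluded
#' from both (with a warning). When thresholds are not supplied they
#' default to the 10th percentile of the terminal cells' own-marker
#' fractions.
#'
#' @param umi a [UmiMatrix-class].
#' @param markersA,markersB [MarkerSet-class] objects of the two terminal
#'   cell types.
#' @param cellTypes named character, per-cell cell-type annotation (used
#'   for the default thresholds; cells of type `markersA@celltype` /
#'   `markersB@celltype` are the terminals).
#' @param tauA,tauB UMI-fraction thresholds in (0,1); `NULL` (default)
#'   derives them from the terminal cells.
#' @param percentile percentile of terminal own-marker fractions used for
#'   the defaults (default 0.10).
#' @return data.frame with per-cell columns `cell`, `fracA`, `fracB`,
#'   `intermediate` (logical) and the thresholds as attributes `tauA`,
#'   `tauB`.
#' @export
classifyIntermediates <- function(umi, markersA, markersB, cellTypes = NULL,
                                  tauA = NULL, tauB = NULL,
                                  percentile = 0.10) {
  stopifnot(is(umi, "UmiMatrix"), is(markersA, "MarkerSet"),
            is(markersB, "MarkerSet"))
  cnt <- umi@counts
  gA <- intersect(markersA@genes, rownames(cnt))
  gB <- intersect(markersB@genes, rownames(cnt))
  ov <- intersect(gA, gB)
  if (length(ov)) {
    warning(length(ov), " overlapping marker gene(s) excluded from both sets")
    gA <- setdiff(gA, ov); gB <- setdiff(gB, ov)
  }
  if (!length(gA) || !length(gB)) stop("marker set empty after overlap removal")
  tot <- colSums(cnt)
  fracA <- colSums(cnt[gA, , drop = FALSE]) / tot
  fracB <- colSums(cnt[gB, , drop = FALSE]) / tot
  if (is.null(tauA) || is.null(tauB)) {
    if (is.null(cellTypes))
      stop("cellTypes required to derive default thresholds")
    termA <- names(cellTypes)[!is.na(cellTypes) &
                              cellTypes == markersA@celltype]
    termB <- names(cellTypes)[!is.na(cellTypes) &
                              cellTypes == markersB@celltype]
    if (!length(termA) || !length(termB))
      stop("no terminal cells found for default thresholds")
    if (is.null(tauA)) tauA <- quantile(fracA[termA], percentile, names = FALSE)
    if (is.null(tauB)) tauB <- quantile(fracB[termB], percentile, names = FALSE)
  }
  stopifnot(tauA > 0, tauA < 1, tauB > 0, tauB < 1)
  out <- data.frame(cell = colnames(cnt), fracA = fracA, fracB = fracB,
                    intermediate = fracA >= tauA & fracB >= tauB,
                    row.names = NULL)
  attr(out, "tauA") <- tauA
  attr(out, "tauB") <- tauB
  out
}

# exact two-tailed binomial probability by minimum-likelihood summation
.binomTwoSided <- function(k, n, p0) {
  pmfK <- dbinom(k, n, p0)
  pmf <- dbinom(0:n, n, p0)
  # the conventional relative tolerance guards against ties lost to
  # floating-point rounding
  p <- sum(pmf[pmf <= pmfK * (1 + 1e-7)])
  min(1, max(p, .Machine$double.xmin))
}

#' Exact two-tailed binomial test for doublet origin of intermediates
#'
#' Tests whether the observed number of intermediate cells differs from
#' the number of doublets expected from stochastic co-encapsulation of the
#' two terminal cell types, with null probability `p0 = f1 * f2` (the
#' product of the terminal-type fractions). Two-sidedness follows the
#' minimum-likelihood convention: all outcomes with point probability at
#' most that of `k` are summed.
#'
#' @param kIntermediate observed intermediate cell count (0 <= k <= n).
#' @param nTotal total cells.
#' @param f1,f2 terminal cell-type fractions in (0,1).
#' @param doubled multiply the null probability by 2 to count unordered
#'   collisions (default FALSE, matching the product-only null).
#' @return two-sided p-value in (0,1\].
#' @export
doubletBinomialTest <- function(kIntermediate, nTotal, f1, f2,
                                doubled = FALSE) {
  stopifnot(kIntermediate >= 0, kIntermediate <= nTotal,
            f1 > 0, f1 < 1, f2 > 0, f2 < 1)
  p0 <- f1 * f2 * if (doubled) 2 else 1
  if (p0 >= 1) stop("null probability must be < 1")
  .binomTwoSided(kIntermediate, nTotal, p0)
}

#' One-tailed test of marker conservation in intermediate cell types
#'
#' Tests whether intermediate cell types share fewer markers across
#' species than their terminal cell types do: `P(X <= kInt)` with
#' `X ~ Binomial(nInt, kTerm / nTerm)`. A small p-value indicates that
#' intermediate markers are less conserved than terminal markers.
#'
#' @param kInt shared intermediate markers across species.
#' @param nInt total intermediate markers.
#' @param kTerm,nTerm shared / total terminal markers (the reference
#'   rate; `nTerm` > 0).
#' @return lower-tail p-value.
#' @export
markerConservationTest <- function(kInt, nInt, kTerm, nTerm) {
  if (nTerm <= 0) stop("nTerm must be > 0")
  stopifnot(kInt >= 0, kInt <= nInt, kTerm >= 0, kTerm <= nTerm)
  pbinom(kInt, nInt, kTerm / nTerm)
}

#' Call cycling cells from cell-cycle gene load
#'
#' The per-cell fraction of UMIs in the cell-cycle gene set is
#' log10-transformed (with a pseudocount) and z-standardized; a cell is
#' called cycling when its z-score reaches the standard-normal quantile
#' of `quantileCut` (1.6449 at 0.95). If all cells have identical load
#' (zero standard deviation) no cell is called.
#'
#' @param umi a [UmiMatrix-class].
#' @param cycleGenes a [MarkerSet-class] or character vector of
#'   cell-cycle genes (nonempty).
#' @param quantileCut standard-normal quantile in (0.5, 1) (default 0.95).
#' @param pseudo pseudocount added to the UMI fraction before log10
#'   (default 1e-4).
#' @param useFraction standardize the UMI fraction (default TRUE) rather
#'   than the raw in-set UMI count.
#' @return named logical per cell.
#' @export
callCyclingCells <- function(umi, cycleGenes, quantileCut = 0.95,
                             pseudo = 1e-4, useFraction = TRUE) {
  stopifnot(is(umi, "UmiMatrix"), quantileCut > 0.5, quantileCut < 1)
  genes <- if (is(cycleGenes, "MarkerSet")) cycleGenes@genes else cycleGenes
  if (!length(genes)) stop("empty cell-cycle gene set")
  cnt <- umi@counts
  genes <- intersect(genes, rownames(cnt))
  if (!length(genes)) stop("cell-cycle genes absent from matrix")
  load <- colSums(cnt[genes, , drop = FALSE])
  if (useFraction) load <- load / colSums(cnt)
  x <- log10(load + pseudo)
  s <- sd(x)
  if (s == 0) return(setNames(rep(FALSE, ncol(cnt)), colnames(cnt)))
  z <- (x - mean(x)) / s
  setNames(z >= qnorm(quantileCut), colnames(cnt))
}

#' Quality filtering of metacells
#'
#' Drops metacells failing any of: z-score of log10 total UMIs below the
#' 0.01 standard-normal quantile; z-score of log10 median UMIs per cell
#' below the same; fewer than 10 marker genes at FC >= 1.5; no
#' transcription-factor marker at FC >= 1.5. Reasons are recorded per
#' metacell.
#'
#' @param stats data.frame with one row per metacell and columns
#'   `metacell`, `totalUmi`, `medianUmiPerCell`, `nMarkers`,
#'   `nTfMarkers`.
#' @param minMarkers marker-count floor (default 10).
#' @param zQuantile lower standard-normal quantile for the UMI screens
#'   (default 0.01).
#' @return the input with added logical `keep` and character `reasons`
#'   (`";"`-separated, empty when kept).
#' @export
filterMetacells <- function(stats, minMarkers = 10L, zQuantile = 0.01) {
  need <- c("metacell", "totalUmi", "medianUmiPerCell", "nMarkers",
            "nTfMarkers")
  stopifnot(all(need %in% colnames(stats)))
  zcut <- qnorm(zQuantile)
  zOf <- function(v) {
    x <- log10(v)
    s <- sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  zTot <- zOf(stats$totalUmi)
  zMed <- zOf(stats$medianUmiPerCell)
  reasons <- lapply(seq_len(nrow(stats)), function(i) {
    r <- character()
    if (zTot[i] < zcut) r <- c(r, "low_total_umi")
    if (zMed[i] < zcut) r <- c(r, "low_median_umi")
    if (stats$nMarkers[i] < minMarkers) r <- c(r, "markers")
    if (stats$nTfMarkers[i] == 0) r <- c(r, "no_tf")
    r
  })
  stats$keep <- lengths(reasons) == 0L
  stats$reasons <- vapply(reasons, paste, character(1), collapse = ";")
  stats
}
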