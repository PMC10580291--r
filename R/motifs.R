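# Downstream motif processing: information-content filtering, similarity
# clustering into archetypes, scan-threshold calibration, enrichment.

#' Information-content profile of a motif
#'
#' Per-position IC in bits against a uniform background:
#' `IC(pos) = 2 + sum_b p_b log2 p_b` with `0 log 0 = 0`; ranges over
#' \[0, 2\].
#'
#' @param ppm a [MotifPPM-class] or a positions x 4 probability matrix.
#' @return numeric vector of per-position IC values.
#' @export
icProfile <- function(ppm) {
  p <- if (is(ppm, "MotifPPM")) ppm@ppm else as.matrix(ppm)
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-6))
    stop("invalid probability matrix")
  plp <- p * log2(p)
  plp[p == 0] <- 0
  2 + rowSums(plp)
}

# runs of consecutive positions with IC >= cut, as run lengths
.icRuns <- function(ic, cut = 0.5) {
  r <- rle(ic >= cut)
  r$lengths[r$values]
}

#' Filter motifs by contiguous information content
#'
#' A motif is kept when its IC profile has one run of at least 4
#' consecutive positions with IC >= 0.5, or two or more disjoint runs of
#' at least 3 such positions.
#'
#' @param ppms list of [MotifPPM-class].
#' @param icCut IC floor per position (default 0.5).
#' @return the retained sublist.
#' @export
filterMotifs <- function(ppms, icCut = 0.5) {
  keep <- vapply(ppms, function(m) {
    runs <- .icRuns(icProfile(m), icCut)
    any(runs >= 4L) || sum(runs >= 3L) >= 2L
  }, logical(1))
  ppms[keep]
}

# reverse complement of a PPM: reverse positions, swap A<->T, C<->G
.revcompPpm <- function(p) {
  out <- p[rev(seq_len(nrow(p))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(out) <- c("A", "C", "G", "T")
  out
}

# IC-weighted matrix: each row scaled by its information content
.icWeighted <- function(p) p * icProfile(p)

#' Best alignment similarity between two motifs
#'
#' Slides one motif along the other over all ungapped offsets with at
#' least `minOverlap` overlapping positions, on both strands (the reverse
#' complement swaps complementary columns and reverses positions), and
#' returns the maximum Pearson correlation of the flattened IC-weighted
#' probability matrices over the overlap, with the achieving offset and
#' strand.
#'
#' @param a,b [MotifPPM-class] objects, both at least `minOverlap` long.
#' @param minOverlap minimum overlapping positions (default 6).
#' @return list with `score` in \[-1,1\], `offset` (start of `b` relative
#'   to start of `a`; may be negative) and `strand` (`"+"`/`"-"`).
#' @export
motifSimilarity <- function(a, b, minOverlap = 6L) {
  pa <- if (is(a, "MotifPPM")) a@ppm else a
  pb <- if (is(b, "MotifPPM")) b@ppm else b
  la <- nrow(pa); lb <- nrow(pb)
  if (la < minOverlap || lb < minOverlap)
    stop("no admissible offset: motifs shorter than the minimum overlap")
  wa <- .icWeighted(pa)
  best <- list(score = -Inf, offset = NA_integer_, strand = NA_character_)
  for (strand in c("+", "-")) {
    qb <- if (strand == "+") pb else .revcompPpm(pb)
    wb <- .icWeighted(qb)
    for (off in seq(-(lb - minOverlap), la - minOverlap)) {
      ia <- max(1L, 1L + off):min(la, lb + off)
      ib <- ia - off
      if (length(ia) < minOverlap) next
      va <- as.vector(wa[ia, , drop = FALSE])
      vb <- as.vector(wb[ib, , drop = FALSE])
      r <- suppressWarnings(cor(va, vb))
      if (!is.finite(r)) next
      if (r > best$score)
        best <- list(score = r, offset = as.integer(off), strand = strand)
    }
  }
  if (!is.finite(best$score)) stop("no admissible offset")
  best
}

#' Cluster motifs into archetypes
#'
#' Average-linkage hierarchical clustering on `1 - similarity`, cut at
#' `1 - similarityThreshold`. Each cluster's members are aligned to the
#' cluster seed (longest member; ties by name) at their pairwise best
#' offset and strand, and the archetype is the position-wise mean of the
#' aligned member PPMs over positions covered by at least one member,
#' rows renormalized.
#'
#' @param ppms list of [MotifPPM-class] (typically pre-filtered with
#'   [filterMotifs()]).
#' @param similarityThreshold cluster cut (default 0.80).
#' @param minOverlap forwarded to [motifSimilarity()].
#' @return list of [MotifArchetype-class].
#' @export
clusterMotifs <- function(ppms, similarityThreshold = 0.80, minOverlap = 6L) {
  n <- length(ppms)
  if (!n) return(list())
  names(ppms) <- vapply(ppms, function(m) m@name, character(1))
  if (n == 1L) return(list(.buildArchetype(ppms, minOverlap)))
  S <- matrix(1, n, n, dimnames = list(names(ppms), names(ppms)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      S[i, j] <- S[j, i] <- motifSimilarity(ppms[[i]], ppms[[j]],
                                            minOverlap)$score
    }
  }
  hc <- hclust(as.dist(1 - S), method = "average")
  cl <- cutree(hc, h = 1 - similarityThreshold)
  lapply(split(names(ppms), cl), function(members)
    .buildArchetype(ppms[members], minOverlap))
}

# align members to the seed and average the PPMs position-wise
.buildArchetype <- function(members, minOverlap = 6L) {
  lens <- vapply(members, function(m) nrow(m@ppm), integer(1))
  ord <- order(-lens, names(members))
  seed <- members[[ord[1]]]
  offs <- integer(length(members)); strands <- character(length(members))
  names(offs) <- names(strands) <- names(members)
  offs[seed@name] <- 0L; strands[seed@name] <- "+"
  aligned <- list()
  aligned[[seed@name]] <- seed@ppm
  for (nm in setdiff(names(members), seed@name)) {
    al <- motifSimilarity(seed, members[[nm]], minOverlap)
    p <- if (al$strand == "+") members[[nm]]@ppm else
      .revcompPpm(members[[nm]]@ppm)
    offs[nm] <- al$offset; strands[nm] <- al$strand
    aligned[[nm]] <- p
  }
  lo <- min(0L, min(offs))
  hi <- max(vapply(names(aligned), function(nm)
    offs[nm] + nrow(aligned[[nm]]) - 1L, numeric(1)), nrow(seed@ppm) - 1L)
  L <- hi - lo + 1L
  acc <- matrix(0, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  cov <- numeric(L)
  for (nm in names(aligned)) {
    p <- aligned[[nm]]
    rows <- (offs[nm] - lo + 1L):(offs[nm] - lo + nrow(p))
    acc[rows, ] <- acc[rows, ] + p
    cov[rows] <- cov[rows] + 1
  }
  covered <- cov > 0
  avg <- acc[covered, , drop = FALSE] / cov[covered]
  avg <- avg / rowSums(avg)
  new("MotifArchetype", ppm = avg, members = names(aligned),
      offsets = as.integer(offs - lo), strands = strands)
}

# log-odds score matrix against a uniform background with probability floor
.logOdds <- function(ppm, floor = 1e-3) log2(pmax(ppm, floor) / 0.25)

# score every window of a sequence (character) on one strand
.scanScores <- function(scoreMat, seqChars) {
  L <- nrow(scoreMat)
  n <- length(seqChars)
  if (n < L) return(numeric(0))
  idx <- match(seqChars, c("A", "C", "G", "T"))
  vapply(seq_len(n - L + 1L), function(s) {
    cols <- idx[s:(s + L - 1L)]
    if (anyNA(cols)) return(-Inf)
    sum(scoreMat[cbind(seq_len(L), cols)])
  }, numeric(1))
}

#' Calibrate a motif scan threshold from background sequence
#'
#' Scores a deterministic (seeded) subsample of background windows with
#' the motif's log-odds matrix (uniform background, probability floor
#' 1e-3) on both strands, and returns the requested empirical percentile
#' of the score distribution as the scan cutoff.
#'
#' @param motif a [MotifPPM-class] or archetype.
#' @param background character vector of background sequences (total
#'   length at least 100x the motif length).
#' @param subsampleFraction fraction of windows scored (default 0.1).
#' @param percentile percentile of the background score distribution
#'   (default 98; 100 returns the maximum observed score).
#' @param seed integer seed for the subsample.
#' @param floor log-odds probability floor (default 1e-3).
#' @return the score cutoff, with attribute `"nScored"`.
#' @export
calibrateScanThreshold <- function(motif, background,
                                   subsampleFraction = 0.1,
                                   percentile = 98, seed = 1L,
                                   floor = 1e-3) {
  p <- motifMatrix(motif)
  L <- nrow(p)
  totalLen <- sum(nchar(background))
  if (any(nchar(background) < L)) stop("background shorter than motif")
  if (totalLen < 100 * L)
    stop("background total length must be at least 100x the motif length")
  sm <- .logOdds(p, floor)
  smRc <- .logOdds(.revcompPpm(p), floor)
  set.seed(seed)
  scores <- unlist(lapply(background, function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    nWin <- length(ch) - L + 1L
    take <- sort(sample(nWin, max(1L, round(subsampleFraction * nWin))))
    fwd <- .scanScores(sm, ch)[take]
    rev <- .scanScores(smRc, ch)[take]
    pmax(fwd, rev)
  }))
  scores <- scores[is.finite(scores)]
  out <- quantile(scores, percentile / 100, names = FALSE, type = 7)
  attr(out, "nScored") <- length(scores)
  out
}

#' Motif enrichment in foreground vs background regions
#'
#' Per motif, the enrichment fold change is the ratio of foreground to
#' background hit fractions; significance is an upper-tail hypergeometric
#' test on hit regions, and an empirical false discovery rate is computed
#' by permuting the foreground/background labels.
#'
#' @param fgHits,bgHits named integer vectors: per motif, the number of
#'   foreground / background regions with at least one hit.
#' @param nFg,nBg total foreground / background region counts (disjoint
#'   sets).
#' @param nPermutations label permutations for the empirical FDR
#'   (default 1000).
#' @param seed integer seed for the permutations.
#' @return data.frame with columns `motif`, `fgHits`, `bgHits`,
#'   `foldChange`, `p`, `fdr`, ordered by `p`. Motifs with zero
#'   background hits get an infinite fold change with the hypergeometric
#'   p as-is.
#' @export
motifEnrichment <- function(fgHits, bgHits, nFg, nBg,
                            nPermutations = 1000L, seed = 1L) {
  stopifnot(length(fgHits) == length(bgHits))
  motifs <- names(fgHits)
  k <- as.numeric(fgHits)
  K <- k + as.numeric(bgHits)          # total hit regions per motif
  N <- nFg + nBg
  fcv <- (k / nFg) / (as.numeric(bgHits) / nBg)
  p <- phyper(k - 1, K, N - K, nFg, lower.tail = FALSE)
  # permutation null: redraw the foreground hit count of each motif under
  # random label assignment and recompute the hypergeometric p
  set.seed(seed)
  m <- length(k)
  ord <- order(p)
  pSorted <- p[ord]
  exceed <- numeric(m)
  for (b in seq_len(nPermutations)) {
    kPerm <- stats::rhyper(m, K, N - K, nFg)
    pPerm <- phyper(kPerm - 1, K, N - K, nFg, lower.tail = FALSE)
    exceed <- exceed + vapply(pSorted, function(th) sum(pPerm <= th),
                              numeric(1))
  }
  obsCount <- seq_len(m)
  fdrSorted <- pmin(1, (exceed / nPermutations) / obsCount)
  fdr <- numeric(m)
  fdr[ord] <- rev(cummin(rev(fdrSorted)))   # enforce monotonicity in p
  data.frame(motif = motifs, fgHits = fgHits, bgHits = bgHits,
             foldChange = fcv, p = p, fdr = fdr,
             row.names = NULL)[order(p), ]
}
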