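# Fixture builders shared across the suite. All randomness is seeded at
# the call site.

# a MetacellExpression from a bare matrix (gene/metacell labels optional)
mkExpr <- function(m, species = "sp", celltypes = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("mc%02d", seq_len(ncol(m)))
  m2c <- if (is.null(celltypes)) setNames(colnames(m), colnames(m)) else
    setNames(celltypes, colnames(m))
  MetacellExpression(species, m, metacellToCelltype = m2c)
}

# identity one-to-one homology over shared gene labels
identityHomology <- function(genesA, genesB = genesA) {
  HomologyMap(data.frame(geneA = genesA, geneB = genesB,
                         relation = "one2one", setId = NA_character_))
}

# plain (unweighted) correlation-of-correlations oracle for iteration-0 EC
ecOracle <- function(exprA, exprB, pairs) {
  Pa <- cor(t(log(fcMatrix(exprA)[pairs$geneA, ])))
  Pb <- cor(t(log(fcMatrix(exprB)[pairs$geneB, ])))
  Pa[!is.finite(Pa)] <- 0; Pb[!is.finite(Pb)] <- 0
  diag(Pa) <- 1; diag(Pb) <- 1
  r <- vapply(seq_len(nrow(pairs)), function(i)
    suppressWarnings(cor(Pa[i, ], Pb[i, ])), numeric(1))
  r[!is.finite(r)] <- 0
  pmax(r, 0)
}

# Mann-Whitney AUROC separating two score vectors
auroc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# closed-form Log-Det oracle on two binary vectors (same stated formula,
# computed independently from raw counts)
logdetOracle <- function(x, y) {
  n <- length(x)
  f11 <- sum(x == 1 & y == 1) / n; f10 <- sum(x == 1 & y == 0) / n
  f01 <- sum(x == 0 & y == 1) / n; f00 <- sum(x == 0 & y == 0) / n
  dF <- f11 * f00 - f10 * f01
  marg <- c(f11 + f10, f01 + f00, f11 + f01, f10 + f00)
  if (any(marg == 0) || dF <= 0) return(10)
  -0.5 * (log(dF) - 0.5 * sum(log(marg)))
}

# naive O(n^3) UPGMA oracle returning a merge topology signature:
# the set of leaf-label clusters formed during agglomeration
upgmaOracleClades <- function(D) {
  labs <- rownames(D)
  clusters <- as.list(labs)
  sizes <- rep(1, length(labs))
  d <- D
  clades <- list()
  while (length(clusters) > 1L) {
    n <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (d[i, j] < best[1] - 1e-12) best <- c(d[i, j], i, j)
    i <- best[2]; j <- best[3]
    merged <- sort(c(clusters[[i]], clusters[[j]]))
    clades[[length(clades) + 1L]] <- merged
    newRow <- vapply(seq_len(n), function(k) {
      if (k %in% c(i, j)) return(NA_real_)
      (sizes[i] * d[i, k] + sizes[j] * d[j, k]) / (sizes[i] + sizes[j])
    }, numeric(1))
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newRow[keep]),
               c(newRow[keep], 0))
    clusters <- c(clusters[keep], list(merged))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
  }
  clades
}

# clades (leaf-label sets) of a rooted phylo
phyloClades <- function(tree) {
  nTip <- length(tree$tip.label)
  lapply((nTip + 1):(nTip + tree$Nnode), function(nd)
    sort(ape::extract.clade(tree, nd)$tip.label))
}

# brute-force Dollo oracle: for each candidate gain node, find the
# smallest set of loss edges (enumerated in increasing cardinality)
# reproducing the observed leaf pattern; returns the overall minimum.
dolloOracle <- function(tree, present) {
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  parent <- integer(nNode); parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  nodePath <- function(tip) {            # nodes from tip up to root
    p <- tip; out <- tip
    while (p != root) { p <- parent[p]; out <- c(out, p) }
    out
  }
  paths <- lapply(seq_len(nTip), nodePath)
  presentTips <- which(tree$tip.label %in% present)
  absentTips <- setdiff(seq_len(nTip), presentTips)
  bestLoss <- Inf; bestGain <- NA
  for (gain in seq_len(nNode)) {
    # gain must be an ancestor-or-self of every present tip
    if (!all(vapply(presentTips, function(t) gain %in% paths[[t]],
                    logical(1)))) next
    edges <- tree$edge[, 2]           # candidate loss edges (child ids)
    found <- FALSE
    for (k in 0:length(edges)) {
      if (k >= bestLoss) break
      combs <- if (k == 0) list(integer(0)) else
        utils::combn(edges, k, simplify = FALSE)
      for (lost in combs) {
        ok <- TRUE
        for (t in presentTips) {
          pth <- paths[[t]]
          if (any(lost %in% pth[seq_len(which(pth == gain))])) { ok <- FALSE; break }
        }
        if (ok) for (t in absentTips) {
          pth <- paths[[t]]
          below <- gain %in% pth
          cut <- below && any(lost %in% pth[seq_len(which(pth == gain))])
          if (below && !cut) { ok <- FALSE; break }
        }
        if (ok) {
          if (k < bestLoss) { bestLoss <- k; bestGain <- gain }
          found <- TRUE; break
        }
      }
      if (found) break
    }
  }
  list(gain = bestGain, nLosses = bestLoss)
}

# uniform random PPM of length L with one sharp column pattern
randomPpm <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- matrix(stats::rgamma(L * 4, 1), L, 4)
  p / rowSums(p)
}

# exhaustive offset/strand alignment oracle for motif similarity
motifSimOracle <- function(pa, pb, minOverlap = 6L) {
  ic <- function(p) { q <- p * log2(p); q[p == 0] <- 0; 2 + rowSums(q) }
  wt <- function(p) p * ic(p)
  rc <- function(p) {
    o <- p[rev(seq_len(nrow(p))), c(4, 3, 2, 1)]
    colnames(o) <- c("A", "C", "G", "T"); o
  }
  best <- -Inf
  for (pbv in list(pb, rc(pb))) {
    wa <- wt(pa); wb <- wt(pbv)
    for (off in -(nrow(pb)):nrow(pa)) {
      ia <- max(1, 1 + off):min(nrow(pa), nrow(pbv) + off)
      if (length(ia) < minOverlap || ia[1] > ia[length(ia)]) next
      ib <- ia - off
      if (min(ib) < 1 || max(ib) > nrow(pbv)) next
      r <- suppressWarnings(cor(as.vector(wa[ia, , drop = FALSE]),
                                as.vector(wb[ib, , drop = FALSE])))
      if (is.finite(r) && r > best) best <- r
    }
  }
  best
}

# regex oracle for neuropeptide-like signatures (overlapping + nested)
npScanOracle <- function(s) {
  ch <- strsplit(s, "")[[1]]
  hits <- list()
  for (L in 3:10) {
    pat <- sprintf("(?=([KR][KR].{%d}G[RK]))", L)
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1) next
    for (st in as.integer(m))
      hits[[length(hits) + 1L]] <- c(st + 2L, st + 1L + L)
  }
  if (!length(hits)) return(matrix(integer(), 0, 2))
  out <- unique(do.call(rbind, hits))
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}
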