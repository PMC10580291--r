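# Synthetic multi-species atlases and auxiliary inputs with planted,
# machine-readable ground truth. All generators are pure functions of
# (config, seed): no global state is consulted, and a fixed seed gives
# byte-identical output.

#' Generate a synthetic multi-species metacell atlas
#'
#' Plants a known comparative structure: conserved genes share their
#' cell-type-specific log-FC profile across species (up to Gaussian
#' metacell noise), diverged genes draw independent profiles per species,
#' module genes share a common cell-type program, and paralog sets carry
#' one designated expression-retaining member (ancestral profile plus
#' jitter) among randomized decoys. Homologous cell types carry the same
#' label in every species; metacell counts per type are drawn per species,
#' so the atlases are deliberately unmatched in size.
#'
#' @param species character vector of species ids (>= 2).
#' @param nCelltypes number of shared cell types (>= 3).
#' @param metacellsPerType integer range `c(lo, hi)` of metacells per cell
#'   type, drawn per species and type (lo >= 2).
#' @param nGenes ortholog pairs to simulate (default 400).
#' @param nModules planted co-expression modules (default 5); each module
#'   takes `moduleSize` conserved genes.
#' @param moduleSize genes per module (default 25).
#' @param conservedFraction fraction of genes with conserved profiles
#'   (default 0.5).
#' @param noiseSd per-metacell Gaussian noise on the log-FC scale
#'   (default 0.3).
#' @param moduleEffect log-FC effect of a module in its home cell type
#'   (default 3).
#' @param markersPerClade when > 0, cell types are additionally related by
#'   a planted balanced hierarchy: every clade of the cell-type tree
#'   (including singletons, excluding the root) receives this many
#'   exclusive conserved marker genes with effect `markerEffect` in its
#'   member types. The hierarchy is recorded in
#'   `truth$celltypeTree`. Default 0 (cell types unrelated).
#' @param markerEffect log-FC effect of clade markers (default 3).
#' @param nParalogSets paralog sets to plant (default 0).
#' @param paralogsPerSet candidate genes per set in the second species
#'   (default 3).
#' @param paralogJitterSd log-FC jitter of the expression-retaining
#'   member (default 0.2).
#' @param seed integer seed.
#' @return list with `atlases` (named list of
#'   [MetacellExpression-class]), `homology` (a [HomologyMap-class]
#'   between the first two species), `tree` (Newick string over the
#'   species) and `truth` (conservation class, module membership, paralog
#'   answers, cell types).
#' @export
generateAtlases <- function(species = c("spA", "spB"), nCelltypes = 6L,
                            metacellsPerType = c(3L, 5L), nGenes = 400L,
                            nModules = 5L, moduleSize = 25L,
                            conservedFraction = 0.5, noiseSd = 0.3,
                            moduleEffect = 3, markersPerClade = 0L,
                            markerEffect = 3, nParalogSets = 0L,
                            paralogsPerSet = 3L, paralogJitterSd = 0.2,
                            seed = 1L) {
  if (length(species) < 2L) stop("at least 2 species required")
  if (nCelltypes < 3L) stop("at least 3 cell types required")
  if (metacellsPerType[1] < 2L) stop("at least 2 metacells per type required")
  if (nModules * moduleSize > nGenes)
    stop("infeasible config: more module genes than genes")
  set.seed(seed)
  celltypes <- sprintf("T%02d", seq_len(nCelltypes))
  genes <- sprintf("g%04d", seq_len(nGenes))
  nCons <- round(conservedFraction * nGenes)
  consClass <- setNames(rep("diverged", nGenes), genes)
  consIdx <- sample(nGenes, nCons)
  consClass[consIdx] <- "conserved"
  # planted modules live among the conserved genes
  moduleOf <- setNames(rep(NA_character_, nGenes), genes)
  consGenes <- genes[consIdx]
  if (nModules > 0L) {
    if (nModules * moduleSize > length(consGenes))
      stop("infeasible config: more module genes than conserved genes")
    picked <- sample(consGenes, nModules * moduleSize)
    moduleOf[picked] <- rep(sprintf("PM%02d", seq_len(nModules)),
                            each = moduleSize)
  }
  # ancestral (shared) log-FC profile over cell types. Without a planted
  # hierarchy, profiles are i.i.d. across cell types; with one, profiles
  # evolve on the cell-type tree (independent Gaussian clade effects), so
  # cell-type relatedness is hierarchical as in real atlases.
  hierClades <- if (markersPerClade > 0L) .balancedClades(celltypes) else NULL
  drawProfiles <- function(n) {
    if (is.null(hierClades))
      return(matrix(rnorm(n * nCelltypes), n, nCelltypes))
    prof <- matrix(0, n, nCelltypes)
    for (cl in hierClades) {
      idx <- match(cl, celltypes)
      prof[, idx] <- prof[, idx] + rnorm(n, sd = 1 / sqrt(2))
    }
    prof
  }
  ancestral <- drawProfiles(nGenes)
  dimnames(ancestral) <- list(genes, celltypes)
  if (nModules > 0L) {
    homeCt <- sample(nCelltypes, nModules, replace = nModules > nCelltypes)
    for (j in seq_len(nModules)) {
      mg <- names(moduleOf)[!is.na(moduleOf) &
                            moduleOf == sprintf("PM%02d", j)]
      prof <- rep(0, nCelltypes)
      prof[homeCt[j]] <- moduleEffect
      ancestral[mg, ] <- matrix(prof, length(mg), nCelltypes, byrow = TRUE) +
        matrix(rnorm(length(mg) * nCelltypes, sd = 0.2),
               length(mg), nCelltypes)
    }
  }
  # planted cell-type hierarchy: exclusive markers per clade
  celltypeTree <- NULL
  cladeMarkers <- list()
  if (markersPerClade > 0L) {
    clades <- .balancedClades(celltypes)
    free <- setdiff(consGenes, names(moduleOf)[!is.na(moduleOf)])
    need <- markersPerClade * length(clades)
    if (length(free) < need)
      stop("infeasible config: not enough conserved genes for clade markers")
    pool <- sample(free, need)
    for (k in seq_along(clades)) {
      mg <- pool[((k - 1) * markersPerClade + 1):(k * markersPerClade)]
      prof <- rep(0, nCelltypes)
      prof[match(clades[[k]], celltypes)] <- markerEffect
      ancestral[mg, ] <- matrix(prof, length(mg), nCelltypes, byrow = TRUE) +
        matrix(rnorm(length(mg) * nCelltypes, sd = 0.1),
               length(mg), nCelltypes)
      cladeMarkers[[paste(clades[[k]], collapse = "+")]] <- mg
    }
    celltypeTree <- .balancedNewick(celltypes)
  }
  # paralog sets: planted between the first two species
  paralogTruth <- list()
  parGenes <- character(0)
  if (nParalogSets > 0L) {
    free <- setdiff(consGenes, names(moduleOf)[!is.na(moduleOf)])
    if (length(free) < nParalogSets)
      stop("infeasible config: not enough conserved genes for paralog sets")
    parGenes <- sample(free, nParalogSets)
  }
  atlases <- list()
  pairRows <- list()
  for (si in seq_along(species)) {
    sp <- species[si]
    mcRange <- seq(metacellsPerType[1], metacellsPerType[2])
    nMc <- if (length(mcRange) == 1L) rep(mcRange, nCelltypes) else
      sample(mcRange, nCelltypes, replace = TRUE)
    mcType <- rep(celltypes, nMc)
    mcs <- sprintf("%s_mc%03d", sp, seq_along(mcType))
    profile <- ancestral
    div <- names(consClass)[consClass == "diverged"]
    profile[div, ] <- drawProfiles(length(div))
    spGenes <- paste(sp, genes, sep = "_")
    logfc <- profile[, mcType, drop = FALSE] +
      matrix(rnorm(nGenes * length(mcType), sd = noiseSd),
             nGenes, length(mcType))
    rownames(logfc) <- spGenes
    # paralog expansion in the second species
    if (si == 2L && length(parGenes)) {
      extra <- list()
      for (k in seq_along(parGenes)) {
        g <- parGenes[k]
        setId <- sprintf("PS%02d", k)
        cand <- sprintf("%s_%s_p%d", sp, g, seq_len(paralogsPerSet))
        retain <- sample(paralogsPerSet, 1L)
        for (j in seq_len(paralogsPerSet)) {
          prof <- if (j == retain)
            unname(ancestral[g, ]) + rnorm(nCelltypes, sd = paralogJitterSd)
          else rnorm(nCelltypes)
          extra[[cand[j]]] <- prof[match(mcType, celltypes)] +
            rnorm(length(mcType), sd = noiseSd)
        }
        paralogTruth[[setId]] <- list(geneA = paste(species[1], g, sep = "_"),
                                      trueGeneB = cand[retain],
                                      candidates = cand)
      }
      logfc <- rbind(logfc, do.call(rbind, extra))
    }
    # renormalize per gene so the across-metacell median FC is 1
    logfc <- logfc - apply(logfc, 1L, median)
    fc <- exp(logfc)
    colnames(fc) <- mcs
    atlases[[sp]] <- MetacellExpression(sp, fc,
      metacellToCelltype = setNames(mcType, mcs))
  }
  # homology map between the first two species
  o2oGenes <- setdiff(genes, parGenes)
  pairs <- data.frame(geneA = paste(species[1], o2oGenes, sep = "_"),
                      geneB = paste(species[2], o2oGenes, sep = "_"),
                      relation = "one2one", setId = NA_character_)
  if (length(paralogTruth)) {
    parRows <- do.call(rbind, lapply(names(paralogTruth), function(setId) {
      tr <- paralogTruth[[setId]]
      data.frame(geneA = tr$geneA, geneB = tr$candidates,
                 relation = "candidate_paralog", setId = setId)
    }))
    pairs <- rbind(pairs, parRows)
  }
  treeStr <- .balancedNewick(species)
  truth <- list(tree = treeStr,
                conservationClass = as.list(consClass),
                modules = as.list(moduleOf[!is.na(moduleOf)]),
                paralogs = paralogTruth,
                celltypes = celltypes,
                celltypeTree = celltypeTree,
                cladeMarkers = cladeMarkers)
  list(atlases = atlases, homology = HomologyMap(pairs), tree = treeStr,
       truth = truth)
}

# all clades (including singletons, excluding the root set) of the
# balanced binary hierarchy .balancedNewick builds
.balancedClades <- function(labels) {
  out <- list()
  recurse <- function(x, isRoot) {
    if (!isRoot) out[[length(out) + 1L]] <<- x
    if (length(x) == 1L) return(invisible())
    k <- ceiling(length(x) / 2)
    recurse(x[seq_len(k)], FALSE)
    recurse(x[-seq_len(k)], FALSE)
  }
  recurse(labels, TRUE)
  out
}

# simple balanced (ladderized) rooted Newick over the given labels
.balancedNewick <- function(labels) {
  build <- function(x) {
    if (length(x) == 1L) return(x)
    k <- ceiling(length(x) / 2)
    paste0("(", build(x[seq_len(k)]), ",", build(x[-seq_len(k)]), ")")
  }
  paste0(build(labels), ";")
}

#' Generate a synthetic UMI matrix from a metacell atlas
#'
#' Terminal cells are drawn multinomially from their metacell's FC-derived
#' expression profile at the requested depth. Doublets replace terminal
#' cells at the stated rate and mix the mean profiles of two random
#' distinct cell types 50/50. Intermediate cells mix the two configured
#' parental profiles 50/50 after down-sampling each parent's marker
#' program to `markerFraction` of its markers. Cycling cells receive a
#' multiplicative load on a cell-cycle gene set. Every cell's true state
#' is recorded.
#'
#' @param expr a [MetacellExpression-class].
#' @param cellsPerMetacell terminal cells per metacell (default 20).
#' @param depth UMIs per cell (>= 100; default 2000).
#' @param doubletRate doublet probability per cell in \[0,1\].
#' @param intermediate list `(fraction, pair = c(typeA, typeB),
#'   markerFraction, markerFc)`; `fraction` of terminal-cell count is
#'   added as intermediate cells.
#' @param cycling list `(fraction, genes, load)`; `fraction` of terminal
#'   cells are converted to cycling cells with `load`-fold elevated
#'   cell-cycle gene mass. `genes = NULL` picks 30 random genes.
#' @param seed integer seed.
#' @return list with `umi` (a [UmiMatrix-class]) and `truth` (per-cell
#'   state and the gene sets used).
#' @export
generateUmi <- function(expr, cellsPerMetacell = 20L, depth = 2000L,
                        doubletRate = 0,
                        intermediate = list(fraction = 0),
                        cycling = list(fraction = 0), seed = 1L) {
  stopifnot(is(expr, "MetacellExpression"))
  if (depth < 100) stop("depth must be >= 100")
  interFrac <- intermediate$fraction %||% 0
  cycFrac <- cycling$fraction %||% 0
  for (r in c(doubletRate, interFrac, cycFrac))
    if (r < 0 || r > 1) stop("rates must lie in [0,1]")
  set.seed(seed)
  fc <- expr@fc
  mcType <- expr@metacellToCelltype
  mcs <- colnames(fc)
  profiles <- sweep(fc, 2L, colSums(fc), "/")
  typeProfile <- vapply(unique(mcType), function(tt) {
    p <- rowMeans(profiles[, names(mcType)[mcType == tt], drop = FALSE])
    p / sum(p)
  }, numeric(nrow(fc)))
  counts <- list(); state <- list(); assign <- character()
  cellId <- 0L
  nextCell <- function() sprintf("cell%05d", cellId)
  # cycling gene set
  cycGenes <- cycling$genes
  if (cycFrac > 0 && is.null(cycGenes))
    cycGenes <- sample(rownames(fc), 30L)
  cycLoad <- cycling$load %||% 5
  for (m in mcs) {
    p <- profiles[, m]
    for (i in seq_len(cellsPerMetacell)) {
      cellId <- cellId + 1L; cn <- nextCell()
      isDoublet <- doubletRate > 0 && runif(1) < doubletRate
      isCycling <- !isDoublet && cycFrac > 0 && runif(1) < cycFrac
      if (isDoublet) {
        pair <- sample(colnames(typeProfile), 2L)
        pd <- (typeProfile[, pair[1]] + typeProfile[, pair[2]]) / 2
        counts[[cn]] <- rmultinom(1, depth, pd)[, 1]
        state[[cn]] <- list(state = "doublet", pair = pair)
      } else if (isCycling) {
        pc <- p
        pc[cycGenes] <- pc[cycGenes] * cycLoad
        pc <- pc / sum(pc)
        counts[[cn]] <- rmultinom(1, depth, pc)[, 1]
        state[[cn]] <- list(state = "cycling", metacell = m)
        assign[cn] <- m
      } else {
        counts[[cn]] <- rmultinom(1, depth, p)[, 1]
        state[[cn]] <- list(state = "terminal", metacell = m,
                            celltype = unname(mcType[m]))
        assign[cn] <- m
      }
    }
  }
  interTruth <- list()
  if (interFrac > 0) {
    pair <- intermediate$pair
    if (is.null(pair) || length(pair) != 2L)
      stop("intermediate$pair must name two cell types")
    mf <- intermediate$markerFraction %||% 0.5
    markerFc <- intermediate$markerFc %||% 2
    ctab <- celltypeFc(expr)
    mA <- rownames(ctab)[ctab[, pair[1]] >= markerFc]
    mB <- rownames(ctab)[ctab[, pair[2]] >= markerFc]
    shared <- intersect(mA, mB)
    mA <- setdiff(mA, shared); mB <- setdiff(mB, shared)
    keepA <- sample(mA, max(1L, round(mf * length(mA))))
    keepB <- sample(mB, max(1L, round(mf * length(mB))))
    pA <- typeProfile[, pair[1]]; pB <- typeProfile[, pair[2]]
    # each parental marker program keeps its full program-level UMI mass,
    # concentrated on the selected marker subset; the rest of the
    # transcriptome is the parental average
    fA <- sum(pA[mA]); fB <- sum(pB[mB])
    pInt <- (pA + pB) / 2
    pInt[c(mA, mB)] <- 0
    pInt <- pInt / sum(pInt) * max(0, 1 - fA - fB)
    pInt[keepA] <- pA[keepA] / sum(pA[keepA]) * fA
    pInt[keepB] <- pB[keepB] / sum(pB[keepB]) * fB
    pInt <- pInt / sum(pInt)
    nInt <- round(interFrac * cellId)
    for (i in seq_len(nInt)) {
      cellId <- cellId + 1L; cn <- nextCell()
      counts[[cn]] <- rmultinom(1, depth, pInt)[, 1]
      state[[cn]] <- list(state = "intermediate", pair = pair)
    }
    interTruth <- list(pair = pair, markersA = keepA, markersB = keepB)
  }
  cnt <- do.call(cbind, counts)
  rownames(cnt) <- rownames(fc)
  umi <- UmiMatrix(cnt, cellToMetacell = assign)
  list(umi = umi,
       truth = list(states = state, intermediate = interTruth,
                    cyclingGenes = cycGenes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample uniformly from an inclusive integer range (safe for lo == hi)
.sampleRange <- function(lo, hi, n = 1L) {
  rng <- seq(lo, hi)
  if (length(rng) == 1L) rep(rng, n) else sample(rng, n, replace = TRUE)
}

#' Generate jittered motif families with known archetypes
#'
#' Each archetype is a sharp random PPM; copies mix the archetype with
#' Dirichlet-style column noise at weight `jitter`, and may be trimmed by
#' one flanking position (shift) or reverse-complemented.
#'
#' @param nArchetypes archetype count (default 5).
#' @param copiesPerArchetype copies per archetype (default 6).
#' @param jitter noise mixing weight in \[0, 0.5) (default 0.05).
#' @param lengthRange archetype length range (default `c(8, 12)`).
#' @param revcompProb probability a copy is reverse-complemented
#'   (default 0.3).
#' @param shiftProb probability a copy is trimmed by one position
#'   (default 0.2).
#' @param seed integer seed.
#' @return list with `motifs` (list of [MotifPPM-class]), `archetypes`
#'   (list of the true PPMs) and `truth` (data.frame: motif, archetype,
#'   strand, shifted).
#' @export
generateMotifs <- function(nArchetypes = 5L, copiesPerArchetype = 6L,
                           jitter = 0.05, lengthRange = c(8L, 12L),
                           revcompProb = 0.3, shiftProb = 0.2, seed = 1L) {
  if (jitter < 0 || jitter >= 0.5) stop("jitter must lie in [0, 0.5)")
  set.seed(seed)
  arch <- list()
  for (a in seq_len(nArchetypes)) {
    L <- .sampleRange(lengthRange[1], lengthRange[2])
    p <- t(vapply(seq_len(L), function(i) {
      v <- rep(0.05, 4); v[sample(4, 1)] <- 0.85; v
    }, numeric(4)))
    colnames(p) <- c("A", "C", "G", "T")
    arch[[sprintf("arch%02d", a)]] <- p
  }
  motifs <- list(); truth <- list()
  for (a in names(arch)) {
    for (k in seq_len(copiesPerArchetype)) {
      p <- arch[[a]]
      if (jitter > 0) {
        noise <- matrix(stats::rgamma(nrow(p) * 4, shape = 1), nrow(p), 4)
        noise <- noise / rowSums(noise)
        p <- (1 - jitter) * p + jitter * noise
      }
      shifted <- runif(1) < shiftProb && nrow(p) > 6L
      if (shifted)
        p <- if (runif(1) < 0.5) p[-1, , drop = FALSE] else
          p[-nrow(p), , drop = FALSE]
      strand <- if (runif(1) < revcompProb) "-" else "+"
      if (strand == "-") p <- .revcompPpm(p)
      nm <- sprintf("%s_copy%02d", a, k)
      motifs[[nm]] <- MotifPPM(nm, p, source = "synthetic")
      truth[[nm]] <- data.frame(motif = nm, archetype = a,
                                strand = strand, shifted = shifted)
    }
  }
  list(motifs = unname(motifs),
       archetypes = arch,
       truth = do.call(rbind, unname(truth)))
}

#' Generate synthetic propeptide sequences with planted cleavage cassettes
#'
#' Random amino-acid background with `[KR][KR] + core + G[RK]` cassettes
#' inserted at recorded positions. Core spans are recorded 1-based
#' inclusive.
#'
#' @param n sequences (default 20).
#' @param lengthRange sequence length range (default `c(80, 120)`).
#' @param cassettesPerSeq planted cassettes per sequence (default 1; may
#'   be 0).
#' @param coreLengthRange planted core lengths, within \[3, 10\]
#'   (default `c(3, 10)`).
#' @param backgroundAlphabet residues used for background (default all 20
#'   canonical; exclude K/R/G to make backgrounds signature-free).
#' @param seed integer seed.
#' @return list with `sequences` (named character) and `truth`
#'   (data.frame: id, coreStart, coreEnd, core).
#' @export
generatePropeptides <- function(n = 20L, lengthRange = c(80L, 120L),
                                cassettesPerSeq = 1L,
                                coreLengthRange = c(3L, 10L),
                                backgroundAlphabet =
                                  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                seed = 1L) {
  if (coreLengthRange[1] < 3L || coreLengthRange[2] > 10L)
    stop("planted core lengths must lie in [3, 10]")
  set.seed(seed)
  seqs <- character(n); names(seqs) <- sprintf("pp%03d", seq_len(n))
  truth <- list()
  basic <- c("K", "R")
  for (i in seq_len(n)) {
    L <- .sampleRange(lengthRange[1], lengthRange[2])
    ch <- sample(backgroundAlphabet, L, replace = TRUE)
    if (cassettesPerSeq > 0L) {
      for (k in seq_len(cassettesPerSeq)) {
        coreLen <- .sampleRange(coreLengthRange[1], coreLengthRange[2])
        cassette <- c(sample(basic, 2L, replace = TRUE),
                      sample(backgroundAlphabet, coreLen, replace = TRUE),
                      "G", sample(basic, 1L))
        maxStart <- L - length(cassette) + 1L
        if (maxStart < 1L) next
        at <- sample(maxStart, 1L)
        ch[at:(at + length(cassette) - 1L)] <- cassette
        truth[[length(truth) + 1L]] <- data.frame(
          id = names(seqs)[i], coreStart = at + 2L,
          coreEnd = at + 1L + coreLen,
          core = paste(cassette[3:(2 + coreLen)], collapse = ""))
      }
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  truthDf <- if (length(truth)) do.call(rbind, truth) else
    data.frame(id = character(), coreStart = integer(),
               coreEnd = integer(), core = character())
  list(sequences = seqs, truth = truthDf)
}

#' Simulate Dollo character histories on a species tree
#'
#' Each character is gained at a random tree node and lost along random
#' branches below the gain (each lost branch wipes its whole subtree).
#' Histories are resampled until they are in canonical Dollo form -- the
#' gain node is the most recent common ancestor of the surviving present
#' leaves -- so the planted history is exactly the minimal single-gain
#' scenario and can be recovered without ambiguity.
#'
#' @param tree an `ape::phylo`.
#' @param nCharacters characters to simulate (default 50).
#' @param lossProb per-branch loss probability below the gain
#'   (default 0.2).
#' @param seed integer seed.
#' @return list with `chars` (a [CharacterMatrix-class]) and `truth`
#'   (per character: gain node id and loss child-node ids, ape
#'   numbering).
#' @export
generateDolloCharacters <- function(tree, nCharacters = 50L,
                                    lossProb = 0.2, seed = 1L) {
  set.seed(seed)
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  desc <- .nodeDescendants(tree)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  m <- matrix(0L, nCharacters, nTip,
              dimnames = list(sprintf("char%04d", seq_len(nCharacters)),
                              tree$tip.label))
  truth <- list()
  for (ci in seq_len(nCharacters)) {
    repeat {
      gain <- sample(nNode, 1L)
      lost <- integer(0)
      presentTips <- integer(0)
      wipe <- function(v) unlist(desc[[v]])
      # top-down simulation below the gain
      stack <- gain
      presentNodes <- gain
      while (length(stack)) {
        v <- stack[1]; stack <- stack[-1]
        if (v <= nTip) { presentTips <- c(presentTips, v); next }
        chs <- children[[as.character(v)]]
        lostHere <- runif(length(chs)) < lossProb
        # a present node must keep at least one surviving child, or the
        # minimal history would place the loss one branch higher
        if (all(lostHere)) lostHere[sample(length(chs), 1L)] <- FALSE
        lost <- c(lost, chs[lostHere])
        stack <- c(stack, chs[!lostHere])
      }
      if (!length(presentTips)) next
      # canonical form: the gain must be the MRCA of the present tips
      if (gain <= nTip) { mrca <- gain } else {
        anc <- which(vapply(desc, function(d) all(presentTips %in% d),
                            logical(1)))
        mrca <- anc[which.min(lengths(desc[anc]))]
      }
      if (mrca != gain) next
      m[ci, presentTips] <- 1L
      truth[[rownames(m)[ci]]] <- list(gainNode = gain, losses = sort(lost))
      break
    }
  }
  list(chars = new("CharacterMatrix", chars = m), truth = truth)
}
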