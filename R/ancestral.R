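# Binary expression characters over species and their Dollo-parsimony
# gain/loss histories on a species tree.

#' Build binary expression characters from cell-type atlases
#'
#' A character (orthogroup) is scored present (1) in a species when at
#' least one member gene reaches `fcThreshold` in at least `minFraction`
#' of the species' target metacells (both boundaries inclusive), absent
#' (0) when genes exist but never reach the rule, and missing (`NA`) when
#' the orthogroup has no gene in that genome. Characters absent (or
#' missing) everywhere are dropped.
#'
#' @param atlases named list of [MetacellExpression-class], one per
#'   species.
#' @param orthogroups named list per species: named character gene ->
#'   orthogroup id.
#' @param targetMetacells named list per species: metacell labels to
#'   evaluate (e.g. the neuron-like metacells); all nonempty.
#' @param fcThreshold fold-change floor (default 2).
#' @param minFraction minimum fraction of target metacells (default 0.25).
#' @return a [CharacterMatrix-class] (characters x species).
#' @export
buildExpressionCharacters <- function(atlases, orthogroups, targetMetacells,
                                      fcThreshold = 2, minFraction = 0.25) {
  species <- names(atlases)
  stopifnot(length(species) >= 2L,
            all(species %in% names(orthogroups)),
            all(species %in% names(targetMetacells)))
  allOg <- sort(unique(unlist(lapply(orthogroups, unique))))
  m <- matrix(NA_integer_, length(allOg), length(species),
              dimnames = list(allOg, species))
  for (sp in species) {
    fc <- fcMatrix(atlases[[sp]])
    mcs <- targetMetacells[[sp]]
    if (!length(mcs)) stop("empty target metacell set for ", sp)
    mcs <- intersect(mcs, colnames(fc))
    og <- orthogroups[[sp]]
    genes <- intersect(names(og), rownames(fc))
    hit <- rowMeans(fc[genes, mcs, drop = FALSE] >= fcThreshold) >= minFraction
    present <- tapply(hit, og[genes], any)
    m[names(present), sp] <- as.integer(present)
  }
  keep <- rowSums(m == 1L, na.rm = TRUE) > 0
  if (any(!keep))
    message(sum(!keep), " orthogroup(s) absent everywhere dropped")
  new("CharacterMatrix", chars = m[keep, , drop = FALSE])
}

# descendant tips of every node of an ape phylo (tips included)
.nodeDescendants <- function(tree) {
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  desc <- vector("list", nNode)
  for (i in seq_len(nTip)) desc[[i]] <- i
  edge <- tree$edge[order(tree$edge[, 1], decreasing = TRUE), , drop = FALSE]
  # children are processed before parents in reverse node-id order for
  # standard ape numbering; iterate until fixed point to be safe with
  # arbitrary orderings
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edge))) {
      p <- edge[k, 1]; ch <- edge[k, 2]
      if (!is.null(desc[[ch]])) {
        add <- setdiff(desc[[ch]], desc[[p]])
        if (length(add)) { desc[[p]] <- c(desc[[p]], add); changed <- TRUE }
      }
    }
    if (!changed) break
  }
  desc
}

#' Dollo-parsimony reconstruction of character gains and losses
#'
#' Each character is gained exactly once, at the most recent common
#' ancestor of the species that have it (for a single present species, at
#' that leaf), and lost as many times as needed below the gain: an
#' internal node below the gain is present unless all its non-missing
#' descendant leaves are absent, and losses are the branches into maximal
#' all-absent subtrees. Leaves where the character is missing (no gene in
#' the genome) are ignored: they neither pull the gain node down nor get
#' charged a loss.
#'
#' @param chars a [CharacterMatrix-class]; its species must all be tree
#'   leaves.
#' @param tree a rooted `ape::phylo` (multifurcations allowed).
#' @return a [DolloReconstruction-class].
#' @export
dolloReconstruct <- function(chars, tree) {
  stopifnot(is(chars, "CharacterMatrix"))
  m <- chars@chars
  if (!all(colnames(m) %in% tree$tip.label))
    stop("character species must be tree leaves")
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  desc <- .nodeDescendants(tree)
  tipId <- setNames(seq_len(nTip), tree$tip.label)
  parent <- integer(nNode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  states <- matrix(0L, nrow(m), nNode,
                   dimnames = list(rownames(m), NULL))
  gainNode <- integer(nrow(m))
  losses <- vector("list", nrow(m))
  for (ci in seq_len(nrow(m))) {
    obs <- m[ci, ]
    presentTips <- tipId[colnames(m)[which(obs == 1L)]]
    informTips <- tipId[colnames(m)[which(!is.na(obs))]]
    if (!length(presentTips))
      stop("character with zero present leaves: ", rownames(m)[ci])
    # gain = MRCA of present leaves (the leaf itself if only one)
    if (length(presentTips) == 1L) {
      gain <- unname(presentTips)
    } else {
      anc <- which(vapply(desc, function(d) all(presentTips %in% d),
                          logical(1)))
      gain <- anc[which.min(lengths(desc[anc]))]
    }
    # presence below the gain: any non-missing descendant leaf present
    st <- integer(nNode)
    inGain <- desc[[gain]]
    nodesBelow <- c(gain, which(vapply(seq_len(nNode), function(v)
      all(desc[[v]] %in% inGain) && v != gain, logical(1))))
    for (v in nodesBelow) {
      dts <- desc[[v]]
      st[v] <- as.integer(any(dts %in% presentTips))
    }
    # losses: edges from a present parent into an absent child whose
    # subtree holds at least one informative (non-missing) leaf
    lost <- integer(0)
    for (v in nodesBelow) {
      if (v == gain) next
      p <- parent[v]
      if (st[p] == 1L && st[v] == 0L && any(desc[[v]] %in% informTips))
        lost <- c(lost, v)
    }
    # absent subtrees below a loss stay 0; ensure no doubly-counted losses
    # (children of an already-lost node are never flagged because their
    # parent state is 0)
    states[ci, ] <- st
    gainNode[ci] <- gain
    losses[[ci]] <- sort(lost)
  }
  names(losses) <- rownames(m)
  new("DolloReconstruction", tree = tree,
      gainNode = setNames(gainNode, rownames(m)),
      losses = losses, states = states)
}

#' Per-node summary of character presence, gains and losses
#'
#' For each node of the tree (extant leaves and ancestral nodes):
#' `nGained` counts characters whose gain node is this node, `nLost`
#' characters with a loss on the branch into this node, and `nPresent`
#' characters in state 1 at this node.
#'
#' @param rec a [DolloReconstruction-class].
#' @return data.frame with columns `node`, `label`, `nPresent`, `nGained`,
#'   `nLost`, one row per tree node (ape node ids).
#' @export
summarizeGainsLosses <- function(rec) {
  stopifnot(is(rec, "DolloReconstruction"))
  tree <- rec@tree
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label) && length(tree$node.label))
                tree$node.label else paste0("node", (nTip + 1):nNode))
  lostCounts <- tabulate(unlist(rec@losses), nbins = nNode)
  gainCounts <- tabulate(rec@gainNode, nbins = nNode)
  data.frame(node = seq_len(nNode), label = labels,
             nPresent = colSums(rec@states),
             nGained = gainCounts, nLost = lostCounts)
}
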