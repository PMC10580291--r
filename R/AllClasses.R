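#' @import methods
#' @importFrom stats cor median quantile sd qnorm phyper dbinom pbinom
#'   rmultinom rnorm runif rbinom prcomp hclust cutree as.dist cophenetic
#'   setNames ave rhyper
#' @importFrom utils head read.delim write.table combn
NULL

#' Metacell-level expression atlas for one species
#'
#' The universal currency of the package: a genes x metacells matrix of
#' fold-change (FC) values -- the regularized geometric mean of a gene's
#' expression within each metacell divided by its median across metacells --
#' together with the metacell -> cell-type -> broad-type annotation.
#'
#' @slot species single character, species identifier.
#' @slot fc numeric matrix (genes x metacells) of strictly positive, finite
#'   fold changes; rownames are gene labels, colnames metacell labels.
#' @slot metacellToCelltype named character; names are metacell labels,
#'   values cell-type labels. Every metacell has exactly one cell type.
#' @slot celltypeToBroadtype named character mapping cell types to broad
#'   types (may be empty).
#'
#' @seealso [MetacellExpression()], [fcMatrix()], [fcFromUmi()]
#' @export
setClass("MetacellExpression",
  representation(
    species = "character",
    fc = "matrix",
    metacellToCelltype = "character",
    celltypeToBroadtype = "character"
  )
)

setValidity("MetacellExpression", function(object) {
  msg <- character()
  fc <- object@fc
  if (length(object@species) != 1L) msg <- c(msg, "species must be a single label")
  if (is.null(rownames(fc)) || is.null(colnames(fc)))
    msg <- c(msg, "fc must have gene rownames and metacell colnames")
  else {
    if (anyDuplicated(rownames(fc))) msg <- c(msg, "gene labels must be unique")
    if (!all(is.finite(fc)) || any(fc <= 0))
      msg <- c(msg, "all fc values must be finite and > 0")
    if (!setequal(colnames(fc), names(object@metacellToCelltype)))
      msg <- c(msg, "every metacell must have exactly one cell-type annotation")
  }
  if (length(msg)) msg else TRUE
})

#' UMI count matrix
#'
#' Raw unique-molecular-identifier counts per gene per cell, with an optional
#' cell -> metacell assignment.
#'
#' @slot counts numeric matrix (genes x cells) of non-negative integers.
#' @slot cellToMetacell named character (possibly empty) assigning cells to
#'   metacells.
#'
#' @seealso [UmiMatrix()], [fcFromUmi()], [generateUmi()]
#' @export
setClass("UmiMatrix",
  representation(counts = "matrix", cellToMetacell = "character")
)

setValidity("UmiMatrix", function(object) {
  msg <- character()
  cnt <- object@counts
  if (is.null(rownames(cnt)) || is.null(colnames(cnt)))
    msg <- c(msg, "counts must have gene rownames and cell colnames")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(object@cellToMetacell) &&
      !all(names(object@cellToMetacell) %in% colnames(cnt)))
    msg <- c(msg, "cellToMetacell names must be cells of the matrix")
  if (length(msg)) msg else TRUE
})

#' Ortholog/paralog pairings between two species
#'
#' @slot pairs data.frame with columns `geneA`, `geneB`,
#'   `relation` (one of `"one2one"`, `"candidate_paralog"`) and `setId`
#'   (paralog-set label, `NA` for one-to-one pairs).
#'
#' @seealso [HomologyMap()], [computeEC()], [selectBestParalogs()]
#' @export
setClass("HomologyMap", representation(pairs = "data.frame"))

setValidity("HomologyMap", function(object) {
  p <- object@pairs
  msg <- character()
  need <- c("geneA", "geneB", "relation", "setId")
  if (!all(need %in% colnames(p)))
    return(sprintf("pairs must have columns %s", paste(need, collapse = ", ")))
  if (!all(p$relation %in% c("one2one", "candidate_paralog")))
    msg <- c(msg, "relation must be one2one or candidate_paralog")
  o2o <- p[p$relation == "one2one", , drop = FALSE]
  if (anyDuplicated(o2o$geneA) || anyDuplicated(o2o$geneB))
    msg <- c(msg, "a one2one gene may appear in exactly one pair")
  if (any(p$relation == "candidate_paralog" & is.na(p$setId)))
    msg <- c(msg, "candidate_paralog pairs need a setId")
  if (length(msg)) msg else TRUE
})

#' Expression-conservation (EC) weights for ortholog pairs
#'
#' Per-pair EC scores in \[0,1\] produced by the iterative comparison of
#' co-expression (ICC) between two species.
#'
#' @slot pairs data.frame with columns `geneA`, `geneB`.
#' @slot ec numeric vector in \[0,1\], one score per pair.
#' @slot iterations integer, number of ICC iterations actually run.
#' @slot converged logical, whether the stopping criterion was met before
#'   the iteration cap.
#'
#' @seealso [computeEC()], [ecScores()]
#' @export
setClass("ECWeights",
  representation(pairs = "data.frame", ec = "numeric",
                 iterations = "integer", converged = "logical")
)

setValidity("ECWeights", function(object) {
  msg <- character()
  if (nrow(object@pairs) != length(object@ec))
    msg <- c(msg, "one ec value per pair required")
  if (length(object@ec) && (min(object@ec) < 0 || max(object@ec) > 1))
    msg <- c(msg, "ec values must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Binary presence/expression characters over species
#'
#' @slot chars integer matrix (characters x species) with entries 1
#'   (present), 0 (absent) or `NA` (missing: the orthogroup has no gene in
#'   that genome, which is distinct from present-but-not-expressed).
#'
#' @seealso [buildExpressionCharacters()], [dolloReconstruct()]
#' @export
setClass("CharacterMatrix", representation(chars = "matrix"))

setValidity("CharacterMatrix", function(object) {
  m <- object@chars
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("chars must have character rownames and species colnames")
  v <- m[!is.na(m)]
  if (!all(v %in% c(0L, 1L))) return("entries must be 0, 1 or NA")
  if (nrow(m) && any(rowSums(m == 1L, na.rm = TRUE) == 0))
    return("every retained character must be present in at least one species")
  TRUE
})

#' Dollo-parsimony reconstruction of character histories
#'
#' Under Dollo parsimony a character is gained exactly once -- at the most
#' recent common ancestor of the species that have it -- and lost as many
#' times as needed below that node.
#'
#' @slot tree the `ape::phylo` species tree used.
#' @slot gainNode integer vector, per character the node id (ape numbering)
#'   where the character is gained.
#' @slot losses list, per character an integer vector of node ids whose
#'   incoming branch carries a loss.
#' @slot states integer matrix (characters x nodes) of 0/1 ancestral and
#'   extant states, columns ordered by ape node id.
#'
#' @seealso [dolloReconstruct()], [summarizeGainsLosses()]
#' @export
setClass("DolloReconstruction",
  representation(tree = "ANY", gainNode = "integer", losses = "list",
                 states = "matrix")
)

#' Co-expression modules for one species
#'
#' @slot species single character.
#' @slot membership named character: gene -> module id, covering only
#'   assigned genes (each gene belongs to at most one module).
#' @slot eigengenes numeric matrix (modules x metacells) of module
#'   eigengenes (first principal component of the standardized module
#'   submatrix).
#' @slot kme named numeric: per assigned gene, its correlation with the
#'   module eigengene.
#'
#' @seealso [detectModules()], [moduleEigengene()]
#' @export
setClass("GeneModuleSet",
  representation(species = "character", membership = "character",
                 eigengenes = "matrix", kme = "numeric")
)

#' Cross-species module clusters
#'
#' Connected components of the ortholog-overlap (Jaccard) graph between
#' per-species modules.
#'
#' @slot components list of character vectors; each element holds member
#'   module ids in `"species|module"` notation.
#' @slot edges data.frame with columns `moduleA`, `moduleB`, `jaccard`
#'   for all retained between-species edges.
#' @slot jaccardMin numeric threshold used.
#'
#' @seealso [clusterModulesAcrossSpecies()], [scoreModuleActivity()]
#' @export
setClass("MultiSpeciesModuleSet",
  representation(components = "list", edges = "data.frame",
                 jaccardMin = "numeric")
)

#' Position probability matrix of a DNA motif
#'
#' @slot name single character motif name.
#' @slot ppm numeric matrix (positions x 4) with columns A, C, G, T; every
#'   row sums to 1 within 1e-6; at least 4 positions.
#' @slot source single character tag for provenance (free text).
#'
#' @seealso [MotifPPM()], [icProfile()], [motifSimilarity()]
#' @export
setClass("MotifPPM",
  representation(name = "character", ppm = "matrix", source = "character")
)

setValidity("MotifPPM", function(object) {
  p <- object@ppm
  msg <- character()
  if (ncol(p) != 4L || !identical(colnames(p), c("A", "C", "G", "T")))
    msg <- c(msg, "ppm must have columns A, C, G, T")
  if (nrow(p) < 4L) msg <- c(msg, "motif length must be >= 4")
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-6))
    msg <- c(msg, "each ppm row must be a probability vector (sum 1 +/- 1e-6)")
  if (length(msg)) msg else TRUE
})

#' Averaged motif archetype
#'
#' The position-wise average of a cluster of aligned position probability
#' matrices, with the alignment (offset, strand) of each member.
#'
#' @slot ppm numeric matrix (positions x 4), rows renormalized to sum 1.
#' @slot members character vector of member motif names.
#' @slot offsets integer vector of member start offsets on the archetype
#'   coordinate system.
#' @slot strands character vector of `"+"`/`"-"` per member.
#'
#' @seealso [clusterMotifs()]
#' @export
setClass("MotifArchetype",
  representation(ppm = "matrix", members = "character",
                 offsets = "integer", strands = "character")
)

#' Cell-type marker gene set
#'
#' @slot celltype single character label.
#' @slot genes character vector of marker genes (nonempty).
#' @slot fcThreshold numeric, the FC cutoff the set was selected at.
#'
#' @seealso [markerSet()], [aucScores()], [classifyIntermediates()]
#' @export
setClass("MarkerSet",
  representation(celltype = "character", genes = "character",
                 fcThreshold = "numeric")
)

setValidity("MarkerSet", function(object) {
  if (!length(object@genes)) "marker set must be nonempty" else TRUE
})
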