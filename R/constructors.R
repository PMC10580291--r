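#' Construct a MetacellExpression object
#'
#' @param species single character species id.
#' @param fc genes x metacells matrix of positive fold changes with
#'   dimnames.
#' @param metacellToCelltype named character, metacell -> cell type. If
#'   missing, every metacell becomes its own cell type.
#' @param celltypeToBroadtype named character, cell type -> broad type
#'   (optional).
#' @return a [MetacellExpression-class] object.
#' @examples
#' fc <- matrix(c(2, .5, 1, 1, .5, 2), 3, 2,
#'              dimnames = list(c("g1", "g2", "g3"), c("m1", "m2")))
#' MetacellExpression("spA", fc, c(m1 = "T1", m2 = "T2"))
#' @export
MetacellExpression <- function(species, fc,
                               metacellToCelltype = NULL,
                               celltypeToBroadtype = character()) {
  fc <- as.matrix(fc)
  if (is.null(metacellToCelltype))
    metacellToCelltype <- setNames(colnames(fc), colnames(fc))
  new("MetacellExpression", species = species, fc = fc,
      metacellToCelltype = metacellToCelltype,
      celltypeToBroadtype = celltypeToBroadtype)
}

#' Construct a UmiMatrix object
#'
#' @param counts genes x cells matrix of non-negative integer UMI counts
#'   (dense, or any matrix coercible with `as.matrix`).
#' @param cellToMetacell optional named character, cell -> metacell.
#' @return a [UmiMatrix-class] object.
#' @export
UmiMatrix <- function(counts, cellToMetacell = character()) {
  new("UmiMatrix", counts = as.matrix(counts),
      cellToMetacell = cellToMetacell)
}

#' Construct a HomologyMap from a pair table
#'
#' @param pairs data.frame with columns `geneA`, `geneB`, `relation`
#'   (`"one2one"` or `"candidate_paralog"`) and `setId`; `setId` may be
#'   omitted and defaults to `NA`.
#' @return a [HomologyMap-class] object.
#' @export
HomologyMap <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (!"setId" %in% colnames(pairs)) pairs$setId <- NA_character_
  if (!"relation" %in% colnames(pairs)) pairs$relation <- "one2one"
  rownames(pairs) <- NULL
  new("HomologyMap", pairs = pairs)
}

#' Construct a MotifPPM
#'
#' @param name motif name.
#' @param ppm positions x 4 probability matrix; column names are set to
#'   A, C, G, T.
#' @param source free-text provenance tag.
#' @return a [MotifPPM-class] object.
#' @export
MotifPPM <- function(name, ppm, source = "unknown") {
  ppm <- as.matrix(ppm)
  colnames(ppm) <- c("A", "C", "G", "T")
  rownames(ppm) <- NULL
  new("MotifPPM", name = name, ppm = ppm, source = source)
}

#' Select cell-type markers from an FC table
#'
#' Markers of a cell type are the genes with fold change at or above
#' `fcThreshold` in that cell type (boundary inclusive).
#'
#' @param fcTable genes x cell-types numeric matrix of fold changes.
#' @param celltype column label to select markers for.
#' @param fcThreshold minimum fold change (default 2).
#' @return a [MarkerSet-class] object.
#' @export
markerSet <- function(fcTable, celltype, fcThreshold = 2) {
  stopifnot(celltype %in% colnames(fcTable))
  genes <- rownames(fcTable)[fcTable[, celltype] >= fcThreshold]
  new("MarkerSet", celltype = celltype, genes = genes,
      fcThreshold = fcThreshold)
}

# ---- accessors ----

#' Accessors for crosscell containers
#'
#' `fcMatrix` returns the genes x metacells FC matrix; `speciesId` the
#' species label; `metacellTypes` the metacell -> cell-type map;
#' `umiCounts` the UMI count matrix; `homologyPairs` the pair table;
#' `ecScores` the named EC vector (`"geneA|geneB"`); `ecPairs` the pair
#' table with an `ec` column; `moduleMembership` the gene -> module map;
#' `moduleEigengenes` the module x metacell eigengene matrix;
#' `characterStates` the character x species 0/1/NA matrix; `motifMatrix`
#' the positions x 4 probability matrix; `markerGenes` the marker gene
#' vector.
#'
#' @param x a crosscell S4 object.
#' @return the underlying data described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fcMatrix", function(x) standardGeneric("fcMatrix"))
#' @rdname accessors
#' @export
setMethod("fcMatrix", "MetacellExpression", function(x) x@fc)

#' @rdname accessors
#' @export
setGeneric("speciesId", function(x) standardGeneric("speciesId"))
#' @rdname accessors
#' @export
setMethod("speciesId", "MetacellExpression", function(x) x@species)
#' @rdname accessors
#' @export
setMethod("speciesId", "GeneModuleSet", function(x) x@species)

#' @rdname accessors
#' @export
setGeneric("metacellTypes", function(x) standardGeneric("metacellTypes"))
#' @rdname accessors
#' @export
setMethod("metacellTypes", "MetacellExpression",
          function(x) x@metacellToCelltype)

#' @rdname accessors
#' @export
setGeneric("umiCounts", function(x) standardGeneric("umiCounts"))
#' @rdname accessors
#' @export
setMethod("umiCounts", "UmiMatrix", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("homologyPairs", function(x) standardGeneric("homologyPairs"))
#' @rdname accessors
#' @export
setMethod("homologyPairs", "HomologyMap", function(x) x@pairs)

#' @rdname accessors
#' @export
setGeneric("ecScores", function(x) standardGeneric("ecScores"))
#' @rdname accessors
#' @export
setMethod("ecScores", "ECWeights", function(x)
  setNames(x@ec, paste(x@pairs$geneA, x@pairs$geneB, sep = "|")))

#' @rdname accessors
#' @export
setGeneric("ecPairs", function(x) standardGeneric("ecPairs"))
#' @rdname accessors
#' @export
setMethod("ecPairs", "ECWeights", function(x) {
  out <- x@pairs
  out$ec <- x@ec
  out
})

#' @rdname accessors
#' @export
setGeneric("moduleMembership", function(x) standardGeneric("moduleMembership"))
#' @rdname accessors
#' @export
setMethod("moduleMembership", "GeneModuleSet", function(x) x@membership)

#' @rdname accessors
#' @export
setGeneric("moduleEigengenes", function(x) standardGeneric("moduleEigengenes"))
#' @rdname accessors
#' @export
setMethod("moduleEigengenes", "GeneModuleSet", function(x) x@eigengenes)

#' @rdname accessors
#' @export
setGeneric("characterStates", function(x) standardGeneric("characterStates"))
#' @rdname accessors
#' @export
setMethod("characterStates", "CharacterMatrix", function(x) x@chars)

#' @rdname accessors
#' @export
setGeneric("motifMatrix", function(x) standardGeneric("motifMatrix"))
#' @rdname accessors
#' @export
setMethod("motifMatrix", "MotifPPM", function(x) x@ppm)
#' @rdname accessors
#' @export
setMethod("motifMatrix", "MotifArchetype", function(x) x@ppm)

#' @rdname accessors
#' @export
setGeneric("markerGenes", function(x) standardGeneric("markerGenes"))
#' @rdname accessors
#' @export
setMethod("markerGenes", "MarkerSet", function(x) x@genes)

# ---- show methods ----

setMethod("show", "MetacellExpression", function(object) {
  cat("MetacellExpression [", object@species, "]: ",
      nrow(object@fc), " genes x ", ncol(object@fc), " metacells, ",
      length(unique(object@metacellToCelltype)), " cell types\n", sep = "")
})

setMethod("show", "UmiMatrix", function(object) {
  cat("UmiMatrix: ", nrow(object@counts), " genes x ",
      ncol(object@counts), " cells; median library size ",
      median(colSums(object@counts)), "\n", sep = "")
})

setMethod("show", "HomologyMap", function(object) {
  p <- object@pairs
  cat("HomologyMap: ", sum(p$relation == "one2one"), " one2one pairs, ",
      length(unique(p$setId[p$relation == "candidate_paralog"])),
      " paralog sets\n", sep = "")
})

setMethod("show", "ECWeights", function(object) {
  cat("ECWeights: ", length(object@ec), " pairs; mean EC ",
      round(mean(object@ec), 3), "; ", object@iterations, " iterations (",
      if (object@converged) "converged" else "not converged", ")\n",
      sep = "")
})

setMethod("show", "CharacterMatrix", function(object) {
  cat("CharacterMatrix: ", nrow(object@chars), " characters x ",
      ncol(object@chars), " species (",
      sum(is.na(object@chars)), " missing entries)\n", sep = "")
})

setMethod("show", "DolloReconstruction", function(object) {
  cat("DolloReconstruction: ", length(object@gainNode),
      " characters on a ", length(object@tree$tip.label),
      "-species tree; total losses ",
      sum(lengths(object@losses)), "\n", sep = "")
})

setMethod("show", "GeneModuleSet", function(object) {
  cat("GeneModuleSet [", object@species, "]: ",
      nrow(object@eigengenes), " modules, ",
      length(object@membership), " assigned genes\n", sep = "")
})

setMethod("show", "MultiSpeciesModuleSet", function(object) {
  cat("MultiSpeciesModuleSet: ", length(object@components),
      " cross-species module clusters from ", nrow(object@edges),
      " edges (Jaccard >= ", object@jaccardMin, ")\n", sep = "")
})

setMethod("show", "MotifPPM", function(object) {
  cat("MotifPPM ", object@name, ": ", nrow(object@ppm), " bp, total IC ",
      round(sum(icProfile(object)), 2), " bits\n", sep = "")
})

setMethod("show", "MotifArchetype", function(object) {
  cat("MotifArchetype: ", nrow(object@ppm), " bp, ",
      length(object@members), " member motifs\n", sep = "")
})

setMethod("show", "MarkerSet", function(object) {
  cat("MarkerSet [", object@celltype, "]: ", length(object@genes),
      " genes at FC >= ", object@fcThreshold, "\n", sep = "")
})
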