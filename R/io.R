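# File I/O for the plain-text formats used across the package. Labels, not
# positions, are the join keys everywhere.

#' Read / write metacell FC tables
#'
#' The FC table is a TSV with gene labels in the first column and metacell
#' labels in the header; annotations travel in two sidecar TSVs
#' (metacell -> cell type, cell type -> broad type), written next to the
#' main table as `<path>.celltypes.tsv` and `<path>.broadtypes.tsv`.
#'
#' @param path TSV file path.
#' @param species species label to attach on read.
#' @param expr a [MetacellExpression-class] to write.
#' @return `readFcTable` returns a [MetacellExpression-class];
#'   `writeFcTable` returns `path` invisibly.
#' @export
readFcTable <- function(path, species = sub("\\.tsv$", "", basename(path))) {
  df <- read.delim(path, check.names = FALSE)
  fc <- as.matrix(df[, -1, drop = FALSE])
  rownames(fc) <- df[[1]]
  ctPath <- paste0(path, ".celltypes.tsv")
  btPath <- paste0(path, ".broadtypes.tsv")
  m2c <- if (file.exists(ctPath)) {
    a <- read.delim(ctPath, check.names = FALSE)
    setNames(as.character(a[[2]]), a[[1]])
  } else NULL
  c2b <- if (file.exists(btPath)) {
    a <- read.delim(btPath, check.names = FALSE)
    setNames(as.character(a[[2]]), a[[1]])
  } else character()
  MetacellExpression(species, fc, metacellToCelltype = m2c,
                     celltypeToBroadtype = c2b)
}

#' @rdname readFcTable
#' @export
writeFcTable <- function(expr, path) {
  stopifnot(is(expr, "MetacellExpression"))
  df <- data.frame(gene = rownames(expr@fc), expr@fc, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  m2c <- expr@metacellToCelltype
  write.table(data.frame(metacell = names(m2c), celltype = unname(m2c)),
              paste0(path, ".celltypes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (length(expr@celltypeToBroadtype)) {
    c2b <- expr@celltypeToBroadtype
    write.table(data.frame(celltype = names(c2b), broadtype = unname(c2b)),
                paste0(path, ".broadtypes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read / write homology pair tables
#'
#' Four-column TSV: `geneA`, `geneB`, `relation`, `setId`.
#'
#' @param path TSV file path.
#' @param map a [HomologyMap-class] to write.
#' @return `readHomologyMap` returns a [HomologyMap-class].
#' @export
readHomologyMap <- function(path) {
  df <- read.delim(path, check.names = FALSE,
                   colClasses = c("character", "character", "character",
                                  "character"))
  df$setId[df$setId %in% c("", "NA")] <- NA_character_
  HomologyMap(df)
}

#' @rdname readHomologyMap
#' @export
writeHomologyMap <- function(map, path) {
  stopifnot(is(map, "HomologyMap"))
  write.table(map@pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a UMI matrix from MatrixMarket or dense TSV
#'
#' For MatrixMarket input, `path` is the `.mtx` file and row/column labels
#' are read from `<path>.genes.txt` / `<path>.cells.txt` (one label per
#' line). Dense input is a TSV with genes in the first column.
#'
#' @param path `.mtx` or `.tsv` file.
#' @param cellToMetacell optional named character assignment.
#' @return a [UmiMatrix-class].
#' @export
readUmiMatrix <- function(path, cellToMetacell = character()) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(paste0(path, ".genes.txt"))
    colnames(m) <- readLines(paste0(path, ".cells.txt"))
  } else {
    df <- read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  }
  UmiMatrix(m, cellToMetacell)
}

#' @rdname readUmiMatrix
#' @param umi a [UmiMatrix-class] to write (sparse MatrixMarket plus label
#'   files).
#' @export
writeUmiMatrix <- function(umi, path) {
  stopifnot(is(umi, "UmiMatrix"), grepl("\\.mtx$", path))
  Matrix::writeMM(Matrix::Matrix(umi@counts, sparse = TRUE), path)
  writeLines(rownames(umi@counts), paste0(path, ".genes.txt"))
  writeLines(colnames(umi@counts), paste0(path, ".cells.txt"))
  invisible(path)
}

#' Read / write species trees in Newick format
#'
#' Thin wrappers over \pkg{ape} that enforce the package's species-tree
#' contract (unique leaf labels, a single root).
#'
#' @param path Newick file.
#' @param tree an `ape::phylo` object.
#' @return `readSpeciesTree` returns an `ape::phylo`.
#' @export
readSpeciesTree <- function(path) {
  tr <- ape::read.tree(path)
  if (anyDuplicated(tr$tip.label)) stop("leaf labels must be unique")
  tr
}

#' @rdname readSpeciesTree
#' @export
writeSpeciesTree <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}

#' Read / write motifs in MEME minimal text format
#'
#' @param path MEME-format text file.
#' @param motifs list of [MotifPPM-class] to write.
#' @return `readMeme` returns a list of [MotifPPM-class].
#' @export
readMeme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF", lines)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    name <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix", lines)
    hdr <- hdr[hdr > starts[i]][1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    block <- lines[(hdr + 1):(hdr + w)]
    ppm <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"),
                                 as.numeric))
    out[[i]] <- MotifPPM(name, ppm, source = basename(path))
  }
  out
}

#' @rdname readMeme
#' @export
writeMeme <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (m in motifs) {
    p <- motifMatrix(m)
    writeLines(c(paste("MOTIF", if (is(m, "MotifPPM")) m@name else "archetype"),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                         nrow(p))), con)
    writeLines(apply(p, 1L, function(r) paste(sprintf("%.8f", r),
                                              collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write protein sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
writeFastaSeqs <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
readFastaSeqs <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Serialize / deserialize planted ground truth
#'
#' Ground-truth descriptions produced by the synthetic-data generators are
#' plain nested lists; they round-trip losslessly through JSON.
#'
#' @param truth a truth list.
#' @param path JSON file path.
#' @return `readTruth` returns the truth list.
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
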