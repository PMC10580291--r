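# Deterministic sequence utilities: amino-acid alphabet recoding and
# neuropeptide-like signature scanning.

# the three published reduced-alphabet schemes; classes partition the 20
# canonical residues (asserted at load)
.recodingSchemes <- local({
  expand <- function(classes) {
    out <- character()
    for (sym in names(classes))
      for (aa in strsplit(classes[[sym]], "")[[1]])
        out[aa] <- sym
    out
  }
  schemes <- list(
    Dayhoff6 = expand(c("0" = "AGPST", "1" = "DENQ", "2" = "HKR",
                        "3" = "ILMV", "4" = "FWY", "5" = "C")),
    SR4 = expand(c(A = "AGNPST", C = "CHWY", G = "DEKQR", T = "FILMV")),
    SR6 = expand(c("0" = "APST", "1" = "DENG", "2" = "QKR",
                   "3" = "MIVL", "4" = "WC", "5" = "FYH"))
  )
  canonical <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (nm in names(schemes))
    stopifnot(setequal(names(schemes[[nm]]), canonical))
  schemes
})

#' Recode an amino-acid alignment into a reduced alphabet
#'
#' Maps residues per scheme -- Dayhoff6 (0 = AGPST, 1 = DENQ, 2 = HKR,
#' 3 = ILMV, 4 = FWY, 5 = C), SR4 (A = AGNPST, C = CHWY, G = DEKQR,
#' T = FILMV) or SR6 (0 = APST, 1 = DENG, 2 = QKR, 3 = MIVL, 4 = WC,
#' 5 = FYH). Gaps (`-`, `.`) are preserved; ambiguity codes
#' (X, B, Z, J, U, O, `*`) map to missing (`?`); any other character is
#' an error naming sequence and position. Alignment dimensions are
#' unchanged.
#'
#' @param msa named character vector of aligned sequences (or an
#'   `AAStringSet`).
#' @param scheme one of `"Dayhoff6"`, `"SR4"`, `"SR6"`.
#' @return named character vector of recoded sequences.
#' @examples
#' recodeAlignment(c(s1 = "DEKQR"), "SR4")   # "GGGGG"
#' @export
recodeAlignment <- function(msa, scheme = c("Dayhoff6", "SR4", "SR6")) {
  scheme <- match.arg(scheme)
  if (is(msa, "XStringSet")) msa <- setNames(as.character(msa), names(msa))
  map <- .recodingSchemes[[scheme]]
  gap <- c("-", ".")
  ambig <- c("X", "B", "Z", "J", "U", "O", "*")
  out <- vapply(seq_along(msa), function(i) {
    ch <- strsplit(toupper(msa[[i]]), "")[[1]]
    rec <- map[ch]
    rec[ch %in% gap] <- ch[ch %in% gap]
    rec[ch %in% ambig] <- "?"
    bad <- which(is.na(rec))
    if (length(bad))
      stop(sprintf("unknown character '%s' in sequence %s at position %d",
                   ch[bad[1]],
                   if (!is.null(names(msa))) names(msa)[i] else i, bad[1]))
    paste(rec, collapse = "")
  }, character(1))
  names(out) <- names(msa)
  out
}

#' Scan a protein for neuropeptide-like cleavage signatures
#'
#' Finds all (possibly overlapping and nested) occurrences of a core of 3
#' to 10 residues flanked by a dibasic pair (`[KR][KR]`) immediately at
#' the N-terminus and a glycine followed by a basic residue (`G[RK]`) at
#' the C-terminus. The glycine is reported as part of the C-flank (it is
#' the amide donor), not the core. Cores may themselves contain K, R or
#' G; for the same N-flank every admissible core length is reported.
#'
#' @param protein single amino-acid sequence (character).
#' @param id sequence id carried into the result (default `"seq"`).
#' @param coreRange admissible core lengths (default `c(3, 10)`).
#' @param longestOnly keep only the longest core per N-flank position
#'   (default FALSE: report all).
#' @return data.frame with columns `id`, `coreStart`, `coreEnd` (1-based
#'   inclusive on the input), `core`, `nFlank`, `cFlank`; zero rows when
#'   nothing matches.
#' @examples
#' scanNpSignatures("MKKAFNPWGRA")   # core "AFNPW", span (4, 8)
#' @export
scanNpSignatures <- function(protein, id = "seq", coreRange = c(3L, 10L),
                             longestOnly = FALSE) {
  stopifnot(length(protein) == 1L, coreRange[1] >= 1L,
            coreRange[2] >= coreRange[1])
  ch <- strsplit(toupper(protein), "")[[1]]
  n <- length(ch)
  basic <- c("K", "R")
  hits <- list()
  for (p in seq_len(max(0L, n - 3L))) {
    if (!(ch[p] %in% basic && ch[p + 1L] %in% basic)) next
    for (L in seq(coreRange[1], coreRange[2])) {
      gPos <- p + 2L + L
      if (gPos + 1L > n) break
      if (ch[gPos] == "G" && ch[gPos + 1L] %in% basic) {
        hits[[length(hits) + 1L]] <- data.frame(
          id = id, coreStart = p + 2L, coreEnd = p + 1L + L,
          core = paste(ch[(p + 2L):(p + 1L + L)], collapse = ""),
          nFlank = paste(ch[p:(p + 1L)], collapse = ""),
          cFlank = paste(ch[gPos:(gPos + 1L)], collapse = ""))
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(id = character(), coreStart = integer(),
               coreEnd = integer(), core = character(),
               nFlank = character(), cFlank = character())
  if (longestOnly && nrow(out)) {
    out <- do.call(rbind, lapply(split(out, out$coreStart), function(d)
      d[which.max(d$coreEnd), , drop = FALSE]))
    rownames(out) <- NULL
  }
  out
}
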