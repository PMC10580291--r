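# Per-species co-expression module detection and cross-species module
# integration by ortholog overlap.

#' Module eigengene
#'
#' First principal component scores of the standardized module submatrix
#' across metacells: each gene's ln(FC) profile is z-scored, and the first
#' right-singular vector of the genes x metacells matrix gives the
#' per-metacell eigengene. The sign is oriented so the eigengene correlates
#' positively with the module's mean standardized expression.
#'
#' @param genes module gene labels (>= 2).
#' @param expr a [MetacellExpression-class].
#' @return numeric eigengene over metacells (named).
#' @export
moduleEigengene <- function(genes, expr) {
  stopifnot(is(expr, "MetacellExpression"), length(genes) >= 2L)
  X <- log(expr@fc[genes, , drop = FALSE])
  sds <- apply(X, 1L, sd)
  if (all(sds == 0)) stop("zero-variance module")
  X <- X[sds > 0, , drop = FALSE]
  Z <- t(scale(t(X)))
  sv <- svd(Z, nu = 0, nv = 1)
  e <- sv$v[, 1] * sv$d[1]
  m <- colMeans(Z)
  if (sum(e * m) < 0) e <- -e
  setNames(e, colnames(expr@fc))
}

# mean silhouette width of a flat clustering under a dissimilarity matrix
.meanSilhouette <- function(cl, diss) {
  ids <- unique(cl)
  if (length(ids) < 2L) return(-Inf)
  s <- vapply(seq_along(cl), function(i) {
    own <- cl[i]
    within <- diss[i, cl == own]
    if (length(within) <= 1L) return(0)   # singleton convention
    a <- sum(within) / (length(within) - 1L)
    b <- min(vapply(setdiff(ids, own), function(k)
      mean(diss[i, cl == k]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Detect co-expression modules within one species
#'
#' Variable genes (FC >= `fcMin` in at least one metacell) are correlated
#' pairwise on ln(FC); a signed adjacency `((1 + r)/2)^softPower` is
#' converted to the dissimilarity `1 - a` and clustered by average-linkage
#' hierarchical clustering. The dendrogram is cut at the height (over the
#' merge-height grid) maximizing the mean silhouette width; clusters
#' smaller than `minSize` are discarded, and each gene is finally kept in
#' its module only if its correlation with the module eigengene reaches
#' `assignR` (otherwise unassigned). Every gene ends up in at most one
#' module.
#'
#' @param expr a [MetacellExpression-class].
#' @param fcMin variable-gene fold-change floor (default 1.25).
#' @param softPower soft-thresholding exponent (default 7).
#' @param minSize minimum module size (default 10).
#' @param assignR eigengene-correlation threshold for final gene
#'   assignment (default 0.7).
#' @param maxCutCandidates number of distinct cut heights examined
#'   (default 25).
#' @return a [GeneModuleSet-class]; empty (with a warning) when fewer than
#'   `minSize` variable genes exist.
#' @export
detectModules <- function(expr, fcMin = 1.25, softPower = 7L, minSize = 10L,
                          assignR = 0.7, maxCutCandidates = 25L) {
  stopifnot(is(expr, "MetacellExpression"))
  fc <- expr@fc
  variable <- rownames(fc)[apply(fc, 1L, max) >= fcMin]
  if (length(variable) < minSize) {
    warning("fewer than ", minSize, " variable genes; no modules detected")
    return(new("GeneModuleSet", species = expr@species,
               membership = setNames(character(), character()),
               eigengenes = matrix(0, 0, ncol(fc),
                                   dimnames = list(NULL, colnames(fc))),
               kme = setNames(numeric(), character())))
  }
  X <- t(log(fc[variable, , drop = FALSE]))
  r <- suppressWarnings(cor(X))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  adj <- ((1 + r) / 2)^softPower
  diss <- 1 - adj
  hc <- hclust(as.dist(diss), method = "average")
  heights <- unique(hc$height)
  if (length(heights) > maxCutCandidates)
    heights <- quantile(heights, seq(0.05, 0.95,
                                     length.out = maxCutCandidates),
                        names = FALSE)
  best <- NULL; bestSil <- -Inf
  for (h in heights) {
    cl <- cutree(hc, h = h)
    if (length(unique(cl)) < 2L || length(unique(cl)) == length(cl)) next
    sil <- .meanSilhouette(cl, diss)
    if (sil > bestSil) { bestSil <- sil; best <- cl }
  }
  if (is.null(best)) best <- cutree(hc, k = min(2L, length(variable)))
  sizes <- table(best)
  keepIds <- names(sizes)[sizes >= minSize]
  membership <- character(0)
  kme <- numeric(0)
  egList <- list()
  mid <- 0L
  for (id in keepIds) {
    genes <- variable[best == id]
    eg <- tryCatch(moduleEigengene(genes, expr), error = function(e) NULL)
    if (is.null(eg)) next
    cors <- vapply(genes, function(g)
      suppressWarnings(cor(log(fc[g, ]), eg)), numeric(1))
    cors[!is.finite(cors)] <- 0
    assigned <- genes[cors >= assignR]
    if (length(assigned) < minSize) next
    mid <- mid + 1L
    modName <- sprintf("M%02d", mid)
    membership[assigned] <- modName
    kme[assigned] <- cors[assigned]
    egList[[modName]] <- moduleEigengene(assigned, expr)
  }
  eigengenes <- if (length(egList)) do.call(rbind, egList) else
    matrix(0, 0, ncol(fc), dimnames = list(NULL, colnames(fc)))
  new("GeneModuleSet", species = expr@species, membership = membership,
      eigengenes = eigengenes, kme = kme)
}

#' Cluster modules across species by orthogroup overlap
#'
#' Modules from different species are linked when the Jaccard index of
#' their orthogroup sets reaches `jaccardMin`; connected components of the
#' resulting graph are the multi-species module clusters. Modules of the
#' same species are never linked directly.
#'
#' @param moduleSets list of [GeneModuleSet-class], one per species.
#' @param orthogroups named character gene -> orthogroup id (genes of all
#'   species share this namespace).
#' @param jaccardMin edge threshold (default 0.1).
#' @return a [MultiSpeciesModuleSet-class]; module ids are
#'   `"species|module"`.
#' @export
clusterModulesAcrossSpecies <- function(moduleSets, orthogroups,
                                        jaccardMin = 0.1) {
  ogSets <- list()
  for (ms in moduleSets) {
    memb <- ms@membership
    for (mod in unique(memb)) {
      genes <- names(memb)[memb == mod]
      og <- unique(orthogroups[genes])
      og <- og[!is.na(og)]
      ogSets[[paste(ms@species, mod, sep = "|")]] <- og
    }
  }
  ids <- names(ogSets)
  spOf <- sub("\\|.*", "", ids)
  edges <- data.frame(moduleA = character(), moduleB = character(),
                      jaccard = numeric())
  if (length(ids) >= 2L) {
    cmb <- combn(length(ids), 2L)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      if (spOf[i] == spOf[j]) next
      u <- length(union(ogSets[[i]], ogSets[[j]]))
      if (u == 0) next
      jc <- length(intersect(ogSets[[i]], ogSets[[j]])) / u
      if (jc >= jaccardMin)
        edges <- rbind(edges, data.frame(moduleA = ids[i], moduleB = ids[j],
                                         jaccard = jc))
    }
  }
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  components <- split(ids, comp$membership)
  names(components) <- sprintf("MS%02d", seq_along(components))
  new("MultiSpeciesModuleSet", components = unname(components),
      edges = edges, jaccardMin = jaccardMin)
}

#' Score multi-species module activity per cell type
#'
#' For one multi-species module cluster, the fraction of its member genes
#' with FC >= `activeFc` is computed in every cell type of every member
#' species, then averaged over member species per matched cell-type label.
#'
#' @param msComponent character vector of member module ids
#'   (`"species|module"`), one element of
#'   `MultiSpeciesModuleSet@components`.
#' @param moduleSets list of [GeneModuleSet-class] named by species.
#' @param fcTables list of genes x cell-types FC matrices named by
#'   species.
#' @param activeFc activity threshold (default 1.5).
#' @return named numeric vector of per-cell-type active fractions in
#'   \[0,1\].
#' @export
scoreModuleActivity <- function(msComponent, moduleSets, fcTables,
                                activeFc = 1.5) {
  sp <- sub("\\|.*", "", msComponent)
  mod <- sub(".*\\|", "", msComponent)
  perSpecies <- list()
  for (k in seq_along(msComponent)) {
    ms <- moduleSets[[sp[k]]]
    genes <- names(ms@membership)[ms@membership == mod[k]]
    if (!length(genes)) stop("empty module: ", msComponent[k])
    tab <- fcTables[[sp[k]]]
    genes <- intersect(genes, rownames(tab))
    if (!length(genes)) stop("module genes absent from FC table: ",
                             msComponent[k])
    frac <- colMeans(tab[genes, , drop = FALSE] >= activeFc)
    perSpecies[[k]] <- frac
  }
  cts <- sort(unique(unlist(lapply(perSpecies, names))))
  out <- vapply(cts, function(ct) {
    vals <- unlist(lapply(perSpecies, function(f) f[ct]))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  setNames(out, cts)
}
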