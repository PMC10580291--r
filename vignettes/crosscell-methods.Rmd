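---
title: "Cross-species comparison of single-cell atlases with crosscell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species comparison of single-cell atlases with crosscell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosscell)
```

# The problem

Whole-body single-cell atlases of distantly related animals cannot be
compared cell-by-cell: the species have different numbers of cell states,
no shared coordinate system, and genes related by complicated
ortholog/paralog histories. `crosscell` implements a comparative toolkit
for metacell-level atlases — expression summarized as fold change (FC),
the regularized geometric mean of a gene's expression within a metacell
divided by its median across metacells — that works entirely through
gene-gene and gene-set relationships, so no cell-state matching between
species is ever required.

The pipeline has six stages, each usable on its own:

1. **Expression conservation (ICC).** For a pair of species, each
   one-to-one ortholog pair is represented by its within-species
   co-expression profile — the vector of correlations (on ln FC, across
   metacells) with every other matched gene. The correlation between the
   two species' profiles of a pair is its expression-conservation score
   EC, clamped to $[0,1]$. Because a profile lives in gene space rather
   than metacell space, profiles are comparable even when the atlases
   have different numbers of metacells ($m_a \neq m_b$). Iterating —
   recomputing the between-species correlation as a *weighted* Pearson
   over the gene-pair dimensions with the previous EC vector as weights —
   concentrates the comparison on pairs that are already conserved. The
   iteration stops when $\sum_i (EC_i - EC_{i-1})^2 < 0.05$ or after 20
   rounds. Paralog sets are resolved by appending each candidate pair to
   a reference panel of up to 1,000 random one-to-one pairs, recomputing
   EC to convergence, and keeping the candidate with the highest score.
2. **Cell-type similarity and trees.** Cell-type-level FC vectors of
   matched gene pairs are quantile-normalized against each other and
   compared by EC-weighted Pearson correlation. For trees, marker
   expression is binarized (FC $\ge 2$, availability in $\ge 70\%$ of
   cell types), pairwise Log-Det (paralinear) distances are computed from
   the $2\times2$ joint state tables, and UPGMA builds the tree with
   Felsenstein bootstrap supports from resampling characters.
3. **Gene modules.** Per species, variable genes (FC $\ge 1.25$
   anywhere) are clustered on a signed adjacency
   $((1+r)/2)^7$ with average linkage; clusters under 10 genes are
   dropped and genes are kept only if they correlate $\ge 0.7$ with the
   module eigengene (first principal component of the z-scored ln FC
   submatrix). Modules are then linked across species when the Jaccard
   index of their orthogroup sets is $\ge 0.1$, and connected components
   form multi-species modules whose activity is the fraction of member
   genes with FC $\ge 1.5$ per cell type.
4. **Ancestral expression programs.** Binary characters (orthogroup
   expressed in a species' target metacells: any member gene with FC
   $\ge 2$ in $\ge 25\%$ of them) are reconstructed on a species tree
   under Dollo parsimony: one gain at the MRCA of the present species,
   losses on the branches into maximal all-absent subtrees.
5. **Cell-state statistics.** AUC scores for dual marker-program
   expression, exact binomial tests for doublet origin of intermediate
   cells and for cross-species marker conservation, cycling-cell calls
   from standardized log10 cell-cycle UMI fractions, and rule-based
   metacell quality filters.
6. **Motif archetypes and small screens.** Information-content filtering
   of position probability matrices, best-offset/strand similarity of
   IC-weighted matrices, average-linkage clustering into archetypes,
   98th-percentile scan-threshold calibration, hypergeometric enrichment
   with a permutation FDR; plus SR4/SR6/Dayhoff6 alphabet recoding and
   the dibasic neuropeptide-cassette scanner (`[KR][KR]`-core(3–10)-`G[RK]`).

# Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `epsilon`, `librarySize` | 1, 10,000 | FC regularization pseudocount and per-cell scaling target (counts). |
| `tol`, `maxIterations` | 0.05, 20 | ICC stopping rule on the squared EC change, and iteration cap. |
| `nReference` | 1,000 | one-to-one pairs in the paralog reference panel. |
| `fcThreshold`, `minPresenceFraction` | 2, 0.7 | marker binarization floor; data-availability filter. |
| `fcMin`, `softPower`, `minSize`, `assignR` | 1.25, 7, 10, 0.7 | module detection: variable-gene floor, adjacency exponent, minimum module size, eigengene assignment threshold. |
| `jaccardMin` | 0.1 | cross-species module linking threshold. |
| `activeFc` | 1.5 | module-activity floor per cell type. |
| `fcThreshold`, `minFraction` (characters) | 2, 0.25 | expression-character rule over target metacells. |
| `quantileCut` | 0.95 | cycling-cell z cutoff (standard-normal quantile, 1.6449). |
| `similarityThreshold`, `minOverlap` | 0.80, 6 | motif clustering cut and minimum alignment overlap (bp). |
| `percentile`, `subsampleFraction` | 98, 0.1 | scan-threshold calibration. |

Expression-character selection is also meaningful at `minFraction =
0.10` (a broader inclusion rule); both values are plain arguments.

# Numerical choices and degenerate inputs

* **Fold change.** `fcFromUmi` keeps the regularization pseudocount in
  both the geometric mean and its across-metacell median, so every FC is
  finite and strictly positive even for genes absent from most
  metacells; a zero median cannot then occur, but the defensive branch
  (flag the gene, set FC to 1, warn) is retained.
* **Undefined correlations.** Zero-variance vectors make a Pearson
  correlation undefined; `weightedPearson` returns `NA` and each
  consumer states its convention. Co-expression profiles use 0;
  constant genes are pinned to EC 0 at every ICC iteration, since a
  degenerate profile carries no comparable signal.
* **Log-Det degeneracies.** A zero marginal (a taxon constant across the
  shared characters) makes the distance undefined: a capped value of 10
  is returned with a warning, and such tables invalidate a bootstrap
  replicate. A *negative* determinant (net negative association, common
  between unrelated cell types) also saturates at the cap but does not
  discard the replicate — treating it as degenerate would throw away
  nearly every replicate on sparse binary data.
* **Ties.** Quantile normalization averages target values over tied
  blocks; UPGMA operates on a lexicographically ordered distance matrix;
  paralog and motif-seed ties break by lexicographic label order; gene
  ranking in AUC scores breaks FC ties by gene label.
* **Module tree cut.** The dendrogram is cut at the height (over the
  merge-height grid, at most 25 candidates) maximizing the mean
  silhouette width, with the convention that singletons score 0. This
  static cut replaces a hybrid dynamic tree cut: it is deterministic,
  dependency-free, and on planted block structure selects the same
  partition; the min-size and eigengene-assignment rules are applied
  verbatim afterwards. Signed (not unsigned) adjacency is used so
  anti-correlated genes are never co-clustered.
* **Exact tests.** The two-tailed binomial test uses the
  minimum-likelihood ("minlike") convention — all outcomes with point
  probability at most that of the observation (with the conventional
  $1+10^{-7}$ tie guard) — so the modal outcome gives exactly $p = 1$.
  The doublet null probability is the plain product $f_1 f_2$ of the
  terminal-type fractions; a flag doubles it for unordered collisions.
* **Motif scanning.** Log-odds scores use a uniform background with a
  $10^{-3}$ probability floor; windows containing non-ACGT characters
  score $-\infty$ and are excluded from calibration.

# What the synthetic atlases emulate — and what they do not

`generateAtlases` plants, in log-FC space, cell-type-specific profiles
shared across species (conserved genes), independent per-species
profiles (diverged genes), co-expression modules (a shared cell-type
program plus small per-gene offsets), paralog sets with one
expression-retaining member, and optionally a hierarchical cell-type
tree in which every profile is a sum of independent Gaussian clade
effects — so cell-type relatedness itself is hierarchical, as in real
atlases — plus dedicated exclusive clade markers. Per-metacell Gaussian
noise (default sd 0.3 on the log scale) and species-specific metacell
counts (3–5 per type) make the two atlases deliberately unmatched.
`generateUmi` draws terminal cells multinomially from metacell profiles
(2,000 UMIs per cell by default), converts a configured fraction into
50/50 doublets of random cell-type pairs, adds intermediate cells that
express a down-sampled subset of both parental marker programs at full
program-level UMI mass (the regime in which percentile-based dual-marker
thresholds are attainable at all), and gives cycling cells a 5-fold
load on a cell-cycle gene set. `generateDolloCharacters` simulates
canonical single-gain histories (the gain is the MRCA of the surviving
leaves, every present node keeps a surviving child), so the planted
history is exactly the minimal scenario and recovery is unambiguous.

These generators validate the *algorithms*, not the biology: they have
no ambient RNA, no batch effects, no library-size gradients, Gaussian
(not overdispersed) expression noise, and clean orthology. Passing the
planted-truth tests shows the methods recover what they are designed to
recover under their own model assumptions; it does not certify
performance on real atlases.

Problem sizes used by the validation suite and the acceptance script —
400-gene two-species atlases for conservation scoring, 300-gene
four-species atlases for modules, 200 random 8-leaf trees for the Dollo
oracle, 200 bootstrap replicates, 30 motifs, 10-kb peptide screens —
were chosen so every planted effect is recovered with wide margins while
the whole suite stays quick on a laptop.

# A worked example

```{r example}
sim <- generateAtlases(nGenes = 120, nModules = 3, moduleSize = 15,
                       conservedFraction = 0.5, noiseSd = 0.3,
                       nParalogSets = 5, seed = 3)
ec <- computeEC(sim$atlases$spA, sim$atlases$spB, sim$homology)
ec
p <- ecPairs(ec)
cls <- unlist(sim$truth$conservationClass)[sub("^spA_", "", p$geneA)]
tapply(p$ec, cls, mean)
```

Conserved pairs score far higher than diverged ones. Downstream, the
EC vector weights every cell-type comparison:

```{r example2}
sm <- celltypeSimilarity(celltypeFc(sim$atlases$spA),
                         celltypeFc(sim$atlases$spB), ec)
round(sm@similarity, 2)
```

The diagonal — homologous cell types carry the same label in the
simulation — dominates each row and column.

# Known limitations

* ICC is strictly pairwise; multi-species analyses are built from
  pairwise EC vectors, and within-species co-expression profiles are
  held fixed across iterations (only the between-species correlation is
  re-weighted). The alternative — re-weighting the within-species
  correlations too — is untested here and left for sensitivity analysis.
* The marker-availability reading of the 70% binarization filter is a
  design choice (the broad-expression reading would discard exactly the
  specific markers the trees rely on); the filter operates on data
  availability, not expression breadth.
* Whether module overlap should use orthogroup sets or gene sets is
  resolved in favor of orthogroups; the threshold is exposed
  (`jaccardMin`) for either convention.
* The Dollo machinery distinguishes missing (no gene in the genome)
  from absent (gene present, not expressed); missing leaves are excluded
  from MRCA and loss accounting. Characters observed in a single species
  are retained as lineage-specific gains.
* Naive $O(nL)$ motif scanning; no indexing or genome-scale
  optimizations.
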