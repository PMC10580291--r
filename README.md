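# crosscell

Cross-species comparison of single-cell expression atlases.

Whole-body atlases of distantly related animals cannot be matched cell
by cell: species differ in their cell states, their metacell counts,
and their gene complements. `crosscell` compares such atlases entirely
through gene-level relationships, for comparative biologists working
with metacell-level fold-change (FC) tables — expression summarized as
the regularized geometric mean within a metacell divided by the
per-gene median across metacells.

At its core is the **iterative comparison of co-expression (ICC)**.
Each one-to-one ortholog pair $(g_a, g_b)$ between species $a$ and $b$
is represented by its within-species co-expression profiles — the
vectors of Pearson correlations of $g_a$ (resp. $g_b$) with every other
matched gene on $\ln \mathrm{FC}$ across metacells. The
**expression-conservation score** is

$$EC_0(g_a,g_b) = \max\!\big(0,\ \mathrm{cor}\big(P_a[g_a,\cdot],\,P_b[g_b,\cdot]\big)\big),$$

and each iteration recomputes that correlation as a weighted Pearson
over the $n$ gene-pair dimensions using the previous EC vector as
weights, until $\sum_i (EC_i - EC_{i-1})^2 < 0.05$ (or 20 iterations).
Because profiles live in gene space, the two atlases never need the
same number of metacells. Paralog sets are resolved to the candidate
pair with the highest EC against a 1,000-pair random ortholog reference
panel.

Around the EC scores the package provides:

* EC-weighted, quantile-normalized cell-type similarity and cell-type
  trees from binarized markers (Log-Det paralinear distances, UPGMA,
  Felsenstein bootstrap);
* per-species co-expression modules (signed adjacency, eigengenes) and
  cross-species module clusters by orthogroup Jaccard overlap;
* Dollo-parsimony reconstruction of binary expression characters on a
  species tree (single gain at the MRCA, minimal losses);
* statistics for intermediate, doublet and cycling cells (AUC scores,
  exact binomial tests, standardized cell-cycle load) and metacell
  quality filters;
* motif-archetype construction from position probability matrices (IC
  filtering, offset/strand alignment, average-linkage clustering,
  98th-percentile scan thresholds, hypergeometric enrichment with a
  permutation FDR);
* SR4/SR6/Dayhoff6 amino-acid recoding and a neuropeptide-cassette
  scanner (`[KR][KR]` + 3–10-residue core + `G[RK]`);
* synthetic multi-species atlas generators with machine-readable
  planted truth, so every stage is testable without external data.

## Worked example

```r
library(crosscell)

sim <- generateAtlases(nGenes = 120, nModules = 3, moduleSize = 15,
                       conservedFraction = 0.5, noiseSd = 0.3,
                       nParalogSets = 5, seed = 3)
ec <- computeEC(sim$atlases$spA, sim$atlases$spB, sim$homology)
ec
#> ECWeights: 115 pairs; mean EC 0.556; 2 iterations (converged)

p <- ecPairs(ec)
cls <- unlist(sim$truth$conservationClass)[sub("^spA_", "", p$geneA)]
tapply(p$ec, cls, mean)
#> conserved  diverged
#> 0.8841612 0.2557380
```

Genes planted with conserved cell-type programs score a mean EC of
0.88; genes with independently drawn per-species programs score 0.26 —
the separation ICC is built to deliver. The EC vector then weights the
cell-type comparison:

```r
sm <- celltypeSimilarity(celltypeFc(sim$atlases$spA),
                         celltypeFc(sim$atlases$spB), ec)
round(sm@similarity, 2)
#>       T01   T02   T03   T04   T05   T06
#> T01  0.24 -0.11 -0.01  0.16 -0.14 -0.09
#> T02 -0.14  0.93 -0.04 -0.13 -0.29 -0.27
#> ...
```

Homologous cell types (same label across the simulated species) are
reciprocal best hits in every row and column; the three module-bearing
cell types (T02, T05, T06) stand out because their shared programs
dominate the weighted correlation.

See `vignettes/crosscell-methods.Rmd` for the model, parameter and
design documentation.

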