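# primeNet

Does a brief heat exposure early in life change how an animal copes with
heat later — and does the answer depend on its genotype? `primeNet`
implements the transcriptomic inference chain used to ask that question in
a 2-family × 2-priming × 2-temperature common-garden design (thermally
primed vs. naive oyster spat, later exposed to control or heat-stress
temperature):

1. **Preprocessing** — CPM-based low-expression filtering, median-of-ratios
   size factors, `log2(count / sf + 1)` normalization, low-variance gene
   removal and sample-connectivity outlier removal.
2. **Differential expression** — per-gene negative-binomial GLMs (log link,
   size-factor offset, method-of-moments dispersion) tested by
   likelihood-ratio (priming, temperature, interaction models) or Wald
   contrasts, with Benjamini–Hochberg FDR.
3. **Signed co-expression networks** per family — adjacency
   `a_ij = ((1 + cor_ij)/2)^β` (β = 6), topological overlap
   `TOM_ij = (ℓ_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`, average-linkage
   clustering with a static percentile-height cut (minimum module size 50,
   eigengene merge threshold 0.25), module eigengenes (first principal
   component), kME, gene significance, and module–trait Spearman
   correlations.
4. **Module preservation** across families — seven statistics (average edge
   weight, coherence, average/concordance of node contribution, average
   signed correlation, concordance of correlation structure, concordance of
   weighted degree) against a permutation null that re-draws gene sets of
   module size from the test dataset; p = (b + 1)/(N + 1), one-sided.
5. **Candidate triangulation** — module genes that are simultaneously DEGs,
   in the top decile of gene significance for priming and in the top decile
   of intramodular weighted degree; candidate-centered subnetworks with
   top-correlated neighbors, quantile-binarized edges, cross-family module
   tags ("NI" for genes absent from the other family) and GraphML/TSV
   export.
6. **Enrichment** — delta-rank Mann–Whitney tests on log2 fold-changes (or
   kME-or-zero vectors) for single-class annotations, pairwise Pearson
   correlation of delta ranks across contrasts, and Fisher exact tests for
   term sets.
7. **Phenotypes** — Kaplan–Meier survival, LT50 (first time survival drops
   to 50%), Fleming–Harrington G^ρ group tests (ρ = 0 log-rank, ρ = 1
   Wilcoxon-type, chosen by a curve-crossing rule), and allometric
   standardization of respiration rates, `Ys = (Ws/We)^b · Ye` with
   b = 0.75.

A synthetic-data generator (`simulateExperiment()`) plants the full ground
truth — trait-linked module eigengenes, one module whose co-expression
structure is scrambled in family A, hub-DE candidate genes, background DE
genes — so every stage of the chain can be validated end to end.

## Worked example

```r
library(primeNet)

se <- simulateExperiment(simConfig(seed = 1))     # 4,000 genes, 48 samples
design <- as.data.frame(SummarizedExperiment::colData(se))
gt <- S4Vectors::metadata(se)$groundTruth

prep <- function(f) {
  cts <- filterLowExpression(SummarizedExperiment::assay(se)[, design$family == f])
  removeConnectivityOutliers(filterLowVariance(normalizeCounts(cts)))
}
exprA <- prep("A"); exprB <- prep("B")

nwB <- buildNetwork(exprB)                        # family B network
nwB$modules
#> ModuleSet with 4 modules over 4000 genes
#>   sizes: ME1=942, ME2=850, ME3=210, ME4=112
#>   unassigned (label 0): 1886 genes

pres <- modulePreservation(exprB, exprA, gt$module_labels[rownames(exprB)],
                           preservationConfig(n_permutations = 1000, seed = 1))
round(preservationPValues(pres), 3)
#>     avg_weight coherence avg_contrib cor_contrib avg_cor cor_cor cor_degree
#> ME1      1.000     1.000       0.136       0.741   0.005   0.991      0.712
#> ME2      0.001     0.001       0.001       0.001   0.001   0.001      0.001
#> ME3      0.001     0.001       0.001       0.001   0.001   0.001      0.001
#> ME4      0.001     0.001       0.001       0.001   0.001   0.001      0.001
```

(The preservation call scores the planted module gene sets; detected
cluster sizes are larger than the planted ones because temperature-driven
background DE genes legitimately co-express and ride along with
temperature-linked modules.) Modules 2–4 are preserved in family A (every
statistic at the permutation floor); module 1 — the module correlated with
both priming and temperature — fails on average edge weight, coherence and
concordance of correlation structure (p ≈ 1): its genes are still
expressed in family A but no longer co-expressed, the genotype-dependent
network reorganization the pipeline is built to detect.
Candidate triage on that module then intersects DEGs with the top decile of
gene significance and intramodular degree:

```r
de  <- runDE(filterLowExpression(SummarizedExperiment::assay(se)[, design$family == "B"]),
             design[design$family == "B", ], "temperature")
deg <- weightedDegree(nwB$network, gt$module_labels[rownames(exprB)], "intramodular")
gs  <- geneSignificance(exprB, codeTraits(design[colnames(exprB), ])[, "priming"])
cand <- triangulateCandidates(de$gene[de$significant], gs, deg,
                              names(which(gt$module_labels == 1)))
mean(gt$candidates %in% cand)
#> [1] 1
```

All ten planted hub-DE candidates are recovered. `runPipeline()` chains the
whole analysis (both families, both preservation directions, enrichment)
and writes every table plus a JSON run manifest to an output directory.

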