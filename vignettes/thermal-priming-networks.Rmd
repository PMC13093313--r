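---
title: "Detecting genotype-dependent thermal-priming memory with co-expression networks"
author: "primeNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genotype-dependent thermal-priming memory with co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the inference chain

Hormetic thermal priming — a brief sublethal heat exposure during early
development — may leave a transcriptomic "memory" that changes how an
animal responds to heat later in life. Whether that memory helps or hurts
can depend on genotype. `primeNet` implements the full inference chain for
a 2-family × 2-priming × 2-temperature factorial transcriptome experiment:
per-family differential expression, per-family signed co-expression
networks, cross-family module-preservation permutation tests, candidate
triangulation inside non-preserved modules, rank-based functional
enrichment, and thermal-tolerance phenotype scoring. The evidence for
genotype-dependent memory is a module that is coherent in one family,
trait-correlated, and *not preserved* in the other family.

This vignette documents the models, their assumptions, the tunable
parameters, and the design decisions taken where the design was genuinely
open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Preprocessing

* **Low-expression filter.** A gene is kept when it reaches `min_cpm`
  (default 1) counts-per-million in at least `min_samples` (default 4)
  samples. We read the filtering rule as a *keep* rule — genes expressed in
  at least four individuals are retained — because only that reading
  produces a large retained gene set from a sparse count matrix; the
  wording "low-abundance in at least four individuals removed" is ambiguous
  between keep and drop readings, and both thresholds are configurable.
* **Normalization.** Median-of-ratios size factors (per-sample median of
  count / per-gene geometric mean over genes expressed everywhere),
  followed by `log2(count / sf + 1)`. This is a deliberate, documented
  stand-in for a blind variance-stabilizing transformation: it preserves
  the variance-curbing intent without re-implementing dispersion-trend
  fitting, at the cost of exact numerical parity with vst output.
* **Variance filter.** Genes with normalized-expression variance below
  0.05 (unbiased, n−1 denominator) are dropped before network
  construction. Genes dropped in one family but kept in the other are the
  "NI" genes that later annotate cross-family subnetworks.
* **Sample outliers.** Sample connectivity is
  $k_s = \sum_{t \ne s} (1 + \mathrm{cor}(s, t))/2$; samples with
  connectivity z-score below −2.5 are removed in one pass. The cutoff is
  applied one-sided on the *low* tail: an outlying individual decorrelates
  from its cohort, it does not over-correlate. The sign is a design choice
  (the threshold is conventionally quoted unsigned); the magnitude is
  configurable.

## Differential expression

Each gene is fitted with a log-link negative-binomial GLM with a
`log(size factor)` offset. Dispersion is a per-gene method-of-moments
estimate on normalized counts pooled within design cells,
$\alpha_g = \max(10^{-8}, (s^2 - \bar\mu)/\bar\mu^2)$, held fixed between
the full and reduced fits so likelihood-ratio statistics remain valid for
nested models. There is deliberately **no** empirical-Bayes dispersion
shrinkage: that machinery belongs to the approximated upstream tool, and
per-gene MoM with a floor is the documented substitute — DEG counts from
real data will therefore not numerically match shrinkage-based results.

Three LRTs mirror the factorial questions — temperature (dropped from
priming + temperature), priming (dropped likewise), and the interaction
(dropped from the full factorial). The reduced model for each test is a
package decision; only the tested effect is stated by the design. Wald
contrasts on the same fits serve grouped comparisons. Genes whose IRLS fit
fails to converge (at most 50 iterations, relative deviance tolerance
1e-8) get `p = NA` and are excluded from the Benjamini–Hochberg
multiplicity count rather than silently dropped. Significance defaults to
FDR < 0.01.

## Signed networks and modules

The gene–gene adjacency is $a_{ij} = ((1 + r_{ij})/2)^\beta$ with
$\beta = 6$ and Pearson correlation on normalized expression (Pearson is
the network convention even though module–trait correlations below are
Spearman). A signed network maps strong negative correlation near 0, so
anti-correlated gene sets form separate modules. `pickSoftPower()` selects
the smallest power whose scale-free fit index (signed $R^2$ of
$\log_{10} p(k)$ on $\log_{10} k$ over 10 connectivity bins, negated for a
positive slope) reaches the target, defaulting to 0.8.

Topological overlap credits shared neighborhoods:
$\mathrm{TOM}_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$.
Modules are average-linkage clusters of $1 - \mathrm{TOM}$, cut at a
fixed quantile of the dendrogram merge heights; clusters under
`min_module_size = 50` become background (label 0), and modules whose
eigengenes correlate above $1 - 0.25$ are iteratively merged.

**Why a static percentile cut, and why the 0.7 quantile.** The dynamic
hybrid tree cut used by the established network package is a large
branch-shape heuristic out of proportion to its role here; a static cut at
a merge-height percentile is transparent and configurable. The default
quantile is 0.70: co-expression modules finish agglomerating in the lower
half of the merge-height distribution while unstructured background genes
coalesce near the top, so a cut between the two isolates modules and
shatters the background into sub-threshold fragments. Cuts near the top of
the height distribution (e.g. the 99th percentile) sit *inside* the
background agglomeration range and merge distinct modules — with planted
data they visibly degrade recovery, which is why the default moved down.
A static global cut also constrains the data it can resolve: two modules
driven by the same trait in the same direction merge below any usable
height. This is a known limitation, not a removable one.

Module eigengenes are first principal components of the standardized
member genes, scaled to unit variance and oriented so the mean member kME
is positive. Gene significance is $|\mathrm{cor}(x_g, \text{trait})|$;
module–trait associations use Spearman rank correlation (exact p for
n ≤ 9, t approximation otherwise) against the coded priming (−1/+1),
temperature (−1/+1) and weight traits.

## Module preservation

A discovery module is scored in the test family by seven statistics
computed on the module's gene positions in the test data: average edge
weight, coherence (share of module variance explained by the module
summary profile), average and concordance of node contribution, average
signed correlation, concordance of correlation structure (`cor_cor`), and
concordance of intramodular weighted degree. The permutation null re-draws
gene sets of module size from **all** test-dataset genes (module members
included — the simplest exchangeable null; exclusion is flag-switchable)
and recomputes every statistic against frozen discovery-side references.
P-values use the $(b+1)/(N+1)$ estimator with the one-sided "greater"
alternative — preservation predicts large values — so they can never be
exactly 0 and the test is valid at any $N$. Defaults are $N = 10{,}000$
and a per-statistic threshold of $10^{-4}$; a module is called
not-preserved when *any* requested statistic fails (small p on a statistic
is evidence of preservation for that statistic; the failing statistics are
listed with the verdict).

## Candidate triangulation and subnetworks

Within a target (typically non-preserved) module, candidates are genes
that are simultaneously (i) significant DEGs, (ii) at or above the 0.90
quantile of gene significance for priming within the module, and (iii) at
or above the 0.90 quantile of intramodular weighted degree. Quantile
boundaries include ties, so the operation is deterministic. "Top decile"
is the operational reading of the selection region; a top-k variant is a
trivial caller-side change since the quantiles are parameters.

Around a candidate, the `top_corr_fraction` (default 1%) most correlated
genes are selected (signed correlation, descending, lexicographic id
tie-break), edges among them are kept where correlation reaches the 0.90
quantile of the off-diagonal values *and* is positive, and nodes carry
their other-family module label or "NI" when absent from the other
family's filtered matrix. Subnetworks export to GraphML (via igraph) or a
node/edge TSV pair and round-trip through the package's own reader.

## Enrichment

For single-class (KOG-style) annotations, the class statistic is the
delta rank: mean rank of the class's scores minus mean rank of all other
scores, with mid-ranks for ties, over the annotated universe. P-values are
two-sided Mann–Whitney U (exact for small untied samples, normal
approximation with tie correction otherwise), BH-adjusted across classes.
Unannotated genes are dropped and counted. The same rank engine applied to
a kME-or-zero vector (module members keep their kME, everything else 0)
gives module-based rank enrichment with one code path. Cross-contrast
delta-rank agreement is plain Pearson correlation over shared classes.
Term-set (GO-style) enrichment is a two-sided Fisher exact test per term
with BH correction and a 0.01 significance default; the dichotomization of
a continuous score into in/out membership happens at the caller's
threshold, which is exposed rather than fixed.

One bookkeeping identity worth noting: over a partition of the universe,
$\sum_c n_c (N - n_c)\,\delta_c = 0$ (each class's delta rank weighted by
its in–out pair count) — the form the property test asserts; the unweighted
sum $\sum_c n_c \delta_c$ is *not* conserved for unequal class sizes.

## Phenotypes

Kaplan–Meier curves use the product-limit estimator (censored individuals
remain at risk at their censoring time). LT50 is defined on the step
function — the first event time with $S(t) \le 0.5$ — rather than by
interpolation, matching tank-level "time until mortality reached half"
bookkeeping; a curve that never reaches 0.5 returns a not-reached
sentinel. Group comparisons use the Fleming–Harrington $G^\rho$ family
(weights $\hat S(t^-)^\rho$): $\rho = 0$ is the log-rank test for
proportional hazards, $\rho = 1$ the Wilcoxon-type test preferred when
curves cross. `crossingRule()` chooses $\rho$ by a strict sign change of
$S_1 - S_2$ across event times (ties ignored). Mixed-effects survival
models with random tank effects are out of scope; tank enters as an
optional stratification of the $G^\rho$ test instead. Respiration rates
standardize to a 1 g reference dry weight as
$Y_s = (W_s / W_e)^b \, Y_e$ with $b = 0.75$, the conventional allometric
exponent for this taxon.

## The synthetic-data generator

`simConfig()` defaults are the package's reference study conditions:
4,000 genes; four planted modules of 300/250/150/100 genes; 6 replicates
per family × priming × temperature cell (48 samples); negative-binomial
counts (dispersion 0.1) around depth-scaled means with baseline
log2 means uniform on [3, 9] and depth factors in [0.7, 1.4]; 10% of
background genes given a ±2 log2 fold-change under stress; spat weights
log-normal with mean 0.19 g and sd 0.06 g.

Structural choices, and why:

* **Eigengenes with constant total variance.** Each module's eigengene is
  `aT·T + aP·P + noise`, where the residual noise tops the variance up to
  `eigengene_sd^2` (default 1.1²). Without this, a trait-free module would
  be systematically weaker than trait-linked ones, confounding
  preservation comparisons.
* **Orthogonalized latent noise.** Within a family, eigengene noise
  vectors are drawn orthogonal to the trait codings and to each other
  (QR construction). At 24 samples per family, raw random noise vectors
  correlate by chance at |r| ≈ 0.2–0.3, which couples unrelated modules
  and makes clustering outcomes depend on luck rather than structure.
* **Non-positively-correlated trait effects.** Default effects are
  m1: T+0.8/P+0.7, m2: T−0.9, m3: P−0.9, m4: trait-free. In a *signed*
  network, negative cross-module correlation maps near adjacency 0; two
  modules sharing a positive trait driver genuinely co-express and merge
  under any static cut, so the defaults avoid that configuration.
* **Per-gene biological noise.** Every gene draws its own extra noise sd
  from [0.1, 0.6] (log2 scale). Real modules have heterogeneous
  membership strength; without this, correlations saturate and
  degree/kME rankings within a module become noise-dominated.
* **Non-preservation mechanism.** In the scrambled family the module's
  genes get re-drawn loadings applied to *private* per-gene latent
  factors: the genes stay expressed with the same marginal spread but
  decorrelate completely. (An alternative — splitting the module over two
  shared factors — leaves the module coherent enough in the scrambled
  family that its coherence statistic still beats the permutation null;
  full decorrelation makes average weight, coherence and `cor_cor` fail
  cleanly, which is the planted truth the acceptance checks assert.)
* **Planted candidates.** Ten genes inside the scrambled module are
  planted as hub-DE candidates: loading gain 1.3 (above the regular
  [0.4, 0.85] interval), minimal gene noise, and direct cis effects on
  priming (+0.8 log2) and temperature (+0.3 log2) **in the intact family
  only** — the genotype-dependent response the triage stage is meant to
  find. The cis effects exist because a loading gain alone cannot separate
  candidates: correlation-derived quantities saturate in the loading, so
  top-decile membership in gene significance would otherwise be a coin
  flip.

What the generator does **not** emulate: GC/length biases and other
library-composition artifacts, batch effects, count outliers, annotation
errors, or any genetic (SNP) structure. Passing the planted-structure
checks therefore demonstrates that the inference chain is correct and
calibrated under its own model assumptions — not that it is robust to
every artifact of real libraries.

## Validation sizes and numerical choices

The test suite and `scripts/acceptance.R` exercise, on one CPU:

* end-to-end recovery at the reference conditions above (adjusted Rand
  index on planted-module genes; preservation with $N = 1{,}000$
  permutations; candidate sensitivity) — a few minutes;
* permutation calibration under a fully null generator configuration
  (600 genes, no planted structure): 200 random 30-gene modules at 500
  permutations each, with each statistic's p-value ECDF compared to the
  95% Kolmogorov band ($1.358/\sqrt{200}$). With seven statistics checked
  jointly, an occasional single-statistic excursion beyond the band is
  expected behavior for a perfectly calibrated test (the family-wise
  exceedance probability is about 30%); the suite asserts the bands under
  its fixed seeds, and the acceptance script reports the maximal distance
  and the in-band count;
* type-I error of the NB-GLM LRT (1,000 Poisson null genes, two groups of
  10) and of the log-rank $G^\rho$ test (500 replicates of two identical
  exponential groups of 30), both required to land in [0.03, 0.07] at
  nominal 0.05.

Numerical conventions collected in one place: dispersion floor $10^{-8}$
(at or below which the GLM collapses to Poisson); IRLS limits 50
iterations / 1e-8 relative deviance; adjacency, TOM and kME are clamped by
construction to their defining ranges, with symmetric and unit-diagonal
matrices asserted by validity checks; eigengene sign is fixed by the mean
member kME; quantile boundaries everywhere include ties; the permutation
p floor is $1/(N+1)$; ARI on planted structure is computed over genes with
a planted module label, because background genes that share a common DE
shift co-express legitimately and would otherwise score generator
side-effects rather than module recovery.

## Known limitations

* The static percentile tree cut cannot separate modules whose average
  inter-module TOM dissimilarity falls below the background agglomeration
  range — in particular same-sign trait-coupled modules.
* The log2 stand-in transform does not reproduce vst values; variance at
  very low counts is under-stabilized relative to a fitted
  dispersion trend.
* MoM dispersion is noisy at small cell sizes and heavy-tailed for genes
  with large multiplicative noise, which costs DE power relative to
  shrinkage estimators.
* Preservation p-values lower-bound at $1/(N+1)$; distinguishing "no
  evidence against preservation" from "evidence of preservation" at very
  small thresholds requires correspondingly large $N$.
* The whole-matrix TOM is kept in memory; beyond ~20,000 genes a blockwise
  path (contracted to produce identical values) is the intended extension.
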