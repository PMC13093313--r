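## Signed weighted co-expression network construction and module detection.
##
## Adjacency a_ij = ((1 + cor_ij) / 2)^beta keeps sign information (strong
## negative correlations map near 0), topological overlap credits shared
## neighbors, modules come from average-linkage clustering of 1 - TOM with
## a percentile-height static cut, and each module is summarized by its
## eigengene (first principal component of member genes).

#' Network construction parameters
#'
#' @param power soft-threshold exponent beta (default 6).
#' @param target_r2 scale-free topology fit target for power selection
#'   (default 0.8).
#' @param min_module_size smallest cluster kept as a module (default 50).
#' @param merge_height eigengene dissimilarity (1 - cor) below which
#'   modules are merged (default 0.25).
#' @param cut_quantile quantile of the dendrogram merge heights at which
#'   the static tree cut is made (default 0.7: co-expression modules
#'   finish agglomerating in the lower half of the merge-height
#'   distribution, while unstructured background genes coalesce near the
#'   top, so a cut between the two isolates modules and leaves the
#'   background in sub-threshold fragments).
#' @param correlation_kind gene-gene correlation, "pearson" (default) or
#'   "spearman".
#' @return validated `networkConfig` list.
#' @export
networkConfig <- function(power = 6L, target_r2 = 0.8, min_module_size = 50L,
                          merge_height = 0.25, cut_quantile = 0.7,
                          correlation_kind = c("pearson", "spearman")) {
  cfg <- list(power = as.integer(power), target_r2 = target_r2,
              min_module_size = as.integer(min_module_size),
              merge_height = merge_height, cut_quantile = cut_quantile,
              correlation_kind = match.arg(correlation_kind))
  if (cfg$power < 1L) pnStop("invalidConfig", "power must be >= 1")
  if (cfg$merge_height <= 0 || cfg$merge_height >= 1) {
    pnStop("invalidConfig", "merge_height must be in (0, 1)")
  }
  class(cfg) <- "networkConfig"
  cfg
}

geneCor <- function(expr, kind = "pearson") {
  v <- apply(expr, 1, var)
  if (any(v == 0)) {
    pnStop("inputError", "zero-variance gene present (e.g. %s); filter first",
           rownames(expr)[which(v == 0)[1]])
  }
  cor(t(expr), method = kind)
}

#' Signed adjacency matrix
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta` with unit diagonal.
#'
#' @param expr normalized expression matrix (genes x samples, >= 3 samples).
#' @param power soft-threshold beta.
#' @param correlation_kind "pearson" or "spearman".
#' @return list of class `coexNetwork`: `adjacency`, `correlation`,
#'   `power`, `gene_ids`.
#' @export
signedAdjacency <- function(expr, power = 6L,
                            correlation_kind = c("pearson", "spearman")) {
  correlation_kind <- match.arg(correlation_kind)
  m <- assayMatrix(expr)
  if (ncol(m) < 3) pnStop("inputError", "need >= 3 samples")
  rho <- geneCor(m, correlation_kind)
  a <- ((1 + rho) / 2)^power
  diag(a) <- 1
  structure(list(adjacency = a, correlation = rho, power = power,
                 gene_ids = rownames(m)),
            class = "coexNetwork")
}

#' Pick the soft-threshold power by scale-free topology fit
#'
#' For each candidate power, builds the signed adjacency, computes
#' connectivities k_i, bins log10 k into 10 bins and regresses log10 p(k)
#' on the bin means of log10 k. The fit index is the regression R^2,
#' negated when the slope is positive (scale-free topology requires a
#' decreasing degree distribution). Returns the smallest power whose index
#' reaches `target_r2`, else the argmax.
#'
#' @param expr normalized expression matrix.
#' @param powers candidate integer powers.
#' @param target_r2 fit target (default 0.8).
#' @param correlation_kind "pearson" or "spearman".
#' @return list(power, fit = data.frame(power, r_squared, slope, mean_k)).
#' @export
pickSoftPower <- function(expr, powers = c(1:10, 12, 14, 16, 18, 20),
                          target_r2 = 0.8,
                          correlation_kind = c("pearson", "spearman")) {
  correlation_kind <- match.arg(correlation_kind)
  m <- assayMatrix(expr)
  if (ncol(m) < 4) pnStop("inputError", "need >= 4 samples")
  rho <- geneCor(m, correlation_kind)
  base <- (1 + rho) / 2
  diag(base) <- 0
  fit <- lapply(powers, function(b) {
    k <- rowSums(base^b)
    scaleFreeFit(k)
  })
  tab <- data.frame(power = powers,
                    r_squared = vapply(fit, `[[`, numeric(1), "r2"),
                    slope = vapply(fit, `[[`, numeric(1), "slope"),
                    mean_k = vapply(fit, `[[`, numeric(1), "meank"))
  hit <- which(tab$r_squared >= target_r2)
  chosen <- if (length(hit)) tab$power[hit[1]] else tab$power[which.max(tab$r_squared)]
  list(power = chosen, fit = tab)
}

## Scale-free topology index of a connectivity vector: signed R^2 of
## log10 p(k) ~ log10 k over 10 bins.
scaleFreeFit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(unique(k)) < 2) pnStop("fitError", "degenerate connectivity distribution")
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  kbar <- tapply(k, bin, mean)
  ok <- !is.na(pk) & pk > 0
  if (sum(ok) < 3) pnStop("fitError", "too few occupied connectivity bins")
  x <- log10(kbar[ok]); y <- log10(pk[ok])
  f <- stats::lm.fit(cbind(1, x), y)
  ssr <- sum(f$residuals^2); sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 0
  slope <- f$coefficients[2]
  list(r2 = unname(if (slope > 0) -r2 else r2), slope = unname(slope),
       meank = mean(k))
}

#' Topological overlap similarity
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over u distinct from i, j and
#' `k_i = sum_{u != i} a_iu`; unit diagonal.
#'
#' @param net a `coexNetwork` from [signedAdjacency()].
#' @return symmetric matrix in \[0, 1\].
#' @export
tomSimilarity <- function(net) {
  a <- net$adjacency
  k <- rowSums(a) - 1
  l <- a %*% a - 2 * a          # remove u = i and u = j terms (diag = 1)
  minK <- outer(k, k, pmin)
  tom <- (l + a) / (minK + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect modules by hierarchical clustering of 1 - TOM
#'
#' Average-linkage clustering; the tree is cut at the `cut_quantile`
#' quantile of its merge heights, clusters smaller than `min_module_size`
#' become background (label 0), and survivors are labeled 1..K by
#' decreasing size.
#'
#' @param tom TOM similarity matrix.
#' @param cfg a [networkConfig()].
#' @return named integer label vector.
#' @export
detectModules <- function(tom, cfg = networkConfig()) {
  d <- as.dist(1 - tom)
  tree <- hclust(d, method = "average")
  h <- unname(quantile(tree$height, cfg$cut_quantile))
  raw <- cutree(tree, h = h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= cfg$min_module_size]
  labels <- integer(length(raw))
  if (length(keep)) {
    ord <- keep[order(sizes[keep], decreasing = TRUE)]
    for (i in seq_along(ord)) labels[raw == as.integer(ord[i])] <- i
  } else {
    pnWarn("no cluster reached min_module_size; all genes unassigned")
  }
  if (length(unique(labels[labels > 0])) == 1L && all(labels > 0)) {
    pnWarn("all genes fell into a single module")
  }
  names(labels) <- rownames(tom)
  labels
}

## First principal component of a standardized gene x sample block:
## returns unit-variance sample scores and the variance share explained.
firstPC <- function(block) {
  z <- t(scale(t(block)))          # standardize each gene across samples
  sv <- svd(z, nu = 0, nv = 1)
  scores <- sv$v[, 1]
  list(scores = scores / sd(scores),
       varExplained = sv$d[1]^2 / sum(sv$d^2))
}

#' Module eigengenes and module membership (kME)
#'
#' Each module's eigengene is the first principal component of its
#' standardized member genes, scaled to unit variance across samples and
#' oriented so that the mean correlation of member genes with it (kME) is
#' non-negative. kME is returned for every gene against every module.
#'
#' @param expr normalized expression matrix (genes x samples).
#' @param labels gene -> module labels (0 = background).
#' @return a [ModuleSet-class] (gene significance / module-trait slots
#'   empty until computed).
#' @export
moduleEigengenesFromLabels <- function(expr, labels) {
  m <- assayMatrix(expr)
  labels <- labels[rownames(m)]
  mods <- sort(unique(labels[labels > 0]))
  me <- matrix(0, length(mods), ncol(m),
               dimnames = list(paste0("ME", mods), colnames(m)))
  varExp <- numeric(length(mods))
  for (i in seq_along(mods)) {
    gIdx <- which(labels == mods[i])
    if (length(gIdx) == 1L) {
      pnWarn("module %d has a single gene; eigengene = standardized gene", mods[i])
      v <- m[gIdx, ]
      me[i, ] <- (v - mean(v)) / sd(v)
      varExp[i] <- 1
      next
    }
    pc <- firstPC(m[gIdx, , drop = FALSE])
    me[i, ] <- pc$scores
    varExp[i] <- pc$varExplained
  }
  kme <- cor(t(m), t(me))
  ## orient each eigengene so member genes load positively on average
  for (i in seq_along(mods)) {
    members <- labels == mods[i]
    if (mean(kme[members, i]) < 0) {
      me[i, ] <- -me[i, ]
      kme[, i] <- -kme[, i]
    }
  }
  attr(me, "varExplained") <- varExp
  new("ModuleSet", labels = labels, eigengenes = me, kME = kme,
      geneSignificance = numeric(0),
      moduleTrait = data.frame())
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the module pair with the most similar eigengenes
#' while their dissimilarity `1 - cor(ME_a, ME_b)` is below
#' `merge_height`, recomputing eigengenes after each merge.
#'
#' @param expr normalized expression matrix.
#' @param modules a [ModuleSet-class].
#' @param merge_height merge threshold (default 0.25).
#' @return a [ModuleSet-class] with merged, re-numbered labels.
#' @export
mergeModules <- function(expr, modules, merge_height = 0.25) {
  labels <- moduleLabels(modules)
  repeat {
    ms <- moduleEigengenesFromLabels(expr, labels)
    me <- moduleEigengenes(ms)
    if (nrow(me) < 2) return(ms)
    diss <- 1 - cor(t(me))
    diag(diss) <- Inf
    if (min(diss) >= merge_height) return(ms)
    pair <- which(diss == min(diss), arr.ind = TRUE)[1, ]
    ids <- as.integer(sub("ME", "", rownames(me)))
    from <- ids[max(pair)]; to <- ids[min(pair)]
    labels[labels == from] <- to
    ## renumber by decreasing size
    sizes <- sort(table(labels[labels > 0]), decreasing = TRUE)
    remap <- setNames(seq_along(sizes), names(sizes))
    labels[labels > 0] <- remap[as.character(labels[labels > 0])]
  }
}

#' Gene significance for a trait
#'
#' `GS_g = |cor(expression_g, trait)|`.
#'
#' @param expr normalized expression matrix.
#' @param trait per-sample numeric coding (e.g. priming -1/+1).
#' @param correlation_kind "pearson" or "spearman".
#' @return named numeric vector in \[0, 1\].
#' @export
geneSignificance <- function(expr, trait,
                             correlation_kind = c("pearson", "spearman")) {
  correlation_kind <- match.arg(correlation_kind)
  m <- assayMatrix(expr)
  if (length(unique(trait)) < 2) pnStop("inputError", "trait is constant")
  gs <- abs(drop(cor(t(m), trait, method = correlation_kind)))
  names(gs) <- rownames(m)
  gs
}

#' Module-trait Spearman correlations
#'
#' Correlates each module eigengene with each coded trait (priming,
#' temperature, weight by default) using Spearman rank correlation and a
#' two-sided p-value (exact for n <= 9, t approximation otherwise).
#'
#' @param modules a [ModuleSet-class].
#' @param traits numeric sample x trait matrix (see [codeTraits()]).
#' @return data.frame(module, trait, rho, p_value).
#' @export
moduleTraitCor <- function(modules, traits) {
  me <- moduleEigengenes(modules)
  if (ncol(me) < 4) pnStop("inputError", "need >= 4 samples")
  res <- expand.grid(module = rownames(me), trait = colnames(traits),
                     stringsAsFactors = FALSE)
  res$rho <- NA_real_; res$p_value <- NA_real_
  for (i in seq_len(nrow(res))) {
    tr <- traits[, res$trait[i]]
    if (length(unique(tr)) < 2) pnStop("inputError", "trait %s is constant",
                                       res$trait[i])
    ct <- suppressWarnings(
      cor.test(me[res$module[i], ], tr, method = "spearman",
               exact = ncol(me) <= 9)
    )
    res$rho[i] <- unname(ct$estimate)
    res$p_value[i] <- ct$p.value
  }
  res
}

#' Weighted degree (afferent connection strength)
#'
#' `k_i = sum_{j != i} a_ij`, either over the whole network or restricted
#' to gene i's own module (genes with label 0 get intramodular degree 0).
#'
#' @param net a `coexNetwork`.
#' @param labels gene -> module labels (required for intramodular scope).
#' @param scope "intramodular" or "whole".
#' @return named numeric vector.
#' @export
weightedDegree <- function(net, labels = NULL,
                           scope = c("intramodular", "whole")) {
  scope <- match.arg(scope)
  a <- net$adjacency
  if (scope == "whole") {
    k <- rowSums(a) - 1
  } else {
    if (is.null(labels)) pnStop("inputError", "labels required for intramodular degree")
    labels <- labels[rownames(a)]
    k <- numeric(nrow(a))
    for (mod in unique(labels[labels > 0])) {
      ix <- which(labels == mod)
      k[ix] <- rowSums(a[ix, ix, drop = FALSE]) - 1
    }
  }
  names(k) <- rownames(a)
  k
}

#' Build a family's network and modules in one call
#'
#' Chains [signedAdjacency()], [tomSimilarity()], [detectModules()],
#' [moduleEigengenesFromLabels()] and [mergeModules()].
#'
#' @param expr normalized, variance-filtered expression matrix.
#' @param cfg a [networkConfig()].
#' @return list(network, tom, modules) where `modules` is a
#'   [ModuleSet-class].
#' @export
buildNetwork <- function(expr, cfg = networkConfig()) {
  net <- signedAdjacency(expr, cfg$power, cfg$correlation_kind)
  tom <- tomSimilarity(net)
  labels <- detectModules(tom, cfg)
  modules <- moduleEigengenesFromLabels(expr, labels)
  if (nrow(moduleEigengenes(modules)) >= 2) {
    modules <- mergeModules(expr, modules, cfg$merge_height)
  }
  list(network = net, tom = tom, modules = modules)
}
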