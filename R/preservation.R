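## Cross-family module preservation: seven statistics and a permutation null.
##
## A discovery module's gene set is scored in the test dataset by average
## edge weight, coherence (variance explained by the module summary
## profile), average and concordance of node contribution, average signed
## correlation, concordance of correlation structure, and concordance of
## intramodular weighted degree. The null re-draws gene sets of the same
## size from the test dataset; discovery-side references stay frozen.

#' Preservation test configuration
#'
#' @param n_permutations permutation count (default 10,000; >= 100).
#' @param alpha per-statistic significance threshold (default 1e-4).
#' @param seed integer seed for the permutation stream.
#' @param statistics subset of the seven statistic names to evaluate
#'   (default all).
#' @param exclude_members if TRUE, null gene sets are drawn from test genes
#'   outside the module; default FALSE (label-permutation logic, members
#'   included).
#' @return validated `preservationConfig` list.
#' @export
preservationConfig <- function(n_permutations = 10000L, alpha = 1e-4,
                               seed = 1L, statistics = presStatNames(),
                               exclude_members = FALSE) {
  cfg <- list(n_permutations = as.integer(n_permutations), alpha = alpha,
              seed = as.integer(seed),
              statistics = match.arg(statistics, presStatNames(),
                                     several.ok = TRUE),
              exclude_members = isTRUE(exclude_members))
  if (cfg$n_permutations < 100L) {
    pnStop("invalidConfig", "n_permutations must be >= 100")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    pnStop("invalidConfig", "alpha must be in (0, 1)")
  }
  class(cfg) <- "preservationConfig"
  cfg
}

## Standardize genes of a (genes x samples) matrix into samples x genes
## columns with mean 0 / sd 1.
standardizeSamplesByGenes <- function(expr) {
  z <- scale(t(expr))
  if (any(!is.finite(z))) {
    pnStop("inputError", "zero-variance gene in expression matrix")
  }
  z
}

## Module summary profile of a samples x genes standardized block:
## first-PC sample scores, sign-aligned to positive mean node contribution.
summaryProfile <- function(zmod) {
  sv <- svd(zmod, nu = 1, nv = 0)
  h <- sv$u[, 1] * sv$d[1]
  nc <- drop(cor(zmod, h))
  if (mean(nc) < 0) {
    h <- -h
    nc <- -nc
  }
  list(h = h, nc = nc, coherence = sv$d[1]^2 / sum(sv$d^2))
}

## Frozen discovery-side references for one module.
presReference <- function(discExpr, moduleGenes, power) {
  z <- standardizeSamplesByGenes(discExpr[moduleGenes, , drop = FALSE])
  rho <- crossprod(z) / (nrow(z) - 1)
  adj <- ((1 + rho) / 2)^power
  deg <- colSums(adj) - 1
  sp <- summaryProfile(z)
  list(cor = rho, corLower = lowerTri(rho), signLower = sign(lowerTri(rho)),
       degree = deg, nc = sp$nc, ncSign = sign(sp$nc), size = length(moduleGenes))
}

## The seven statistics of a test-side gene set against frozen references.
## ztest: samples x genes standardized test matrix; idx: column indices.
presTestStats <- function(ztest, idx, ref, power) {
  z <- ztest[, idx, drop = FALSE]
  n <- nrow(z)
  rho <- crossprod(z) / (n - 1)
  adj <- ((1 + rho) / 2)^power
  lower <- lowerTri(rho)
  deg <- colSums(adj) - 1
  sp <- summaryProfile(z)
  c(avg_weight = mean(lowerTri(adj)),
    coherence = sp$coherence,
    avg_contrib = mean(ref$ncSign * sp$nc),
    cor_contrib = cor(ref$nc, sp$nc),
    avg_cor = mean(lower * ref$signLower),
    cor_cor = cor(ref$corLower, lower),
    cor_degree = cor(ref$degree, deg))
}

#' Observed preservation statistics for one module
#'
#' Computes the seven preservation statistics of a discovery module's gene
#' set in a test dataset. Genes absent from the test matrix are dropped
#' and reported in `attr(, "missing")` ("NI" genes); more than 50% missing
#' is an error.
#'
#' @param disc_expr,test_expr normalized expression matrices
#'   (genes x samples) for the discovery and test datasets.
#' @param module_genes character vector of module gene ids (>= 3 present
#'   in both datasets).
#' @param power soft-threshold beta for the implied adjacency (default 6).
#' @return named numeric vector of the seven statistics.
#' @export
preservationStatistics <- function(disc_expr, test_expr, module_genes,
                                   power = 6L) {
  missing <- setdiff(module_genes, rownames(test_expr))
  present <- intersect(module_genes, rownames(disc_expr))
  present <- setdiff(present, missing)
  if (length(missing) > 0.5 * length(module_genes)) {
    pnStop("coverageError", "%d of %d module genes missing from test dataset",
           length(missing), length(module_genes))
  }
  if (length(present) < 3) {
    pnStop("sizeError", "module must have >= 3 genes present in both datasets")
  }
  ref <- presReference(disc_expr, present, power)
  ztest <- standardizeSamplesByGenes(test_expr[present, , drop = FALSE])
  stats <- presTestStats(ztest, seq_along(present), ref, power)
  attr(stats, "missing") <- missing
  attr(stats, "genes_used") <- present
  stats
}

#' Permutation test of module preservation
#'
#' For every discovery module (labels > 0), draws `n_permutations` random
#' gene sets of the module's size from the test dataset, recomputes all
#' statistics against the frozen discovery references, and reports the
#' one-sided (greater) permutation p-value per statistic with the
#' (b + 1) / (N + 1) estimator.
#'
#' @param disc_expr,test_expr normalized expression matrices.
#' @param labels discovery gene -> module labels (0 = background), or a
#'   [ModuleSet-class].
#' @param cfg a [preservationConfig()].
#' @param power soft-threshold beta (default 6).
#' @return a [PreservationResult-class].
#' @export
modulePreservation <- function(disc_expr, test_expr, labels,
                               cfg = preservationConfig(), power = 6L) {
  if (is(labels, "ModuleSet")) labels <- moduleLabels(labels)
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) pnStop("inputError", "no modules to test")
  nTestGenes <- nrow(test_expr)
  ztestAll <- standardizeSamplesByGenes(test_expr)
  statNames <- cfg$statistics
  obs <- matrix(NA_real_, length(mods), length(statNames),
                dimnames = list(paste0("ME", mods), statNames))
  pv <- obs
  missingGenes <- vector("list", length(mods))
  names(missingGenes) <- rownames(obs)

  withSeed(fanOutSeed(cfg$seed, "preservation"), {
    for (i in seq_along(mods)) {
      genes <- names(labels)[labels == mods[i]]
      st <- preservationStatistics(disc_expr, test_expr, genes, power)
      missingGenes[[i]] <- attr(st, "missing")
      present <- attr(st, "genes_used")
      m <- length(present)
      if (nTestGenes < 2L * m) {
        pnStop("coverageError",
               "test dataset (%d genes) smaller than 2x module size (%d)",
               nTestGenes, m)
      }
      ref <- presReference(disc_expr, present, power)
      pool <- if (cfg$exclude_members) {
        which(!(colnames(ztestAll) %in% present))
      } else seq_len(ncol(ztestAll))
      obs[i, ] <- st[statNames]
      exceed <- integer(length(statNames))
      for (b in seq_len(cfg$n_permutations)) {
        idx <- sample(pool, m)
        nullStats <- presTestStats(ztestAll, idx, ref, power)[statNames]
        exceed <- exceed + (nullStats >= obs[i, ])
      }
      pv[i, ] <- (1 + exceed) / (cfg$n_permutations + 1)
    }
  })
  new("PreservationResult", observed = obs, pValues = pv,
      nPermutations = cfg$n_permutations, missingGenes = missingGenes)
}

#' Classify modules as preserved or not
#'
#' Small permutation p-values are evidence of preservation for that
#' statistic. Under the default rule `"all"`, a module is preserved only
#' if every requested statistic has p < alpha; any statistic at or above
#' the threshold is listed as failing. Rule `"any"` requires a single
#' passing statistic.
#'
#' @param result a [PreservationResult-class].
#' @param alpha significance threshold (default 1e-4).
#' @param rule "all" (default) or "any".
#' @return data.frame(module, preserved, failing_statistics).
#' @export
classifyPreservation <- function(result, alpha = 1e-4,
                                 rule = c("all", "any")) {
  rule <- match.arg(rule)
  p <- preservationPValues(result)
  failing <- apply(p, 1, function(row) {
    paste(colnames(p)[row >= alpha], collapse = ",")
  })
  preserved <- switch(rule,
    all = apply(p, 1, function(row) all(row < alpha)),
    any = apply(p, 1, function(row) any(row < alpha)))
  data.frame(module = rownames(p),
             preserved = unname(preserved),
             failing_statistics = unname(failing),
             stringsAsFactors = FALSE)
}
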