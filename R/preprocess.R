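## Count filtering and normalization ahead of DE and network stages.

#' Filtering thresholds
#'
#' @param min_cpm minimum counts-per-million for a gene to count as
#'   expressed in a sample (default 1).
#' @param min_samples number of samples in which a gene must reach
#'   `min_cpm` to be kept (default 4).
#' @param min_variance minimum per-gene variance of normalized expression
#'   (default 0.05).
#' @param outlier_z connectivity z-score below \code{-outlier_z} flags a
#'   sample as an outlier (default 2.5).
#' @return validated `filterConfig` list.
#' @export
filterConfig <- function(min_cpm = 1, min_samples = 4L,
                         min_variance = 0.05, outlier_z = 2.5) {
  cfg <- list(min_cpm = min_cpm, min_samples = as.integer(min_samples),
              min_variance = min_variance, outlier_z = outlier_z)
  if (any(unlist(cfg) < 0)) pnStop("invalidConfig", "thresholds must be >= 0")
  class(cfg) <- "filterConfig"
  cfg
}

#' Remove low-abundance genes by a CPM rule
#'
#' Keeps genes with at least `min_cpm` counts-per-million in at least
#' `min_samples` samples (CPM = count / library size x 1e6). The filter is
#' scale-free in per-sample depth.
#'
#' @param counts integer matrix (genes x samples) or a
#'   SummarizedExperiment with a `counts` assay.
#' @param cfg a [filterConfig()].
#' @return object of the same class with low-abundance genes dropped,
#'   gene order preserved.
#' @export
filterLowExpression <- function(counts, cfg = filterConfig()) {
  if (prod(dim(counts)) == 0) pnStop("emptyInput", "empty count matrix")
  m <- assayMatrix(counts)
  if (ncol(m) < cfg$min_samples) {
    pnStop("inputError", "fewer samples (%d) than min_samples (%d)",
           ncol(m), cfg$min_samples)
  }
  lib <- colSums(m)
  if (any(lib == 0)) {
    pnStop("normalizationError", "zero library size in sample %s",
           colnames(m)[which(lib == 0)[1]])
  }
  cpm <- sweep(m, 2, lib, `/`) * 1e6
  keep <- rowSums(cpm >= cfg$min_cpm) >= cfg$min_samples
  counts[keep, ]
}

#' Median-of-ratios size factors
#'
#' Per-sample factor = median over all-sample-expressed genes of the ratio
#' of the sample's count to the gene's geometric mean across samples.
#'
#' @param counts count matrix or SummarizedExperiment.
#' @return named positive numeric vector, one factor per sample.
#' @export
sizeFactors <- function(counts) {
  m <- assayMatrix(counts)
  expressed <- rowSums(m > 0) == ncol(m)
  if (!any(expressed)) {
    pnStop("degenerateInput", "no gene is expressed in every sample")
  }
  lg <- log(m[expressed, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(lg, 2, function(col) exp(median(col - geo)))
}

#' Normalize counts to a log2 expression matrix
#'
#' `log2(count / size factor + 1)`: a simple variance-curbing transform of
#' median-of-ratios-normalized counts used for all correlation-based
#' downstream stages.
#'
#' @param counts count matrix or SummarizedExperiment.
#' @param factors optional precomputed size factors.
#' @return numeric matrix of the same shape (or the SummarizedExperiment
#'   with a new `logexpr` assay).
#' @export
normalizeCounts <- function(counts, factors = sizeFactors(counts)) {
  m <- assayMatrix(counts)
  expr <- log2(sweep(m, 2, factors, `/`) + 1)
  if (is(counts, "SummarizedExperiment")) {
    SummarizedExperiment::assay(counts, "logexpr") <- expr
    counts
  } else {
    expr
  }
}

#' Remove low-variance genes
#'
#' Drops genes whose normalized-expression sample variance (n - 1
#' denominator) falls below `min_variance`. Genes removed here in one
#' family but analysed in the other are the "NI" genes of cross-family
#' comparisons.
#'
#' @param expr normalized expression matrix (genes x samples).
#' @param cfg a [filterConfig()].
#' @return the matrix minus low-variance rows, order preserved.
#' @export
filterLowVariance <- function(expr, cfg = filterConfig()) {
  m <- assayMatrix(expr)
  if (ncol(m) < 2) pnStop("degenerateInput", "variance needs >= 2 samples")
  v <- apply(m, 1, var)
  m[v >= cfg$min_variance, , drop = FALSE]
}

#' Remove low-connectivity outlier samples
#'
#' Sample connectivity k_s = sum over other samples of
#' (1 + cor(s, t)) / 2; samples whose connectivity z-score falls below
#' \code{-outlier_z} are removed in a single pass (low tail only: an
#' outlier individual decorrelates from the rest of the cohort).
#'
#' @param expr normalized expression matrix (genes x samples).
#' @param cfg a [filterConfig()].
#' @return the matrix minus outlier columns, with the removed sample ids in
#'   `attr(, "removed")`.
#' @export
removeConnectivityOutliers <- function(expr, cfg = filterConfig()) {
  m <- assayMatrix(expr)
  if (ncol(m) < 4) pnStop("inputError", "need >= 4 samples")
  sc <- cor(m)
  k <- colSums((1 + sc) / 2) - 1  # exclude self term
  s <- sd(k)
  if (!is.finite(s) || s == 0) {
    pnWarn("sample connectivity has zero spread; no outliers removed")
    out <- m
    attr(out, "removed") <- character(0)
    return(out)
  }
  z <- (k - mean(k)) / s
  drop <- which(z < -cfg$outlier_z)
  out <- m[, setdiff(seq_len(ncol(m)), drop), drop = FALSE]
  attr(out, "removed") <- colnames(m)[drop]
  out
}

#' Summarize differential-expression counts as transcriptome percentages
#'
#' The reporting arithmetic used for headline DE summaries: what percentage
#' of the filtered transcriptome a DEG count represents, rounded to whole
#' percent as conventionally printed.
#'
#' @param n_significant number of significant genes (scalar or vector).
#' @param n_total size of the filtered gene universe.
#' @return percentages, rounded to the nearest whole percent.
#' @export
degPercent <- function(n_significant, n_total) {
  if (any(n_significant < 0) || n_total <= 0 || any(n_significant > n_total)) {
    pnStop("inputError", "need 0 <= n_significant <= n_total")
  }
  round(100 * n_significant / n_total)
}
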