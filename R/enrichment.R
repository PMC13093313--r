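## Functional enrichment: rank-based delta-rank MWU on per-gene scores
## (log2 fold-changes or kME-or-zero vectors) for single-class annotations,
## and Fisher exact membership enrichment for term sets.

#' Read or build an annotation map
#'
#' @param x either a data.frame with columns gene and class (single class
#'   per gene) or a named list of character vectors (term -> gene set).
#' @return a `classMap` list: `gene2class` (named character, possibly
#'   empty) and `term2genes` (named list).
#' @export
classMap <- function(x) {
  if (is.data.frame(x)) {
    checkIds(x[[1]], "gene")
    out <- list(gene2class = setNames(as.character(x[[2]]), x[[1]]),
                term2genes = split(as.character(x[[1]]), x[[2]]))
  } else if (is.list(x)) {
    out <- list(gene2class = character(0), term2genes = x)
  } else {
    pnStop("inputError", "annotation must be a data.frame or named list")
  }
  if (any(!nzchar(names(out$term2genes)))) {
    pnStop("inputError", "empty class/term name in annotation")
  }
  class(out) <- "classMap"
  out
}

#' Delta-rank Mann-Whitney enrichment of functional classes
#'
#' Ranks the score vector (mid-ranks for ties) over the whole annotated
#' universe; each class's delta rank is the mean rank of its genes minus
#' the mean rank of all other genes. Two-sided Mann-Whitney U p-values
#' (exact for small untied samples, normal approximation with tie
#' correction otherwise) are BH-adjusted across classes. Genes without an
#' annotation are dropped (count reported via `attr(, "n_unannotated")`).
#'
#' @param scores named numeric vector (log2 fold-changes, or kME-or-zero).
#' @param classes a [classMap()] with a single class per gene.
#' @return data.frame(class, delta_rank, n_in_class, p_value, p_adjusted),
#'   ordered by class name.
#' @export
kogMWU <- function(scores, classes) {
  g2c <- classes$gene2class
  if (!length(g2c)) pnStop("inputError", "classMap has no gene->class entries")
  common <- intersect(names(scores), names(g2c))
  nUnann <- length(scores) - length(common)
  scores <- scores[common]
  cls <- g2c[common]
  counts <- table(cls)
  if (any(counts == length(scores))) {
    pnStop("degenerateClass", "a class covers the whole universe")
  }
  if (sum(counts >= 2) < 2) {
    pnStop("inputError", "need >= 2 classes with >= 2 genes")
  }
  rk <- rank(scores)  # mid-ranks for ties
  out <- lapply(names(counts), function(cl) {
    inC <- cls == cl
    dr <- mean(rk[inC]) - mean(rk[!inC])
    p <- suppressWarnings(
      wilcox.test(scores[inC], scores[!inC])$p.value
    )
    data.frame(class = cl, delta_rank = dr,
               n_in_class = sum(inC), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$p_adjusted <- adjustBH(out$p_value)
  attr(out, "n_unannotated") <- nUnann
  out[order(out$class), ]
}

#' Pairwise Pearson correlation of delta ranks
#'
#' Correlates delta-rank vectors from several contrasts over their shared
#' classes; used to ask whether functional responses agree across families
#' and early-life environments.
#'
#' @param results named list of [kogMWU()] tables (>= 2).
#' @return list with matrices `r` and `p_value` (two-sided).
#' @export
deltaRankCorrelation <- function(results) {
  stopifnot(length(results) >= 2)
  shared <- Reduce(intersect, lapply(results, `[[`, "class"))
  if (length(shared) < 3) pnStop("inputError", "< 3 shared classes")
  mat <- vapply(results, function(r) {
    r$delta_rank[match(shared, r$class)]
  }, numeric(length(shared)))
  k <- ncol(mat)
  rmat <- cor(mat)
  pmat <- matrix(NA_real_, k, k, dimnames = dimnames(rmat))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { pmat[i, j] <- 0; next }
    pmat[i, j] <- cor.test(mat[, i], mat[, j])$p.value
  }
  list(r = rmat, p_value = pmat, classes = shared)
}

#' Fisher exact enrichment of a module in term sets
#'
#' Per term, tests the 2x2 in-module x in-term table against the universe
#' with a two-sided Fisher exact test (hypergeometric sum). Terms with no
#' gene in the universe are skipped. Odds ratios are the conditional MLE;
#' infinite estimates are reported as `Inf`.
#'
#' @param module_genes character vector, subset of `universe`.
#' @param term_map a [classMap()] with `term2genes`.
#' @param universe character vector of all analysed genes.
#' @param alpha adjusted-p significance threshold (default 0.01).
#' @return data.frame(term, n_in_term, n_overlap, odds_ratio, p_value,
#'   p_adjusted, significant).
#' @export
fisherEnrichment <- function(module_genes, term_map, universe, alpha = 0.01) {
  if (!length(universe)) pnStop("inputError", "empty universe")
  if (!all(module_genes %in% universe)) {
    pnStop("inputError", "module genes must be a subset of the universe")
  }
  inMod <- universe %in% module_genes
  rows <- lapply(names(term_map$term2genes), function(tm) {
    genes <- intersect(term_map$term2genes[[tm]], universe)
    if (!length(genes)) return(NULL)  # term disjoint from universe: skipped
    inTerm <- universe %in% genes
    tab <- table(factor(inMod, c(TRUE, FALSE)), factor(inTerm, c(TRUE, FALSE)))
    ft <- fisher.test(tab)
    data.frame(term = tm, n_in_term = length(genes),
               n_overlap = sum(inMod & inTerm),
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) pnStop("inputError", "no term overlaps the universe")
  rows$p_adjusted <- adjustBH(rows$p_value)
  rows$significant <- rows$p_adjusted < alpha
  rows[order(rows$term), ]
}

#' kME-or-zero score vector for module-based rank enrichment
#'
#' Genes in the module keep their kME to the module eigengene; all other
#' universe genes score zero — the input vector for running the delta-rank
#' machinery on module membership strength.
#'
#' @param modules a [ModuleSet-class].
#' @param module integer module id.
#' @param universe gene ids to cover.
#' @return named numeric vector over `universe`.
#' @export
kmeOrZero <- function(modules, module, universe) {
  km <- kME(modules)
  col <- paste0("ME", module)
  if (!col %in% colnames(km)) pnStop("inputError", "no module %s", module)
  v <- setNames(numeric(length(universe)), universe)
  members <- names(moduleLabels(modules))[moduleLabels(modules) == module]
  members <- intersect(members, universe)
  v[members] <- km[members, col]
  v
}
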