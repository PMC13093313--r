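#' ModuleSet: co-expression modules with eigengene summaries
#'
#' Holds the result of module detection on one family's signed network:
#' gene labels (0 = background / unassigned), module eigengenes (first
#' principal component of member genes, unit variance across samples),
#' module-membership correlations (kME) and, once computed, gene
#' significance and module-trait correlations.
#'
#' @slot labels named integer vector, gene -> module id (0 = unassigned).
#' @slot eigengenes numeric matrix, modules x samples; rows named
#'   \code{ME1}, \code{ME2}, ... and scaled to unit variance.
#' @slot kME numeric matrix, genes x modules, correlations in \[-1, 1\].
#' @slot geneSignificance named numeric vector (may be empty until
#'   \code{geneSignificance()} is run).
#' @slot moduleTrait data.frame of module-trait Spearman correlations
#'   (may have zero rows until \code{moduleTraitCor()} is run).
#'
#' @aliases ModuleSet-class
#' @export
setClass("ModuleSet", representation(
  labels = "integer",
  eigengenes = "matrix",
  kME = "matrix",
  geneSignificance = "numeric",
  moduleTrait = "data.frame"
))

setValidity("ModuleSet", function(object) {
  msgs <- character()
  if (is.null(names(object@labels))) msgs <- c(msgs, "labels must be named by gene id")
  if (any(object@labels < 0L)) msgs <- c(msgs, "labels must be >= 0")
  if (nrow(object@eigengenes) > 0) {
    sds <- apply(object@eigengenes, 1, sd)
    if (any(abs(sds - 1) > 1e-6)) msgs <- c(msgs, "eigengenes must have unit variance")
  }
  if (length(object@kME) && max(abs(object@kME), na.rm = TRUE) > 1 + 1e-8) {
    msgs <- c(msgs, "kME entries must lie in [-1, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ModuleSet gene -> module label vector.
#' @param x,object a \code{ModuleSet}.
#' @export
moduleLabels <- function(x) {
  stopifnot(is(x, "ModuleSet"))
  x@labels
}

#' @describeIn ModuleSet module x sample eigengene matrix.
#' @export
moduleEigengenes <- function(x) {
  stopifnot(is(x, "ModuleSet"))
  x@eigengenes
}

#' @describeIn ModuleSet gene x module membership correlations.
#' @export
kME <- function(x) {
  stopifnot(is(x, "ModuleSet"))
  x@kME
}

#' @export
setMethod("show", "ModuleSet", function(object) {
  k <- nrow(object@eigengenes)
  sizes <- table(object@labels[object@labels > 0L])
  cat("ModuleSet with", k, "modules over", length(object@labels), "genes\n")
  if (k > 0) {
    cat("  sizes:", paste(sprintf("ME%s=%d", names(sizes), as.integer(sizes)),
                          collapse = ", "), "\n")
  }
  cat("  unassigned (label 0):", sum(object@labels == 0L), "genes\n")
  if (nrow(object@moduleTrait)) cat("  module-trait correlations: computed\n")
  invisible(NULL)
})

#' PreservationResult: permutation evidence of module preservation
#'
#' Observed values and permutation p-values of seven module preservation
#' statistics (average edge weight, coherence, average and concordance of
#' node contribution, average correlation, concordance of correlation
#' structure, concordance of weighted degree) for each discovery module
#' evaluated in a test dataset.
#'
#' p-values use the (b + 1) / (N + 1) estimator with the one-sided
#' "greater" alternative, so they lie in (0, 1\].
#'
#' @slot observed numeric matrix, modules x statistics.
#' @slot pValues numeric matrix, modules x statistics, entries in (0, 1\].
#' @slot nPermutations integer, permutations actually used.
#' @slot missingGenes named list: per module, discovery genes absent from
#'   the test dataset ("NI" genes).
#'
#' @aliases PreservationResult-class
#' @export
setClass("PreservationResult", representation(
  observed = "matrix",
  pValues = "matrix",
  nPermutations = "integer",
  missingGenes = "list"
))

setValidity("PreservationResult", function(object) {
  msgs <- character()
  if (!identical(dim(object@observed), dim(object@pValues))) {
    msgs <- c(msgs, "observed and pValues must have the same shape")
  }
  p <- object@pValues
  if (length(p) && (any(p <= 0) || any(p > 1))) {
    msgs <- c(msgs, "p-values must lie in (0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn PreservationResult observed statistic matrix.
#' @param x,object a \code{PreservationResult}.
#' @export
observedStats <- function(x) {
  stopifnot(is(x, "PreservationResult"))
  x@observed
}

#' @describeIn PreservationResult permutation p-value matrix.
#' @export
preservationPValues <- function(x) {
  stopifnot(is(x, "PreservationResult"))
  x@pValues
}

#' @export
setMethod("show", "PreservationResult", function(object) {
  cat("PreservationResult:", nrow(object@observed), "module(s),",
      object@nPermutations, "permutations\n")
  cat("  statistics:", paste(colnames(object@observed), collapse = ", "), "\n")
  ni <- vapply(object@missingGenes, length, integer(1))
  if (length(ni) && any(ni > 0)) {
    cat("  NI genes (absent from test):",
        paste(sprintf("%s=%d", names(ni)[ni > 0], ni[ni > 0]), collapse = ", "),
        "\n")
  }
  invisible(NULL)
})

#' Names of the seven module preservation statistics
#'
#' Canonical statistic order used by [preservationStatistics()] and
#' [modulePreservation()].
#'
#' @return character vector of length 7.
#' @export
presStatNames <- function() {
  c("avg_weight", "coherence", "avg_contrib", "cor_contrib",
    "avg_cor", "cor_cor", "cor_degree")
}
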