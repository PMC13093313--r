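## Internal helpers shared across modules.

#' @importFrom methods is new validObject setValidity slot
#' @importFrom stats cor var sd quantile median rnorm runif rbinom rnbinom
#'   rlnorm rpois p.adjust pchisq pnorm fisher.test wilcox.test
#'   cor.test hclust cutree as.dist glm.fit glm.control poisson
#'   model.matrix as.formula lm.fit dpois setNames rexp
#' @importFrom utils read.delim write.table packageVersion
NULL

## Stop with a classed condition so callers/tests can discriminate error kinds.
pnStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "primeNetError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

pnWarn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Fan a single user seed out to named stages so that toggling one stage does
## not perturb the stream another stage sees. Kept below 2^31.
fanOutSeed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

## Run expr under a local RNG state (does not disturb the caller's stream).
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Extract a numeric matrix from a matrix or SummarizedExperiment.
assayMatrix <- function(x, assay = 1L) {
  if (is(x, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(x, assay)
  } else if (is.matrix(x)) {
    m <- x
  } else {
    pnStop("inputError", "expected a matrix or SummarizedExperiment, got %s",
           class(x)[1])
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    pnStop("inputError", "matrix must carry gene (row) and sample (column) ids")
  }
  m
}

checkIds <- function(ids, what) {
  if (anyDuplicated(ids)) {
    pnStop("inputError", "duplicated %s id: %s", what,
           ids[duplicated(ids)][1])
  }
  invisible(TRUE)
}

## Lower triangle of a square matrix as a vector (column-major, i > j).
lowerTri <- function(m) m[lower.tri(m)]

## Adjusted Rand index between two labelings (pair-counting form).
#' Adjusted Rand index
#'
#' Agreement between two partitions of the same items, corrected for chance.
#' Used to score recovery of planted modules by the clustering stage.
#'
#' @param a,b integer or character label vectors of equal length.
#' @return A number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b)) pnStop("inputError", "label lengths differ")
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  maxidx <- (ai + bj) / 2
  if (maxidx == expected) return(1)
  (nij - expected) / (maxidx - expected)
}
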