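## Per-gene negative-binomial GLM differential expression.
##
## Dispersion is a per-gene method-of-moments estimate on normalized counts
## within design cells (no empirical-Bayes shrinkage); the GLM is a log-link
## NB regression with a log(size factor) offset and the dispersion held
## fixed between nested fits, so likelihood-ratio statistics remain valid.

DISPERSION_EPS <- 1e-8

#' Method-of-moments dispersion per gene
#'
#' Within each design cell (unique factor combination), normalized counts
#' contribute a pooled variance and mean; the NB dispersion is
#' `alpha = max(eps, (pooled_var - mean) / mean^2)` with `eps = 1e-8`.
#'
#' @param counts count matrix (genes x samples).
#' @param cells factor (or interaction of factors) giving each sample's
#'   design cell.
#' @param factors per-sample size factors.
#' @return named non-negative numeric vector of dispersions; all-zero genes
#'   get `eps` and are flagged in `attr(, "flagged")`.
#' @export
estimateDispersionMoM <- function(counts, cells, factors = sizeFactors(counts)) {
  m <- assayMatrix(counts)
  cells <- as.factor(cells)
  if (max(table(cells)) < 2) pnStop("inputError", "no design cell has replicates")
  norm <- sweep(m, 2, factors, `/`)
  groups <- split(seq_len(ncol(norm)), cells)
  nPooled <- sum(vapply(groups, function(ix) max(length(ix) - 1L, 0L), integer(1)))
  ssq <- 0
  for (ix in groups) {
    if (length(ix) < 2) next
    sub <- norm[, ix, drop = FALSE]
    mu <- rowMeans(sub)
    ssq <- ssq + rowSums((sub - mu)^2)
  }
  s2 <- ssq / nPooled
  mbar <- rowMeans(norm)
  alpha <- ifelse(mbar > 0, (s2 - mbar) / mbar^2, DISPERSION_EPS)
  alpha <- pmax(alpha, DISPERSION_EPS)
  names(alpha) <- rownames(m)
  attr(alpha, "flagged") <- rownames(m)[mbar == 0]
  alpha
}

## Build a design matrix from a sample table and a factor list.
designMatrix <- function(design, terms) {
  allowed <- c("priming", "temperature", "interaction")
  if (!all(terms %in% allowed)) {
    pnStop("designError", "unknown design term(s): %s",
           paste(setdiff(terms, allowed), collapse = ", "))
  }
  if ("interaction" %in% terms &&
      !all(c("priming", "temperature") %in% terms)) {
    pnStop("designError", "interaction requires both main effects")
  }
  rhs <- if (length(terms) == 0) "1" else {
    paste(sub("interaction", "priming:temperature", terms), collapse = " + ")
  }
  df <- data.frame(
    priming = factor(design$priming, levels = c("naive", "primed")),
    temperature = factor(design$temperature, levels = c("control", "stress"))
  )
  mm <- model.matrix(stats::as.formula(paste("~", rhs)), df)
  if (qr(mm)$rank < ncol(mm)) pnStop("designError", "design matrix is rank deficient")
  mm
}

#' Fit a negative-binomial GLM to one gene
#'
#' Log-link NB regression with fixed dispersion and `log(size factor)`
#' offset, fitted by iteratively reweighted least squares (at most 50
#' iterations, relative deviance tolerance 1e-8). Dispersions at or below
#' the floor collapse to a Poisson GLM.
#'
#' @param y integer count vector.
#' @param mm design matrix (full column rank).
#' @param factors per-sample size factors.
#' @param dispersion fixed NB dispersion alpha (variance mu + alpha mu^2).
#' @return list with coefficients, standard errors, covariance, deviance,
#'   log-likelihood, and `converged` flag.
#' @export
fitNbGlm <- function(y, mm, factors, dispersion) {
  if (nrow(mm) != length(y)) pnStop("designError", "design/count length mismatch")
  if (qr(mm)$rank < ncol(mm)) pnStop("designError", "design matrix is rank deficient")
  fam <- if (dispersion <= DISPERSION_EPS) poisson(link = "log") else {
    MASS::negative.binomial(theta = 1 / dispersion, link = "log")
  }
  off <- log(factors)
  fit <- suppressWarnings(
    glm.fit(mm, y, family = fam, offset = off,
            control = glm.control(epsilon = 1e-8, maxit = 50))
  )
  eta <- drop(mm %*% fit$coefficients) + off
  mu <- exp(eta)
  w <- fit$weights
  XtWX <- crossprod(mm * sqrt(w))
  cov <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_,
                                                          ncol(mm), ncol(mm)))
  ll <- if (dispersion <= DISPERSION_EPS) {
    sum(stats::dpois(y, mu, log = TRUE))
  } else {
    theta <- 1 / dispersion
    sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
          theta * log(theta / (theta + mu)) + y * log(mu / (theta + mu)))
  }
  list(coefficients = fit$coefficients,
       se = sqrt(diag(cov)),
       cov = cov,
       deviance = fit$deviance,
       logLik = ll,
       dispersion = dispersion,
       converged = isTRUE(fit$converged))
}

#' Likelihood-ratio test between nested NB fits
#'
#' Statistic 2(ll_full - ll_reduced), clamped at 0, against chi-squared
#' with df = parameter-count difference. The dispersion must be shared.
#'
#' @param full,reduced fits from [fitNbGlm()] of nested models on the same
#'   gene and dispersion.
#' @return list(statistic, df, p_value).
#' @export
nbLRT <- function(full, reduced) {
  df <- length(full$coefficients) - length(reduced$coefficients)
  if (df < 0) pnStop("designError", "reduced model must be nested in the full model")
  if (df == 0) {
    stat <- max(0, 2 * (full$logLik - reduced$logLik))
    if (stat > 1e-6) pnStop("designError", "models differ but have equal size")
    return(list(statistic = 0, df = 0L, p_value = 1))
  }
  if (!isTRUE(all.equal(full$dispersion, reduced$dispersion))) {
    pnStop("designError", "LRT requires a shared dispersion")
  }
  stat <- max(0, 2 * (full$logLik - reduced$logLik))
  list(statistic = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Wald test of a coefficient contrast
#'
#' @param fit a converged [fitNbGlm()] result.
#' @param contrast numeric weight vector over the fit's coefficients.
#' @return list(log2_fold_change, statistic, p_value).
#' @export
waldContrast <- function(fit, contrast) {
  if (length(contrast) != length(fit$coefficients)) {
    pnStop("designError", "contrast length does not match coefficients")
  }
  est <- sum(contrast * fit$coefficients)
  se <- sqrt(drop(t(contrast) %*% fit$cov %*% contrast))
  z <- if (se > 0) est / se else 0
  list(log2_fold_change = est / log(2),
       statistic = z,
       p_value = if (se > 0) 2 * pnorm(-abs(z)) else 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with enforced monotonicity, capped at 1; NA
#' p-values (non-converged genes) are excluded from the multiplicity count.
#'
#' @param p numeric p-values in \[0, 1\] (NAs allowed).
#' @return adjusted p-values.
#' @export
adjustBH <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) pnStop("inputError", "p-values outside [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-gene differential expression for one family
#'
#' Runs the full LRT chain for one model on every gene: MoM dispersion,
#' full and reduced NB GLM fits (dispersion held fixed between them), LRT
#' p-values, BH adjustment, and a temperature log2 fold-change from the
#' full fit. `model` selects the tested effect: `"temperature"` drops
#' temperature from priming + temperature, `"priming"` drops priming, and
#' `"interaction"` drops the interaction term from the full factorial.
#' `model = "wald_temperature"` instead tests the temperature coefficient
#' by Wald z within the priming + temperature model.
#'
#' @param counts filtered count matrix (genes x samples).
#' @param design matching sample table.
#' @param model one of "temperature", "priming", "interaction",
#'   "wald_temperature".
#' @param factors size factors (recomputed if omitted).
#' @param alpha FDR threshold recorded in the `significant` column
#'   (default 0.01).
#' @return data.frame: gene, log2_fold_change, statistic, p_value,
#'   p_adjusted, dispersion, test_kind, converged, significant.
#' @export
runDE <- function(counts, design, model = c("temperature", "priming",
                                            "interaction", "wald_temperature"),
                  factors = sizeFactors(counts), alpha = 0.01) {
  model <- match.arg(model)
  m <- assayMatrix(counts)
  cells <- interaction(design$priming, design$temperature, drop = TRUE)
  disp <- estimateDispersionMoM(m, cells, factors)
  plan <- switch(model,
    temperature = list(full = c("priming", "temperature"),
                       reduced = "priming", kind = "lrt"),
    priming = list(full = c("priming", "temperature"),
                   reduced = "temperature", kind = "lrt"),
    interaction = list(full = c("priming", "temperature", "interaction"),
                       reduced = c("priming", "temperature"), kind = "lrt"),
    wald_temperature = list(full = c("priming", "temperature"),
                            reduced = NULL, kind = "wald"))
  mmFull <- designMatrix(design, plan$full)
  mmRed <- if (plan$kind == "lrt") designMatrix(design, plan$reduced) else NULL
  tempCol <- grep("temperature", colnames(mmFull))[1]

  res <- lapply(seq_len(nrow(m)), function(g) {
    fitF <- fitNbGlm(m[g, ], mmFull, factors, disp[g])
    lfc <- fitF$coefficients[tempCol] / log(2)
    if (!fitF$converged) {
      return(c(lfc, NA, NA, disp[g], 0))
    }
    if (plan$kind == "lrt") {
      fitR <- fitNbGlm(m[g, ], mmRed, factors, disp[g])
      if (!fitR$converged) return(c(lfc, NA, NA, disp[g], 0))
      t <- nbLRT(fitF, fitR)
      c(lfc, t$statistic, t$p_value, disp[g], 1)
    } else {
      ctr <- numeric(ncol(mmFull)); ctr[tempCol] <- 1
      t <- waldContrast(fitF, ctr)
      c(t$log2_fold_change, t$statistic, t$p_value, disp[g], 1)
    }
  })
  res <- do.call(rbind, res)
  padj <- adjustBH(res[, 3])
  data.frame(
    gene = rownames(m),
    log2_fold_change = res[, 1],
    statistic = res[, 2],
    p_value = res[, 3],
    p_adjusted = padj,
    dispersion = res[, 4],
    test_kind = plan$kind,
    converged = res[, 5] == 1,
    significant = !is.na(padj) & padj < alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
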