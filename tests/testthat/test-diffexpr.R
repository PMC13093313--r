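test_that("method-of-moments dispersion tracks the generating value", {
  ## Poisson counts: variance = mean, so alpha should sit near the floor
  y <- withr::with_seed(1, matrix(rpois(50 * 20, 40), 20, 50))
  dimnames(y) <- list(sprintf("g%d", 1:20), sprintf("s%d", 1:50))
  a <- estimateDispersionMoM(y, rep(1, 50), rep(1, 50))
  expect_true(all(a <= 0.05))
  ## NB with size 2 (alpha = 0.5) at n = 200
  y2 <- withr::with_seed(2, matrix(rnbinom(200 * 10, mu = 50, size = 2), 10, 200))
  dimnames(y2) <- list(sprintf("g%d", 1:10), sprintf("s%d", 1:200))
  a2 <- estimateDispersionMoM(y2, rep(1, 200), rep(1, 200))
  expect_true(all(a2 > 0.3 & a2 < 0.7))
  ## all-zero gene gets the floor and a flag
  y3 <- rbind(y[1:2, ], g0 = 0L)
  a3 <- estimateDispersionMoM(y3, rep(1, 50), rep(1, 50))
  expect_equal(unname(a3["g0"]), 1e-8)
  expect_identical(attr(a3, "flagged"), "g0")
})

test_that("NB GLM recovers closed-form coefficients", {
  mm <- matrix(1, 4, 1)
  fit <- fitNbGlm(c(4L, 4L, 4L, 4L), mm, rep(1, 4), dispersion = 1e-12)
  expect_equal(unname(fit$coefficients), log(4), tolerance = 1e-8)
  ## two groups with means 4 and 8 -> group coefficient log 2
  g <- rep(0:1, each = 4)
  mm2 <- cbind(1, g)
  y <- c(4L, 4L, 4L, 4L, 8L, 8L, 8L, 8L)
  fit2 <- fitNbGlm(y, mm2, rep(1, 8), dispersion = 0.1)
  expect_equal(unname(fit2$coefficients[2]), log(2), tolerance = 1e-6)
  expect_error(fitNbGlm(y, cbind(mm2, g), rep(1, 8), 0.1),
               class = "designError")
})

test_that("NB fit converges to an independent Poisson oracle as dispersion -> 0", {
  y <- withr::with_seed(3, rpois(24, exp(3 + 0.5 * rep(c(-1, 1), 12))))
  x <- rep(c(-1, 1), 12)
  mm <- cbind(1, x)
  sf <- rep(1, 24)
  nb <- fitNbGlm(y, mm, sf, dispersion = 1e-6)   # NB family path
  oracle <- glm(y ~ x, family = poisson())
  expect_equal(unname(nb$coefficients), unname(coef(oracle)),
               tolerance = 1e-4)
  expect_equal(unname(nb$se), unname(sqrt(diag(vcov(oracle)))),
               tolerance = 1e-3)
})

test_that("LRT handles identical and nested models", {
  mm <- cbind(1, rep(0:1, each = 4))
  y <- c(2L, 3L, 4L, 3L, 9L, 7L, 8L, 9L)
  full <- fitNbGlm(y, mm, rep(1, 8), 0.05)
  same <- nbLRT(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  red <- fitNbGlm(y, mm[, 1, drop = FALSE], rep(1, 8), 0.05)
  t <- nbLRT(full, red)
  expect_equal(t$df, 1L)
  expect_gt(t$statistic, 0)
  expect_lt(t$p_value, 0.05)
  expect_error(nbLRT(red, full), class = "designError")
  ## invariant to sample reordering
  o <- c(5, 2, 7, 1, 8, 3, 6, 4)
  fullR <- fitNbGlm(y[o], mm[o, ], rep(1, 8), 0.05)
  redR <- fitNbGlm(y[o], mm[o, 1, drop = FALSE], rep(1, 8), 0.05)
  expect_equal(nbLRT(fullR, redR)$statistic, t$statistic, tolerance = 1e-8)
})

test_that("Wald contrasts behave as z-tests on coefficient combinations", {
  mm <- cbind(1, rep(0:1, each = 10))
  y <- withr::with_seed(4, rnbinom(20, mu = rep(c(30, 60), each = 10), size = 10))
  fit <- fitNbGlm(y, mm, rep(1, 20), 0.1)
  z0 <- waldContrast(fit, c(0, 0))
  expect_equal(z0$statistic, 0)
  expect_equal(z0$p_value, 1)
  w <- waldContrast(fit, c(0, 1))
  expect_equal(w$statistic, fit$coefficients[2] / fit$se[2],
               ignore_attr = TRUE, tolerance = 1e-12)
  ## comparable to the LRT on well-separated groups
  red <- fitNbGlm(y, mm[, 1, drop = FALSE], rep(1, 20), 0.1)
  l <- nbLRT(fit, red)
  expect_lt(w$p_value / l$p_value, 2)
  expect_gt(w$p_value / l$p_value, 0.5)
  expect_error(waldContrast(fit, c(1, 0, 0)), class = "designError")
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustBH(0.2), 0.2)
  expect_equal(adjustBH(rep(1, 5)), rep(1, 5))
  ## hand computation with distinct values:
  ## sorted p (.005,.02,.03,.1): m/i * p = (.02,.04,.04,.1) after monotonicity
  expect_equal(adjustBH(c(0.03, 0.005, 0.1, 0.02)),
               c(0.04, 0.02, 0.10, 0.04))
  expect_error(adjustBH(c(0.5, 1.2)), class = "inputError")
  expect_equal(adjustBH(c(0.01, NA, 0.04)),
               p.adjust(c(0.01, NA, 0.04), "BH"))
})

test_that("planted fold-changes are detected with high power at n = 10 per group", {
  n <- 10L
  des <- data.frame(
    sample_id = sprintf("s%d", 1:(2 * n)),
    family = "B",
    priming = rep(c("naive", "primed"), n),
    temperature = rep(c("control", "stress"), each = n)
  )
  nDE <- 60L; nNull <- 240L
  mu0 <- 50
  counts <- withr::with_seed(5, {
    lfc <- c(rep(2, nDE), rep(0, nNull))
    t(sapply(lfc, function(l) {
      mu <- mu0 * 2^(l * (des$temperature == "stress"))
      rnbinom(2 * n, mu = mu, size = 10)
    }))
  })
  dimnames(counts) <- list(sprintf("g%d", seq_len(nDE + nNull)), des$sample_id)
  res <- runDE(counts, des, "temperature", factors = rep(1, 2 * n))
  power <- mean(res$significant[seq_len(nDE)])
  expect_gt(power, 0.8)
  ## discoveries shrink as alpha drops
  expect_lte(sum(res$p_adjusted < 0.001, na.rm = TRUE),
             sum(res$p_adjusted < 0.01, na.rm = TRUE))
})

test_that("the three DEG model sets partition their union set-algebraically", {
  se <- simulateExperiment(tinyConfig(seed = 9L))
  design <- as.data.frame(SummarizedExperiment::colData(se))
  cts <- filterLowExpression(SummarizedExperiment::assay(se)[, design$family == "B"])
  des <- design[design$family == "B", ]
  sets <- lapply(c("temperature", "priming", "interaction"), function(mod) {
    r <- runDE(cts, des, mod)
    r$gene[r$significant]
  })
  union <- Reduce(base::union, sets)
  venn <- c(
    only1 = length(setdiff(sets[[1]], union(sets[[2]], sets[[3]]))),
    only2 = length(setdiff(sets[[2]], union(sets[[1]], sets[[3]]))),
    only3 = length(setdiff(sets[[3]], union(sets[[1]], sets[[2]]))),
    i12 = length(setdiff(intersect(sets[[1]], sets[[2]]), sets[[3]])),
    i13 = length(setdiff(intersect(sets[[1]], sets[[3]]), sets[[2]])),
    i23 = length(setdiff(intersect(sets[[2]], sets[[3]]), sets[[1]])),
    i123 = length(Reduce(intersect, sets))
  )
  expect_equal(sum(venn), length(union))
})
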