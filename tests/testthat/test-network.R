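test_that("signed adjacency maps correlation through ((1+r)/2)^beta", {
  ## construct genes with exact correlations 1, -1 and 0
  x <- c(1, 2, 3, 4)
  m <- rbind(a = x, b = 2 * x + 1, c = -x, d = c(1, -1, 1, -1) * sd(x))
  colnames(m) <- sprintf("s%d", 1:4)
  m["d", ] <- c(1, -1, -1, 1)   # orthogonal to the linear trend
  net <- signedAdjacency(m, power = 6L)
  expect_equal(net$adjacency["a", "b"], 1)
  expect_equal(net$adjacency["a", "c"], 0)
  expect_equal(net$adjacency["a", "d"], 0.5^6)
  expect_true(isSymmetric(net$adjacency))
  expect_equal(unname(diag(net$adjacency)), rep(1, 4))
  mz <- rbind(m, e = c(2, 2, 2, 2))
  expect_error(signedAdjacency(mz), class = "inputError")
})

test_that("TOM matches closed forms and a triple-loop oracle", {
  ## 2-gene network: TOM_12 = a_12
  m2 <- blockExpr(2, 8, loading = 0.9, seed = 3)[1:2, ]
  net2 <- signedAdjacency(m2, 6L)
  tom2 <- tomSimilarity(net2)
  expect_equal(tom2[1, 2], net2$adjacency[1, 2], tolerance = 1e-12)
  ## complete graph with all a = 1
  netc <- list(adjacency = matrix(1, 5, 5,
                                  dimnames = list(letters[1:5], letters[1:5])))
  expect_true(all(abs(tomSimilarity(netc) - 1) < 1e-12))
  ## random 6-gene adjacency vs brute-force triple loop
  a <- withr::with_seed(4, {
    r <- matrix(runif(36, 0, 0.9), 6, 6)
    r <- (r + t(r)) / 2
    diag(r) <- 1
    r
  })
  dimnames(a) <- list(sprintf("g%d", 1:6), sprintf("g%d", 1:6))
  tom <- tomSimilarity(list(adjacency = a))
  oracle <- matrix(1, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    if (i == j) next
    l <- 0
    for (u in 1:6) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    oracle[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  expect_equal(unname(tom), oracle, tolerance = 1e-12)
})

test_that("planted correlation blocks are detected as modules", {
  m <- blockExpr(c(60, 60), 40, loading = 0.95, n_noise = 0, seed = 5)
  nw <- signedAdjacency(m, 6L)
  labs <- detectModules(tomSimilarity(nw), networkConfig(min_module_size = 50))
  truth <- rep(1:2, c(60, 60))
  expect_equal(adjustedRandIndex(truth, labs), 1)
  ## min size above n -> everything background, with a warning
  expect_warning(
    labs0 <- detectModules(tomSimilarity(nw),
                           networkConfig(min_module_size = 200L)),
    "min_module_size")
  expect_true(all(labs0 == 0L))
  ## a 30-gene block dissolves under min size 50
  m30 <- blockExpr(c(30, 60), 40, loading = 0.95, n_noise = 60, seed = 6)
  labs30 <- detectModules(tomSimilarity(signedAdjacency(m30, 6L)),
                          networkConfig(min_module_size = 50))
  expect_true(all(labs30[1:30] == 0L))
  expect_equal(length(unique(labs30[31:90])), 1L)
})

test_that("module labels are stable under gene reordering", {
  m <- blockExpr(c(60, 60), 30, loading = 0.9, n_noise = 30, seed = 7)
  cfg <- networkConfig(min_module_size = 50)
  labs <- detectModules(tomSimilarity(signedAdjacency(m, 6L)), cfg)
  perm <- withr::with_seed(8, sample(nrow(m)))
  labsP <- detectModules(tomSimilarity(signedAdjacency(m[perm, ], 6L)), cfg)
  expect_equal(adjustedRandIndex(labs[rownames(m)], labsP[rownames(m)]), 1)
})

test_that("eigengenes equal the first principal component, sign-oriented", {
  ## identical genes: ME is the standardized common profile, kME = 1
  prof <- c(1, 4, 2, 6, 3, 5)
  m <- matrix(rep(prof, each = 4), 4, 6,
              dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:6)))
  m <- m + withr::with_seed(9, matrix(rnorm(24, sd = 1e-8), 4, 6))
  ms <- moduleEigengenesFromLabels(m, setNames(rep(1L, 4), rownames(m)))
  me <- moduleEigengenes(ms)
  expect_equal(unname(drop(me)), (prof - mean(prof)) / sd(prof),
               tolerance = 1e-4, ignore_attr = TRUE)
  expect_true(all(kME(ms)[, 1] > 1 - 1e-6))
  ## random 20-gene module vs full SVD oracle
  m2 <- blockExpr(20, 15, loading = 0.8, seed = 10)
  ms2 <- moduleEigengenesFromLabels(m2, setNames(rep(1L, 20), rownames(m2)))
  z <- t(scale(t(m2)))
  sv <- svd(z)
  oracle <- sv$v[, 1] / sd(sv$v[, 1])
  me2 <- drop(moduleEigengenes(ms2))
  expect_equal(abs(cor(me2, oracle)), 1, tolerance = 1e-10)
  expect_true(mean(kME(ms2)[, 1]) >= 0)  # orientation convention
  ## no unit vector explains more member variance than the eigengene
  proj <- function(v) sum(crossprod(t(z), v / sqrt(sum(v^2)))^2)
  meRaw <- me2 / sqrt(sum(me2^2))
  best <- proj(me2)
  rand <- withr::with_seed(11, replicate(50, proj(rnorm(15))))
  expect_true(all(best >= rand - 1e-8))
})

test_that("modules merge when their eigengenes nearly coincide", {
  ## two blocks driven by the same factor (cor(ME) ~ 0.95) plus one
  ## independent block
  m <- withr::with_seed(12, {
    f1 <- rnorm(30); f2 <- rnorm(30)
    rbind(
      0.9 * matrix(f1, 60, 30, byrow = TRUE) + matrix(rnorm(1800, sd = .3), 60),
      0.9 * matrix(f1, 60, 30, byrow = TRUE) + matrix(rnorm(1800, sd = .45), 60),
      0.9 * matrix(f2, 60, 30, byrow = TRUE) + matrix(rnorm(1800, sd = .3), 60)
    )
  })
  dimnames(m) <- list(sprintf("g%04d", 1:180), sprintf("s%d", 1:30))
  labels <- setNames(rep(1:3, each = 60), rownames(m))
  ms <- moduleEigengenesFromLabels(m, labels)
  me <- moduleEigengenes(ms)
  expect_gt(cor(me[1, ], me[2, ]), 0.75)   # will merge at height 0.25
  expect_lt(abs(cor(me[1, ], me[3, ])), 0.5)
  merged <- mergeModules(m, ms, merge_height = 0.25)
  labM <- moduleLabels(merged)
  expect_equal(length(unique(labM)), 2L)
  expect_equal(length(unique(labM[1:120])), 1L)
  ## merge_height -> 0 is the identity
  same <- mergeModules(m, ms, merge_height = 1e-9)
  expect_equal(length(unique(moduleLabels(same))), 3L)
})

test_that("gene significance is the absolute trait correlation", {
  tr <- rep(c(-1, 1), each = 10)
  m <- rbind(hit = tr, anti = -tr,
             null = withr::with_seed(13, rnorm(20)))
  colnames(m) <- sprintf("s%d", 1:20)
  gs <- geneSignificance(m, tr)
  expect_equal(unname(gs[c("hit", "anti")]), c(1, 1))
  ## affine transformation of the trait changes nothing
  expect_equal(gs, geneSignificance(m, 3 * tr + 7))
  expect_error(geneSignificance(m, rep(1, 20)), class = "inputError")
  ## a trait-independent gene stays near zero at n = 1000
  m2 <- matrix(withr::with_seed(14, rnorm(1000)), 1, 1000,
               dimnames = list("g", sprintf("s%d", 1:1000)))
  tr2 <- rep(c(-1, 1), 500)
  expect_lt(geneSignificance(m2, tr2), 0.1)
})

test_that("module-trait correlations recover planted trait links", {
  tr <- cbind(priming = rep(c(-1, 1), 8),
              temperature = rep(c(-1, -1, 1, 1), 4),
              weight = withr::with_seed(15, runif(16, 0.1, 0.3)))
  me <- rbind(ME1 = scale(tr[, "temperature"])[, 1])
  colnames(me) <- sprintf("s%d", 1:16)
  ms <- new("ModuleSet", labels = setNames(integer(0), character(0)),
            eigengenes = me, kME = matrix(numeric(0), 0, 0),
            geneSignificance = numeric(0), moduleTrait = data.frame())
  mt <- moduleTraitCor(ms, tr)
  row <- mt[mt$trait == "temperature", ]
  expect_equal(row$rho, 1)
  expect_lt(row$p_value, 1e-6)
  ## joint sign flip leaves rho unchanged
  ms2 <- ms; ms2@eigengenes <- -me
  mt2 <- moduleTraitCor(ms2, tr * cbind(-1, -1, -1)[rep(1, 16), ])
  expect_equal(mt2[mt2$trait == "temperature", "rho"], 1)
  expect_error(moduleTraitCor(ms, cbind(flat = rep(1, 16))),
               class = "inputError")
})

test_that("weighted degree sums adjacency within scope", {
  a <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  net <- list(adjacency = a)
  labs <- setNames(c(1L, 1L, 1L, 2L, 0L), letters[1:5])
  k <- weightedDegree(net, labs, "intramodular")
  expect_equal(unname(k[1:3]), rep(2, 3))  # 3-gene complete module
  expect_equal(unname(k["d"]), 0)          # singleton module
  expect_equal(unname(k["e"]), 0)          # background
  kw <- weightedDegree(net, scope = "whole")
  expect_equal(unname(kw), rep(4, 5))
  ## row-sum oracle on a random network
  ar <- withr::with_seed(16, {
    r <- matrix(runif(49), 7, 7); r <- (r + t(r)) / 2; diag(r) <- 1; r
  })
  dimnames(ar) <- list(sprintf("g%d", 1:7), sprintf("g%d", 1:7))
  kr <- weightedDegree(list(adjacency = ar), scope = "whole")
  expect_equal(unname(kr), unname(rowSums(ar) - 1), tolerance = 1e-12)
})

test_that("soft-threshold selection matches an independent binning oracle", {
  ## heterogeneous-hub toy: connectivity spans orders of magnitude
  m <- withr::with_seed(17, {
    f <- rnorm(30)
    l <- runif(150, 0.05, 0.95)
    l * matrix(f, 150, 30, byrow = TRUE) +
      matrix(rnorm(4500, sd = sqrt(1 - l^2)), 150, 30)
  })
  dimnames(m) <- list(sprintf("g%04d", 1:150), sprintf("s%d", 1:30))
  pick <- pickSoftPower(m, powers = c(2, 4, 6, 8), target_r2 = 0.8)
  expect_true(pick$power %in% c(2, 4, 6, 8))
  ## oracle: recompute the fit index for the chosen power independently
  rho <- cor(t(m))
  a <- ((1 + rho) / 2)^pick$power
  diag(a) <- 0
  k <- rowSums(a)
  bin <- cut(k, seq(min(k), max(k), length.out = 11), include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  kb <- tapply(k, bin, mean)
  ok <- !is.na(pk) & pk > 0
  fit <- summary(lm(log10(pk[ok]) ~ log10(kb[ok])))
  oracleR2 <- unname(fit$r.squared * ifelse(coef(fit)[2, 1] > 0, -1, 1))
  chosen <- pick$fit$r_squared[pick$fit$power == pick$power]
  expect_lt(abs(chosen - oracleR2), 0.05)
  ## single candidate power is returned as-is
  one <- pickSoftPower(m, powers = 6L)
  expect_equal(one$power, 6L)
  ## duplicating every gene does not change the selection
  m2 <- rbind(m, m + withr::with_seed(18, matrix(rnorm(4500, sd = 1e-6), 150)))
  rownames(m2) <- sprintf("g%04d", 1:300)
  expect_equal(pickSoftPower(m2, powers = c(2, 4, 6, 8))$power, pick$power)
})
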