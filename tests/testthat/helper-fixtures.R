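## Shared fixtures, all built in code.

## A small, fast simulation: two planted modules, second one scrambled in
## family A, no candidates unless asked.
tinyConfig <- function(seed = 1L, ...) {
  defaults <- list(
    n_genes = 600L, module_sizes = c(80L, 60L), samples_per_cell = 4L,
    eigengene_effects = list(list(temperature = 0.8), list(priming = -0.9)),
    nonpreserved_module_index = 2L, n_candidates = 0L,
    de_fraction = 0.05, seed = seed
  )
  do.call(simConfig, utils::modifyList(defaults, list(...)))
}

## Expression matrix with two planted correlation blocks plus noise genes.
## Block genes = loading * shared factor + noise; exact control over sizes.
blockExpr <- function(sizes, n_samples, loading = 0.9, n_noise = 0,
                      seed = 1L) {
  withr::with_seed(seed, {
    nG <- sum(sizes) + n_noise
    m <- matrix(rnorm(nG * n_samples, sd = sqrt(1 - loading^2)),
                nG, n_samples)
    at <- 1L
    for (s in sizes) {
      f <- rnorm(n_samples)
      m[at:(at + s - 1L), ] <- loading * matrix(f, s, n_samples, byrow = TRUE) +
        m[at:(at + s - 1L), ]
      at <- at + s
    }
    dimnames(m) <- list(sprintf("g%04d", seq_len(nG)),
                        sprintf("s%03d", seq_len(n_samples)))
    m
  })
}

## Deterministic toy count matrix with ids.
toyCounts <- function(values, nr, nc) {
  matrix(as.integer(values), nr, nc,
         dimnames = list(sprintf("g%d", seq_len(nr)),
                         sprintf("s%d", seq_len(nc))))
}

## Seven preservation statistics by explicit pairwise loops -- the
## independent oracle against the vectorized implementation.
presOracle <- function(discExpr, testExpr, genes, power = 6) {
  nd <- ncol(discExpr); nt <- ncol(testExpr)
  m <- length(genes)
  corD <- matrix(1, m, m); corT <- matrix(1, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    corD[i, j] <- cor(discExpr[genes[i], ], discExpr[genes[j], ])
    corT[i, j] <- cor(testExpr[genes[i], ], testExpr[genes[j], ])
  }
  adjT <- ((1 + corT) / 2)^power
  adjD <- ((1 + corD) / 2)^power
  degT <- numeric(m); degD <- numeric(m)
  for (i in seq_len(m)) {
    degT[i] <- sum(adjT[i, -i])
    degD[i] <- sum(adjD[i, -i])
  }
  ncOf <- function(expr) {
    z <- t(scale(t(expr[genes, ])))
    pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
    h <- pc$x[, 1]
    nc <- apply(expr[genes, ], 1, function(g) cor(g, h))
    if (mean(nc) < 0) nc <- -nc
    list(nc = nc,
         coherence = pc$sdev[1]^2 / sum(pc$sdev^2))
  }
  d <- ncOf(discExpr); t <- ncOf(testExpr)
  lt <- lower.tri(corT)
  c(avg_weight = mean(adjT[lt]),
    coherence = t$coherence,
    avg_contrib = mean(sign(d$nc) * t$nc),
    cor_contrib = cor(d$nc, t$nc),
    avg_cor = mean(corT[lt] * sign(corD[lt])),
    cor_cor = cor(corD[lt], corT[lt]),
    cor_degree = cor(degD, degT))
}
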