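## Synthetic factorial transcriptome generator with planted ground truth.
##
## Emulates a 2-family x 2-priming x 2-temperature spat rearing design:
## latent module eigengenes respond to the coded temperature and/or priming
## factors, genes load on their module's eigengene, and counts are negative
## binomial with per-sample depth offsets. One module can be "scrambled" in
## family 1: each of its genes gets a re-drawn loading on its own private
## latent factor, so the genes stay expressed with the same marginal spread
## but decorrelate from each other -- the ground truth for the
## module-preservation stage.

#' Simulation configuration
#'
#' Builds and validates the parameter set for [simulateExperiment()].
#' Defaults are the package's reference study conditions: 4,000 genes, four
#' planted modules of 300/250/150/100 genes, 6 samples per
#' family x priming x temperature cell (48 samples in all), module
#' eigengenes responding to temperature and/or priming, the first module
#' non-preserved in family 1, and 10 planted high-loading candidate genes
#' inside that module.
#'
#' @param n_genes total number of genes.
#' @param module_sizes integer vector of planted module sizes; remaining
#'   genes are unstructured background.
#' @param samples_per_cell replicates per family x priming x temperature
#'   cell (>= 2).
#' @param eigengene_effects list, one element per module, each a list with
#'   numeric `temperature` and/or `priming` effects on the latent eigengene
#'   (factors coded -1/+1).
#' @param eigengene_sd total standard deviation of every module
#'   eigengene: the trait effects take their share of the variance and
#'   independent latent noise fills the remainder, so trait-linked and
#'   trait-free modules are equally coherent. Noise vectors are drawn
#'   orthogonal to the trait codings and to each other within a family,
#'   so distinct modules do not align by sampling accident.
#' @param loading_range interval in (0, 1] from which gene loadings on the
#'   module eigengene are drawn uniformly.
#' @param nb_dispersion negative-binomial dispersion alpha
#'   (variance = mu + alpha * mu^2).
#' @param gene_noise_range interval of per-gene biological noise standard
#'   deviations (log2 scale): each gene draws its own sd, giving the
#'   heterogeneous module membership seen in real data. Planted candidates
#'   take the interval minimum — hub genes are the module's most cleanly
#'   coupled members.
#' @param mean_log_expression interval of baseline log2 mean counts.
#' @param library_size_range interval of per-sample relative depth factors
#'   (log-normal, clamped to the interval).
#' @param nonpreserved_module_index module whose family-1 structure is
#'   scrambled, or `NA` for none.
#' @param de_fraction fraction of background genes given a temperature
#'   log2 fold-change of `de_effect` (random sign per gene).
#' @param de_effect absolute log2 fold-change for planted DE genes.
#' @param n_candidates number of planted hub-DE candidate genes in the
#'   scrambled (triage) module; they get loading `candidate_loading`,
#'   above the regular loading range, so they are the module's strongest
#'   hubs and most trait-correlated members.
#' @param candidate_loading eigengene gain of planted candidates; above
#'   the regular loading interval (may exceed 1), making them the module's
#'   cleanest, strongest hubs.
#' @param candidate_priming_effect direct log2 shift of candidate genes
#'   with the coded priming factor (a cis effect on top of the module
#'   eigengene), making them the module's most priming-correlated genes.
#' @param candidate_temperature_effect direct log2 shift of candidates
#'   with the coded temperature factor, reinforcing their heat-stress
#'   differential expression.
#' @param seed integer; fully determines all output.
#' @return a validated `simConfig` list.
#' @export
simConfig <- function(n_genes = 4000L,
                      module_sizes = c(300L, 250L, 150L, 100L),
                      samples_per_cell = 6L,
                      eigengene_effects = list(
                        list(temperature = 0.8, priming = 0.7),
                        list(temperature = -0.9),
                        list(priming = -0.9),
                        list()
                      ),
                      loading_range = c(0.4, 0.85),
                      eigengene_sd = 1.1,
                      nb_dispersion = 0.1,
                      gene_noise_range = c(0.1, 0.6),
                      mean_log_expression = c(3, 9),
                      library_size_range = c(0.7, 1.4),
                      nonpreserved_module_index = 1L,
                      de_fraction = 0.1,
                      de_effect = 2,
                      n_candidates = 10L,
                      candidate_loading = 1.3,
                      candidate_priming_effect = 0.8,
                      candidate_temperature_effect = 0.3,
                      seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), module_sizes = as.integer(module_sizes),
    samples_per_cell = as.integer(samples_per_cell), n_families = 2L,
    eigengene_effects = eigengene_effects, loading_range = loading_range,
    eigengene_sd = eigengene_sd, nb_dispersion = nb_dispersion, gene_noise_range = gene_noise_range,
    mean_log_expression = mean_log_expression,
    library_size_range = library_size_range,
    nonpreserved_module_index =
      if (is.na(nonpreserved_module_index)) NA_integer_
      else as.integer(nonpreserved_module_index),
    de_fraction = de_fraction, de_effect = de_effect,
    n_candidates = as.integer(n_candidates),
    candidate_loading = candidate_loading,
    candidate_priming_effect = candidate_priming_effect,
    candidate_temperature_effect = candidate_temperature_effect,
    seed = as.integer(seed)
  )
  if (cfg$samples_per_cell < 2L) {
    pnStop("invalidConfig", "samples_per_cell must be >= 2, got %d",
           cfg$samples_per_cell)
  }
  if (any(cfg$module_sizes < 1L)) {
    pnStop("invalidConfig", "module sizes must be positive")
  }
  if (sum(cfg$module_sizes) > cfg$n_genes) {
    pnStop("invalidConfig",
           "module sizes sum (%d) exceeds n_genes (%d)",
           sum(cfg$module_sizes), cfg$n_genes)
  }
  if (length(cfg$eigengene_effects) != length(cfg$module_sizes)) {
    pnStop("invalidConfig", "need one eigengene_effects entry per module")
  }
  effs <- unlist(cfg$eigengene_effects)
  if (length(effs) && any(!is.finite(effs))) {
    pnStop("invalidConfig", "eigengene effects must be finite")
  }
  if (cfg$loading_range[1] <= 0 || cfg$loading_range[2] > 1 ||
      diff(cfg$loading_range) < 0) {
    pnStop("invalidConfig", "loading_range must be an interval within (0, 1]")
  }
  if (!is.na(cfg$nonpreserved_module_index) &&
      (cfg$nonpreserved_module_index < 1L ||
       cfg$nonpreserved_module_index > length(cfg$module_sizes))) {
    pnStop("invalidConfig", "nonpreserved_module_index out of range")
  }
  class(cfg) <- "simConfig"
  cfg
}

#' Simulate the factorial sample design
#'
#' Produces the sample sheet of a 2-family x 2-priming (naive/primed) x
#' 2-temperature (control/stress) design with `samples_per_cell` replicates
#' per cell. Tanks alternate between two duplicates within each cell;
#' individual weights are log-normal with mean 0.19 g and sd 0.06 g (the
#' size class of the assayed spat).
#'
#' @param config a [simConfig()].
#' @return data.frame with columns sample_id, family, priming, temperature,
#'   tank, weight.
#' @export
simulateDesign <- function(config = simConfig()) {
  stopifnot(inherits(config, "simConfig"))
  withSeed(fanOutSeed(config$seed, "design"), {
    cells <- expand.grid(
      rep = seq_len(config$samples_per_cell),
      temperature = c("control", "stress"),
      priming = c("naive", "primed"),
      family = c("A", "B"),
      stringsAsFactors = FALSE
    )
    n <- nrow(cells)
    ## weight: log-normal matching mean 0.19 g, sd 0.06 g
    cv <- 0.06 / 0.19
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(0.19) - sdlog^2 / 2
    data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      family = cells$family,
      priming = cells$priming,
      temperature = cells$temperature,
      tank = sprintf("%s_%s_%s_T%d", cells$family, cells$priming,
                     cells$temperature, 1L + (cells$rep - 1L) %% 2L),
      weight = rlnorm(n, meanlog, sdlog),
      stringsAsFactors = FALSE
    )
  })
}

## -1/+1 coding of the two treatment factors plus weight.
#' Numeric trait coding of a sample table
#'
#' Codes priming (naive = -1, primed = +1) and temperature
#' (control = -1, stress = +1) and carries weight through; the coding used
#' by the generator, gene significance and module-trait correlations.
#'
#' @param design a sample table as returned by [simulateDesign()].
#' @return numeric matrix with columns priming, temperature, weight.
#' @export
codeTraits <- function(design) {
  cbind(
    priming = ifelse(design$priming == "primed", 1, -1),
    temperature = ifelse(design$temperature == "stress", 1, -1),
    weight = design$weight
  )
}

#' Simulate counts with planted module and trait structure
#'
#' For each family and module, a latent eigengene is a linear combination
#' of the coded temperature/priming factors plus standard normal noise;
#' each member gene's log2 mean is its baseline plus loading x eigengene.
#' In the non-preserved module, family-1 genes are split across two
#' independent latent factors with re-drawn loadings and random sign, so
#' the module stays expressed but its family-1 correlation structure no
#' longer matches family 2. A configured fraction of background genes gets
#' a +/- `de_effect` log2 fold-change under stress. Counts are negative
#' binomial around depth-scaled means.
#'
#' @param config a [simConfig()].
#' @param design the matching sample table from [simulateDesign()].
#' @return list with `counts` (integer matrix genes x samples) and
#'   `groundTruth` (module labels, DE genes, candidates, eigengenes,
#'   non-preserved module id).
#' @export
simulateExpression <- function(config = simConfig(),
                               design = simulateDesign(config)) {
  stopifnot(inherits(config, "simConfig"))
  nG <- config$n_genes
  nS <- nrow(design)
  nMod <- length(config$module_sizes)
  geneIds <- sprintf("g%05d", seq_len(nG))
  labels <- integer(nG)
  idx <- 1L
  for (m in seq_len(nMod)) {
    labels[idx:(idx + config$module_sizes[m] - 1L)] <- m
    idx <- idx + config$module_sizes[m]
  }
  names(labels) <- geneIds
  traits <- codeTraits(design)
  fams <- unique(design$family)

  withSeed(fanOutSeed(config$seed, "expression"), {
    baseline <- runif(nG, config$mean_log_expression[1],
                      config$mean_log_expression[2])
    ## shared loadings; planted candidates sit at candidate_loading
    loading <- runif(nG, config$loading_range[1], config$loading_range[2])
    tri <- config$nonpreserved_module_index
    candidates <- character(0)
    if (!is.na(tri) && config$n_candidates > 0L) {
      modGenes <- geneIds[labels == tri]
      candidates <- sort(sample(modGenes, min(config$n_candidates,
                                              length(modGenes))))
      loading[match(candidates, geneIds)] <- config$candidate_loading
    }
    ## background DE genes: temperature log2FC with random sign
    bg <- which(labels == 0L)
    nDE <- floor(config$de_fraction * length(bg))
    deIdx <- sort(sample(bg, nDE))
    deSign <- sample(c(-1, 1), nDE, replace = TRUE)
    deShift <- numeric(nG)
    deShift[deIdx] <- deSign * config$de_effect / 2  # +/- half per condition

    ## per-sample depth factors, log-normal clamped to the configured range
    lr <- config$library_size_range
    depth <- rlnorm(nS, mean(log(lr)), (log(lr[2]) - log(lr[1])) / 4)
    depth <- pmin(pmax(depth, lr[1]), lr[2])

    log2mu <- matrix(rep(baseline, nS), nrow = nG)
    eig <- matrix(0, nMod, nS,
                  dimnames = list(
                    if (nMod) paste0("module", seq_len(nMod)) else character(0),
                    design$sample_id))
    for (f in fams) {
      sIdx <- which(design$family == f)
      ns <- length(sIdx)
      Tc <- traits[sIdx, "temperature"]
      Pc <- traits[sIdx, "priming"]
      ## latent eigengene noise, orthogonal to the trait codings and
      ## mutually orthogonal (when sample count allows), unit sd
      rawNoise <- matrix(rnorm(nMod * ns), ns, nMod)
      if (ns >= nMod + 3L) {
        Q <- qr.Q(qr(cbind(1, Tc, Pc, rawNoise)))
        noise <- Q[, 3L + seq_len(nMod), drop = FALSE] * sqrt(ns - 1)
      } else {
        noise <- scale(rawNoise)
      }
      for (m in seq_len(nMod)) {
        eff <- config$eigengene_effects[[m]]
        aT <- if (!is.null(eff$temperature)) eff$temperature else 0
        aP <- if (!is.null(eff$priming)) eff$priming else 0
        resid <- sqrt(max(config$eigengene_sd^2 - aT^2 - aP^2, 0.0625))
        E <- aT * Tc + aP * Pc + resid * noise[, m]
        eig[m, sIdx] <- E
        gIdx <- which(labels == m)
        if (!is.na(tri) && m == tri && f == fams[1]) {
          ## scrambled family: loadings re-drawn independently per gene,
          ## each applied to that gene's own latent factor, so the genes
          ## stay expressed (same marginal spread) but decorrelate
          lNew <- runif(length(gIdx), config$loading_range[1],
                        config$loading_range[2])
          Eown <- matrix(rnorm(length(gIdx) * length(sIdx),
                               sd = config$eigengene_sd),
                         length(gIdx), length(sIdx))
          log2mu[gIdx, sIdx] <- log2mu[gIdx, sIdx] + lNew * Eown
        } else {
          log2mu[gIdx, sIdx] <- log2mu[gIdx, sIdx] +
            outer(loading[gIdx], E)
        }
      }
    }
    ## per-gene biological noise; candidates are clean hubs (minimum sd)
    geneSd <- runif(nG, config$gene_noise_range[1], config$gene_noise_range[2])
    ## direct (cis) effects on planted candidates, in the family where the
    ## module is intact only (the genotype-dependent response the triage
    ## stage is meant to find): priming shift plus the full DE temperature
    ## response (hub-DE genes), minimal gene noise
    if (length(candidates)) {
      cIdx <- match(candidates, geneIds)
      geneSd[cIdx] <- config$gene_noise_range[1]
      sB <- which(design$family == fams[length(fams)])
      log2mu[cIdx, sB] <- log2mu[cIdx, sB] +
        config$candidate_priming_effect *
        matrix(traits[sB, "priming"], length(cIdx), length(sB), byrow = TRUE) +
        config$candidate_temperature_effect *
        matrix(traits[sB, "temperature"], length(cIdx), length(sB), byrow = TRUE)
    }
    log2mu <- log2mu + matrix(rnorm(nG * nS, 0, geneSd), nG, nS)
    ## background temperature DE
    stress <- traits[, "temperature"] > 0
    log2mu[, stress] <- log2mu[, stress] + deShift[row(log2mu[, stress])]
    log2mu[, !stress] <- log2mu[, !stress] - deShift[row(log2mu[, !stress])]

    mu <- sweep(2^log2mu, 2, depth, `*`)
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                     nrow = nG, dimnames = list(geneIds, design$sample_id))
    storage.mode(counts) <- "integer"

    gt <- list(
      module_labels = labels,
      de_genes = geneIds[deIdx],
      de_sign = setNames(deSign, geneIds[deIdx]),
      candidates = candidates,
      nonpreserved_module = tri,
      eigengenes = eig,
      gene_noise_sd = setNames(geneSd, geneIds),
      baseline_log2 = setNames(baseline, geneIds),
      depth = setNames(depth, design$sample_id)
    )
    list(counts = counts, groundTruth = gt)
  })
}

#' Simulate a complete experiment as a SummarizedExperiment
#'
#' Convenience wrapper chaining [simulateDesign()] and
#' [simulateExpression()]; the ground truth and configuration are stored in
#' `metadata()`.
#'
#' @param config a [simConfig()].
#' @return a [SummarizedExperiment::SummarizedExperiment] with a `counts`
#'   assay, the sample table as `colData`, and
#'   `metadata(x)$groundTruth` / `metadata(x)$config`.
#' @export
simulateExperiment <- function(config = simConfig()) {
  design <- simulateDesign(config)
  sim <- simulateExpression(config, design)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = sim$counts),
    colData = S4Vectors::DataFrame(design, row.names = design$sample_id),
    metadata = list(groundTruth = sim$groundTruth, config = config)
  )
}
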