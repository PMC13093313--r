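## End-to-end orchestration: preprocess -> DE -> per-family networks ->
## cross-family preservation (both directions) -> candidate triage ->
## enrichment, with every output written as TSV plus a JSON run manifest.

#' Pipeline configuration
#'
#' Bundles per-stage configurations, the input container, the output
#' directory and a single global seed that is fanned out to every
#' stochastic stage.
#'
#' @param se a [SummarizedExperiment::SummarizedExperiment] with a
#'   `counts` assay and family/priming/temperature colData (e.g. from
#'   [simulateExperiment()]).
#' @param out_dir output directory.
#' @param filter a [filterConfig()].
#' @param network a [networkConfig()].
#' @param preservation a [preservationConfig()].
#' @param triage a [triageConfig()].
#' @param annotations optional [classMap()] for enrichment.
#' @param de_alpha FDR threshold for DEG calls (default 0.01).
#' @param stages subset of `c("diffexpr", "network", "preservation",
#'   "candidates", "enrichment")` to run (preprocessing always runs).
#'   Dependencies are validated: preservation and candidates require
#'   network, candidates also require diffexpr and preservation.
#' @param seed global seed.
#' @return validated `pipelineConfig` list.
#' @export
pipelineConfig <- function(se, out_dir, filter = filterConfig(),
                           network = networkConfig(),
                           preservation = preservationConfig(),
                           triage = triageConfig(),
                           annotations = NULL, de_alpha = 0.01,
                           stages = c("diffexpr", "network", "preservation",
                                      "candidates", "enrichment"),
                           seed = 1L) {
  stopifnot(is(se, "SummarizedExperiment"))
  stages <- match.arg(stages, several.ok = TRUE)
  needs <- list(preservation = "network",
                candidates = c("diffexpr", "network", "preservation"))
  for (st in names(needs)) {
    if (st %in% stages && !all(needs[[st]] %in% stages)) {
      pnStop("invalidConfig", "stage '%s' requires stage(s): %s",
             st, paste(setdiff(needs[[st]], stages), collapse = ", "))
    }
  }
  cfg <- list(se = se, out_dir = out_dir, filter = filter, network = network,
              preservation = preservation, triage = triage,
              annotations = annotations, de_alpha = de_alpha,
              stages = stages, seed = as.integer(seed))
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Run the full analysis chain
#'
#' Per family: CPM filtering, size factors, log normalization, variance
#' filtering, connectivity-outlier removal, temperature/priming/interaction
#' DE, network + module detection, module-trait correlations. Then module
#' preservation in both directions (each family as discovery, the other as
#' test), candidate triangulation on the first module that fails
#' preservation (or the largest module), and — when annotations are
#' supplied — delta-rank enrichment on the temperature fold-changes.
#' All tables are written under `out_dir`; a JSON manifest of parameters,
#' input checksum and outputs is written last.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, the manifest list (also saved as manifest.json).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  se <- config$se
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- as.data.frame(SummarizedExperiment::colData(se))
  fams <- sort(unique(design$family))
  outputs <- character(0)
  emit <- function(df, name) {
    p <- writeTsv(df, file.path(config$out_dir, name))
    outputs <<- c(outputs, p)
    p
  }

  perFamily <- list()
  for (f in fams) {
    sIdx <- design$family == f
    cts <- assayMatrix(se)[, sIdx, drop = FALSE]
    des <- design[sIdx, , drop = FALSE]
    cts <- filterLowExpression(cts, config$filter)
    sf <- sizeFactors(cts)

    ## DE runs on the CPM-filtered counts over all of the family's samples
    de <- NULL
    if ("diffexpr" %in% config$stages) {
      de <- lapply(c(temperature = "temperature", priming = "priming",
                     interaction = "interaction"),
                   function(mod) runDE(cts, des, mod, sf, config$de_alpha))
    }

    ## network stages additionally drop low-variance genes and outliers
    expr <- normalizeCounts(cts, sf)
    expr <- filterLowVariance(expr, config$filter)
    expr <- removeConnectivityOutliers(expr, config$filter)
    des <- des[colnames(expr), , drop = FALSE]
    sf <- sf[colnames(expr)]
    cts <- cts[rownames(expr), colnames(expr), drop = FALSE]
    for (mod in names(de)) emit(de[[mod]], sprintf("de_%s_%s.tsv", f, mod))

    nw <- NULL; gs <- NULL; mt <- NULL
    if ("network" %in% config$stages) {
      nw <- buildNetwork(expr, config$network)
      labels <- moduleLabels(nw$modules)
      emit(data.frame(gene_id = names(labels), module = labels),
           sprintf("modules_%s.tsv", f))
      me <- moduleEigengenes(nw$modules)
      emit(data.frame(module = rownames(me), me, check.names = FALSE),
           sprintf("eigengenes_%s.tsv", f))
      km <- kME(nw$modules)
      emit(data.frame(gene_id = rownames(km), km, check.names = FALSE),
           sprintf("kme_%s.tsv", f))
      traits <- codeTraits(des)
      rownames(traits) <- des$sample_id
      mt <- moduleTraitCor(nw$modules, traits)
      emit(mt, sprintf("module_trait_%s.tsv", f))
      gs <- geneSignificance(expr, traits[, "priming"])
    }
    perFamily[[f]] <- list(counts = cts, expr = expr, design = des,
                           sizeFactors = sf, de = de, network = nw,
                           gs = gs, moduleTrait = mt)
  }

  ## preservation in both directions
  pres <- list()
  if ("preservation" %in% config$stages) for (d in seq_along(fams)) {
    t <- if (d == 1L) 2L else 1L
    disc <- fams[d]; test <- fams[t]
    key <- sprintf("%s_in_%s", disc, test)
    pres[[key]] <- modulePreservation(
      perFamily[[disc]]$expr, perFamily[[test]]$expr,
      moduleLabels(perFamily[[disc]]$network$modules),
      config$preservation, config$network$power)
    ob <- observedStats(pres[[key]]); pv <- preservationPValues(pres[[key]])
    emit(data.frame(module = rownames(ob), ob, check.names = FALSE),
         sprintf("preservation_observed_%s.tsv", key))
    emit(data.frame(module = rownames(pv), pv, check.names = FALSE),
         sprintf("preservation_p_%s.tsv", key))
    emit(classifyPreservation(pres[[key]], config$preservation$alpha),
         sprintf("preservation_verdict_%s.tsv", key))
  }

  ## candidate triage on the discovery family whose module fails preservation
  candidates <- data.frame(gene_id = character(0), family = character(0),
                           module = integer(0))
  if ("candidates" %in% config$stages) for (d in seq_along(fams)) {
    t <- if (d == 1L) 2L else 1L
    key <- sprintf("%s_in_%s", fams[d], fams[t])
    verdict <- classifyPreservation(pres[[key]], config$preservation$alpha)
    target <- verdict$module[!verdict$preserved]
    if (!length(target)) next
    fam <- perFamily[[fams[d]]]
    labels <- moduleLabels(fam$network$modules)
    deg <- weightedDegree(fam$network$network, labels, "intramodular")
    degSet <- fam$de$temperature$gene[fam$de$temperature$significant]
    for (tgt in target) {
      modId <- as.integer(sub("ME", "", tgt))
      modGenes <- names(labels)[labels == modId]
      cand <- triangulateCandidates(degSet, fam$gs, deg, modGenes,
                                    config$triage)
      if (length(cand)) {
        candidates <- rbind(candidates,
                            data.frame(gene_id = cand, family = fams[d],
                                       module = modId))
      }
    }
  }
  if ("candidates" %in% config$stages) emit(candidates, "candidates.tsv")

  if ("enrichment" %in% config$stages && !is.null(config$annotations)) {
    enr <- lapply(perFamily, function(fam) {
      lfc <- setNames(fam$de$temperature$log2_fold_change,
                      fam$de$temperature$gene)
      kogMWU(lfc, config$annotations)
    })
    for (f in names(enr)) emit(enr[[f]], sprintf("enrichment_%s.tsv", f))
    if (length(enr) >= 2) {
      drc <- deltaRankCorrelation(enr)
      emit(data.frame(pair = "families", r = drc$r[1, 2],
                      p_value = drc$p_value[1, 2]),
           "delta_rank_correlation.tsv")
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("primeNet")),
    seed = config$seed,
    parameters = list(filter = unclass(config$filter),
                      network = unclass(config$network),
                      preservation = unclass(config$preservation)[
                        c("n_permutations", "alpha", "seed")],
                      triage = unclass(config$triage),
                      de_alpha = config$de_alpha),
    n_input_genes = nrow(se), n_input_samples = ncol(se),
    input_checksum = digestCounts(assayMatrix(se)),
    outputs = basename(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  mpath <- file.path(config$out_dir, "manifest.json")
  tmp <- paste0(mpath, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, mpath)  # atomic manifest write
  invisible(manifest)
}

## Cheap stable checksum of a count matrix (sum-based; input fingerprint).
digestCounts <- function(m) {
  sprintf("%d-%d-%.0f-%.4f", nrow(m), ncol(m), sum(as.numeric(m)),
          mean(as.numeric(m[seq_len(min(100, nrow(m))), ])))
}
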