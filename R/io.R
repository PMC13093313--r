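## Canonical table dialect: UTF-8 TSV, '.' decimal, no quoting, header row.

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a count matrix
#'
#' TSV with a header row of sample ids and gene ids in the first column.
#' Validation rejects duplicate ids and negative or non-integer counts,
#' naming the offending gene/sample.
#'
#' @param path file path.
#' @return integer matrix, genes x samples.
#' @export
readCounts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  checkIds(df[[1]], "gene")
  checkIds(colnames(df)[-1], "sample")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    pnStop("parseError",
           "invalid count at gene %s, sample %s",
           rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]])
  }
  storage.mode(m) <- "integer"
  m
}

#' @rdname readCounts
#' @param counts matrix or SummarizedExperiment to write.
#' @export
writeCounts <- function(counts, path) {
  m <- assayMatrix(counts)
  writeTsv(data.frame(gene_id = rownames(m), m, check.names = FALSE), path)
}

#' Read / write a sample table
#'
#' Requires sample_id, family, priming, temperature columns; priming must
#' be naive/primed and temperature control/stress (offending rows named),
#' tank and weight are carried through when present.
#'
#' @param path file path.
#' @return data.frame keyed by sample_id.
#' @export
readSampleTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "family", "priming", "temperature")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) pnStop("parseError", "missing column(s): %s",
                           paste(miss, collapse = ", "))
  checkIds(df$sample_id, "sample")
  badP <- which(!df$priming %in% c("naive", "primed"))
  if (length(badP)) pnStop("parseError", "unknown priming level '%s' at row %d",
                           df$priming[badP[1]], badP[1])
  badT <- which(!df$temperature %in% c("control", "stress"))
  if (length(badT)) pnStop("parseError",
                           "unknown temperature level '%s' at row %d",
                           df$temperature[badT[1]], badT[1])
  df
}

#' @rdname readSampleTable
#' @param design sample table to write.
#' @export
writeSampleTable <- function(design, path) writeTsv(design, path)

#' Read annotations as a class map
#'
#' Dialects: `"tsv"` (two columns: gene_id, class — one class per gene)
#' or `"gmt"` (term, description, genes...; one term set per line).
#'
#' @param path file path.
#' @param dialect "tsv" or "gmt".
#' @return a [classMap()].
#' @export
readAnnotations <- function(path, dialect = c("tsv", "gmt")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (ncol(df) < 2) pnStop("parseError", "annotation TSV needs 2 columns")
    classMap(df[, 1:2])
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    sets <- lapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
    short <- which(vapply(sets, length, integer(1)) < 3)
    if (length(short)) pnStop("parseError", "GMT line %d has < 3 fields",
                              short[1])
    terms <- vapply(sets, `[[`, character(1), 1)
    checkIds(terms, "term")
    classMap(setNames(lapply(sets, function(s) s[-(1:2)]), terms))
  }
}

#' Read / write survival records
#'
#' TSV with columns individual, time, event (0/1) and optional group
#' columns (family, priming, tank).
#'
#' @param path file path.
#' @return data.frame of survival records.
#' @export
readSurvival <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual", "time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) pnStop("parseError", "missing column(s): %s",
                           paste(miss, collapse = ", "))
  if (any(df$time <= 0)) pnStop("parseError", "non-positive time at row %d",
                                which(df$time <= 0)[1])
  if (!all(df$event %in% c(0, 1))) pnStop("parseError", "event must be 0/1")
  df
}

#' Write a simulated experiment to a directory
#'
#' Emits counts.tsv, samples.tsv, the ground-truth tables
#' (truth_modules.tsv, truth_de.tsv, truth_eigengenes.tsv) and the
#' configuration as JSON; all re-readable by the package's own readers.
#'
#' @param se a [simulateExperiment()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
writeSimulation <- function(se, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- S4Vectors::metadata(se)$groundTruth
  cfg <- S4Vectors::metadata(se)$config
  files <- c(
    writeCounts(se, file.path(dir, "counts.tsv")),
    writeSampleTable(as.data.frame(SummarizedExperiment::colData(se)),
                     file.path(dir, "samples.tsv")),
    writeTsv(data.frame(gene_id = names(gt$module_labels),
                        module = gt$module_labels),
             file.path(dir, "truth_modules.tsv")),
    writeTsv(data.frame(gene_id = gt$de_genes,
                        sign = gt$de_sign,
                        candidate = gt$de_genes %in% gt$candidates),
             file.path(dir, "truth_de.tsv")),
    writeTsv(data.frame(module = rownames(gt$eigengenes), gt$eigengenes,
                        check.names = FALSE),
             file.path(dir, "truth_eigengenes.tsv"))
  )
  cfgPath <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfgPath, auto_unbox = TRUE, digits = NA)
  invisible(c(files, cfgPath))
}
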