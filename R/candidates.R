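## Candidate-gene triangulation and subnetwork export.
##
## Candidates are module genes that are simultaneously differentially
## expressed, in the top gene-significance quantile and in the top
## intramodular-degree quantile. Around a candidate, the most correlated
## genes are selected, edges are binarized at a correlation quantile, and
## the subnetwork is exported with cross-family module annotations.

#' Triage thresholds
#'
#' @param gs_quantile gene-significance quantile within the module
#'   (default 0.90: top decile).
#' @param degree_quantile intramodular-degree quantile (default 0.90).
#' @param top_corr_fraction fraction of most-correlated genes kept around
#'   a candidate (default 0.01).
#' @param edge_quantile correlation quantile above which an edge is kept
#'   when binarizing (default 0.90).
#' @return validated `triageConfig` list.
#' @export
triageConfig <- function(gs_quantile = 0.90, degree_quantile = 0.90,
                         top_corr_fraction = 0.01, edge_quantile = 0.90) {
  cfg <- list(gs_quantile = gs_quantile, degree_quantile = degree_quantile,
              top_corr_fraction = top_corr_fraction,
              edge_quantile = edge_quantile)
  q <- c(cfg$gs_quantile, cfg$degree_quantile, cfg$edge_quantile)
  if (any(q <= 0 | q >= 1)) pnStop("invalidConfig", "quantiles must be in (0, 1)")
  if (cfg$top_corr_fraction <= 0 || cfg$top_corr_fraction > 1) {
    pnStop("invalidConfig", "top_corr_fraction must be in (0, 1]")
  }
  class(cfg) <- "triageConfig"
  cfg
}

#' Triangulate candidate genes
#'
#' Intersects, within a module, (i) the DEG set, (ii) genes at or above
#' the module's `gs_quantile` of gene significance, and (iii) genes at or
#' above the `degree_quantile` of intramodular weighted degree. Ties at a
#' quantile boundary are included.
#'
#' @param deg_set character vector of significant genes.
#' @param gs named gene-significance vector (covers the module).
#' @param degree named intramodular-degree vector (covers the module).
#' @param module_genes character vector of module gene ids.
#' @param cfg a [triageConfig()].
#' @return sorted character vector of candidate gene ids.
#' @export
triangulateCandidates <- function(deg_set, gs, degree, module_genes,
                                  cfg = triageConfig()) {
  if (!length(module_genes)) pnStop("inputError", "empty module")
  gs <- gs[module_genes]
  degree <- degree[module_genes]
  if (anyNA(gs) || anyNA(degree)) {
    pnStop("inputError", "gene significance / degree not defined on all module genes")
  }
  gsCut <- quantile(gs, cfg$gs_quantile)
  degCut <- quantile(degree, cfg$degree_quantile)
  sort(intersect(
    intersect(module_genes[gs >= gsCut], module_genes[degree >= degCut]),
    intersect(module_genes, deg_set)
  ))
}

#' Most correlated neighbors of a seed gene
#'
#' The `ceiling(fraction * (n - 1))` genes with largest signed correlation
#' to the seed, ties at the cutoff broken by lexicographic gene id.
#'
#' @param corr gene x gene correlation matrix.
#' @param seed_gene gene id present in `corr`.
#' @param fraction fraction of the other genes to keep.
#' @return character vector of neighbor gene ids.
#' @export
topCorrelated <- function(corr, seed_gene, fraction = 0.01) {
  if (!seed_gene %in% rownames(corr)) {
    pnStop("lookupError", "seed gene %s not in correlation matrix", seed_gene)
  }
  r <- corr[seed_gene, setdiff(colnames(corr), seed_gene)]
  kTop <- ceiling(fraction * length(r))
  ord <- order(-r, names(r))  # descending r, lexicographic id tie-break
  names(r)[ord[seq_len(kTop)]]
}

#' Binarize correlations into edges
#'
#' Threshold = the `edge_quantile` quantile of the off-diagonal
#' upper-triangle correlations; an edge is kept iff `r >= threshold` and
#' `r > 0` (weak and negative correlations discarded).
#'
#' @param corr correlation submatrix over the subnetwork nodes (>= 2).
#' @param edge_quantile quantile in (0, 1).
#' @return data.frame(from, to) of undirected edges, each pair once.
#' @export
binarizeEdges <- function(corr, edge_quantile = 0.90) {
  if (nrow(corr) < 2) pnStop("inputError", "need >= 2 nodes")
  ut <- which(upper.tri(corr), arr.ind = TRUE)
  r <- corr[ut]
  t <- quantile(r, edge_quantile)
  keep <- r >= t & r > 0
  if (!any(keep)) {
    pnWarn("no positive correlation reaches the edge threshold; empty edge set")
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(from = rownames(corr)[ut[keep, 1]],
             to = colnames(corr)[ut[keep, 2]],
             stringsAsFactors = FALSE)
}

#' Annotate nodes with the other family's module membership
#'
#' Each node is tagged with its module label in the other family, or
#' `"NI"` when the gene is absent from that family's filtered matrix.
#'
#' @param nodes character vector of gene ids.
#' @param other_labels named label vector from the other family.
#' @param other_universe gene ids present in the other family's matrix.
#' @return character vector of tags, named by node.
#' @export
annotateCrossFamily <- function(nodes, other_labels, other_universe) {
  tags <- ifelse(nodes %in% other_universe,
                 as.character(other_labels[nodes]), "NI")
  setNames(tags, nodes)
}

#' Build a candidate-centered subnetwork
#'
#' Selects the seed's most correlated genes, binarizes edges among the
#' seed + neighbors, and attaches degree and cross-family annotations.
#'
#' @param corr module correlation matrix (discovery family).
#' @param seed_gene candidate gene id.
#' @param cfg a [triageConfig()].
#' @param other_labels,other_universe optional cross-family annotation
#'   inputs (see [annotateCrossFamily()]).
#' @return list of class `subNetwork`: `nodes` (data.frame id, degree,
#'   other_family) and `edges` (data.frame from, to).
#' @export
candidateSubnetwork <- function(corr, seed_gene, cfg = triageConfig(),
                                other_labels = NULL, other_universe = NULL) {
  nbrs <- topCorrelated(corr, seed_gene, cfg$top_corr_fraction)
  ids <- c(seed_gene, nbrs)
  edges <- binarizeEdges(corr[ids, ids, drop = FALSE], cfg$edge_quantile)
  degree <- vapply(ids, function(g) sum(edges$from == g | edges$to == g),
                   numeric(1))
  nodes <- data.frame(id = ids, degree = degree, stringsAsFactors = FALSE)
  nodes$other_family <- if (!is.null(other_labels)) {
    unname(annotateCrossFamily(ids, other_labels, other_universe))
  } else NA_character_
  structure(list(nodes = nodes, edges = edges), class = "subNetwork")
}

#' Export / read a subnetwork
#'
#' `exportGraph()` writes GraphML (via igraph, node attributes carried) or
#' a node-list + edge-list TSV pair; `readGraph()` reads either back into
#' the same `subNetwork` shape, losslessly.
#'
#' @param subnet a `subNetwork`.
#' @param path output path (for "edge_tsv", the stem: `<stem>_nodes.tsv`
#'   and `<stem>_edges.tsv` are written).
#' @param format "graphml" or "edge_tsv".
#' @return invisibly, the file path(s) written.
#' @export
exportGraph <- function(subnet, path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  nodes <- subnet$nodes[order(subnet$nodes$id), , drop = FALSE]
  edges <- subnet$edges
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
  } else {
    np <- paste0(path, "_nodes.tsv")
    ep <- paste0(path, "_edges.tsv")
    writeTsv(nodes, np)
    writeTsv(edges, ep)
    invisible(c(np, ep))
  }
}

#' @rdname exportGraph
#' @export
readGraph <- function(path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    at <- igraph::as_data_frame(g, what = "vertices")
    nodes <- data.frame(id = at$name, degree = at$degree,
                        other_family = if ("other_family" %in% names(at))
                          at$other_family else NA_character_,
                        stringsAsFactors = FALSE)
    e <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(from = e$from, to = e$to, stringsAsFactors = FALSE)
  } else {
    nodes <- utils::read.delim(paste0(path, "_nodes.tsv"),
                               stringsAsFactors = FALSE)
    edges <- utils::read.delim(paste0(path, "_edges.tsv"),
                               stringsAsFactors = FALSE,
                               colClasses = "character")
  }
  structure(list(nodes = nodes, edges = edges), class = "subNetwork")
}
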