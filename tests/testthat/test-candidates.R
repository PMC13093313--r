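test_that("triangulation intersects DEGs, top GS and top degree with tie handling", {
  genes <- sprintf("g%02d", 1:10)
  gs <- setNames(c(9, 8, 7, 6, 5, 4, 3, 2, 1, 0) / 10, genes)
  deg <- setNames(c(1, 9, 8, 2, 7, 3, 6, 4, 5, 0), genes)
  degSet <- c("g02", "g03", "g05", "g09")
  ## gs q90 over 10 genes = 0.82 -> {g01}; plus boundary ties included
  cfg <- triageConfig(gs_quantile = 0.8, degree_quantile = 0.8)
  ## gs >= quantile(.8) = 0.74 -> g01, g02, g03 (0.72? no: 0.7 < 0.74)
  got <- triangulateCandidates(degSet, gs, deg, genes, cfg)
  handGs <- genes[gs >= quantile(gs, 0.8)]
  handDeg <- genes[deg >= quantile(deg, 0.8)]
  expect_identical(got, sort(intersect(intersect(handGs, handDeg), degSet)))
  ## disjoint DEG set -> empty
  expect_identical(
    triangulateCandidates("g10", gs, deg, genes, cfg), character(0))
  ## candidate set shrinks as quantiles rise
  loose <- triangulateCandidates(degSet, gs, deg, genes,
                                 triageConfig(gs_quantile = 0.5,
                                              degree_quantile = 0.5))
  expect_true(all(got %in% loose))
  expect_error(triangulateCandidates(degSet, gs, deg, character(0), cfg),
               class = "inputError")
})

test_that("top correlated neighbors use ceiling arithmetic and id tie-breaks", {
  n <- 101
  cm <- diag(n)
  dimnames(cm) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  cm["g001", -1] <- seq(0.9, 0.1, length.out = n - 1)
  cm[-1, "g001"] <- cm["g001", -1]
  top <- topCorrelated(cm, "g001", fraction = 0.01)
  expect_identical(top, "g002")   # ceiling(0.01 * 100) = 1, the argmax
  expect_equal(length(topCorrelated(cm, "g001", fraction = 1)), n - 1)
  ## tie at the cutoff: lexicographically smaller id retained
  cm2 <- cm
  cm2["g001", c("g050", "g049")] <- 0.95
  top2 <- topCorrelated(cm2, "g001", fraction = 0.01)
  expect_identical(top2, "g049")
  expect_error(topCorrelated(cm, "nope", 0.01), class = "lookupError")
})

test_that("edge binarization thresholds the upper-triangle correlations", {
  cm <- matrix(c(1, .9, .2, -.5,
                 .9, 1, .4, .1,
                 .2, .4, 1, .3,
                 -.5, .1, .3, 1), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  ## off-diagonal values: .9 .2 -.5 .4 .1 .3; q50 = .25
  e <- binarizeEdges(cm, edge_quantile = 0.5)
  expect_setequal(paste(e$from, e$to), c("a b", "b c", "c d"))
  ## all equal -> every pair is an edge
  ce <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(ce) <- 1
  expect_equal(nrow(binarizeEdges(ce, 0.9)), 3L)
  ## quantile -> 1 keeps only the maximal pair
  eMax <- binarizeEdges(cm, edge_quantile = 0.999)
  expect_equal(nrow(eMax), 1L)
  expect_identical(c(eMax$from, eMax$to), c("a", "b"))
  ## all-negative correlations: empty with a warning
  neg <- -abs(cm); diag(neg) <- 1
  expect_warning(e0 <- binarizeEdges(neg, 0.5), "threshold")
  expect_equal(nrow(e0), 0L)
})

test_that("cross-family annotation tags absences as NI", {
  labs <- setNames(c(1L, 2L, 2L), c("a", "b", "c"))
  tags <- annotateCrossFamily(c("a", "b", "z"), labs, names(labs))
  expect_identical(unname(tags), c("1", "2", "NI"))
  same <- annotateCrossFamily(names(labs), labs, names(labs))
  expect_identical(unname(same), c("1", "2", "2"))
})

test_that("scrambled-module genes scatter across the other family's modules", {
  cfg <- tinyConfig(seed = 24L)
  se <- simulateExperiment(cfg)
  design <- as.data.frame(SummarizedExperiment::colData(se))
  gt <- S4Vectors::metadata(se)$groundTruth
  prep <- function(f) {
    cts <- filterLowExpression(
      SummarizedExperiment::assay(se)[, design$family == f])
    removeConnectivityOutliers(filterLowVariance(normalizeCounts(cts)))
  }
  exprA <- prep("A")
  nwA <- buildNetwork(exprA, networkConfig(min_module_size = 30L))
  labsA <- moduleLabels(nwA$modules)
  scrGenes <- names(gt$module_labels)[gt$module_labels == 2L]
  tags <- annotateCrossFamily(scrGenes, labsA, rownames(exprA))
  ## the intact-family module dissolves in the scrambled family:
  ## most genes become background or split over modules there
  expect_gt(mean(tags %in% c("0", "NI")), 0.5)
})

test_that("subnetworks round-trip through GraphML and TSV exports", {
  cm <- withr::with_seed(25, {
    z <- matrix(rnorm(19 * 30), 19, 30)
    z[1:10, ] <- 0.8 * matrix(z[1, ], 10, 30, byrow = TRUE) + 0.4 * z[1:10, ]
    cor(t(z))
  })
  dimnames(cm) <- list(sprintf("g%02d", 1:19), sprintf("g%02d", 1:19))
  labs <- setNames(rep(c(1L, 2L), c(10, 9)), rownames(cm))
  sub <- candidateSubnetwork(cm, "g01", triageConfig(top_corr_fraction = 0.95),
                             other_labels = labs, other_universe = rownames(cm)[1:15])
  expect_true(all(sub$edges$from %in% sub$nodes$id))
  expect_true(all(sub$nodes$degree ==
    vapply(sub$nodes$id,
           function(g) sum(sub$edges$from == g | sub$edges$to == g),
           numeric(1))))
  dir <- withr::local_tempdir()
  gml <- file.path(dir, "net.graphml")
  exportGraph(sub, gml, "graphml")
  back <- readGraph(gml, "graphml")
  expect_setequal(back$nodes$id, sub$nodes$id)
  pairKey <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_setequal(pairKey(back$edges), pairKey(sub$edges))
  niBack <- setNames(back$nodes$other_family, back$nodes$id)
  niOrig <- setNames(sub$nodes$other_family, sub$nodes$id)
  expect_identical(niBack[names(niOrig)], niOrig)
  ## TSV pair round-trip and byte stability
  stem <- file.path(dir, "net")
  exportGraph(sub, stem, "edge_tsv")
  exportGraph(sub, file.path(dir, "net2"), "edge_tsv")
  expect_identical(readLines(paste0(stem, "_edges.tsv")),
                   readLines(file.path(dir, "net2_edges.tsv")))
  back2 <- readGraph(stem, "edge_tsv")
  expect_setequal(paste(back2$edges$from, back2$edges$to),
                  paste(sub$edges$from, sub$edges$to))
  ## empty graph stays valid
  empty <- structure(list(
    nodes = data.frame(id = "gX", degree = 0,
                       other_family = NA_character_),
    edges = data.frame(from = character(0), to = character(0))),
    class = "subNetwork")
  exportGraph(empty, file.path(dir, "empty.graphml"), "graphml")
  expect_equal(nrow(readGraph(file.path(dir, "empty.graphml"))$edges), 0L)
})
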