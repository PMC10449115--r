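test_that("pseudo-bulk construction filters, blocks, rescales and conserves counts", {
  set.seed(21)
  ng <- 30
  # 12 passing cells with distinct totals + 3 below the coverage floor
  mk_cell <- function(total) {
    x <- rmultinom(1, size = round(total * 0.9), prob = runif(ng))[, 1] +
      rep(round(total * 0.1 / ng), ng)
    x
  }
  totals <- seq(2.4e5, 1.3e5, length.out = 12)
  cells <- vapply(totals, mk_cell, numeric(ng))
  low <- vapply(c(3e4, 5e4, 9e4), mk_cell, numeric(ng))
  sc <- cbind(cells, low)
  dimnames(sc) <- list(sprintf("g%02d", 1:ng), sprintf("c%02d", 1:15))

  expect_warning(
    refs <- buildPseudobulks(sc, rep(c("epi", "str"), c(15, 0)),
                             groupSize = 5),
    NA)
  v <- exprValues(refs)
  expect_equal(ncol(v), 2)  # floor(12 / 5); trailing 2 cells dropped
  expect_equal(classLabels(refs), rep("epi", 2))

  # undo transform and rescaling: each pseudo-bulk must be a scaled version
  # of the sum of its 5 members (members = consecutive blocks of the
  # coverage-ranked passing cells)
  raw <- inverseTransform(refs@profiles)
  ranked <- order(-colSums(sc))[1:12]
  ranked <- ranked[colSums(sc)[ranked] >= 1e5]
  for (b in 1:2) {
    expected <- rowSums(sc[, ranked[((b - 1) * 5 + 1):(b * 5)]])
    ratio <- raw[, b] / expected
    expect_equal(diff(range(ratio)), 0, tolerance = 1e-6)
  }
  # normalized to the highest-coverage pseudo-bulk
  expect_equal(diff(range(colSums(raw))), 0, tolerance = 1e-6)
})

test_that("classes too small for replicated pseudo-bulks are dropped with a warning", {
  set.seed(22)
  sc <- matrix(rpois(20 * 14, 2e4), 20, 14)
  dimnames(sc) <- list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:14))
  labels <- rep(c("big", "tiny"), c(11, 3))
  expect_warning(refs <- buildPseudobulks(sc, labels, groupSize = 5,
                                          minTotalCounts = 1e4),
                 "tiny")
  expect_false("tiny" %in% classLabels(refs))
})

test_that("pseudo-bulk counts reproduce the reported class arithmetic", {
  spec <- data.frame(name = c("epithelial", "stromal", "tcell", "macrophage"),
                     nCells = c(643, 92, 53, 62),
                     nLowCoverage = c(3, 2, 3, 2))
  sc <- generateSyntheticScRNA(nGenes = 120, classSpec = spec, seed = 31)
  refs <- buildPseudobulks(sc$counts, sc$cellLabels)
  tab <- table(classLabels(refs))
  expect_equal(as.vector(tab[c("epithelial", "stromal", "tcell", "macrophage")]),
               c(128, 18, 10, 12))
})

test_that("the Welch t-test agrees with the textbook computation and handles degeneracy", {
  r <- differentialTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0); expect_equal(r$p, 1); expect_equal(r$meanDiff, 0)

  r <- differentialTTest(c(1, 2, 3), c(11, 12, 13))
  expect_equal(r$meanDiff, -10)

  a <- c(2.1, 2.0, 1.9); b <- c(1.1, 1.0, 0.9)
  r <- differentialTTest(a, b)
  se <- sqrt(var(a) / 3 + var(b) / 3)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(r$t, t_hand, tolerance = 1e-6)
  expect_equal(r$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-6)

  # both groups constant
  expect_equal(differentialTTest(c(1, 1), c(1, 1))$p, 1)
  r <- differentialTTest(c(2, 2), c(1, 1))
  expect_equal(r$p, 0); expect_true(is.infinite(r$t))
  expect_error(differentialTTest(1, c(1, 2)), ">= 2 observations")
})

test_that("marker-only panels select exactly the planted markers", {
  fx <- markerOnlyRefs(seed = 41)
  genes <- suppressWarnings(selectInformativeGenes(fx$refs, pThreshold = 1e-4))
  expect_setequal(geneIds(genes), unlist(fx$markers))
  # every marker attributed to its own class's one-vs-rest contrast
  src <- genes@source
  for (cls in names(fx$markers))
    expect_setequal(src$gene_id[src$source == paste0(cls, "_vs_rest")],
                    fx$markers[[cls]])
})

test_that("a gene planted as marker of two classes is excluded entirely", {
  fx <- markerOnlyRefs(seed = 42)
  counts <- fx$raw$counts
  labels <- fx$raw$classLabels
  shared <- setdiff(rownames(counts), unlist(fx$markers))[1]
  boost <- labels %in% c("cancer_epithelial", "immune")
  counts[shared, boost] <- counts[shared, boost] * 50
  refs <- new("ReferenceSet", profiles = transformCounts(counts),
              classLabels = labels, provenance = "bulk reference")
  genes <- suppressMessages(suppressWarnings(selectInformativeGenes(refs, pThreshold = 1e-4)))
  expect_false(shared %in% geneIds(genes))
  # single-class markers are unaffected by the extra planting
  expect_true(all(fx$markers$normal_epithelial %in% geneIds(genes)))
})

test_that("literature genes are intersected, unioned last and exempt from exclusion", {
  fx <- markerOnlyRefs(seed = 43)
  lit <- c(fx$markers$stromal[1:5],        # also DE-selected
           setdiff(rownames(fx$raw$counts), unlist(fx$markers))[1:44],
           "NOT_A_GENE")                   # 50 requested, 49 present
  genes <- suppressWarnings(selectInformativeGenes(fx$refs, pThreshold = 1e-4,
                                                   literatureGenes = lit))
  src <- genes@source
  expect_equal(sum(grepl("literature", src$source)), 49)
  expect_true(all(setdiff(lit, "NOT_A_GENE") %in% geneIds(genes)))
  # missing >10% of the list triggers a warning
  expect_warning(
    selectInformativeGenes(fx$refs, pThreshold = 1e-4,
                           literatureGenes = c(lit[1:5], paste0("X", 1:10))),
    "literature genes")
})

test_that("selection is deterministic and bounded", {
  fx <- markerOnlyRefs(seed = 44)
  g1 <- suppressWarnings(selectInformativeGenes(fx$refs, pThreshold = 1e-4))
  g2 <- suppressWarnings(selectInformativeGenes(fx$refs, pThreshold = 1e-4))
  expect_identical(geneIds(g1), geneIds(g2))
  expect_lte(g1@nTotal, 4 * 2 * 25)
})

test_that("named selection recipes carry the documented thresholds", {
  roles <- c(cancer = "c", normal = "n", stroma = "s", epithelial = "e",
             tcell = "t", macrophage = "m")
  p <- stage0Preset("simulated", roles)
  expect_equal(p$pThreshold, 1e-4); expect_equal(p$nTop, 25)
  expect_length(p$pairwise, 2)
  p <- stage0Preset("cell-line", roles)
  expect_equal(p$pairwise[[1]]$pThreshold, 1e-5)
  expect_equal(p$pairwise[[1]]$nTop, 75)
  p <- stage0Preset("single-cell", roles)
  expect_equal(p$pThreshold, 0.05); expect_equal(p$nTop, 50)
  expect_equal(p$pairwise[[1]]$nTop, 25)
  expect_error(stage0Preset("simulated", roles["cancer"]), "role")
})
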