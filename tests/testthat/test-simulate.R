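test_that("reference generation validates its marker structure", {
  spec <- DeconvoMap:::.defaultTypeSpec()
  bad <- spec; bad$markerFold <- 1
  expect_error(generateReferenceProfiles(typeSpec = bad), "exceed 1")
  expect_error(generateReferenceProfiles(nGenes = 50), "at least")

  raw <- generateReferenceProfiles(seed = 91)
  expect_length(unlist(raw$markers), 100)
  expect_equal(anyDuplicated(unlist(raw$markers)), 0)  # pairwise disjoint
  expect_true(all(raw$counts >= 0))
  expect_equal(table(raw$classLabels)[c("cancer_epithelial",
                                        "normal_epithelial", "immune",
                                        "stromal")],
               table(rep(c("cancer_epithelial", "normal_epithelial",
                           "immune", "stromal"), c(12, 10, 10, 4)))[
                 c("cancer_epithelial", "normal_epithelial", "immune",
                   "stromal")])
  # determinism: same seed reproduces, different seed differs
  raw2 <- generateReferenceProfiles(seed = 91)
  expect_identical(raw$counts, raw2$counts)
  raw3 <- generateReferenceProfiles(seed = 92)
  expect_false(identical(raw$counts, raw3$counts))
})

test_that("profile noise variance tracks the stated fraction of the maximum gene variance", {
  set.seed(93)
  ng <- 2500
  # values well inside (0,1) so clipping cannot distort the check
  base <- matrix(runif(ng, 0.3, 0.7), ng, 4) +
    matrix(rnorm(ng * 4, 0, 0.03), ng, 4)
  base <- pmin(pmax(base, 0.05), 0.95)
  dimnames(base) <- list(sprintf("g%04d", 1:ng), paste0("c", 1:4))
  tm <- new("TransformedMatrix", values = base, scaleA = 1, perGene = FALSE)
  refs <- new("ReferenceSet", profiles = tm,
              classLabels = rep("cancer", 4), provenance = "bulk reference")
  vmax <- max(apply(base, 1, var))
  noisy <- addProfileNoise(refs, cancerTypes = "cancer", seed = 94)
  d <- exprValues(noisy) - base      # 10^4 iid noise draws
  expect_equal(var(as.vector(d)), 0.10 * vmax, tolerance = 0.05)

  # cancer fraction exceeds normal fraction for identical variance structure
  refs2 <- new("ReferenceSet", profiles = tm,
               classLabels = rep("normal", 4), provenance = "bulk reference")
  d2 <- exprValues(addProfileNoise(refs2, cancerTypes = "cancer",
                                   seed = 94)) - base
  expect_gt(sd(as.vector(d)), sd(as.vector(d2)))
  expect_equal(var(as.vector(d2)), 0.05 * vmax,
               tolerance = 0.05)

  expect_error(addProfileNoise(refs, "cancer", cancerNoiseFrac = 1.2),
               "\\(0, 1\\)")
  one_rep <- list(counts = base, classLabels = c("a", "a", "a", "b"))
  expect_error(suppressWarnings(addProfileNoise(one_rep, "a")),
               "single replicate")
})

test_that("mixtures respect the purity-class proportion design", {
  sim <- simulateMixtureStudy(seed = 95)
  props <- sim$truth@trueProportions
  cls <- sim$truth@purityClass
  expect_equal(unname(colSums(props)), rep(1, 100), tolerance = 1e-12)
  expect_equal(as.vector(table(cls)), rep(25L, 4))

  cancer <- props["cancer_epithelial", ]
  normal <- props["normal_epithelial", ]
  expect_true(all(cancer[cls == "high"] > 0.6 & cancer[cls == "high"] < 0.9))
  expect_true(all(cancer[cls == "impure"] == 0.40))
  expect_true(all(cancer[cls == "low"] == 0.10))
  expect_true(all(normal[cls == "low"] >= 0.5 & normal[cls == "low"] <= 0.8))
  expect_true(all(cancer[cls == "control"] == 0))
  expect_true(all(normal[cls == "control"] == 0.70))
  expect_true(all(exprValues(sim$mixtures) >= 0 &
                    exprValues(sim$mixtures) < 1))
})

test_that("a mixture is the exact linear blend of its constituent profiles", {
  set.seed(96)
  ng <- 40
  prof <- matrix(rexp(ng * 4, 1 / 60), ng, 4)
  # two identical replicates per type: the replicate draw cannot matter
  counts <- prof[, rep(1:4, each = 2)]
  dimnames(counts) <- list(sprintf("g%02d", 1:ng), sprintf("r%d", 1:8))
  refs <- list(counts = counts,
               classLabels = rep(c("ca", "no", "st", "im"), each = 2))
  gm <- generateMixtures(refs, roles = c(cancer = "ca", normal = "no",
                                         stroma = "st", immune = "im"),
                         n = 20, classMix = c(high = 5, impure = 5, low = 5,
                                              control = 5), seed = 97)
  recon <- prof %*% gm$truth@trueProportions[c("ca", "no", "st", "im"), ]
  expect_equal(unname(gm$mixtures), unname(recon), tolerance = 1e-12)
})

test_that("synthetic single-cell counts plant coverage failures and markers", {
  spec <- data.frame(name = c("epi", "str"), nCells = c(23, 14),
                     nLowCoverage = c(3, 2))
  sc <- generateSyntheticScRNA(nGenes = 80, classSpec = spec, seed = 98)
  totals <- colSums(sc$counts)
  expect_length(sc$lowCoverageCells, 5)
  expect_true(all(totals[sc$lowCoverageCells] < 1e5))
  expect_true(all(totals[setdiff(colnames(sc$counts),
                                 sc$lowCoverageCells)] >= 1e5))

  refs <- buildPseudobulks(sc$counts, sc$cellLabels)
  expect_equal(as.vector(table(classLabels(refs))[c("epi", "str")]),
               c(4L, 2L))  # floor(20/5), floor(12/5)
  # markers are highest in their own class's pseudo-bulks
  v <- exprValues(refs)
  for (cl in spec$name) {
    own <- rowMeans(v[sc$markers[[cl]], classLabels(refs) == cl,
                      drop = FALSE])
    other <- rowMeans(v[sc$markers[[cl]], classLabels(refs) != cl,
                        drop = FALSE])
    expect_true(all(own > other))
  }
})

test_that("recovery scoring is exact on truth and invariant to relabeling", {
  sim <- simulateMixtureStudy(seed = 99, nGenes = 300)
  truth <- sim$truth
  k <- nrow(truth@trueProportions)
  fake <- new("DeconvolutionResult",
              M = pmin(truth@trueProfiles, 1 - 1e-9),
              P = truth@trueProportions, k = as.integer(k),
              rssTrajectory = c(1, 0.1), iterations = 2L, converged = TRUE,
              explainedVariance = 1, explainedVarianceUncentered = 1,
              seed = 1L)
  colnames(fake@M) <- paste0("component_", 1:k)
  rownames(fake@P) <- colnames(fake@M)
  rec <- scoreRecovery(fake, truth)
  expect_equal(rec@table$proportion_r2, rep(1, k), tolerance = 1e-12)
  expect_equal(rec@table$profile_r2, rep(1, k), tolerance = 1e-12)

  perm <- c(3, 1, 4, 2)
  fake2 <- fake
  fake2@M <- fake@M[, perm]; fake2@P <- fake@P[perm, ]
  colnames(fake2@M) <- paste0("component_", 1:k)
  rownames(fake2@P) <- colnames(fake2@M)
  rec2 <- scoreRecovery(fake2, truth)
  expect_equal(rec2@table$proportion_r2, rep(1, k), tolerance = 1e-12)
  expect_identical(rec2@table$truth,
                   rownames(truth@trueProportions)[perm])
})
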