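test_that("proportion solving recovers exact and mixed columns", {
  set.seed(51)
  M <- matrix(runif(30), 10, 3,
              dimnames = list(sprintf("g%02d", 1:10), paste0("k", 1:3)))
  p <- solveProportions(M, M[, 2])
  expect_equal(unname(p), c(0, 1, 0), tolerance = 1e-8)

  t <- 0.5 * M[, 1] + 0.5 * M[, 2]
  p <- solveProportions(M, t)
  expect_equal(unname(p), c(0.5, 0.5, 0), tolerance = 1e-6)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_error(solveProportions(M * 2, t), "\\[0, 1\\]")
  expect_warning(solveProportions(cbind(M[, 1], M[, 1]), t),
                 "rank deficient")
})

test_that("proportion solving matches the exhaustive grid oracle", {
  set.seed(52)
  for (i in 1:10) {
    k <- sample(2:3, 1); ng <- sample(3:5, 1)
    M <- matrix(runif(ng * k), ng, k)
    t <- runif(ng)
    p <- solveProportions(M, t)
    g <- gridSimplexLS(M, t)
    expect_lt(max(abs(p - g)), 2e-3)
  }
})

test_that("profile solving honours the box constraint and the grid oracle", {
  # single component: closed form clamp(mean(t))
  P1 <- matrix(1, 1, 6, dimnames = list("k1", sprintf("s%d", 1:6)))
  t <- c(0.2, 0.4, 0.3, 0.25, 0.35, 0.5)
  expect_equal(unname(solveProfiles(P1, t)), mean(t), tolerance = 1e-8)
  expect_equal(unname(solveProfiles(P1, rep(0.9, 6) * 1.1 - 0.09)),
               mean(rep(0.9, 6) * 1.1 - 0.09), tolerance = 1e-8)

  set.seed(53)
  P <- matrix(runif(2 * 8), 2, 8); P <- sweep(P, 2, colSums(P), "/")
  mstar <- c(0.35, 0.8)
  expect_equal(unname(solveProfiles(P, drop(mstar %*% P))), mstar,
               tolerance = 1e-6)
  for (i in 1:10) {
    t <- runif(8)
    m <- solveProfiles(P, t)
    g <- gridBoxLS(P, t)
    expect_lt(max(abs(m - g)), 2e-3)
  }
})

test_that("noiseless three-type mixtures are identified up to permutation", {
  set.seed(54)
  ng <- 40; n <- 30
  Mstar <- matrix(runif(ng * 3, 0, 0.25), ng, 3)
  Mstar[1:10, 1] <- 0.6; Mstar[11:20, 2] <- 0.6; Mstar[21:30, 3] <- 0.6
  # a few pure samples make the noiseless factorization identifiable
  Pstar <- cbind(t(.rdirich(n - 3, 3)), diag(3))
  T <- Mstar %*% Pstar
  dimnames(T) <- list(sprintf("g%02d", 1:ng), sprintf("s%02d", 1:n))
  rownames(Pstar) <- paste0("true", 1:3); colnames(Pstar) <- colnames(T)
  fit <- runStage1(T, 3, seed = 7)
  m <- matchComponents(fit, Pstar, on = "proportions")
  expect_true(all(m$correlations >= 0.999))
})

test_that("the RSS trajectory is non-increasing and seeded runs are bitwise identical", {
  set.seed(55)
  T <- matrix(runif(35 * 20, 0, 0.6), 35, 20,
              dimnames = list(sprintf("g%02d", 1:35), sprintf("s%02d", 1:20)))
  f1 <- runStage1(T, 3, seed = 99, nStarts = 2)
  f2 <- runStage1(T, 3, seed = 99, nStarts = 2)
  expect_identical(rssTrajectory(f1), rssTrajectory(f2))
  expect_identical(f1@M, f2@M)
  expect_true(all(diff(rssTrajectory(f1)) <= 0))
  f3 <- runStage1(T, 3, seed = 100, nStarts = 1)
  expect_true(all(diff(rssTrajectory(f3)) <= 0))
  # result invariants
  expect_true(all(abs(colSums(sampleProportions(f1)) - 1) < 1e-8))
  expect_true(all(profilesMatrix(f1) >= 0 & profilesMatrix(f1) <= 1))
})

test_that("shuffling sample order permutes the result without changing it", {
  set.seed(56)
  T <- matrix(runif(30 * 16, 0, 0.6), 30, 16,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:16)))
  perm <- sample(ncol(T))
  f1 <- runStage1(T, 3, seed = 5)
  f2 <- runStage1(T[, perm], 3, seed = 5)
  # equal up to floating-point accumulation over a few hundred iterations
  expect_equal(sampleProportions(f2)[, colnames(T)], sampleProportions(f1),
               tolerance = 1e-6)
  expect_equal(profilesMatrix(f2), profilesMatrix(f1), tolerance = 1e-6)
})

test_that("stage-1 precondition violations error out", {
  T <- matrix(runif(20, 0, 0.5), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expect_error(runStage1(T, 1), ">= 2")
  expect_error(runStage1(T, 5), "exceeds")
})

test_that("component matching finds identity, reversals and the oracle optimum", {
  set.seed(57)
  T <- matrix(runif(30 * 15, 0, 0.6), 30, 15,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:15)))
  fit <- runStage1(T, 3, seed = 3)
  m <- matchComponents(fit, fit)
  expect_identical(m$permutation, 1:3)
  expect_equal(m$correlations, rep(1, 3))

  rev_fit <- fit
  rev_fit@P <- fit@P[3:1, ]; rev_fit@M <- fit@M[, 3:1]
  m <- matchComponents(fit, rev_fit, on = "proportions")
  expect_identical(m$permutation, 3:1)
  m <- matchComponents(fit, rev_fit, on = "profiles")
  expect_identical(m$permutation, 3:1)

  # Hungarian solution equals brute-force enumeration of permutations
  for (i in 1:20) {
    k <- sample(2:5, 1)
    C <- matrix(runif(k * k, -1, 1), k, k)
    perms <- .permutations(k)
    scores <- apply(perms, 1, function(pp) sum(C[cbind(1:k, pp)]))
    best <- max(scores)
    hung <- .hungarianMax(C)
    expect_equal(sum(C[cbind(1:k, hung)]), best, tolerance = 1e-12)
  }
})

test_that("stability selection recovers the true number of types and rejects degenerate input", {
  T4 <- fourTypeMixture(seed = 1)
  stab <- estimateStability(T4, kRange = 3:8, seed = 51)
  expect_s4_class(stab, "StabilityReport")
  expect_equal(chosenK(stab), 4L)
  expect_true(all(stab@table$all_significant[stab@table$k <= 4]))

  expect_error(estimateStability(T4, kRange = 3:6, nReps = 1), "nReps")
  expect_error(estimateStability(T4, kRange = 90:91), "subsample")

  set.seed(62)
  noise <- matrix(runif(40 * 30), 40, 30,
                  dimnames = list(sprintf("g%02d", 1:40),
                                  sprintf("s%02d", 1:30)))
  expect_error(suppressWarnings(estimateStability(noise, kRange = 6:8,
                                                  seed = 63)),
               "no stable k")
})

test_that("estimated components are assigned to the correct reference classes", {
  fx <- markerOnlyRefs(seed = 64)
  refs <- fx$refs
  classes <- unique(classLabels(refs))
  v <- exprValues(refs)
  refmeans <- vapply(classes, function(cl)
    rowMeans(v[, classLabels(refs) == cl, drop = FALSE]),
    numeric(nrow(v)))
  M <- refmeans
  colnames(M) <- paste0("component_", seq_along(classes))
  fit <- new("DeconvolutionResult", M = M,
             P = matrix(1 / 4, 4, 6,
                        dimnames = list(colnames(M), paste0("s", 1:6))),
             k = 4L, rssTrajectory = c(1, 0.5), iterations = 2L,
             converged = TRUE, explainedVariance = 0.9,
             explainedVarianceUncentered = 0.95, seed = 1L)
  asn <- assignCellTypes(fit, refs)
  tab <- assignmentTable(asn)
  expect_identical(tab$class_label, classes)
  expect_equal(tab$correlation, rep(1, 4), tolerance = 1e-12)

  # constant column has no usable correlation
  fit2 <- fit
  fit2@M[, 2] <- 0.5
  tab2 <- assignmentTable(assignCellTypes(fit2, refs))
  expect_identical(tab2$class_label[2], "unassigned")
})

test_that("epithelial components inherit the subtype they dominate", {
  set.seed(65)
  samples <- sprintf("s%02d", 1:30)
  subtype <- rep(c("Basal", "HER2", "LumA", "Control"), c(8, 7, 8, 7))
  P <- matrix(0.05, 5, 30, dimnames = list(paste0("component_", 1:5), samples))
  P[1, subtype == "Basal"] <- 0.7
  P[2, subtype == "HER2"] <- 0.7
  P[3, subtype == "LumA"] <- 0.7
  P[4, subtype == "Control"] <- 0.7
  P <- sweep(P, 2, colSums(P), "/")
  fit <- new("DeconvolutionResult",
             M = matrix(0.5, 3, 5,
                        dimnames = list(paste0("g", 1:3), rownames(P))),
             P = P, k = 5L, rssTrajectory = 1, iterations = 1L,
             converged = TRUE, explainedVariance = 0.9,
             explainedVarianceUncentered = 0.9, seed = 1L)
  ann <- data.frame(sample_id = samples, subtype_label = subtype)
  labels <- labelEpithelialSubtypes(fit, ann, paste0("component_", 1:4))
  expect_identical(unname(labels), c("Basal", "HER2", "LumA", "Normal"))

  # two components claiming one subtype: both labelled, tie reported
  P2 <- P; P2[2, ] <- P[1, ]
  fit@P <- sweep(P2, 2, colSums(P2), "/")
  expect_warning(
    labels <- labelEpithelialSubtypes(fit, ann, paste0("component_", 1:2)),
    "tie")
  expect_identical(unname(labels), c("Basal", "Basal"))
})
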