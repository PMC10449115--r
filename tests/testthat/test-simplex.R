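test_that("mappability filtering enforces strict epithelial and cancer thresholds", {
  P <- rbind(
    basal  = c(0.30, 0.30, 0.03, 0.35),
    her2   = c(0.20, 0.20, 0.01, 0.35),
    lum    = c(0.16, 0.10, 0.01, 0.00),
    normal = c(0.06, 0.05, 0.75, 0.00),
    stroma = c(0.28, 0.35, 0.20, 0.30))
  colnames(P) <- c("keep", "s_low_epi", "s_low_cancer", "boundary")
  epi <- c("basal", "her2", "lum", "normal")
  trio <- c("basal", "her2", "lum")
  kept <- filterMappableSamples(P, epi, trio)
  # keep: epithelial 0.72, trio 0.66; s_low_epi: epithelial 0.65 < 0.7; s_low_cancer: trio 0.05 < 0.1;
  # boundary: epithelial exactly 0.70 is excluded (strict >)
  expect_identical(kept, "keep")
  P2 <- P
  P2["normal", "boundary"] <- 0.001  # epithelial 0.701, trio 0.70
  expect_identical(filterMappableSamples(P2, epi, trio),
                   c("keep", "boundary"))
})

test_that("simplex coordinates normalize the trio and use the unit ternary frame", {
  P <- rbind(b = c(0.2, 0.5, 0.1), h = c(0.2, 0, 0.2), l = c(0.2, 0, 0.3),
             o = c(0.4, 0.5, 0.4))
  colnames(P) <- paste0("s", 1:3)
  map <- toSimplexCoordinates(P, c("b", "h", "l"))
  expect_equal(map$basal, c(1 / 3, 1, 1 / 6))
  expect_equal(map$her2, c(1 / 3, 0, 1 / 3))
  expect_equal(map$luminal, c(1 / 3, 0, 1 / 2))
  # centroid, Basal vertex
  expect_equal(c(map$x[1], map$y[1]), c(0.5, sqrt(3) / 6))
  expect_equal(c(map$x[2], map$y[2]), c(0, 0))
  expect_identical(map$vertex_class, c("Basal", "Basal", "Luminal"))
  expect_identical(map$tie, c(TRUE, FALSE, FALSE))

  # the three vertices span an equilateral triangle with unit side
  V <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  xy <- cbind(V[, 2] + V[, 3] / 2, sqrt(3) / 2 * V[, 3])
  d <- as.matrix(dist(xy))
  expect_equal(unname(d[upper.tri(d)]), rep(1, 3))
})

test_that("vertex classification matches raw argmax and flags exact ties", {
  cls <- classifyByVertex(c(0.6, 0.3, 0.1))
  expect_identical(cls$class, "Basal"); expect_false(cls$tie)
  cls <- classifyByVertex(c(1, 1, 1) / 3)
  expect_identical(cls$class, "Basal"); expect_true(cls$tie)
  cls <- classifyByVertex(c(0.2, 0.4, 0.4))
  expect_identical(cls$class, "HER2"); expect_true(cls$tie)

  set.seed(81)
  raw <- matrix(runif(3 * 1e4), 3)
  norm <- sweep(raw, 2, colSums(raw), "/")
  expect_identical(classifyByVertex(t(norm))$class,
                   c("Basal", "HER2", "Luminal")[apply(raw, 2, which.max)])
})

test_that("classification comparisons tabulate and score agreement", {
  a <- c(s1 = "Basal", s2 = "HER2", s3 = "Luminal", s4 = "Basal",
         s5 = "Luminal")
  cmp <- compareClassifications(a, a)
  expect_equal(cmp$agreement, 1)
  expect_equal(sum(diag(cmp$table)), 5)

  b <- a; b[a == "Basal"] <- "HER2"; b[a == "HER2"] <- "Basal"
  cmp <- compareClassifications(a, b)
  expect_equal(cmp$table["Basal", "Basal"] + cmp$table["HER2", "HER2"],
               as.integer(0))

  # constructed 80% agreement
  set.seed(82)
  x <- sample(c("Basal", "HER2", "Luminal"), 200, replace = TRUE)
  y <- x
  flip <- sample(200, 40)
  y[flip] <- vapply(x[flip], function(v)
    setdiff(c("Basal", "HER2", "Luminal"), v)[1], character(1))
  expect_equal(compareClassifications(x, y)$agreement, 0.8)
  expect_error(compareClassifications(a, a[1:3]), "mismatched")
})

test_that("proportion correlations recover planted dependence", {
  P <- rbind(a = c(0.2, 0.3, 0.5), b = c(0.8, 0.7, 0.5))
  colnames(P) <- paste0("s", 1:3)
  expect_equal(correlateProportions(P, "a", "a")$r, 1)
  expect_equal(correlateProportions(P, "a", "b")$r, -1)

  set.seed(83)
  n <- 500
  x <- rnorm(n)
  y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  P2 <- rbind(mac = plogis(x) / 4, bas = plogis(y) / 4)
  colnames(P2) <- sprintf("s%03d", 1:n)
  r <- correlateProportions(P2, "mac", "bas")
  expect_gt(r$r, 0.35); expect_lt(r$r, 0.62)
  expect_lt(r$p_value, 1e-6)
  Pz <- rbind(a = rep(0.5, 5), b = runif(5))
  colnames(Pz) <- paste0("s", 1:5)
  expect_error(correlateProportions(Pz, "a", "b"), "zero variance")
})

test_that("filter-map-classify is invariant to sample order", {
  set.seed(84)
  P <- matrix(runif(5 * 40), 5, 40)
  P <- sweep(P, 2, colSums(P), "/")
  dimnames(P) <- list(c("b", "h", "l", "n", "st"), sprintf("s%02d", 1:40))
  epi <- c("b", "h", "l", "n"); trio <- c("b", "h", "l")
  perm <- sample(40)
  k1 <- filterMappableSamples(P, epi, trio)
  k2 <- filterMappableSamples(P[, perm], epi, trio)
  expect_setequal(k1, k2)
  m1 <- toSimplexCoordinates(P, trio, samples = k1)
  m2 <- toSimplexCoordinates(P[, perm], trio, samples = k2)
  m2 <- m2[match(m1$sample_id, m2$sample_id), ]
  expect_equal(m1$x, m2$x); expect_identical(m1$vertex_class, m2$vertex_class)
})
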