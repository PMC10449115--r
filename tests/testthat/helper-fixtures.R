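# shared fixture builders; everything is generated in code at test time

namedMatrix <- function(values, nr, nc, genes = NULL, samples = NULL) {
  m <- matrix(values, nr, nc)
  dimnames(m) <- list(genes %||% sprintf("g%02d", seq_len(nr)),
                      samples %||% sprintf("s%02d", seq_len(nc)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal marker-only reference panel: types differ ONLY by planted markers
# (typeVariation = 0), so Stage 0 behaviour on it is fully predictable
markerOnlyRefs <- function(seed = 1, nGenes = 400, nMarkers = 25,
                           markerFold = 50, nReps = 6) {
  spec <- data.frame(
    name = c("cancer_epithelial", "normal_epithelial", "immune", "stromal"),
    nReplicates = nReps, nMarkers = nMarkers, markerFold = markerFold)
  raw <- generateReferenceProfiles(nGenes = nGenes, typeSpec = spec,
                                   typeVariation = 0, replicateNoise = 0.02,
                                   seed = seed)
  refs <- new("ReferenceSet", profiles = transformCounts(raw$counts),
              classLabels = raw$classLabels, provenance = "bulk reference")
  list(raw = raw, refs = refs, markers = raw$markers)
}

# brute-force oracle: simplex-constrained LS by exhaustive grid search
gridSimplexLS <- function(M, t, step = 1e-3) {
  k <- ncol(M)
  if (k == 2) {
    p1 <- seq(0, 1, by = step)
    G <- rbind(p1, 1 - p1)
  } else if (k == 3) {
    p1 <- seq(0, 1, by = step)
    G <- do.call(cbind, lapply(p1, function(a) {
      b <- seq(0, 1 - a, by = step)
      rbind(a, b, 1 - a - b)
    }))
  } else stop("grid oracle supports k <= 3")
  obj <- colSums((matrix(t, nrow(M), ncol(G)) - M %*% G)^2)
  G[, which.min(obj)]
}

# brute-force oracle: box-constrained LS on [0,1]^2 by exhaustive grid
gridBoxLS <- function(P, t, step = 1e-3) {
  stopifnot(nrow(P) == 2)
  g <- seq(0, 1, by = step)
  G <- t(as.matrix(expand.grid(g, g)))
  obj <- colSums((matrix(t, ncol(P), ncol(G)) - t(P) %*% G)^2)
  G[, which.min(obj)]
}

# brute-force oracle: nonnegative LS for 2 components by grid on [0, hi]^2
gridNonnegLS <- function(P, t, hi, step) {
  g <- seq(0, hi, by = step)
  G <- t(as.matrix(expand.grid(g, g)))
  obj <- colSums((matrix(t, ncol(P), ncol(G)) - t(P) %*% G)^2)
  G[, which.min(obj)]
}

# pair-enumeration oracle for the AUC (positives vs negatives, ties = 1/2)
enumAUC <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# the exactly-four-types stability fixture: type-mean profiles mixed by the
# study's proportion design plus unstructured gaussian noise
fourTypeMixture <- function(seed, noiseSd = 0.01) {
  sim <- simulateMixtureStudy(seed = seed)
  genes <- suppressWarnings(suppressMessages(
    selectInformativeGenes(sim$refs, pairwise = list(
      list(classA = "cancer_epithelial", classB = "stromal"),
      list(classA = "normal_epithelial", classB = "stromal")))))
  gids <- intersect(geneIds(genes), rownames(exprValues(sim$mixtures)))
  Mt <- sim$truth@trueProfiles[gids, ]
  P <- sim$truth@trueProportions
  set.seed(seed + 999)
  T4 <- Mt %*% P + matrix(rnorm(length(gids) * ncol(P), 0, noiseSd),
                          length(gids))
  T4[T4 < 0] <- 0; T4[T4 >= 1] <- 1 - 1e-9
  T4
}

# run the full simulated study (stage 0 selection + anchored stage 1) and
# score recovery against truth; used by unit and acceptance tests
runSimulatedStudy <- function(seed, k = 4, ...) {
  sim <- simulateMixtureStudy(seed = seed, ...)
  genes <- suppressWarnings(suppressMessages(
    selectInformativeGenes(sim$refs, pairwise = list(
      list(classA = "cancer_epithelial", classB = "stromal"),
      list(classA = "normal_epithelial", classB = "stromal")))))
  tm <- exprValues(sim$mixtures)
  tm <- tm[intersect(geneIds(genes), rownames(tm)), , drop = FALSE]
  anchors <- anchorProfiles(sim$refs, c(normal_epithelial = 4, immune = 4,
                                        stromal = 4))[rownames(tm), ]
  fit <- runStage1(tm, k, seed = .deriveSeedPublic(seed),
                   anchors = anchors)
  list(sim = sim, genes = genes, tm = tm, fit = fit,
       recovery = scoreRecovery(fit, sim$truth, genes))
}

.deriveSeedPublic <- function(seed) as.integer((seed * 7919 + 13) %% 2147483587)

.rdirich <- function(n, k) {
  g <- matrix(rgamma(n * k, 1), n, k)
  g / rowSums(g)
}

# all permutations of 1..k, rows = permutations
.permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- .permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, matrix(setdiff(1:k, i)[sub], nrow(sub))) }))
}

# maximum-correlation assignment via the package's Hungarian routine
.hungarianMax <- function(C) as.integer(DeconvoMap:::.cppHungarian(-C))

.deriveSeed <- DeconvoMap:::.deriveSeed
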