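## Synthetic-data generator: reference profiles with planted markers,
## noisy replicates, purity-structured linear mixtures, and labelled
## single-cell counts for exercising the pseudo-bulk stage.

.defaultTypeSpec <- function() {
  data.frame(
    name = c("cancer_epithelial", "normal_epithelial", "immune", "stromal"),
    nReplicates = c(12L, 10L, 10L, 4L),
    nMarkers = c(25L, 25L, 25L, 25L),
    markerFold = c(8, 8, 8, 8),
    stringsAsFactors = FALSE)
}

# near-equal split of n mixtures over the four purity classes
.balancedClassMix <- function(n) {
  base <- n %/% 4
  mix <- c(high = base, impure = base, low = base, control = base)
  extra <- n - 4 * base
  if (extra > 0) mix[seq_len(extra)] <- mix[seq_len(extra)] + 1L
  mix
}

# symmetric Dirichlet draw
.rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), ncol = length(alpha),
              byrow = TRUE)
  g / rowSums(g)
}

#' Generate reference expression profiles with planted markers
#'
#' Emulates a panel of cell-line/reference expression profiles for several
#' cell types. Per gene, a log-normal baseline is drawn; each type receives
#' its own multiplicative log-normal effect per gene (`typeVariation` on the
#' log scale) so that types differ transcriptome-wide, as distinct cell
#' lineages do; each type's planted markers are additionally multiplied by
#' `markerFold` (markers are disjoint across types by construction); and
#' replicate profiles vary by multiplicative log-normal noise
#' (`replicateNoise`). Setting `typeVariation = 0` yields a minimal fixture
#' in which only the planted markers separate the types.
#'
#' @param nGenes number of genes (must be at least the total marker count).
#' @param typeSpec data.frame with columns `name`, `nReplicates`,
#'   `nMarkers`, `markerFold` (> 1); the default mirrors a
#'   12/10/10/4-replicate four-type panel with 25 markers each.
#' @param typeVariation sd (log scale) of per-type per-gene effects
#'   (default 0.9, transcriptome-wide separation comparable to distinct
#'   lineages).
#' @param replicateNoise sd (log scale) of replicate-to-replicate noise
#'   (default 0.05, replicate profiles of the same line/type).
#' @param baselineMeanlog,baselineSdlog log-normal baseline parameters
#'   (defaults log(100) and 0.6).
#' @param seed integer seed.
#' @return list with `counts` (genes x profiles nonnegative matrix),
#'   `classLabels` (per profile), and `markers` (named list of planted
#'   marker ids per type).
#' @export
generateReferenceProfiles <- function(nGenes = 2000,
                                      typeSpec = .defaultTypeSpec(),
                                      typeVariation = 0.9,
                                      replicateNoise = 0.05,
                                      baselineMeanlog = log(100),
                                      baselineSdlog = 0.6,
                                      seed = 1) {
  if (any(typeSpec$markerFold <= 1))
    stop("markerFold must exceed 1: markers are up-shifts")
  if (nGenes < sum(typeSpec$nMarkers))
    stop("nGenes must be at least the total number of planted markers")
  .setSeed(seed)
  genes <- sprintf("gene_%04d", seq_len(nGenes))
  baseline <- rlnorm(nGenes, baselineMeanlog, baselineSdlog)

  # disjoint marker blocks
  marker_idx <- split(seq_len(sum(typeSpec$nMarkers)),
                      rep(seq_len(nrow(typeSpec)), typeSpec$nMarkers))
  markers <- lapply(marker_idx, function(i) genes[i])
  names(markers) <- typeSpec$name

  cols <- list(); labels <- character()
  for (ty in seq_len(nrow(typeSpec))) {
    type_mean <- baseline *
      exp(rnorm(nGenes, 0, typeVariation))
    type_mean[marker_idx[[ty]]] <- type_mean[marker_idx[[ty]]] *
      typeSpec$markerFold[ty]
    for (r in seq_len(typeSpec$nReplicates[ty])) {
      cols[[length(cols) + 1L]] <-
        type_mean * exp(rnorm(nGenes, 0, replicateNoise))
      labels <- c(labels, typeSpec$name[ty])
    }
  }
  counts <- do.call(cbind, cols)
  dimnames(counts) <- list(genes, make.unique(paste0(labels, "_rep")))
  list(counts = counts, classLabels = labels, markers = markers)
}

#' Add per-profile noise scaled to the maximum per-gene variance
#'
#' For each cell type, the noise variance is a fraction of the maximum
#' per-gene variance observed across that type's replicate profiles:
#' `cancerNoiseFrac` for the cancer types, `normalNoiseFrac` for all others.
#' Zero-mean Gaussian noise of that variance is added independently to every
#' entry. On the transformed scale results are clipped into `[0, 1)`; on the
#' raw scale they are clipped at 0.
#'
#' @param refs a [ReferenceSet-class] (transformed scale) or a list with
#'   `counts` and `classLabels` (raw scale).
#' @param cancerTypes character vector of class labels treated as cancerous.
#' @param cancerNoiseFrac,normalNoiseFrac variance fractions (defaults 0.10
#'   and 0.05).
#' @param seed integer seed.
#' @return object of the same type with noisy profile values.
#' @export
addProfileNoise <- function(refs, cancerTypes, cancerNoiseFrac = 0.10,
                            normalNoiseFrac = 0.05, seed = 1) {
  if (cancerNoiseFrac <= 0 || cancerNoiseFrac >= 1 ||
      normalNoiseFrac <= 0 || normalNoiseFrac >= 1)
    stop("noise fractions must lie in (0, 1)")
  transformed <- is(refs, "ReferenceSet")
  v <- if (transformed) refs@profiles@values else refs$counts
  labels <- if (transformed) refs@classLabels else refs$classLabels
  .setSeed(seed)
  out <- v
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < 2)
      stop("class '", cls, "' has a single replicate; variance undefined")
    gv <- apply(v[, idx, drop = FALSE], 1, var)
    frac <- if (cls %in% cancerTypes) cancerNoiseFrac else normalNoiseFrac
    noise_sd <- sqrt(frac * max(gv))
    out[, idx] <- v[, idx] +
      matrix(rnorm(nrow(v) * length(idx), 0, noise_sd), nrow(v))
  }
  if (transformed) {
    out[out < 0] <- 0
    out[out >= 1] <- 1 - 1e-9
    new("ReferenceSet",
        profiles = new("TransformedMatrix", values = out,
                       scaleA = refs@profiles@scaleA,
                       perGene = refs@profiles@perGene),
        classLabels = labels, provenance = refs@provenance)
  } else {
    out[out < 0] <- 0
    list(counts = out, classLabels = labels)
  }
}

#' Generate purity-structured linear mixtures
#'
#' Builds `n` in-silico bulk samples as linear combinations of one randomly
#' chosen (noisy) replicate profile per cell type. Proportions follow four
#' purity classes: `high` draws the cancer proportion from Uniform(0.6,
#' 0.9); `impure` fixes it at 0.40; `low` fixes cancer at 0.10 with the
#' normal-epithelial proportion from Uniform(0.5, 0.8); `control` has zero
#' cancer and normal epithelial fixed at 0.70. The remaining mass is split
#' between the stromal and immune types by a symmetric Dirichlet(1, 1) draw.
#'
#' @param refs noisy profiles: a [ReferenceSet-class] (mixing on the
#'   transformed scale, the default study design) or a list with `counts`
#'   and `classLabels` (raw scale).
#' @param roles named character vector mapping the roles `cancer`, `normal`,
#'   `stroma`, `immune` to class labels of `refs`.
#' @param n number of mixtures (default 100).
#' @param classMix named integer vector of mixtures per purity class; must
#'   sum to `n`. Defaults to a near-equal split over high / impure / low /
#'   control.
#' @param truthProfiles optional genes x types matrix recorded as ground
#'   truth (e.g. clean type means); defaults to the type means of `refs`.
#' @param seed integer seed.
#' @return list with `mixtures` (a [TransformedMatrix-class] or raw
#'   matrix) and `truth` (a [SimulationTruth-class]).
#' @export
generateMixtures <- function(refs, roles, n = 100, classMix = NULL,
                             truthProfiles = NULL, seed = 1) {
  if (is.null(classMix)) classMix <- .balancedClassMix(n)
  if (sum(classMix) != n) stop("classMix must sum to n")
  if (!all(c("cancer", "normal", "stroma", "immune") %in% names(roles)))
    stop("roles must name cancer, normal, stroma and immune classes")
  transformed <- is(refs, "ReferenceSet")
  v <- if (transformed) refs@profiles@values else refs$counts
  labels <- if (transformed) refs@classLabels else refs$classLabels
  types <- unname(roles[c("cancer", "normal", "stroma", "immune")])
  if (!all(types %in% labels)) stop("roles not present in reference labels")

  .setSeed(seed)
  purity <- rep(names(classMix), classMix)
  props <- matrix(0, 4, n, dimnames = list(types, sprintf("mix_%03d", 1:n)))
  for (i in seq_len(n)) {
    split2 <- .rdirichlet(1, c(1, 1))
    pc <- switch(purity[i],
      high = { ca <- runif(1, 0.6, 0.9); c(ca, 0, (1 - ca) * split2) },
      impure = c(0.40, 0, 0.60 * split2),
      low = { no <- runif(1, 0.5, 0.8); c(0.10, no, (0.9 - no) * split2) },
      control = c(0, 0.70, 0.30 * split2),
      stop("unknown purity class ", purity[i]))
    if (any(pc < 0)) stop("infeasible purity constraints")
    props[, i] <- c(pc[1], pc[2], pc[3], pc[4])
  }

  mix <- matrix(0, nrow(v), n, dimnames = list(rownames(v), colnames(props)))
  for (i in seq_len(n)) {
    for (ty in seq_along(types)) {
      reps <- which(labels == types[ty])
      pick <- reps[sample.int(length(reps), 1)]
      mix[, i] <- mix[, i] + props[ty, i] * v[, pick]
    }
  }
  if (is.null(truthProfiles)) {
    truthProfiles <- vapply(types, function(ty)
      rowMeans(v[, labels == ty, drop = FALSE]), numeric(nrow(v)))
  }
  truth <- new("SimulationTruth", trueProfiles = truthProfiles,
               trueProportions = props,
               purityClass = factor(purity, levels = names(classMix)),
               seed = as.integer(seed))
  if (transformed) {
    mix[mix >= 1] <- 1 - 1e-9
    mixtures <- new("TransformedMatrix", values = mix,
                    scaleA = refs@profiles@scaleA,
                    perGene = refs@profiles@perGene)
  } else mixtures <- mix
  list(mixtures = mixtures, truth = truth)
}

#' Run the full simulated mixture study
#'
#' Convenience wrapper reproducing the package's validation design
#' end-to-end: generate reference profiles, transform them, plant
#' profile-level noise (10 percent of maximum per-gene variance for the
#' cancer type, 5 percent for normal types, on the transformed scale) and
#' mix 100 samples across the four purity classes.
#'
#' @param seed integer seed driving every random draw.
#' @param nGenes genes simulated (default 2000).
#' @param n mixtures (default 100).
#' @param classMix mixtures per purity class (default 25 each).
#' @param typeSpec passed to [generateReferenceProfiles()].
#' @param ... further arguments to [generateReferenceProfiles()].
#' @return list with `raw` (reference generator output), `refs` (clean
#'   transformed [ReferenceSet-class]), `noisy` (noisy reference set),
#'   `mixtures` ([TransformedMatrix-class]), `truth`
#'   ([SimulationTruth-class]), `markers`, and `roles`.
#' @export
simulateMixtureStudy <- function(seed = 1, nGenes = 2000, n = 100,
                                 classMix = NULL,
                                 typeSpec = .defaultTypeSpec(), ...) {
  raw <- generateReferenceProfiles(nGenes = nGenes, typeSpec = typeSpec,
                                   seed = seed, ...)
  refs <- new("ReferenceSet", profiles = transformCounts(raw$counts),
              classLabels = raw$classLabels, provenance = "bulk reference")
  noisy <- addProfileNoise(refs, cancerTypes = "cancer_epithelial",
                           seed = .deriveSeed(seed, 2))
  roles <- c(cancer = "cancer_epithelial", normal = "normal_epithelial",
             stroma = "stromal", immune = "immune")
  clean_means <- vapply(unname(roles[c("cancer", "normal", "stroma",
                                       "immune")]),
                        function(ty) rowMeans(
                          refs@profiles@values[, raw$classLabels == ty,
                                               drop = FALSE]),
                        numeric(nGenes))
  gm <- generateMixtures(noisy, roles, n = n, classMix = classMix,
                         truthProfiles = clean_means,
                         seed = .deriveSeed(seed, 3))
  c(list(raw = raw, refs = refs, noisy = noisy, markers = raw$markers,
         roles = roles), gm)
}

#' Generate labelled synthetic single-cell counts
#'
#' Negative-binomial counts with per-cell log-normal depth factors, planted
#' class markers, and (optionally) cells planted below the coverage
#' threshold so that pseudo-bulk filtering is exercised.
#'
#' @param nGenes genes (default 300).
#' @param classSpec data.frame with columns `name`, `nCells` and optionally
#'   `nLowCoverage` (cells planted at `lowDepth`).
#' @param meanDepth mean total counts of a passing cell (default 3e5).
#' @param depthSdlog log-normal spread of per-cell depth (default 0.2).
#' @param lowDepth depth of planted low-coverage cells (default 2e4).
#' @param nMarkers,markerFold markers per class and their fold (defaults 20
#'   and 6).
#' @param dispersion negative-binomial `size` parameter (default 2).
#' @param seed integer seed.
#' @return list with `counts` (genes x cells), `cellLabels`, `markers` and
#'   `lowCoverageCells` (planted cell ids).
#' @export
generateSyntheticScRNA <- function(nGenes = 300, classSpec,
                                   meanDepth = 3e5, depthSdlog = 0.2,
                                   lowDepth = 2e4, nMarkers = 20,
                                   markerFold = 6, dispersion = 2,
                                   seed = 1) {
  if (any(classSpec$nCells < 1)) stop("each class needs at least one cell")
  if (is.null(classSpec$nLowCoverage)) classSpec$nLowCoverage <- 0L
  if (nGenes < nMarkers * nrow(classSpec))
    stop("nGenes too small for the requested marker structure")
  .setSeed(seed)
  genes <- sprintf("gene_%04d", seq_len(nGenes))
  base <- rlnorm(nGenes, log(10), 1)
  marker_idx <- split(seq_len(nMarkers * nrow(classSpec)),
                      rep(seq_len(nrow(classSpec)), each = nMarkers))
  markers <- lapply(marker_idx, function(i) genes[i])
  names(markers) <- classSpec$name

  cols <- list(); labels <- character(); low_ids <- character()
  for (cl in seq_len(nrow(classSpec))) {
    rel <- base
    rel[marker_idx[[cl]]] <- rel[marker_idx[[cl]]] * markerFold
    rel <- rel / sum(rel)
    for (cell in seq_len(classSpec$nCells[cl])) {
      is_low <- cell <= classSpec$nLowCoverage[cl]
      depth <- if (is_low) lowDepth else
        meanDepth * exp(rnorm(1, 0, depthSdlog))
      cnt <- rnbinom(nGenes, size = dispersion, mu = rel * depth)
      id <- paste0(classSpec$name[cl], "_cell", cell)
      if (is_low) low_ids <- c(low_ids, id)
      cols[[length(cols) + 1L]] <- cnt
      labels <- c(labels, classSpec$name[cl])
    }
  }
  counts <- do.call(cbind, cols)
  dimnames(counts) <- list(genes, paste0(labels, "_cell",
                                         unlist(lapply(classSpec$nCells,
                                                       seq_len))))
  list(counts = counts, cellLabels = labels, markers = markers,
       lowCoverageCells = low_ids)
}

#' Score deconvolution accuracy against simulation truth
#'
#' Matches estimated components to the true cell types by the optimal
#' correlation assignment on the per-sample proportions, then reports the
#' squared Pearson correlation per matched pair for both the proportion
#' vectors and the profile columns (over `genes` when given).
#'
#' @param result a [DeconvolutionResult-class].
#' @param truth a [SimulationTruth-class] with the same number of types as
#'   `result@k` and the same samples.
#' @param genes optional gene restriction for the profile correlations
#'   (an [InformativeGeneSet-class] or character vector).
#' @return a [RecoveryReport-class].
#' @export
scoreRecovery <- function(result, truth, genes = NULL) {
  stopifnot(is(result, "DeconvolutionResult"), is(truth, "SimulationTruth"))
  if (result@k != nrow(truth@trueProportions))
    stop("component count mismatch between result and truth")
  m <- matchComponents(result, truth@trueProportions, on = "proportions")
  perm <- m$permutation
  gids <- if (is.null(genes)) rownames(result@M)
          else if (is(genes, "InformativeGeneSet")) genes@geneIds
          else as.character(genes)
  shared <- intersect(intersect(gids, rownames(result@M)),
                      rownames(truth@trueProfiles))
  tab <- do.call(rbind, lapply(seq_len(result@k), function(i) {
    j <- perm[i]
    prof_r2 <- if (length(shared) >= 3)
      as.numeric(.safeCor(result@M[shared, i],
                          truth@trueProfiles[shared, j]))^2 else NA_real_
    data.frame(component = colnames(result@M)[i],
               truth = colnames(truth@trueProfiles)[j] %||%
                 rownames(truth@trueProportions)[j],
               proportion_r2 = m$correlations[i]^2,
               profile_r2 = prof_r2, stringsAsFactors = FALSE)
  }))
  new("RecoveryReport", table = tab, permutation = as.integer(perm))
}

#' Extract anchor profiles from a reference set
#'
#' Picks the first `n` reference profile columns of each requested class,
#' for use as stabilizing anchor samples in [runStage1()].
#'
#' @param refs a [ReferenceSet-class].
#' @param classCounts named integer vector: profiles to take per class
#'   (e.g. `c(normal_epithelial = 4, immune = 4, stromal = 4)`).
#' @return genes x anchors matrix of transformed values.
#' @export
anchorProfiles <- function(refs, classCounts) {
  stopifnot(is(refs, "ReferenceSet"))
  v <- refs@profiles@values
  cols <- unlist(lapply(names(classCounts), function(cls) {
    idx <- which(refs@classLabels == cls)
    if (length(idx) < classCounts[[cls]])
      stop("class '", cls, "' has fewer than ", classCounts[[cls]],
           " profiles")
    idx[seq_len(classCounts[[cls]])]
  }))
  v[, cols, drop = FALSE]
}
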