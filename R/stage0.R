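#' Build pseudo-bulk reference profiles from labelled single-cell counts
#'
#' Within each cell-type class: cells with total counts below
#' `minTotalCounts` are removed, the survivors are ranked by descending total
#' counts (ties broken by cell identifier), consecutive blocks of `groupSize`
#' cells are summed into pseudo-bulks and an incomplete trailing block is
#' dropped. Every pseudo-bulk is then rescaled so its total matches the
#' highest pseudo-bulk total across all classes, and the whole set is
#' transformed to the unit interval.
#'
#' Classes left with fewer than two pseudo-bulks are dropped with a warning:
#' they cannot support the within-class replication the Stage 0 t-tests need.
#'
#' @param sc nonnegative genes x cells count matrix.
#' @param cellLabels character/factor of cell-type labels, one per cell.
#' @param groupSize cells summed per pseudo-bulk (default 5).
#' @param minTotalCounts coverage floor on per-cell total counts
#'   (default 1e5).
#' @return a [ReferenceSet-class] of transformed pseudo-bulk profiles.
#' @export
buildPseudobulks <- function(sc, cellLabels, groupSize = 5,
                             minTotalCounts = 1e5) {
  sc <- .checkExpressionMatrix(sc, "single-cell matrix")
  if (length(cellLabels) != ncol(sc))
    stop("one label per cell required")
  if (groupSize < 1) stop("groupSize must be >= 1")
  cellLabels <- as.character(cellLabels)
  totals <- colSums(sc)

  blocks <- list(); labels <- character()
  for (cls in unique(cellLabels)) {
    idx <- which(cellLabels == cls & totals >= minTotalCounts)
    idx <- idx[order(-totals[idx], colnames(sc)[idx])]
    nb <- length(idx) %/% groupSize
    if (nb < 2) {
      warning("class '", cls, "' dropped: only ", length(idx),
              " cells pass coverage (need >= ", 2 * groupSize,
              " for two pseudo-bulks)")
      next
    }
    for (b in seq_len(nb)) {
      cols <- idx[((b - 1) * groupSize + 1):(b * groupSize)]
      blocks[[length(blocks) + 1L]] <- rowSums(sc[, cols, drop = FALSE])
      labels <- c(labels, cls)
    }
  }
  if (!length(blocks)) stop("no class yielded pseudo-bulk profiles")
  pb <- do.call(cbind, blocks)
  colnames(pb) <- make.unique(paste0(labels, "_pb"))
  # normalize to the highest-coverage pseudo-bulk across all classes
  tot <- colSums(pb)
  pb <- sweep(pb, 2, max(tot) / tot, "*")
  new("ReferenceSet", profiles = transformCounts(pb), classLabels = labels,
      provenance = "single-cell pseudo-bulk")
}

#' Two-sample (Welch) t-test with degenerate-case conventions
#'
#' Thin wrapper around [stats::t.test()] returning the statistic, two-sided
#' p-value and the difference of group means (`a - b`). When both groups have
#' zero variance the test is undefined: equal means give `t = 0, p = 1`,
#' unequal means give `p = 0` with an infinite statistic of the appropriate
#' sign.
#'
#' @param groupA,groupB numeric vectors with at least two observations each.
#' @return list with elements `t`, `p`, `meanDiff`.
#' @export
differentialTTest <- function(groupA, groupB) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("both groups need >= 2 observations")
  d <- mean(groupA) - mean(groupB)
  if (var(groupA) == 0 && var(groupB) == 0) {
    if (d == 0) return(list(t = 0, p = 1, meanDiff = 0))
    return(list(t = sign(d) * Inf, p = 0, meanDiff = d))
  }
  tt <- t.test(groupA, groupB, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value, meanDiff = d)
}

# one contrast: returns the up/down selections for a class-vs-rest or
# pairwise comparison over the rows of `v`
.selectContrast <- function(v, inA, inB, pThreshold, nTop, contrastName) {
  res <- vapply(seq_len(nrow(v)), function(g) {
    r <- differentialTTest(v[g, inA], v[g, inB])
    c(r$p, r$meanDiff)
  }, numeric(2))
  p <- res[1, ]; md <- res[2, ]
  ids <- rownames(v)
  sig <- which(p < pThreshold)
  up <- sig[md[sig] > 0]; dn <- sig[md[sig] < 0]
  # rank by effect size; ties by |meanDiff| then lexicographic id
  up <- up[order(-md[up], ids[up])]
  dn <- dn[order(md[dn], ids[dn])]
  if (length(up) < nTop)
    warning(contrastName, ": only ", length(up), " significant upregulated ",
            "genes available (requested ", nTop, ")")
  if (length(dn) < nTop)
    warning(contrastName, ": only ", length(dn), " significant downregulated ",
            "genes available (requested ", nTop, ")")
  list(up = ids[head(up, nTop)], down = ids[head(dn, nTop)])
}

#' Select informative genes from reference profiles
#'
#' Runs one-vs-rest Welch t-tests on the transformed reference values for
#' every cell-type class and, among genes passing the p-value threshold,
#' keeps the `nTop` most upregulated and `nTop` most downregulated genes per
#' class (ranked by the difference of group means; ties by absolute
#' difference then gene identifier). Additional pairwise contrasts, each with
#' its own threshold and depth, can be requested. Any gene appearing in more
#' than one selection list is then removed entirely (exclusion, not
#' de-duplication): such genes do not discriminate a single class. An
#' optional literature list (e.g. PAM50) is intersected with the available
#' genes, unioned last, and is never subject to the exclusion rule.
#'
#' @param refs a [ReferenceSet-class].
#' @param pThreshold p-value gate for the one-vs-rest contrasts
#'   (default 1e-4).
#' @param nTop genes kept per direction per one-vs-rest contrast
#'   (default 25).
#' @param pairwise list of pairwise contrasts, each a list with elements
#'   `classA`, `classB` and optional `pThreshold`, `nTop` (defaulting to the
#'   one-vs-rest values).
#' @param literatureGenes optional character vector of literature gene
#'   symbols (matched case-sensitively; a warning is issued when less than
#'   90 percent are found).
#' @return an [InformativeGeneSet-class].
#' @export
selectInformativeGenes <- function(refs, pThreshold = 1e-4, nTop = 25,
                                   pairwise = list(),
                                   literatureGenes = NULL) {
  stopifnot(is(refs, "ReferenceSet"))
  v <- refs@profiles@values
  labels <- refs@classLabels
  classes <- unique(labels)

  lists <- list()
  for (cls in classes) {
    sel <- .selectContrast(v, which(labels == cls), which(labels != cls),
                           pThreshold, nTop, paste0(cls, " vs rest"))
    lists[[paste0(cls, "_vs_rest")]] <- sel
  }
  for (pw in pairwise) {
    if (!all(c(pw$classA, pw$classB) %in% classes))
      stop("pairwise contrast classes not present in the reference set")
    thr <- if (is.null(pw$pThreshold)) pThreshold else pw$pThreshold
    nt <- if (is.null(pw$nTop)) nTop else pw$nTop
    nm <- paste0(pw$classA, "_vs_", pw$classB)
    lists[[nm]] <- .selectContrast(v, which(labels == pw$classA),
                                   which(labels == pw$classB), thr, nt, nm)
  }

  membership <- lapply(lists, function(l) unique(c(l$up, l$down)))
  all_genes <- unlist(membership, use.names = FALSE)
  counts <- table(all_genes)
  kept <- names(counts)[counts == 1L]
  excluded <- names(counts)[counts > 1L]

  src <- character(0); ids <- character(0)
  for (nm in names(membership)) {
    g <- intersect(membership[[nm]], kept)
    ids <- c(ids, g)
    src <- c(src, rep(nm, length(g)))
  }
  # keep deterministic order: by contrast then gene id within contrast
  ord <- order(match(src, names(membership)), ids)
  ids <- ids[ord]; src <- src[ord]

  if (!is.null(literatureGenes)) {
    found <- intersect(literatureGenes, rownames(v))
    if (length(found) < 0.9 * length(literatureGenes))
      warning("only ", length(found), " of ", length(literatureGenes),
              " literature genes found in the reference matrix")
    lit_new <- setdiff(found, ids)
    dup <- intersect(found, ids)
    src[ids %in% dup] <- paste0(src[ids %in% dup], ";literature")
    ids <- c(ids, lit_new)
    src <- c(src, rep("literature", length(lit_new)))
  }
  if (length(excluded))
    message(length(excluded), " genes excluded for appearing in multiple ",
            "selection lists")
  new("InformativeGeneSet", geneIds = ids,
      source = data.frame(gene_id = ids, source = src,
                          stringsAsFactors = FALSE),
      nTotal = length(ids))
}

#' Named Stage 0 selection recipes
#'
#' Returns the parameter set of one of the shipped selection recipes:
#' \describe{
#'   \item{simulated}{one-vs-rest p < 1e-4, 25 up / 25 down per class;
#'     pairwise cancer-vs-stroma and normal-vs-stroma at the same threshold
#'     and depth.}
#'   \item{cell-line}{one-vs-rest p < 1e-4, 25/25; pairwise
#'     epithelial-vs-stroma at p < 1e-5, 75/75.}
#'   \item{single-cell}{one-vs-rest p < 0.05, 50/50; pairwise
#'     T-cell-vs-macrophage at p < 0.05, 25/25.}
#' }
#'
#' @param preset recipe name.
#' @param roles named character vector mapping the roles used by the recipe
#'   (`cancer`, `normal`, `stroma`, `epithelial`, `tcell`, `macrophage`) to
#'   class labels of the reference set at hand. Only the roles the recipe
#'   needs must be present.
#' @return list of arguments for [selectInformativeGenes()].
#' @export
stage0Preset <- function(preset = c("simulated", "cell-line", "single-cell"),
                         roles) {
  preset <- match.arg(preset)
  need <- function(r) {
    if (!r %in% names(roles)) stop("preset needs a '", r, "' role")
    unname(roles[[r]])
  }
  switch(preset,
    "simulated" = list(
      pThreshold = 1e-4, nTop = 25,
      pairwise = list(
        list(classA = need("cancer"), classB = need("stroma")),
        list(classA = need("normal"), classB = need("stroma")))),
    "cell-line" = list(
      pThreshold = 1e-4, nTop = 25,
      pairwise = list(
        list(classA = need("epithelial"), classB = need("stroma"),
             pThreshold = 1e-5, nTop = 75))),
    "single-cell" = list(
      pThreshold = 0.05, nTop = 50,
      pairwise = list(
        list(classA = need("tcell"), classB = need("macrophage"),
             pThreshold = 0.05, nTop = 25))))
}
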