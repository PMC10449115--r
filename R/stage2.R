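#' Recover untransformed per-cell-type expression (Stage 2)
#'
#' Given the untransformed expression matrix and the Stage 1 per-sample
#' proportions, solves for each gene independently
#' `argmin || x_g - m' P ||^2` subject to `m >= 0` (nonnegative least
#' squares). The recovered profile is the average expression of each
#' constituent cell type across the chosen sample set. Components whose mean
#' proportion in the set falls below `minMeanProportion` are unidentifiable
#' there and are reported as `NA`, never as zeros.
#'
#' @param x nonnegative genes x samples expression matrix (quantile
#'   normalized upstream if normalization was applied, but untransformed).
#' @param p k x samples proportion matrix, columns on the simplex, sample
#'   names matching `x` (a [DeconvolutionResult-class] is also accepted).
#' @param sampleSubset optional character vector of sample ids to restrict
#'   to (at least k samples must remain).
#' @param groupId label recorded on the output (default "all").
#' @param minMeanProportion identifiability floor (default 0.01).
#' @return a [Stage2Profiles-class].
#' @export
runStage2 <- function(x, p, sampleSubset = NULL, groupId = "all",
                      minMeanProportion = 0.01) {
  x <- .checkExpressionMatrix(x)
  if (is(p, "DeconvolutionResult")) p <- p@P
  stopifnot(is.matrix(p))
  shared <- intersect(colnames(x), colnames(p))
  if (!is.null(sampleSubset)) shared <- intersect(shared, sampleSubset)
  if (length(shared) < nrow(p))
    stop("fewer samples (", length(shared), ") than components (", nrow(p),
         ") after subsetting")
  X <- x[, shared, drop = FALSE]
  P <- p[, shared, drop = FALSE]
  if (any(P < -1e-8) || any(abs(colSums(P) - 1) > 1e-6))
    stop("proportion columns must be nonnegative and sum to 1")
  if (qr(t(P))$rank < nrow(P)) {
    warning("proportion matrix is rank deficient; solving with ridge 1e-10")
    P <- cbind(P, diag(sqrt(1e-10), nrow(P)))
    X <- cbind(X, matrix(0, nrow(X), nrow(P)))
  }
  M <- .cppSolveNonneg(P, X)
  dimnames(M) <- list(rownames(X), rownames(p))
  unident <- rowMeans(p[, shared, drop = FALSE]) < minMeanProportion
  if (any(unident)) {
    warning("components with near-zero proportion in this group reported ",
            "as NA: ", paste(rownames(p)[unident], collapse = ", "))
    M[, unident] <- NA_real_
  }
  new("Stage2Profiles", values = M, groupId = groupId,
      componentLabels = rownames(p) %||% paste0("component_", seq_len(nrow(p))),
      unidentifiable = unname(unident))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group samples by their dominant epithelial component
#'
#' Aggregates component proportions into super-classes (e.g. epithelial /
#' stromal / immune) by summing mapped components — which preserves the
#' per-sample total of one — and assigns every sample to the epithelial
#' component with the largest individual proportion. Exact ties are broken
#' deterministically by component order and logged.
#'
#' @param p k x samples proportion matrix (or
#'   [DeconvolutionResult-class]).
#' @param aggregate named character vector mapping every component name to a
#'   super-class label; components mapped to `"epithelial"` define the
#'   candidate dominant components.
#' @param epithelialClass the super-class treated as epithelial
#'   (default `"epithelial"`).
#' @return list with `groups` (factor of dominant epithelial component per
#'   sample), `counts` (table), `superProportions` (super-classes x samples)
#'   and `ties` (sample ids with exact ties).
#' @export
groupSamplesByDominantProfile <- function(p, aggregate,
                                          epithelialClass = "epithelial") {
  if (is(p, "DeconvolutionResult")) p <- p@P
  stopifnot(is.matrix(p))
  if (!all(rownames(p) %in% names(aggregate)))
    stop("aggregate mapping must cover all components")
  sup <- unique(unname(aggregate[rownames(p)]))
  superP <- t(vapply(sup, function(s)
    colSums(p[rownames(p)[aggregate[rownames(p)] == s], , drop = FALSE]),
    numeric(ncol(p))))
  dimnames(superP) <- list(sup, colnames(p))
  epi <- rownames(p)[aggregate[rownames(p)] == epithelialClass]
  if (!length(epi)) stop("no components mapped to '", epithelialClass, "'")
  pe <- p[epi, , drop = FALSE]
  idx <- apply(pe, 2, which.max)
  ties <- colnames(p)[apply(pe, 2, function(col)
    sum(col == max(col)) > 1)]
  if (length(ties))
    message("dominant-component ties (broken by component order): ",
            paste(ties, collapse = ", "))
  groups <- factor(epi[idx], levels = epi)
  names(groups) <- colnames(p)
  list(groups = groups, counts = table(groups), superProportions = superP,
       ties = ties)
}
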