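## Stage 1: alternating constrained least squares on the transformed scale.
## Profile step (per gene, box constraint [0,1]) then proportion step (per
## sample, simplex constraint); both are exact convex QP solves, so the
## residual sum of squares is non-increasing across iterations.

# ridge augmentation for rank-deficient systems (warned, never silent)
.ridgeGuard <- function(m, what) {
  if (qr(m)$rank < ncol(m)) {
    warning(what, " is rank deficient; solving with ridge 1e-10")
    TRUE
  } else FALSE
}

#' Solve per-sample proportions given cell-type profiles
#'
#' For each sample column `t`, solves the convex quadratic program
#' `argmin || t - M p ||^2` subject to `p >= 0`, `sum(p) = 1`. The solution
#' is unique when `M` has full column rank; rank-deficient `M` is solved
#' with a tiny ridge (1e-10) and a warning.
#'
#' @param M genes x k profile matrix with entries in `[0, 1]`.
#' @param t transformed sample vector, or genes x samples matrix.
#' @return proportion vector (or k x samples matrix), columns on the simplex.
#' @export
solveProportions <- function(M, t) {
  stopifnot(is.matrix(M))
  if (any(M < -1e-12) || any(M > 1 + 1e-12))
    stop("profile matrix entries must lie in [0, 1]")
  tv <- if (is.matrix(t)) t else matrix(t, ncol = 1)
  if (nrow(tv) != nrow(M)) stop("dimension mismatch between M and t")
  Msolve <- M
  if (.ridgeGuard(M, "profile matrix")) {
    Msolve <- rbind(M, diag(sqrt(1e-10), ncol(M)))
    tv2 <- rbind(tv, matrix(0, ncol(M), ncol(tv)))
    P <- .cppSolveProportions(Msolve, tv2)
  } else {
    P <- .cppSolveProportions(Msolve, tv)
  }
  P <- sweep(P, 2, colSums(P), "/")
  rownames(P) <- colnames(M)
  colnames(P) <- colnames(tv)
  if (is.matrix(t)) P else drop(P)
}

#' Solve per-gene profiles given per-sample proportions
#'
#' For each gene row `t`, solves `argmin || t - m' P ||^2` subject to
#' `0 <= m <= 1` elementwise (box-constrained QP).
#'
#' @param P k x samples proportion matrix (columns on the simplex).
#' @param t transformed gene vector across samples, or genes x samples
#'   matrix.
#' @return profile vector (or genes x k matrix) with entries in `[0, 1]`.
#' @export
solveProfiles <- function(P, t) {
  stopifnot(is.matrix(P))
  if (any(P < -1e-8) || any(abs(colSums(P) - 1) > 1e-6))
    stop("proportion columns must be nonnegative and sum to 1")
  tv <- if (is.matrix(t)) t else matrix(t, nrow = 1)
  if (ncol(tv) != ncol(P)) stop("dimension mismatch between P and t")
  Psolve <- P
  if (.ridgeGuard(t(P), "proportion matrix")) {
    Psolve <- cbind(P, diag(sqrt(1e-10), nrow(P)))
    tv <- cbind(tv, matrix(0, nrow(tv), nrow(P)))
  }
  M <- .cppSolveProfiles(Psolve, tv)
  M[M < 0] <- 0; M[M > 1] <- 1
  rownames(M) <- rownames(tv)
  colnames(M) <- rownames(P)
  if (is.matrix(t)) M else drop(M)
}

#' Run the Stage 1 constrained matrix factorization
#'
#' Alternating exact minimization on the transformed bulk matrix restricted
#' to the informative genes: from a seeded random start, each iteration
#' performs the all-genes profile step followed by the all-samples
#' proportion step, and stops when the drop in residual sum of squares falls
#' below `rssTol` or `maxIter` is reached. Initialization samples `k`
#' distinct sample columns and perturbs them with uniform noise of amplitude
#' 0.05 (clipped to `[0, 1]`), which keeps starts data-plausible.
#'
#' @param t a [TransformedMatrix-class] or matrix of transformed values,
#'   already restricted to the informative genes.
#' @param k number of cell types to model (>= 2, at most the number of
#'   samples).
#' @param maxIter iteration cap (default 2000).
#' @param rssTol stop when the RSS decrease falls below this (default
#'   1e-10).
#' @param seed integer seed for the random initialization; start seeds are
#'   derived from it deterministically.
#' @param nStarts number of seeded random restarts; the run with the lowest
#'   final RSS is returned (default 5). The factorization is biconvex, not
#'   convex, so occasional starts settle in poorer local optima; a small
#'   best-of restart pool removes them.
#' @param anchors optional transformed pure reference profiles (matrix or
#'   [TransformedMatrix-class], same genes) appended to the input as extra
#'   samples to stabilize the factorization. Anchor columns take part in the
#'   fit but are excluded from every reported output (proportions, RSS,
#'   explained variance).
#' @return a [DeconvolutionResult-class].
#' @export
runStage1 <- function(t, k, maxIter = 2000, rssTol = 1e-10, seed = 1,
                      nStarts = 5, anchors = NULL) {
  v <- .transformedValues(t)
  n_data <- ncol(v)
  if (!is.null(anchors)) {
    av <- .transformedValues(anchors, "anchors")
    if (!identical(rownames(av), rownames(v)))
      av <- av[rownames(v), , drop = FALSE]
    colnames(av) <- paste0(".anchor_", seq_len(ncol(av)))
    v <- cbind(v, av)
  }
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  if (k > ncol(v)) stop("k exceeds the number of samples")
  if (nStarts < 1) stop("nStarts must be >= 1")
  fit <- NULL
  for (s in seq_len(nStarts)) {
    .setSeed(if (s == 1) seed else .deriveSeed(seed, 101, s))
    # sample initialization columns from the sorted names so the fit is
    # invariant to the order samples arrive in
    init_cols <- if (!is.null(colnames(v))) sample(sort(colnames(v)), k)
                 else sample(ncol(v), k)
    M0 <- v[, init_cols, drop = FALSE] +
      matrix(runif(nrow(v) * k, -0.05, 0.05), nrow(v), k)
    M0[M0 < 0] <- 0; M0[M0 > 1] <- 1
    cand <- .cppAlternate(v, M0, as.integer(maxIter), rssTol)
    if (is.null(fit) || tail(cand$rss, 1) < tail(fit$rss, 1)) fit <- cand
  }
  M <- fit$M; P <- fit$P
  M[M < 0] <- 0; M[M > 1] <- 1
  P[P < 0] <- 0
  P <- sweep(P, 2, colSums(P), "/")
  rownames(M) <- rownames(v)
  colnames(M) <- paste0("component_", seq_len(k))
  dimnames(P) <- list(colnames(M), colnames(v))
  # anchors helped the fit; they are not part of the reported result
  P <- P[, seq_len(n_data), drop = FALSE]
  v <- v[, seq_len(n_data), drop = FALSE]

  rss <- sum((v - M %*% P)^2)
  tss_c <- sum((v - mean(v))^2)
  tss_u <- sum(v^2)
  new("DeconvolutionResult", M = M, P = P, k = k,
      rssTrajectory = fit$rss, iterations = fit$iterations,
      converged = fit$converged,
      explainedVariance = 1 - rss / tss_c,
      explainedVarianceUncentered = 1 - rss / tss_u,
      seed = as.integer(seed))
}

#' Match components between two deconvolution results
#'
#' Builds the Pearson correlation matrix between the components of two
#' results (over shared samples for `on = "proportions"`, shared genes for
#' `on = "profiles"`) and finds the one-to-one assignment maximizing the
#' total correlation (Hungarian algorithm). Components with zero variance
#' are flagged and enter the assignment with correlation 0.
#'
#' @param resultA,resultB [DeconvolutionResult-class] objects with equal
#'   `k`, or bare matrices (k x samples proportions / genes x k profiles).
#' @param on match on `"proportions"` (default) or `"profiles"`.
#' @return list with `permutation` (index into B's components for each
#'   component of A), `correlations` (per matched pair) and
#'   `zeroVariance` flags.
#' @export
matchComponents <- function(resultA, resultB,
                            on = c("proportions", "profiles")) {
  on <- match.arg(on)
  get <- function(r) {
    if (is(r, "DeconvolutionResult"))
      if (on == "proportions") r@P else t(r@M)
    else if (is.matrix(r)) {
      if (on == "proportions") r else t(r)
    } else stop("inputs must be DeconvolutionResult objects or matrices")
  }
  A <- get(resultA); B <- get(resultB)  # components x features
  if (nrow(A) != nrow(B)) stop("results have different numbers of components")
  shared <- intersect(colnames(A), colnames(B))
  if (is.null(colnames(A)) || is.null(colnames(B))) {
    if (ncol(A) != ncol(B)) stop("no identifiers and unequal feature counts")
    shared <- seq_len(ncol(A))
  } else if (length(shared) < 3)
    stop("fewer than 3 shared samples/genes to correlate over")
  A <- A[, shared, drop = FALSE]; B <- B[, shared, drop = FALSE]
  k <- nrow(A)
  C <- matrix(0, k, k); zv <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    r <- .safeCor(A[i, ], B[j, ])
    C[i, j] <- r
    zv[i, j] <- isTRUE(attr(r, "zero_variance"))
  }
  perm <- as.integer(.cppHungarian(-C))
  cors <- C[cbind(seq_len(k), perm)]
  list(permutation = perm, correlations = cors,
       zeroVariance = zv[cbind(seq_len(k), perm)], n = length(shared))
}

#' Stability-based selection of the number of cell types
#'
#' For each candidate `k`, runs Stage 1 on `nReps` independent subsamples of
#' `ceiling(subsampleFrac * n)` samples (drawn without replacement; genes are
#' never subsampled; both the subsample and the initialization are
#' re-randomized per replicate) and correlates the matched proportions of
#' every replicate pair over their shared samples. A `k` is stable when every
#' matched correlation is significant (two-sided Pearson test, `p < alpha`).
#' Scanning upward, the chosen `k` is the largest stable value before the
#' first unstable one (the largest stable `k` overall when no instability is
#' met).
#'
#' @param t transformed matrix restricted to informative genes.
#' @param kRange integer vector of candidate k (default `3:10`).
#' @param nReps subsample replicates per k (default 3; at least 2).
#' @param subsampleFrac fraction of samples per replicate (default 0.8).
#' @param alpha significance level for the correlation tests (default 0.05).
#' @param seed integer seed; replicate seeds are derived deterministically.
#' @param maxIter,rssTol,anchors passed to [runStage1()]; anchors are
#'   appended to every subsample, never subsampled themselves.
#' @return a [StabilityReport-class].
#' @export
estimateStability <- function(t, kRange = 3:10, nReps = 3,
                              subsampleFrac = 0.8, alpha = 0.05, seed = 1,
                              maxIter = 2000, rssTol = 1e-10, anchors = NULL,
                              nStarts = 1) {
  v <- .transformedValues(t)
  if (nReps < 2) stop("nReps must be >= 2: pairwise comparison is undefined")
  nsub <- ceiling(subsampleFrac * ncol(v))
  kRange <- sort(unique(as.integer(kRange)))
  if (max(kRange) > nsub)
    stop("kRange exceeds the subsample size ", nsub)

  rows <- list(); paircors <- list()
  for (k in kRange) {
    fits <- vector("list", nReps)
    for (r in seq_len(nReps)) {
      rs <- .deriveSeed(seed, k, r)
      .setSeed(rs)
      cols <- sample(ncol(v), nsub)
      # one start per replicate by default: replicate-to-replicate
      # variability (subsample AND initialization) is the stability signal
      fits[[r]] <- runStage1(v[, cols, drop = FALSE], k, maxIter = maxIter,
                             rssTol = rssTol, seed = .deriveSeed(rs, 1),
                             nStarts = nStarts, anchors = anchors)
    }
    cors <- c(); pvals <- c()
    for (i in seq_len(nReps - 1)) for (j in (i + 1):nReps) {
      m <- matchComponents(fits[[i]], fits[[j]], on = "proportions")
      pv <- vapply(seq_along(m$correlations), function(c1) {
        if (m$zeroVariance[c1]) return(1)
        r <- m$correlations[c1]; n <- m$n
        tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
        2 * pt(-abs(tt), df = n - 2)
      }, numeric(1))
      cors <- c(cors, m$correlations); pvals <- c(pvals, pv)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      k = k, all_significant = all(pvals < alpha),
      mean_matched_correlation = mean(cors),
      min_matched_correlation = min(cors),
      max_p_value = max(pvals))
    paircors[[as.character(k)]] <- cors
  }
  tab <- do.call(rbind, rows)
  stable <- tab$k[tab$all_significant]
  if (!length(stable))
    stop("no stable k in the scanned range; widen kRange or provide more ",
         "samples")
  # first loss of stability after stability has been reached; an unstable
  # prefix (k too small to even reproduce) is skipped
  unstable_after <- tab$k[!tab$all_significant & tab$k > min(stable)]
  chosen <- if (!length(unstable_after)) max(stable)
            else max(stable[stable < unstable_after[1]])
  new("StabilityReport", table = tab, pairCorrelations = paircors,
      chosenK = as.integer(chosen))
}

#' Assign cell-type identities to estimated components
#'
#' Correlates each estimated profile column against the class-mean reference
#' profiles over the informative genes and assigns the class with the
#' maximal Pearson correlation. Components whose best correlation falls
#' below 0.2 (or which have zero variance) are labelled `"unassigned"`.
#'
#' @param result a [DeconvolutionResult-class].
#' @param refs a [ReferenceSet-class] on a compatible gene universe.
#' @param genes optional [InformativeGeneSet-class] (or character vector)
#'   restricting the correlation; defaults to all shared genes.
#' @param minCorrelation assignment floor (default 0.2).
#' @return a [CellTypeAssignment-class].
#' @export
assignCellTypes <- function(result, refs, genes = NULL, minCorrelation = 0.2) {
  stopifnot(is(result, "DeconvolutionResult"), is(refs, "ReferenceSet"))
  gids <- if (is.null(genes)) rownames(result@M)
          else if (is(genes, "InformativeGeneSet")) genes@geneIds
          else as.character(genes)
  shared <- Reduce(intersect, list(gids, rownames(result@M),
                                   rownames(refs@profiles@values)))
  if (length(shared) < 3) stop("fewer than 3 shared genes for assignment")
  classes <- unique(refs@classLabels)
  refmeans <- vapply(classes, function(cls)
    rowMeans(refs@profiles@values[shared, refs@classLabels == cls,
                                  drop = FALSE]),
    numeric(length(shared)))
  M <- result@M[shared, , drop = FALSE]
  tab <- do.call(rbind, lapply(seq_len(ncol(M)), function(i) {
    rs <- vapply(seq_along(classes),
                 function(j) as.numeric(.safeCor(M[, i], refmeans[, j])),
                 numeric(1))
    ord <- order(-rs)
    best <- rs[ord[1]]
    lab <- if (sd(M[, i]) == 0 || best < minCorrelation) "unassigned"
           else classes[ord[1]]
    data.frame(component = colnames(result@M)[i], class_label = lab,
               correlation = best,
               runner_up = if (length(rs) > 1) rs[ord[2]] else NA_real_,
               subtype = NA_character_, stringsAsFactors = FALSE)
  }))
  new("CellTypeAssignment", table = tab)
}

#' Label epithelial components with annotation subtypes
#'
#' Each epithelial component is labelled with the annotation subtype in which
#' its mean proportion is highest; a component highest in control/normal
#' samples is labelled `"Normal"`. If two components claim the same subtype
#' both keep the label and the tie is reported via a warning, never silently
#' reassigned.
#'
#' @param result a [DeconvolutionResult-class].
#' @param annotations data.frame with columns `sample_id` and
#'   `subtype_label` (see [readSampleAnnotation()]).
#' @param epithelialComponents component names or indices to label.
#' @param controlLabels annotation labels treated as control tissue
#'   (default `c("Control", "Normal")`).
#' @param assignment optional [CellTypeAssignment-class] updated in place.
#' @return named character vector of subtype labels per epithelial
#'   component; when `assignment` is supplied, the updated assignment.
#' @export
labelEpithelialSubtypes <- function(result, annotations, epithelialComponents,
                                    controlLabels = c("Control", "Normal"),
                                    assignment = NULL) {
  stopifnot(is(result, "DeconvolutionResult"))
  P <- result@P
  if (is.numeric(epithelialComponents))
    epithelialComponents <- rownames(P)[epithelialComponents]
  ann <- annotations[!is.na(annotations$subtype_label) &
                       annotations$sample_id %in% colnames(P), ]
  if (!nrow(ann)) stop("no annotated samples overlap the proportion matrix")
  subtypes <- unique(ann$subtype_label)
  labels <- vapply(epithelialComponents, function(comp) {
    means <- vapply(subtypes, function(s)
      mean(P[comp, ann$sample_id[ann$subtype_label == s]]), numeric(1))
    top <- subtypes[which.max(means)]
    if (top %in% controlLabels) "Normal" else top
  }, character(1))
  dup <- labels[duplicated(labels) & !labels %in% "Normal"]
  if (length(dup))
    warning("subtype tie: multiple components labelled ",
            paste(unique(dup), collapse = ", "))
  if (!is.null(assignment)) {
    tab <- assignment@table
    tab$subtype[match(epithelialComponents, tab$component)] <- labels
    return(new("CellTypeAssignment", table = tab))
  }
  labels
}
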