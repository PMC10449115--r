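## S4 classes for the deconvolution pipeline. Expression inputs are plain
## numeric matrices (genes x samples, dimnames mandatory) or
## SummarizedExperiment objects; results are the classes below.

#' TransformedMatrix: expression on the unit-interval scale
#'
#' Holds a genes x samples matrix after the negative-exponential transform
#' `y = 1 - exp(-a * x)` together with the scale parameter `a` used.
#' With the default global fit `a = 1/max(x)` the observed maximum maps to
#' `1 - exp(-1)`; the value 1 is never attained.
#'
#' @slot values numeric matrix in `[0, 1)` with gene rownames and sample
#'   colnames.
#' @slot scaleA positive numeric; a single scalar for the default global fit,
#'   or one value per gene when per-gene scaling was requested.
#' @slot perGene logical flag; `TRUE` when `scaleA` is per-gene.
#'
#' @seealso [transformCounts()], [inverseTransform()]
#' @export
setClass("TransformedMatrix",
  representation(values = "matrix", scaleA = "numeric", perGene = "logical"),
  prototype(perGene = FALSE),
  validity = function(object) {
    v <- object@values
    msg <- character()
    if (is.null(rownames(v)) || is.null(colnames(v)))
      msg <- c(msg, "values must have gene rownames and sample colnames")
    if (anyDuplicated(rownames(v)) || anyDuplicated(colnames(v)))
      msg <- c(msg, "duplicate gene or sample identifiers")
    if (any(!is.finite(v)))
      msg <- c(msg, "non-finite values")
    else if (any(v < 0) || any(v >= 1))
      msg <- c(msg, "values must lie in [0, 1)")
    if (any(object@scaleA <= 0))
      msg <- c(msg, "scaleA must be positive")
    if (object@perGene && length(object@scaleA) != nrow(v))
      msg <- c(msg, "per-gene scaleA must have one value per gene")
    if (!object@perGene && length(object@scaleA) != 1L)
      msg <- c(msg, "global scaleA must be a single value")
    if (length(msg)) msg else TRUE
  })

#' ReferenceSet: transformed reference profiles grouped by cell-type class
#'
#' @slot profiles a [TransformedMatrix-class] of reference profiles
#'   (genes x profiles).
#' @slot classLabels character, one cell-type class per profile column.
#'   Every class must have at least two profiles so that per-gene t-tests
#'   have within-class replication.
#' @slot provenance character, e.g. `"single-cell pseudo-bulk"` or
#'   `"bulk reference"`.
#' @export
setClass("ReferenceSet",
  representation(profiles = "TransformedMatrix", classLabels = "character",
                 provenance = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@classLabels) != ncol(object@profiles@values))
      msg <- c(msg, "one class label per profile column required")
    tab <- table(object@classLabels)
    if (any(tab < 2))
      msg <- c(msg, paste0("every class needs >= 2 profiles; offending: ",
                           paste(names(tab)[tab < 2], collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' InformativeGeneSet: genes selected to drive the factorization
#'
#' @slot geneIds ordered unique gene identifiers.
#' @slot source data.frame with columns `gene_id` and `source` recording the
#'   contrast(s) that selected each gene, or `"literature"`.
#' @slot nTotal integer, number of genes.
#' @export
setClass("InformativeGeneSet",
  representation(geneIds = "character", source = "data.frame",
                 nTotal = "integer"),
  validity = function(object) {
    msg <- character()
    if (anyDuplicated(object@geneIds)) msg <- c(msg, "duplicate gene ids")
    if (object@nTotal != length(object@geneIds))
      msg <- c(msg, "nTotal does not match geneIds length")
    if (length(msg)) msg else TRUE
  })

#' DeconvolutionResult: factor pair from the constrained factorization
#'
#' @slot M numeric matrix genes x k with entries in `[0, 1]`: estimated
#'   cell-type profiles on the transformed scale.
#' @slot P numeric matrix k x samples: per-sample proportions; every column
#'   is nonnegative and sums to one.
#' @slot k integer >= 2, number of modelled cell types.
#' @slot rssTrajectory non-increasing residual sum of squares per iteration.
#' @slot iterations integer, iterations run.
#' @slot converged logical, whether the RSS tolerance was met before the
#'   iteration cap.
#' @slot explainedVariance fraction of centered total sum of squares
#'   explained; `explainedVarianceUncentered` uses the uncentered baseline.
#' @slot explainedVarianceUncentered numeric.
#' @slot seed integer seed used for initialization.
#' @export
setClass("DeconvolutionResult",
  representation(M = "matrix", P = "matrix", k = "integer",
                 rssTrajectory = "numeric", iterations = "integer",
                 converged = "logical", explainedVariance = "numeric",
                 explainedVarianceUncentered = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@k < 2L) msg <- c(msg, "k must be >= 2")
    if (ncol(object@M) != object@k || nrow(object@P) != object@k)
      msg <- c(msg, "M / P dimensions inconsistent with k")
    if (any(object@M < -1e-12) || any(object@M > 1 + 1e-12))
      msg <- c(msg, "M entries must lie in [0, 1]")
    cs <- colSums(object@P)
    if (any(object@P < -1e-12) || any(abs(cs - 1) > 1e-8))
      msg <- c(msg, "P columns must be nonnegative and sum to 1")
    if (length(object@rssTrajectory) > 1 &&
        any(diff(object@rssTrajectory) > 1e-12 * max(object@rssTrajectory[1], 1)))
      msg <- c(msg, "rssTrajectory must be non-increasing")
    if (length(msg)) msg else TRUE
  })

#' StabilityReport: replicate-subsample stability over candidate k
#'
#' @slot table data.frame with one row per scanned k: `k`,
#'   `all_significant`, `mean_matched_correlation`, `min_matched_correlation`,
#'   `max_p_value`.
#' @slot pairCorrelations list (per k) of matched correlations for every
#'   replicate pair.
#' @slot chosenK integer, the selected number of cell types.
#' @export
setClass("StabilityReport",
  representation(table = "data.frame", pairCorrelations = "list",
                 chosenK = "integer"),
  validity = function(object) {
    if (!(object@chosenK %in% object@table$k))
      "chosenK must lie in the scanned range" else TRUE
  })

#' CellTypeAssignment: identities of estimated components
#'
#' @slot table data.frame with columns `component`, `class_label`,
#'   `correlation`, `runner_up`, `subtype` (NA unless epithelial subtypes
#'   were labelled).
#' @export
setClass("CellTypeAssignment",
  representation(table = "data.frame"),
  validity = function(object) {
    need <- c("component", "class_label", "correlation", "runner_up")
    if (!all(need %in% names(object@table)))
      "table must have component/class_label/correlation/runner_up" else TRUE
  })

#' Stage2Profiles: untransformed per-cell-type expression
#'
#' Per-gene nonnegative least-squares estimates of average expression of each
#' constituent cell type over a sample group. Components whose mean
#' proportion in the group is too low to identify are reported as `NA`.
#'
#' @slot values numeric matrix genes x k, nonnegative (or NA for
#'   unidentifiable components).
#' @slot groupId character identifier of the sample subset used.
#' @slot componentLabels character labels inherited from Stage 1.
#' @slot unidentifiable logical vector per component.
#' @export
setClass("Stage2Profiles",
  representation(values = "matrix", groupId = "character",
                 componentLabels = "character", unidentifiable = "logical"),
  validity = function(object) {
    v <- object@values[, !object@unidentifiable, drop = FALSE]
    if (any(v < 0, na.rm = TRUE)) "negative expression estimates" else TRUE
  })

#' SimulationTruth: ground truth of a simulated mixture study
#'
#' @slot trueProfiles genes x types matrix: clean type-mean profiles on the
#'   scale the mixtures were built on.
#' @slot trueProportions types x mixtures matrix; columns on the simplex.
#' @slot purityClass factor per mixture: high / impure / low / control.
#' @slot seed integer.
#' @export
setClass("SimulationTruth",
  representation(trueProfiles = "matrix", trueProportions = "matrix",
                 purityClass = "factor", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(abs(colSums(object@trueProportions) - 1) > 1e-9))
      msg <- c(msg, "proportion columns must sum to 1")
    if (ncol(object@trueProportions) != length(object@purityClass))
      msg <- c(msg, "one purity class per mixture required")
    if (length(msg)) msg else TRUE
  })

#' RecoveryReport: deconvolution accuracy against simulation truth
#'
#' @slot table data.frame per matched component: `component`, `truth`,
#'   `proportion_r2`, `profile_r2`.
#' @slot permutation integer mapping estimated components to truth columns.
#' @export
setClass("RecoveryReport",
  representation(table = "data.frame", permutation = "integer"),
  validity = function(object) {
    r2 <- c(object@table$proportion_r2, object@table$profile_r2)
    r2 <- r2[!is.na(r2)]
    if (any(r2 < 0 | r2 > 1 + 1e-12)) "R^2 values must lie in [0,1]" else TRUE
  })

#' ResponseModel: logistic model of therapy response on subtype proportions
#'
#' @slot coefficients named numeric: intercept plus one coefficient per
#'   predictor (Basal, HER2, Luminal proportions).
#' @slot fit the underlying `glm` object (logit link).
#' @slot separation logical; `TRUE` when quasi-complete separation was
#'   detected (coefficients unreliable; prediction falls back to a weakly
#'   ridge-penalized fit).
#' @slot ridgeCoefficients numeric; penalized coefficients used for
#'   prediction under separation.
#' @slot n integer, training samples.
#' @slot converged logical.
#' @export
setClass("ResponseModel",
  representation(coefficients = "numeric", fit = "ANY", separation = "logical",
                 ridgeCoefficients = "numeric", n = "integer",
                 converged = "logical"),
  validity = function(object) {
    if (length(object@coefficients) != 4L)
      "expected intercept + 3 predictor coefficients" else TRUE
  })
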