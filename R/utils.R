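## internal helpers

# validate a genes x samples expression matrix (counts or abundances)
.checkExpressionMatrix <- function(x, what = "expression matrix") {
  if (is(x, "SummarizedExperiment")) {
    if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
      stop("SummarizedExperiment input requires the SummarizedExperiment package")
    x <- SummarizedExperiment::assay(x)
  }
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene identifier in ", what)
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample identifier in ", what)
  if (any(!is.finite(x)))
    stop("non-finite values in ", what)
  if (any(x < 0))
    stop("negative values in ", what)
  x
}

# coerce TransformedMatrix | matrix -> matrix of transformed values
.transformedValues <- function(t, what = "transformed matrix") {
  if (is(t, "TransformedMatrix")) return(t@values)
  if (!is.matrix(t) || !is.numeric(t))
    stop(what, " must be a TransformedMatrix or numeric matrix")
  if (any(!is.finite(t)) || any(t < 0) || any(t >= 1))
    stop(what, " values must be finite and in [0, 1)")
  t
}

# deterministic derived seed, kept well below .Machine$integer.max
.deriveSeed <- function(seed, ...) {
  offs <- sum(c(...) * (7919L ^ seq_along(c(...))))
  as.integer((as.numeric(seed) + abs(offs)) %% 2147483587)
}

.setSeed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Pearson correlation that returns 0 (flagged via attribute) when either
# vector has zero variance
.safeCor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) {
    r <- 0
    attr(r, "zero_variance") <- TRUE
    return(r)
  }
  cor(x, y)
}
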