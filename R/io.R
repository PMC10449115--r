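#' Read an expression matrix
#'
#' Reads a genes x samples expression matrix from TSV/CSV (header row of
#' sample identifiers, first column of gene identifiers) or from a
#' MatrixMarket coordinate triplet with sidecar one-column gene and cell
#' identifier files (the usual single-cell convention). Duplicate gene or
#' sample identifiers are an error, never silently merged; negative or
#' non-numeric entries are rejected.
#'
#' @param path file path to the matrix (TSV, CSV or `.mtx`).
#' @param format one of `"tsv"`, `"csv"`, `"mtx"`. Defaults from the file
#'   extension.
#' @param genesFile,cellsFile sidecar identifier files, required for
#'   `format = "mtx"` (one identifier per line; genes index matrix rows).
#' @param transpose set `TRUE` when the file stores samples in rows. Never
#'   auto-detected.
#' @return numeric matrix, genes in rows, samples in columns.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeExpressionMatrix(matrix(1:6, 3, 2,
#'   dimnames = list(paste0("g", 1:3), c("s1", "s2"))), f)
#' readExpressionMatrix(f)
#' @export
readExpressionMatrix <- function(path, format = NULL, genesFile = NULL,
                                 cellsFile = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", mtx = "mtx", "tsv")
  }
  format <- match.arg(format, c("tsv", "csv", "mtx"))
  if (format == "mtx") {
    if (is.null(genesFile) || is.null(cellsFile))
      stop("mtx input requires genesFile and cellsFile")
    if (!file.exists(genesFile)) stop("file not found: ", genesFile)
    if (!file.exists(cellsFile)) stop("file not found: ", cellsFile)
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genesFile)
    cells <- readLines(cellsFile)
    genes <- genes[nzchar(genes)]
    cells <- cells[nzchar(cells)]
    if (length(genes) != nrow(m) || length(cells) != ncol(m))
      stop("dimension mismatch between triplet matrix (", nrow(m), " x ",
           ncol(m), ") and identifier files (", length(genes), " genes, ",
           length(cells), " cells)")
    dimnames(m) <- list(genes, cells)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- read.delim(path, sep = sep, check.names = FALSE,
                     stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) stop("duplicate gene identifier in ", path)
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric entries in ", path)
    rownames(m) <- ids
  }
  if (transpose) m <- t(m)
  .checkExpressionMatrix(m, paste0("matrix read from ", path))
}

#' Write an expression matrix to TSV/CSV
#'
#' @param x numeric matrix with gene rownames and sample colnames, or a
#'   [TransformedMatrix-class].
#' @param path output file path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  if (is(x, "TransformedMatrix")) x <- x@values
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = if (format == "csv") "," else "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain-text gene list (one symbol per line)
#'
#' @param path file path; blank lines and leading/trailing whitespace are
#'   dropped.
#' @return character vector of gene symbols.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}

#' Read per-sample annotations
#'
#' Reads a TSV with columns `sample_id`, and optionally `subtype_label`,
#' `response` and `group`; empty strings become `NA`.
#'
#' @param path annotation TSV path.
#' @return data.frame with the columns above.
#' @export
readSampleAnnotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!"sample_id" %in% names(df)) stop("annotation file lacks sample_id column")
  for (col in c("subtype_label", "response", "group"))
    if (!col %in% names(df)) df[[col]] <- NA
  df
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to the same value distribution: the per-rank
#' mean across columns, with ties receiving the mean of their ranks'
#' reference values (via [limma::normalizeQuantiles()]).
#'
#' @param x numeric genes x samples matrix (at least two samples).
#' @return matrix of the same shape; applying the function twice equals
#'   applying it once.
#' @examples
#' m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
#' rownames(m) <- paste0("g", 1:3)
#' quantileNormalize(m)  # both columns become (2.5, 3.5, 4.5)
#' @export
quantileNormalize <- function(x) {
  x <- .checkExpressionMatrix(x)
  if (ncol(x) < 2) stop("quantile normalization needs >= 2 samples")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Remove genes with low transformed expression
#'
#' Drops genes whose across-sample mean transformed expression is below
#' `minMean` (strictly; a gene at exactly the threshold is retained). Mirrors
#' the preprocessing rule "average < 0.01 removed".
#'
#' @param t a [TransformedMatrix-class] (or matrix of values in `[0,1)`).
#' @param minMean retention threshold on the across-sample mean
#'   (default 0.01).
#' @return object of the same type restricted to the retained genes, order
#'   preserved.
#' @export
filterLowExpression <- function(t, minMean = 0.01) {
  v <- .transformedValues(t)
  keep <- rowMeans(v) >= minMean
  if (!any(keep))
    stop("all genes fall below the mean-expression threshold ", minMean)
  if (is(t, "TransformedMatrix")) {
    sa <- if (t@perGene) t@scaleA[keep] else t@scaleA
    new("TransformedMatrix", values = v[keep, , drop = FALSE],
        scaleA = sa, perGene = t@perGene)
  } else v[keep, , drop = FALSE]
}
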