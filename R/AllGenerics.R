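#' Accessors for DeconvoMap classes
#'
#' `exprValues()` returns the numeric matrix held by a container;
#' `scaleA()` the transform scale parameter; `classLabels()` the per-profile
#' cell-type classes; `geneIds()` the gene identifiers; `sampleProportions()` and
#' `profilesMatrix()` the two factors of a deconvolution; `chosenK()` the
#' stability-selected number of cell types; `rssTrajectory()` the per-iteration
#' residual sum of squares; `assignmentTable()` the component-identity table.
#'
#' @param object an object of the matching DeconvoMap class.
#' @return the slot contents described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("scaleA", function(object) standardGeneric("scaleA"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("sampleProportions", function(object) standardGeneric("sampleProportions"))
#' @rdname accessors
#' @export
setGeneric("profilesMatrix", function(object) standardGeneric("profilesMatrix"))
#' @rdname accessors
#' @export
setGeneric("chosenK", function(object) standardGeneric("chosenK"))
#' @rdname accessors
#' @export
setGeneric("rssTrajectory", function(object) standardGeneric("rssTrajectory"))
#' @rdname accessors
#' @export
setGeneric("assignmentTable", function(object) standardGeneric("assignmentTable"))

#' @rdname accessors
#' @export
setMethod("exprValues", "TransformedMatrix", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("exprValues", "ReferenceSet", function(object) object@profiles@values)
#' @rdname accessors
#' @export
setMethod("exprValues", "Stage2Profiles", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("scaleA", "TransformedMatrix", function(object) object@scaleA)
#' @rdname accessors
#' @export
setMethod("classLabels", "ReferenceSet", function(object) object@classLabels)
#' @rdname accessors
#' @export
setMethod("geneIds", "InformativeGeneSet", function(object) object@geneIds)
#' @rdname accessors
#' @export
setMethod("geneIds", "TransformedMatrix", function(object) rownames(object@values))
#' @rdname accessors
#' @export
setMethod("sampleProportions", "DeconvolutionResult", function(object) object@P)
#' @rdname accessors
#' @export
setMethod("profilesMatrix", "DeconvolutionResult", function(object) object@M)
#' @rdname accessors
#' @export
setMethod("chosenK", "StabilityReport", function(object) object@chosenK)
#' @rdname accessors
#' @export
setMethod("rssTrajectory", "DeconvolutionResult",
          function(object) object@rssTrajectory)
#' @rdname accessors
#' @export
setMethod("assignmentTable", "CellTypeAssignment", function(object) object@table)

setMethod("show", "TransformedMatrix", function(object) {
  v <- object@values
  cat("TransformedMatrix:", nrow(v), "genes x", ncol(v), "samples\n")
  if (object@perGene) cat("  per-gene scale a (", length(object@scaleA),
                          " values)\n", sep = "")
  else cat("  scale a =", format(object@scaleA, digits = 6), "\n")
  cat("  value range [", format(min(v), digits = 4), ", ",
      format(max(v), digits = 4), "]\n", sep = "")
})

setMethod("show", "ReferenceSet", function(object) {
  tab <- table(object@classLabels)
  cat("ReferenceSet (", object@provenance, "): ",
      nrow(object@profiles@values), " genes, ",
      ncol(object@profiles@values), " profiles\n", sep = "")
  cat("  classes:", paste0(names(tab), " (n=", tab, ")", collapse = ", "), "\n")
})

setMethod("show", "InformativeGeneSet", function(object) {
  cat("InformativeGeneSet: n =", object@nTotal, "genes\n")
  src <- table(object@source$source)
  cat("  sources:", paste0(names(src), " (", src, ")", collapse = ", "), "\n")
})

setMethod("show", "DeconvolutionResult", function(object) {
  cat("DeconvolutionResult: k =", object@k, "cell types,",
      ncol(object@P), "samples,", nrow(object@M), "genes\n")
  cat("  iterations:", object@iterations,
      if (object@converged) "(converged)" else "(iteration cap reached)", "\n")
  cat("  final RSS:", format(tail(object@rssTrajectory, 1), digits = 6), "\n")
  cat("  explained variance (centered):",
      format(object@explainedVariance, digits = 4), "; (uncentered):",
      format(object@explainedVarianceUncentered, digits = 4), "\n")
})

setMethod("show", "StabilityReport", function(object) {
  cat("StabilityReport over k =", paste(range(object@table$k), collapse = ".."),
      "\n  chosen k =", object@chosenK, "\n")
  print(object@table, row.names = FALSE)
})

setMethod("show", "CellTypeAssignment", function(object) {
  cat("CellTypeAssignment:\n")
  print(object@table, row.names = FALSE)
})

setMethod("show", "Stage2Profiles", function(object) {
  cat("Stage2Profiles (group ", object@groupId, "): ", nrow(object@values),
      " genes x ", ncol(object@values), " components\n", sep = "")
  if (any(object@unidentifiable))
    cat("  unidentifiable components:",
        paste(object@componentLabels[object@unidentifiable], collapse = ", "),
        "\n")
})

setMethod("show", "ResponseModel", function(object) {
  cat("ResponseModel (logit link), n =", object@n, "\n")
  print(object@coefficients)
  if (object@separation)
    cat("  WARNING: separation detected; prediction uses ridge fallback\n")
})
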