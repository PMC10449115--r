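## Cancer cell state map: project the three cancer-epithelial proportions
## (Basal, HER2, Luminal) onto the 2-simplex, classify by nearest vertex.
## Ternary convention: Basal = left vertex (0,0), HER2 = right (1,0),
## Luminal = top (1/2, sqrt(3)/2); the triangle has unit side.

.CANCER_SUBTYPES <- c("Basal", "HER2", "Luminal")

#' Select samples that the three cancer profiles model well
#'
#' Retains samples whose combined epithelial proportion exceeds
#' `minEpithelial` and whose combined Basal + HER2 + Luminal proportion
#' exceeds `minCancer` (both strictly).
#'
#' @param p k x samples proportion matrix (or
#'   [DeconvolutionResult-class]).
#' @param epithelialComponents names/indices of all epithelial components.
#' @param cancerComponents names/indices of the Basal, HER2 and Luminal
#'   components (in that order).
#' @param minEpithelial epithelial threshold (default 0.7).
#' @param minCancer cancer-trio threshold (default 0.1).
#' @return character vector of retained sample ids.
#' @export
filterMappableSamples <- function(p, epithelialComponents, cancerComponents,
                                  minEpithelial = 0.7, minCancer = 0.1) {
  if (is(p, "DeconvolutionResult")) p <- p@P
  if (length(cancerComponents) != 3)
    stop("cancerComponents must identify the Basal, HER2 and Luminal ",
         "components")
  epi <- colSums(p[epithelialComponents, , drop = FALSE])
  trio <- colSums(p[cancerComponents, , drop = FALSE])
  colnames(p)[epi > minEpithelial & trio > minCancer]
}

#' Map samples onto the cancer cell state simplex
#'
#' Normalizes the (Basal, HER2, Luminal) proportion trio of each sample to
#' sum to one and computes Cartesian coordinates for ternary rendering via
#' `x = her2 + luminal/2`, `y = sqrt(3)/2 * luminal`. Samples should already
#' have passed [filterMappableSamples()]; a zero trio is an error.
#'
#' @param p k x samples proportion matrix (or
#'   [DeconvolutionResult-class]).
#' @param cancerComponents names/indices of the Basal, HER2, Luminal
#'   components, in that order.
#' @param samples optional sample subset (e.g. the output of
#'   [filterMappableSamples()]).
#' @return data.frame with columns `sample_id`, `basal`, `her2`, `luminal`,
#'   `x`, `y`, `vertex_class`, `tie`.
#' @examples
#' p <- matrix(c(0.1, 0.2, 0.3, 0.4), 4, 1,
#'             dimnames = list(c("b", "h", "l", "other"), "s1"))
#' toSimplexCoordinates(p, c("b", "h", "l"))  # coords (1/6, 1/3, 1/2)
#' @export
toSimplexCoordinates <- function(p, cancerComponents, samples = NULL) {
  if (is(p, "DeconvolutionResult")) p <- p@P
  if (length(cancerComponents) != 3)
    stop("cancerComponents must have exactly 3 entries (Basal, HER2, Luminal)")
  if (!is.null(samples)) p <- p[, samples, drop = FALSE]
  trio <- p[cancerComponents, , drop = FALSE]
  s <- colSums(trio)
  stopifnot("zero cancer-trio proportion; filter samples first" = all(s > 0))
  trio <- sweep(trio, 2, s, "/")
  cls <- classifyByVertex(t(trio))
  data.frame(
    sample_id = colnames(p),
    basal = trio[1, ], her2 = trio[2, ], luminal = trio[3, ],
    x = trio[2, ] + trio[3, ] / 2,
    y = sqrt(3) / 2 * trio[3, ],
    vertex_class = cls$class, tie = cls$tie,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify simplex points by their dominant vertex
#'
#' Label = argmax of the (basal, her2, luminal) coordinates; exact ties are
#' broken in the fixed order Basal > HER2 > Luminal and flagged.
#'
#' @param coords numeric matrix/data.frame with columns (basal, her2,
#'   luminal), one row per sample, or a single length-3 vector.
#' @return list with `class` (character) and `tie` (logical).
#' @export
classifyByVertex <- function(coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3)
  idx <- apply(coords, 1, which.max)  # which.max takes the first maximum
  tie <- apply(coords, 1, function(r) sum(r == max(r)) > 1)
  list(class = .CANCER_SUBTYPES[idx], tie = unname(tie))
}

#' Cross-tabulate two classifications
#'
#' @param labelsA,labelsB character vectors over the same samples (named
#'   vectors are aligned by name).
#' @param labelOrder fixed ordering for rows/columns; defaults to the
#'   canonical subtype order followed by any extra labels alphabetically.
#' @return list with `table` (contingency) and `agreement` (fraction equal).
#' @export
compareClassifications <- function(labelsA, labelsB, labelOrder = NULL) {
  if (!is.null(names(labelsA)) && !is.null(names(labelsB))) {
    if (!setequal(names(labelsA), names(labelsB)))
      stop("mismatched sample sets")
    labelsB <- labelsB[names(labelsA)]
  } else if (length(labelsA) != length(labelsB))
    stop("mismatched sample sets")
  if (is.null(labelOrder)) {
    known <- c(.CANCER_SUBTYPES, "Normal")
    extra <- sort(setdiff(unique(c(labelsA, labelsB)), known))
    labelOrder <- c(intersect(known, c(labelsA, labelsB)), extra)
  }
  fa <- factor(labelsA, levels = labelOrder)
  fb <- factor(labelsB, levels = labelOrder)
  list(table = table(A = fa, B = fb),
       agreement = mean(labelsA == labelsB))
}

#' Correlate two component proportions across samples
#'
#' Pearson correlation with a two-sided p-value, e.g. macrophage proportion
#' against the Basal epithelial proportion across a cohort.
#'
#' @param p k x samples proportion matrix (or
#'   [DeconvolutionResult-class]).
#' @param componentX,componentY component names or indices.
#' @return list with `r` and `p_value`.
#' @export
correlateProportions <- function(p, componentX, componentY) {
  if (is(p, "DeconvolutionResult")) p <- p@P
  x <- p[componentX, ]; y <- p[componentY, ]
  if (length(x) < 3) stop("need at least 3 samples")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in a component; correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Plot the cancer cell state map
#'
#' Renders the unit-side ternary triangle (Basal left, HER2 right, Luminal
#' top) with one point per sample, colored by vertex class. Requires
#' ggplot2.
#'
#' @param map data.frame from [toSimplexCoordinates()].
#' @return a ggplot object.
#' @export
plotStateMap <- function(map) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotStateMap requires ggplot2")
  tri <- data.frame(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  vertices <- data.frame(x = c(0, 1, 0.5), y = c(0, 0, sqrt(3) / 2),
                         label = .CANCER_SUBTYPES)
  ggplot2::ggplot(map, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = tri, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$vertex_class),
                        alpha = 0.7) +
    ggplot2::geom_text(data = vertices, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       vjust = c(1.5, 1.5, -0.8)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(color = "vertex class")
}
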