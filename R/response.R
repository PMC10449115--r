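#' Fit a logistic model of therapy response on subtype proportions
#'
#' Binomial GLM with logit link (iteratively reweighted least squares via
#' [stats::glm()]) of a binary response on the three cancer-subtype
#' proportions (Basal, HER2, Luminal). Quasi-complete separation is detected
#' (divergent coefficients or fitted probabilities at the boundary) and
#' flagged; in that case the reported maximum-likelihood coefficients are
#' unreliable, and prediction falls back to a weakly ridge-penalized fit.
#'
#' @param p3 samples x 3 numeric matrix or data.frame of proportions, with
#'   columns in the order Basal, HER2, Luminal.
#' @param response binary vector (0/1 or logical), one value per sample,
#'   with both classes present.
#' @param ridgeLambda penalty of the separation fallback (default 1e-3).
#' @return a [ResponseModel-class].
#' @export
fitResponseGLM <- function(p3, response, ridgeLambda = 1e-3) {
  p3 <- as.matrix(p3)
  if (ncol(p3) != 3) stop("p3 must have exactly 3 predictor columns")
  if (is.null(colnames(p3))) colnames(p3) <- c("Basal", "HER2", "Luminal")
  y <- as.numeric(response)
  if (!all(y %in% c(0, 1))) stop("response must be binary")
  if (length(unique(y)) < 2) stop("response has a single class")
  if (any(apply(p3, 2, sd) == 0)) stop("constant predictor column")
  if (nrow(p3) != length(y)) stop("response length mismatch")

  df <- data.frame(y = y, p3)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (any(abs(coef(fit)) > 15)) sep <- TRUE

  # weak ridge fallback: penalized log-likelihood maximized by BFGS
  X <- cbind(1, p3)
  negll <- function(b) {
    eta <- drop(X %*% b)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      ridgeLambda * sum(b[-1]^2) / 2
  }
  ridge <- optim(rep(0, 4), negll, method = "BFGS",
                 control = list(maxit = 500))
  rc <- setNames(ridge$par, c("(Intercept)", colnames(p3)))

  new("ResponseModel", coefficients = coef(fit), fit = fit,
      separation = sep, ridgeCoefficients = rc,
      n = as.integer(length(y)), converged = fit$converged)
}

#' Predict response probabilities
#'
#' @param model a [ResponseModel-class].
#' @param p3 samples x 3 proportion matrix with the training column order.
#' @return numeric vector of response probabilities.
#' @export
predictResponse <- function(model, p3) {
  stopifnot(is(model, "ResponseModel"))
  p3 <- as.matrix(p3)
  b <- if (model@separation) model@ridgeCoefficients else model@coefficients
  plogis(drop(cbind(1, p3) %*% b))
}

#' Area under the ROC curve (rank formulation)
#'
#' Mann-Whitney AUC with midranks for ties: the probability that a random
#' positive outscores a random negative, plus half the tie probability.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1 or logical), both classes present.
#' @return AUC in `[0, 1]`.
#' @examples
#' rocAUC(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
rocAUC <- function(scores, labels) {
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop("labels must be binary")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Dichotomize RECIST response labels
#'
#' @param recist character vector of RECIST categories (CR/PR/SD/PD).
#' @param scheme `"CR"` (complete response vs all else) or `"CRPR"`
#'   (complete or partial response vs all else).
#' @return binary integer vector.
#' @export
dichotomizeResponse <- function(recist, scheme = c("CRPR", "CR")) {
  scheme <- match.arg(scheme)
  recist <- toupper(as.character(recist))
  bad <- setdiff(unique(recist), c("CR", "PR", "SD", "PD"))
  if (length(bad)) stop("unknown RECIST labels: ", paste(bad, collapse = ", "))
  pos <- if (scheme == "CR") "CR" else c("CR", "PR")
  as.integer(recist %in% pos)
}
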