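#' @include AllClasses.R
NULL

#' Analytic shrinkage intensity toward a scaled identity
#'
#' Ledoit-Wolf-type estimator of the optimal intensity gamma for shrinking
#' a sample covariance toward nu*I, where nu is the mean of the sample
#' covariance diagonal (the average eigenvalue). Computed from the
#' variances of the entry-wise cross products (Schafer-Strimmer form) and
#' clipped to [0, 1]. Large, well-conditioned samples give gamma near 0;
#' tiny samples in high dimension give gamma near 1.
#'
#' @param X numeric matrix [n x F] of samples (rows); n >= 2. Columns are
#'   centered internally.
#' @return Shrinkage coefficient in [0, 1].
#' @export
shrinkageGamma <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); F <- ncol(X)
  if (n < 2L) stop("need at least 2 samples to estimate shrinkage")
  Xc <- sweep(X, 2L, colMeans(X))
  S <- crossprod(Xc) / (n - 1)
  nu <- mean(diag(S))
  Wbar <- crossprod(Xc) / n
  A <- crossprod(Xc^2) / n
  varS <- n^2 / (n - 1)^3 * (A - Wbar^2)
  num <- sum(varS)
  den <- sum(S^2) - sum(diag(S)^2) + sum((diag(S) - nu)^2)
  if (den <= .Machine$double.eps) return(1)
  min(1, max(0, num / den))
}

#' Fit shrinkage-regularized linear discriminant analysis
#'
#' Binary LDA with the pooled within-class covariance shrunk toward nu*I
#' (nu = trace/F): \eqn{\tilde\Sigma = (1-\gamma) S + \gamma \nu I},
#' \eqn{w = \tilde\Sigma^{-1}(\mu_2 - \mu_1)}, with the decision boundary
#' at the midpoint of the projected class means. Gamma is selected
#' analytically by [shrinkageGamma()] unless given. Deterministic; assumes
#' balanced class priors.
#'
#' @param X numeric feature matrix [n x F].
#' @param labels class identifiers in {1, 2}, both present.
#' @param gamma "auto" (default) or a fixed value in [0, 1]. With gamma = 0
#'   and a singular pooled covariance the fit is an error.
#' @return An \linkS4class{LDAModel}.
#' @export
fitSLDA <- function(X, labels, gamma = "auto") {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  stopifnot(nrow(X) == length(labels))
  if (!all(sort(unique(labels)) == c(1L, 2L)))
    stop("both classes (1 and 2) must be present")
  i1 <- labels == 1L; i2 <- labels == 2L
  mu1 <- colMeans(X[i1, , drop = FALSE])
  mu2 <- colMeans(X[i2, , drop = FALSE])
  Xc <- rbind(sweep(X[i1, , drop = FALSE], 2L, mu1),
              sweep(X[i2, , drop = FALSE], 2L, mu2))
  n <- nrow(Xc); F <- ncol(Xc)
  S <- crossprod(Xc) / (n - 2)
  g <- if (identical(gamma, "auto")) shrinkageGamma(Xc) else {
    g0 <- as.numeric(gamma)
    if (g0 < 0 || g0 > 1) stop("gamma must lie in [0, 1]")
    g0
  }
  nu <- mean(diag(S))
  St <- (1 - g) * S + g * nu * diag(F)
  w <- tryCatch(solve(St, mu2 - mu1), error = function(err)
    stop("shrunk covariance is singular (gamma = ", signif(g, 3),
         "); increase gamma or reduce the feature count"))
  b <- -sum(w * (mu1 + mu2)) / 2
  new("LDAModel", w = as.numeric(w), b = b, gamma = g,
      classOrder = c(1L, 2L))
}

#' Predict class labels with a fitted LDA model
#'
#' Decision score is \code{w . x + b}; positive scores map to the second
#' class in \code{classOrder}, non-positive scores (including exact
#' boundary hits) to the first — the tie-break is deterministic.
#'
#' @param object an \linkS4class{LDAModel}.
#' @param newdata feature matrix [n x F] with F matching the fit.
#' @param ... ignored.
#' @return Integer vector of predicted labels.
#' @export
setMethod("predict", "LDAModel", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@w))
    stop("feature width ", ncol(newdata), " does not match the model (",
         length(object@w), ")")
  score <- as.numeric(newdata %*% object@w) + object@b
  ifelse(score > 0, object@classOrder[2], object@classOrder[1])
})

#' Classification accuracy
#'
#' @param pred predicted labels.
#' @param truth true labels, same length, non-empty.
#' @return Fraction of agreements in [0, 1].
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) == 0L) stop("empty input")
  if (length(pred) != length(truth)) stop("length mismatch")
  mean(pred == truth)
}
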