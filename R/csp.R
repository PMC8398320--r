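#' @include AllClasses.R
NULL

#' Trial-concatenated class covariance
#'
#' Mean-centers every trial of the requested class per channel, concatenates
#' the trials along time, and returns the sample covariance of the resulting
#' [Ttot x C] signal. This is the per-class covariance entering the CSP
#' generalized eigenproblem.
#'
#' @param e an \linkS4class{Epochs} object.
#' @param label class identifier (1 or 2).
#' @return Symmetric positive semi-definite [C x C] matrix.
#' @export
classCovariance <- function(e, label) {
  stopifnot(is(e, "Epochs"))
  idx <- which(e@labels == label)
  if (!length(idx)) stop("no trials with label ", label)
  cp <- classCrossprod(e, label)
  cp$S / (cp$n - 1)
}

# accumulated centered cross-products: reusable so that pooled-subject
# covariances can be combined without re-touching the raw data
classCrossprod <- function(e, label) {
  idx <- which(e@labels == label)
  C <- nChannels(e)
  S <- matrix(0, C, C)
  n <- 0L
  for (tr in idx) {
    X <- e@data[, , tr]
    X <- sweep(X, 2L, colMeans(X))
    S <- S + crossprod(X)
    n <- n + nrow(X)
  }
  list(S = S, n = n)
}

#' Fit common spatial patterns
#'
#' Solves the generalized eigenproblem \eqn{\Sigma_1 w = \lambda (\Sigma_1 +
#' \Sigma_2) w} on the two trial-concatenated class covariances. The
#' projection matrix W satisfies \eqn{W^T (\Sigma_1+\Sigma_2) W = I} and
#' \eqn{W^T \Sigma_1 W = diag(d)} with d sorted descending in [0, 1], so the
#' first filter maximizes class-1 band power and the last maximizes
#' class-2 band power.
#'
#' @param e an \linkS4class{Epochs} object with both classes present,
#'   already band-pass filtered.
#' @param ridge optional ridge added to \eqn{\Sigma_1+\Sigma_2} as
#'   \code{ridge * trace / C * I} when the composite covariance is
#'   rank-deficient; 0 (off) by default, in which case rank deficiency is an
#'   error.
#' @return A \linkS4class{CSPModel}.
#' @references The joint-diagonalization construction is standard for
#'   oscillatory EEG decoding; see the package vignette for the derivation.
#' @export
fitCSP <- function(e, ridge = 0) {
  stopifnot(is(e, "Epochs"))
  if (length(unique(e@labels)) != 2L)
    stop("both classes must be present to fit CSP")
  fitCSPFromCov(classCovariance(e, 1L), classCovariance(e, 2L),
                channels = e@channels, ridge = ridge)
}

# core solver on explicit covariances (shared by pooled-subject training)
fitCSPFromCov <- function(S1, S2, channels = character(0), ridge = 0) {
  C <- nrow(S1)
  Sc <- S1 + S2
  ec <- eigen(Sc, symmetric = TRUE)
  tol <- C * max(ec$values) * .Machine$double.eps * 100
  if (min(ec$values) < tol) {
    if (ridge > 0) {
      Sc <- Sc + diag(ridge * sum(diag(Sc)) / C, C)
      ec <- eigen(Sc, symmetric = TRUE)
    } else {
      stop("composite covariance is rank-deficient; consider a ridge ",
           "(fitCSP(..., ridge = 1e-9)) or more/longer trials")
    }
  }
  P <- ec$vectors %*% diag(1 / sqrt(ec$values), C)   # whitener: P' Sc P = I
  ew <- eigen(crossprod(P, S1 %*% P), symmetric = TRUE)  # descending
  W <- P %*% ew$vectors
  d <- pmin(pmax(ew$values, 0), 1)
  # sign convention: largest-magnitude entry of each filter positive
  for (j in seq_len(C)) {
    k <- which.max(abs(W[, j]))
    if (W[k, j] < 0) W[, j] <- -W[, j]
  }
  rownames(W) <- channels
  A <- t(solve(W))                                  # activation patterns
  rownames(A) <- channels
  new("CSPModel", W = W, d = d, patterns = A,
      channels = as.character(channels), classOrder = c(1L, 2L))
}

#' Select the outer CSP filter pairs
#'
#' Keeps the first m columns (maximal class-1 variance) and the last m
#' columns (maximal class-2 variance) of the projection matrix, in that
#' order — e.g. m = 2 gives the 4 filters used for subject-specific
#' decoding, m = 3 the 6 filters used for subject-independent decoding.
#'
#' @param model a \linkS4class{CSPModel}.
#' @param m number of filter pairs; requires \code{2 * m <= C}.
#' @return A \linkS4class{SpatialFilterSet} with 2m filters.
#' @export
selectFilters <- function(model, m) {
  stopifnot(is(model, "CSPModel"))
  C <- ncol(model@W)
  m <- as.integer(m)
  if (2L * m > C) stop("2m = ", 2 * m, " exceeds channel count ", C)
  cols <- c(seq_len(m), C - m + seq_len(m))
  new("SpatialFilterSet", filters = model@W[, cols, drop = FALSE], m = m,
      channels = model@channels)
}

#' Log-variance CSP features
#'
#' Projects every trial onto the selected spatial filters and returns the
#' log of the sum-normalized per-filter variance — the variance of a
#' band-pass filtered signal is its band power, so these features score
#' event-related desynchronization. Features are invariant to per-trial
#' amplitude scaling.
#'
#' @param fs a \linkS4class{SpatialFilterSet}.
#' @param e an \linkS4class{Epochs} object on the same montage.
#' @return Numeric matrix [N trials x 2m features].
#' @export
cspFeatures <- function(fs, e) {
  stopifnot(is(fs, "SpatialFilterSet"), is(e, "Epochs"))
  if (nrow(fs@filters) != nChannels(e))
    stop("filter channel count does not match the epochs")
  N <- nTrials(e)
  out <- matrix(0, N, ncol(fs@filters))
  for (tr in seq_len(N)) {
    X <- e@data[, , tr]
    X <- sweep(X, 2L, colMeans(X))
    Z <- X %*% fs@filters
    v <- apply(Z, 2L, stats::var)
    tot <- sum(v)
    if (tot <= 0) stop("trial ", tr, " has zero variance under the filters")
    out[tr, ] <- log(v / tot)
  }
  out
}

#' Export spatial filter weights on a montage
#'
#' Returns per-filter channel weights as a table for topographic
#' inspection, zero-padded for montage channels the filters were not
#' trained on.
#'
#' @param x a \linkS4class{CSPModel} or \linkS4class{SpatialFilterSet}.
#' @param montage optional full channel list to pad to; defaults to the
#'   channels the filters were fitted on.
#' @param what "filters" (projection columns) or "patterns" (activation
#'   patterns; CSPModel only).
#' @return data.frame with a \code{channel} column and one numeric column
#'   per filter.
#' @export
exportPatterns <- function(x, montage = NULL, what = c("filters", "patterns")) {
  what <- match.arg(what)
  if (is(x, "CSPModel")) {
    M <- if (what == "patterns") x@patterns else x@W
    chans <- x@channels
  } else if (is(x, "SpatialFilterSet")) {
    if (what == "patterns") stop("patterns are only stored on a CSPModel")
    M <- x@filters
    chans <- x@channels
  } else stop("unsupported object")
  if (!length(chans)) chans <- paste0("ch", seq_len(nrow(M)))
  if (is.null(montage)) montage <- chans
  out <- matrix(0, length(montage), ncol(M),
                dimnames = list(NULL, paste0(substr(what, 1, 6), seq_len(ncol(M)))))
  hit <- match(chans, montage)
  if (anyNA(hit)) stop("montage lacks fitted channels: ",
                       paste(chans[is.na(hit)], collapse = ", "))
  out[hit, ] <- M
  data.frame(channel = montage, out, stringsAsFactors = FALSE)
}
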