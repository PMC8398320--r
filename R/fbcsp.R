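#' @include csp.R
NULL

#' Mutual information between a feature and the class label
#'
#' Plug-in discrete mutual information in bits after equal-frequency
#' (rank-based; tied values share a bin) discretization of the feature
#' into \code{bins} bins (default \code{ceiling(sqrt(N))}, capped at 16). A constant feature carries 0
#' bits; a feature that separates two balanced classes perfectly carries
#' 1 bit.
#'
#' @param f numeric feature vector.
#' @param labels class identifiers, same length.
#' @param bins number of discretization bins; NULL for the default rule.
#' @return Estimated mutual information I(feature; class) in bits, >= 0.
#' @export
mutualInformation <- function(f, labels, bins = NULL) {
  n <- length(f)
  stopifnot(n == length(labels), n >= 2L)
  if (length(unique(f)) == 1L) return(0)
  if (is.null(bins)) bins <- min(16L, ceiling(sqrt(n)))
  # equal-frequency binning via average ranks; ties always share a bin
  fb <- ceiling(rank(f, ties.method = "average") / (n / bins))
  tab <- table(fb, labels)
  p <- tab / n
  pf <- rowSums(p); pc <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(pf, pc)[nz]))
}

# complement feature index under the FBCSP pair rule: filters within a band
# are mirrored end-to-end, so position j pairs with 2m+1-j in its band
pairComplement <- function(idx, perBand = 4L) {
  band <- (idx - 1L) %/% perBand
  pos <- (idx - 1L) %% perBand + 1L
  band * perBand + (perBand + 1L - pos)
}

#' Mutual-information best-individual-feature selection (MIBIFS)
#'
#' Ranks the candidate features by individual mutual information with the
#' class label (descending, ties broken by ascending index) and walks down
#' the ranking: each feature not already covered claims its CSP pair — the
#' mirrored filter from the opposite end of its band's filter set — until
#' \code{kPairs} pairs are selected. The result (2 x kPairs feature
#' indices) is returned deduplicated in ascending order; selecting all
#' F/2 pairs returns every feature.
#'
#' @param features numeric matrix [N trials x F features]; F must be a
#'   multiple of 4 (two filter pairs per band).
#' @param labels class identifiers of the N trials.
#' @param kPairs number of best feature pairs to keep; at most F/2.
#' @param bins discretization rule passed to [mutualInformation()].
#' @return Integer vector of selected feature indices.
#' @export
mibifsSelect <- function(features, labels, kPairs, bins = NULL) {
  F <- ncol(features)
  if (F %% 4L != 0L)
    stop("feature count must be a multiple of 4 (two pairs per band)")
  kPairs <- as.integer(kPairs)
  if (kPairs < 1L || kPairs > F %/% 2L)
    stop("kPairs must be between 1 and F/2 = ", F %/% 2L)
  mi <- vapply(seq_len(F), function(j)
    mutualInformation(features[, j], labels, bins = bins), numeric(1))
  ord <- order(-mi, seq_len(F))
  covered <- logical(F)
  taken <- 0L
  for (j in ord) {
    if (covered[j]) next
    covered[c(j, pairComplement(j))] <- TRUE
    taken <- taken + 1L
    if (taken == kPairs) break
  }
  which(covered)
}

# per-band feature matrix for (already fitted) filter sets; shared by
# training and prediction so train/test go through identical code
fbcspFeatureMatrix <- function(bands, filterSets, e, window = NULL) {
  feats <- vector("list", length(bands))
  for (b in seq_along(bands)) {
    eb <- bandpass(e, bands[[b]])
    if (!is.null(window)) eb <- cropEpochs(eb, window[1], window[2])
    feats[[b]] <- cspFeatures(filterSets[[b]], eb)
  }
  do.call(cbind, feats)
}

#' Fit multi-resolution filter-bank CSP
#'
#' For each band of the 15-band filter bank: band-pass filter the broadband
#' epochs, fit CSP, keep the outer two filter pairs, and compute the
#' log-variance features. The 60 concatenated candidate features are then
#' pruned by [mibifsSelect()].
#'
#' @param e broadband (unfiltered) \linkS4class{Epochs}.
#' @param kPairs number of best feature pairs for MIBIFS (6, 10 or 20 in
#'   typical use).
#' @param bands filter bank; defaults to [makeFilterBank()].
#' @param window optional analysis window \code{c(start, stop)} in seconds
#'   applied after filtering.
#' @param bins mutual-information discretization rule.
#' @return An \linkS4class{FBCSPModel}.
#' @export
fitFBCSP <- function(e, kPairs, bands = makeFilterBank(), window = NULL,
                     bins = NULL) {
  stopifnot(is(e, "Epochs"))
  filterSets <- vector("list", length(bands))
  feats <- vector("list", length(bands))
  for (b in seq_along(bands)) {
    eb <- bandpass(e, bands[[b]])
    if (!is.null(window)) eb <- cropEpochs(eb, window[1], window[2])
    csp <- fitCSP(eb)
    filterSets[[b]] <- selectFilters(csp, 2L)
    feats[[b]] <- cspFeatures(filterSets[[b]], eb)
  }
  X <- do.call(cbind, feats)
  mi <- vapply(seq_len(ncol(X)), function(j)
    mutualInformation(X[, j], e@labels, bins = bins), numeric(1))
  sel <- mibifsSelect(X, e@labels, kPairs, bins = bins)
  new("FBCSPModel", bands = bands, filters = filterSets, selected = sel,
      kPairs = as.integer(kPairs), mi = mi)
}

#' Selected filter-bank CSP features for new epochs
#'
#' @param model an \linkS4class{FBCSPModel}.
#' @param e broadband \linkS4class{Epochs} on the fitted montage.
#' @param window optional analysis window applied after filtering, as in
#'   [fitFBCSP()].
#' @return Numeric matrix [N x length(selected)] of MIBIFS-selected
#'   features.
#' @export
fbcspFeatures <- function(model, e, window = NULL) {
  stopifnot(is(model, "FBCSPModel"))
  X <- fbcspFeatureMatrix(model@bands, model@filters, e, window)
  X[, model@selected, drop = FALSE]
}
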