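#' @include AllClasses.R
NULL

#' Chance-level confidence limits for classification accuracy
#'
#' Adjusted confidence interval around the expected chance level p0 for a
#' classifier scored on n trials:
#' \deqn{p_0 \pm z_{1-\alpha/2} \sqrt{p_0 (1-p_0) / (n + 4)}}
#' For balanced binary classification p0 = 0.5; with n = 100 and alpha =
#' 0.05 the limits are 0.4039 and 0.5961. The upper limit is the selective
#' pooling threshold: accuracies at or below it are statistically
#' indistinguishable from random guessing.
#'
#' @param p0 expected chance level, in (0, 1); 0.5 for balanced binary
#'   classification.
#' @param n number of test trials, >= 1.
#' @param alpha significance level, in (0, 1).
#' @return Named numeric vector \code{c(lower, upper)}.
#' @examples
#' chanceLimits(0.5, 100, 0.05)
#' @export
chanceLimits <- function(p0 = 0.5, n, alpha = 0.05) {
  if (!(p0 > 0 && p0 < 1)) stop("p0 must lie in (0, 1)")
  if (n < 1) stop("n must be >= 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  half <- stats::qnorm(1 - alpha / 2) * sqrt(p0 * (1 - p0) / (n + 4))
  c(lower = p0 - half, upper = p0 + half)
}

#' Table of pooling thresholds over trial counts and significance levels
#'
#' @param ns trial counts (rows).
#' @param alphas significance levels (columns).
#' @param p0 expected chance level.
#' @return Numeric matrix of upper chance limits, dimnames n x alpha.
#' @examples
#' chanceThresholdTable()
#' @export
chanceThresholdTable <- function(ns = c(50, 100, 150, 200),
                                 alphas = c(0.05, 0.01, 0.005, 0.001),
                                 p0 = 0.5) {
  out <- outer(ns, alphas, Vectorize(function(n, a)
    chanceLimits(p0, n, a)[["upper"]]))
  dimnames(out) <- list(n = ns, alpha = alphas)
  out
}

#' Build the selective subject pool
#'
#' Members are the subjects whose subject-specific accuracy strictly
#' exceeds the upper chance limit for their test-trial count at the given
#' significance level. Smaller alpha means a higher threshold and a pool
#' that can only shrink.
#'
#' @param records data.frame with columns \code{subject_id},
#'   \code{ss_accuracy} and \code{n_test_trials} (as returned by
#'   [subjectSpecificEval()]); all rows must share \code{n_test_trials}.
#' @param alpha significance level of the threshold.
#' @return A \linkS4class{SubjectPool}; members ordered by id. An empty
#'   pool is returned with a warning.
#' @export
buildPool <- function(records, alpha = 0.05) {
  need <- c("subject_id", "ss_accuracy", "n_test_trials")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  n <- unique(records$n_test_trials)
  if (length(n) != 1L)
    stop("records have heterogeneous test-trial counts; threshold undefined")
  thr <- chanceLimits(0.5, n, alpha)[["upper"]]
  members <- sort(records$subject_id[records$ss_accuracy > thr])
  if (!length(members))
    warning("no subject exceeds the chance threshold ", signif(thr, 4),
            "; pool is empty")
  new("SubjectPool", memberIds = as.character(members), threshold = thr,
      alpha = alpha, n = as.integer(n))
}

#' Paired Wilcoxon signed-rank comparison of per-subject accuracies
#'
#' Two-sided signed-rank test on the paired differences; zero differences
#' are dropped (Wilcoxon convention) and the exact null distribution is
#' used for up to 25 non-zero untied differences. If all differences are
#' zero the comparison is degenerate and p = 1 is returned with attribute
#' \code{degenerate = TRUE}.
#'
#' @param a,b paired per-subject accuracy vectors, equal length >= 5.
#' @return p-value (numeric scalar, possibly with a \code{degenerate}
#'   attribute).
#' @export
wilcoxonCompare <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 5L) stop("need at least 5 paired observations")
  d <- a - b
  d <- d[d != 0]
  if (!length(d)) {
    p <- 1
    attr(p, "degenerate") <- TRUE
    warning("all paired differences are zero; p = 1 by convention")
    return(p)
  }
  exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  res <- suppressWarnings(stats::wilcox.test(d, exact = exact,
                                             correct = !exact))
  as.numeric(res$p.value)
}
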