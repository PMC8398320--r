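#' @include AllClasses.R
NULL

# zero-phase application of an IIR filter to the columns of a [T x K]
# matrix: odd-reflection padding against edge transients, then the squared
# magnitude response |H(w)|^2 (forward-backward filtering) applied in the
# frequency domain; one FFT pair filters a whole subject at once
zeroPhaseFilterMat <- function(flt, X) {
  Tn <- nrow(X)
  pad <- min(Tn - 1L, 256L)
  Xp <- if (pad > 0)
    rbind(2 * X[rep(1L, pad), , drop = FALSE] - X[(pad + 1):2, , drop = FALSE],
          X,
          2 * X[rep(Tn, pad), , drop = FALSE] - X[(Tn - 1):(Tn - pad), , drop = FALSE])
  else X
  L <- stats::nextn(nrow(Xp), c(2, 3, 5))
  if (L > nrow(Xp)) Xp <- rbind(Xp, matrix(0, L - nrow(Xp), ncol(Xp)))
  w <- 2 * pi * (seq_len(L) - 1) / L
  ejw <- exp(-1i * outer(w, seq_along(flt$b) - 1))
  H <- as.vector(ejw %*% flt$b) / as.vector(ejw %*% flt$a)
  G <- Mod(H)^2
  Y <- Re(stats::mvfft(stats::mvfft(Xp) * G, inverse = TRUE)) / L
  Y[pad + seq_len(Tn), , drop = FALSE]
}

#' Zero-phase band-pass filter epoched EEG
#'
#' Applies a 4th-order Butterworth band-pass forward and backward (zero
#' phase, squared magnitude response) independently to every channel of
#' every trial. Edge transients are damped by odd-reflection padding. The
#' shape of the data is unchanged.
#'
#' @param e an \linkS4class{Epochs} object.
#' @param band a \linkS4class{BandSpec}; requires \code{band@high < fs/2}.
#' @return Filtered \linkS4class{Epochs}.
#' @examples
#' e <- Epochs(array(rnorm(256 * 2 * 2), c(256, 2, 2)),
#'             c(1, 2), 128, c("C3", "C4"))
#' ef <- bandpass(e, bandSpec(8, 30))
#' @export
bandpass <- function(e, band) {
  stopifnot(is(e, "Epochs"), is(band, "BandSpec"))
  if (band@high >= e@fs / 2)
    stop(sprintf("band upper edge %g Hz is not below Nyquist (%g Hz)",
                 band@high, e@fs / 2))
  flt <- signal::butter(4, c(band@low, band@high) / (e@fs / 2), type = "pass")
  d <- dim(e@data)
  X <- e@data
  dim(X) <- c(d[1], d[2] * d[3])
  Y <- zeroPhaseFilterMat(flt, X)
  dim(Y) <- d
  Epochs(Y, e@labels, e@fs, e@channels, e@t0)
}

#' The 15-band multi-resolution filter bank
#'
#' The fixed bank used by multi-resolution filter-bank CSP: the 8-30 Hz
#' broad band, the four standard rhythms (theta, mu, beta, gamma), five
#' 6-Hz-wide bands starting at 7 Hz, and five 6-Hz-wide bands starting at
#' 10 Hz.
#'
#' @return List of 15 \linkS4class{BandSpec} objects, in the canonical order.
#' @examples
#' length(makeFilterBank())
#' @export
makeFilterBank <- function() {
  edges <- list(
    c(8, 30), c(4, 7), c(8, 13), c(13, 30), c(30, 40),
    c(7, 13), c(13, 19), c(19, 25), c(25, 31), c(31, 37),
    c(10, 16), c(16, 22), c(22, 28), c(28, 34), c(34, 40)
  )
  lapply(edges, function(b) bandSpec(b[1], b[2]))
}

#' Crop epochs to an analysis window
#'
#' Keeps the half-open window \code{[startS, stopS)} relative to stimulus
#' onset; the result has \code{round((stopS - startS) * fs)} samples (e.g.
#' the 1.0-3.5 s imagery window gives 320 samples at 128 Hz, 250 at 100 Hz).
#'
#' @param e an \linkS4class{Epochs} object.
#' @param startS,stopS window bounds in seconds relative to stimulus onset;
#'   must lie within the epoch's time support.
#' @return Cropped \linkS4class{Epochs} with updated \code{t0}.
#' @export
cropEpochs <- function(e, startS, stopS) {
  stopifnot(is(e, "Epochs"), stopS > startS)
  i0 <- round((startS - e@t0) * e@fs)
  count <- round((stopS - startS) * e@fs)
  if (i0 < 0 || i0 + count > nSamples(e))
    stop(sprintf("window [%g, %g) outside epoch support [%g, %g)",
                 startS, stopS, e@t0, e@t0 + nSamples(e) / e@fs))
  Epochs(e@data[i0 + seq_len(count), , , drop = FALSE], e@labels, e@fs,
         e@channels, e@t0 + i0 / e@fs)
}

# rational polyphase resampler for one channel: zero-stuff by p, convolve
# with a Kaiser-windowed sinc low-pass at 1/max(p,q) of Nyquist, decimate
# by q; group delay compensated, odd-reflection padding at the edges
resampleVector <- function(x, p, q) {
  if (p == q) return(x)
  n <- length(x)
  N <- 10L
  M <- 2L * N * max(p, q)
  h <- p * signal::fir1(M, 1 / max(p, q), window = signal::kaiser(M + 1, 5))
  pad <- min(n - 1L, ceiling(M / (2 * p)) + 1L)
  xp <- if (pad > 0)
    c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  else x
  np <- length(xp)
  up <- numeric(np * p)
  up[seq(1, np * p, by = p)] <- xp
  yf <- as.numeric(stats::filter(c(up, numeric(M)), h,
                                 method = "convolution", sides = 1))
  L <- round(n * p / q)
  idx <- pad * p + (seq_len(L) - 1L) * q + 1L + M / 2
  yf[idx]
}

#' Anti-aliased resampling of epoched EEG
#'
#' Rational polyphase resampling (zero-stuffing, windowed-sinc anti-alias
#' low-pass, decimation) applied per channel per trial. The new trial length
#' is \code{round(T * fsTarget / fs)}; integer ratios such as 512 to 128 Hz
#' or 1000 to 100 Hz are exact.
#'
#' @param e an \linkS4class{Epochs} object.
#' @param fsTarget target sampling rate, Hz; must be positive and at most
#'   \code{samplingRate(e)}.
#' @return Resampled \linkS4class{Epochs} with \code{fs = fsTarget}.
#' @export
resampleEpochs <- function(e, fsTarget) {
  stopifnot(is(e, "Epochs"))
  if (fsTarget <= 0) stop("fsTarget must be positive")
  if (fsTarget > e@fs) stop("upsampling not supported: fsTarget > fs")
  if (isTRUE(all.equal(fsTarget, e@fs))) return(e)
  p <- round(fsTarget * 1000); q <- round(e@fs * 1000)
  g <- gcdInt(p, q); p <- p %/% g; q <- q %/% g
  if (max(p, q) > 1024)
    stop("fs ratio ", fsTarget, "/", e@fs, " is not a small rational")
  L <- round(nSamples(e) * p / q)
  out <- array(0, c(L, nChannels(e), nTrials(e)))
  for (tr in seq_len(nTrials(e)))
    for (ch in seq_len(nChannels(e)))
      out[, ch, tr] <- resampleVector(e@data[, ch, tr], p, q)
  Epochs(out, e@labels, fsTarget, e@channels, e@t0)
}

gcdInt <- function(a, b) if (b == 0) a else Recall(b, a %% b)
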