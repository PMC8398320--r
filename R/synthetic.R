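#' @include eval.R
NULL

#' The 20-channel motor-cortex montage
#'
#' The frontocentral / central / centroparietal channel set shared by the
#' large public motor-imagery datasets, used as the default synthetic
#' montage and for cross-dataset harmonization.
#'
#' @return Character vector of 20 channel names.
#' @export
motorMontage20 <- function() {
  c("FC5", "FC3", "FC1", "FC2", "FC4", "FC6",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6")
}

#' The 21-channel motor-cortex montage (adds FCz)
#'
#' @return Character vector of 21 channel names.
#' @export
motorMontage21 <- function() {
  c("FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6")
}

# flattened 2-d scalp coordinates (head radius ~1) for the montages above
chanPositions <- function(montage) {
  lat <- c("5" = -0.62, "3" = -0.37, "1" = -0.13, "z" = 0,
           "2" = 0.13, "4" = 0.37, "6" = 0.62)
  row <- c(FC = 0.26, C = 0, CP = -0.26)
  parse1 <- function(nm) {
    m <- regmatches(nm, regexec("^(FC|CP|C)([1-6z])$", nm))[[1]]
    if (length(m) != 3L) stop("no scalp position known for channel ", nm)
    c(x = unname(lat[m[3]]), y = unname(row[m[2]]))
  }
  pos <- t(vapply(montage, parse1, numeric(2)))
  colnames(pos) <- c("x", "y")
  pos
}

#' Describe one synthetic subject
#'
#' @param erdDepth fractional attenuation of the mu-band source amplitude
#'   during imagery of the contralateral hand, in [0, 1]; 0 is an
#'   undecodable (poor) performer, values above ~0.5 give clearly
#'   decodable trials.
#' @param laterality "contralateral" (physiological) or "ipsilateral"
#'   (anomalous profile: the attenuation side is swapped).
#' @param noiseSd amplitude scale of the background EEG (arbitrary units).
#' @param alphaPeakHz the subject's mu-rhythm center frequency, in
#'   [8, 13] Hz.
#' @param erraticDepth strength in [0, 1] of class-unrelated lateralized
#'   mu modulation: on every trial one hemisphere, chosen at random
#'   independently of the cue, is additionally attenuated by up to this
#'   fraction. Low-skill users show exactly this erratic, side-inconsistent
#'   modulation; it injects class-difference noise without carrying class
#'   information.
#' @param muScale relative amplitude of the sensorimotor mu sources.
#'   Low-skill users have weak mu rhythm over the motor cortex (low alpha
#'   peaks at C3/C4), the neurophysiological marker of BCI inefficiency.
#' @param bgScale relative amplitude of the task-unrelated background
#'   alpha source; relatively dominant in low-skill users.
#' @param driftScale strength of the slow within-session drift of
#'   oscillatory power. Because trials follow a blocked schedule, drift is
#'   confounded with the class labels and plants spurious, non-transferable
#'   class-covariance structure; drift is largest in inattentive low-skill
#'   users.
#' @param seed integer seed driving all of the subject's randomness.
#' @return A named list profile for [simulateSubject()].
#' @export
subjectProfile <- function(erdDepth, laterality = c("contralateral",
                                                    "ipsilateral"),
                           noiseSd = 1, alphaPeakHz = 10.5,
                           erraticDepth = 0.2, muScale = 1, bgScale = 1,
                           driftScale = 0.25, seed = 1L) {
  laterality <- match.arg(laterality)
  if (erdDepth < 0 || erdDepth > 1) stop("erdDepth must lie in [0, 1]")
  if (erraticDepth < 0 || erraticDepth > 1)
    stop("erraticDepth must lie in [0, 1]")
  if (alphaPeakHz < 8 || alphaPeakHz > 13)
    stop("alphaPeakHz must lie in [8, 13]")
  if (muScale <= 0 || bgScale <= 0) stop("muScale and bgScale must be positive")
  if (driftScale < 0) stop("driftScale must be non-negative")
  list(erdDepth = erdDepth, laterality = laterality, noiseSd = noiseSd,
       alphaPeakHz = alphaPeakHz, erraticDepth = erraticDepth,
       muScale = muScale, bgScale = bgScale, driftScale = driftScale,
       seed = as.integer(seed))
}

# 1/f-shaped background noise, spatially correlated across the montage
# (Gaussian kernel over scalp distance; neighboring channels ~0.5)
pinkSpatialNoise <- function(Tn, pos, noiseSd) {
  C <- nrow(pos)
  W <- matrix(stats::rnorm(Tn * C), Tn, C)
  f <- c(1, seq_len(Tn - 1))
  f <- pmin(f, Tn - f + 1)          # two-sided frequency index
  shape <- 1 / sqrt(pmax(f, 1))
  X <- Re(stats::mvfft(stats::mvfft(W) * shape, inverse = TRUE)) / Tn
  X <- scale(X)                     # unit variance per channel
  D2 <- as.matrix(stats::dist(pos))^2
  R <- exp(-D2 * log(2) / 0.25^2)   # corr 0.5 at neighbor distance 0.25
  noiseSd * X %*% chol(R)
}

#' Simulate one subject's epoched motor-imagery EEG
#'
#' Each trial is spatially correlated 1/f background noise plus a mu-band
#' oscillation (center \code{alphaPeakHz}, with a weak second harmonic)
#' radiating through two fixed Gaussian source topographies peaking at C3
#' and C4. On left-hand trials the contralateral (C4) source amplitude is
#' multiplied by \code{1 - erdDepth} — event-related desynchronization —
#' and the C3 source on right-hand trials; the "ipsilateral" profile swaps
#' which source attenuates. Each subject additionally carries fixed
#' idiosyncrasies that do not encode class: random per-channel gains and a
#' task-unrelated background alpha source at a subject-specific scalp
#' location, the inter-subject variability that makes naive pooling hard.
#' Deterministic given the profile seed.
#'
#' @param profile a [subjectProfile()].
#' @param nTrialsPerClass trials per class in each split.
#' @param fs sampling rate, Hz.
#' @param montage channel names; must contain both C3 and C4.
#' @param window epoch support \code{c(start, stop)} in seconds relative
#'   to stimulus onset.
#' @return \code{list(train = Epochs, test = Epochs)}.
#' @export
simulateSubject <- function(profile, nTrialsPerClass = 50, fs = 128,
                            montage = motorMontage20(), window = c(0, 4)) {
  if (!all(c("C3", "C4") %in% montage))
    stop("montage must contain both C3 and C4")
  pos <- chanPositions(montage)
  Tn <- round((window[2] - window[1]) * fs)
  tt <- (seq_len(Tn) - 1) / fs
  muAmp <- 1.2 * profile$noiseSd * profile$muScale  # base mu SNR constant
  # subject idiosyncrasies, fixed across that subject's trials: anatomical
  # jitter of the sensorimotor source locations and extents, multiplicative
  # per-channel gains (electrode/skull differences), and a task-unrelated
  # background alpha source at a subject-specific scalp location
  gauss <- function(center, width) {
    d2 <- (pos[, "x"] - center[1])^2 + (pos[, "y"] - center[2])^2
    exp(-d2 / (2 * width^2))
  }
  subjectTraits <- function() {
    # anomalous-laterality subjects also show atypical spatial organization
    ipsi <- profile$laterality == "ipsilateral"
    jit <- function(ch) pos[ch, ] + stats::rnorm(2, 0, if (ipsi) 0.12 else 0.04)
    width <- stats::runif(2, 0.15, 0.22)
    bgCenter <- c(stats::runif(1, -0.7, 0.7), stats::runif(1, -0.35, 0.35))
    list(g3 = gauss(jit("C3"), width[1]),
         g4 = gauss(jit("C4"), width[2]),
         # global EEG amplitude varies severalfold across people; pooled
         # class covariances are trial-concatenated without normalization,
         # so loud subjects weigh in proportionally to their power
         amp = exp(stats::rnorm(1, 0, 0.35)),
         gains = exp(stats::rnorm(length(montage), 0, 0.15)),
         gBg = gauss(bgCenter, 0.22),
         bgAmp = 0.8 * profile$noiseSd * profile$bgScale *
           stats::runif(1, 0.5, 1.5),
         muGain = stats::runif(1, 0.7, 1.3))
  }
  makeSplit <- function(traits) {
    labels <- rep(c(1L, 2L), each = nTrialsPerClass)
    N <- length(labels)
    # slow within-session drift of oscillatory power (vigilance/fatigue);
    # with a blocked trial schedule this is a classic confound that plants
    # spurious class-covariance structure carrying no transferable signal
    dMu <- profile$driftScale * stats::runif(1, -0.35, 0.35)
    dBg <- profile$driftScale * stats::runif(1, -0.5, 0.5)
    dat <- array(0, c(Tn, length(montage), N))
    for (tr in seq_along(labels)) {
      fr <- 2 * tr / N - 1
      muDrift <- max(0.05, 1 + dMu * fr)
      bgDrift <- max(0.05, 1 + dBg * fr)
      E <- pinkSpatialNoise(Tn, pos, profile$noiseSd)
      att <- 1 - profile$erdDepth
      # class 1 = left hand: contralateral hemisphere is the right (C4)
      a3 <- muAmp * traits$muGain; a4 <- muAmp * traits$muGain
      # class 1 (left hand) physiologically attenuates the right-hemisphere
      # (C4) source; the ipsilateral profile is *dominantly* mirrored, with
      # a weak residual normal component (real anomalous subjects show
      # mixed, not perfectly inverted, patterns)
      attenuateC4 <- labels[tr] == 1L
      if (profile$laterality == "ipsilateral") {
        if (attenuateC4) {
          a3 <- a3 * att
          a4 <- a4 * (1 - 0.35 * profile$erdDepth)
        } else {
          a4 <- a4 * att
          a3 <- a3 * (1 - 0.35 * profile$erdDepth)
        }
      } else {
        if (attenuateC4) a4 <- a4 * att else a3 <- a3 * att
      }
      # erratic, cue-unrelated lateralized modulation (low-skill signature)
      if (profile$erraticDepth > 0) {
        eAtt <- 1 - profile$erraticDepth * stats::runif(1, 0.5, 1)
        if (stats::runif(1) < 0.5) a3 <- a3 * eAtt else a4 <- a4 * eAtt
      }
      osc <- function(a) {
        phi <- stats::runif(2, 0, 2 * pi)
        amp <- a * (0.85 + 0.3 * stats::runif(1))
        env <- 1 + 0.25 * sin(2 * pi * stats::runif(1, 0.3, 1) * tt +
                                stats::runif(1, 0, 2 * pi))
        amp * env * (sin(2 * pi * profile$alphaPeakHz * tt + phi[1]) +
                       0.3 * sin(2 * pi * 2 * profile$alphaPeakHz * tt + phi[2]))
      }
      X <- E + outer(osc(a3 * muDrift), traits$g3) +
        outer(osc(a4 * muDrift), traits$g4) +
        outer(osc(traits$bgAmp * bgDrift), traits$gBg)
      dat[, , tr] <- traits$amp * sweep(X, 2L, traits$gains, "*")
    }
    Epochs(dat, labels, fs, montage, t0 = window[1])
  }
  withSeed(profile$seed, {
    traits <- subjectTraits()
    list(train = makeSplit(traits), test = makeSplit(traits))
  })
}

#' Describe a synthetic multi-subject population
#'
#' @param nSubjects number of subjects (>= 2).
#' @param mixture named proportions \code{c(good, poor, ipsilateral)}
#'   summing to 1; the default reflects the reported 10-30% of users who
#'   cannot produce decodable motor-imagery patterns.
#' @param erdGood,erdPoor,erdIpsi erd-depth ranges \code{c(lo, hi)} each
#'   profile type is drawn from.
#' @param nTrialsPerClass trials per class per split.
#' @param fs sampling rate, Hz.
#' @param montage shared channel list.
#' @param window epoch support in seconds.
#' @param noiseSd background noise scale.
#' @param seed master seed; every subject's stream is derived from it.
#' @return A named list spec for [simulatePopulation()].
#' @export
populationSpec <- function(nSubjects, mixture = c(good = 0.7, poor = 0.2,
                                                  ipsilateral = 0.1),
                           erdGood = c(0.5, 0.9), erdPoor = c(0, 0.1),
                           erdIpsi = c(0.5, 0.9), nTrialsPerClass = 50,
                           fs = 128, montage = motorMontage20(),
                           window = c(0, 4), noiseSd = 1, seed = 1L) {
  if (nSubjects < 2) stop("need at least 2 subjects")
  if (abs(sum(mixture) - 1) > 1e-8) stop("mixture proportions must sum to 1")
  if (!all(names(mixture) == c("good", "poor", "ipsilateral")))
    stop("mixture must be named c(good, poor, ipsilateral)")
  list(nSubjects = as.integer(nSubjects), mixture = mixture,
       erdGood = erdGood, erdPoor = erdPoor, erdIpsi = erdIpsi,
       nTrialsPerClass = nTrialsPerClass, fs = fs, montage = montage,
       window = window, noiseSd = noiseSd, seed = as.integer(seed))
}

#' Simulate a multi-subject dataset
#'
#' Assigns each subject a profile type by the mixture (deterministic
#' largest-remainder counts, randomly permuted under the master seed),
#' draws the per-type erd depth and mu peak frequency, and simulates every
#' subject with a seed derived from the master seed. The ground-truth
#' profiles are attached as \code{attr(result, "profiles")} for recovery
#' tests.
#'
#' @param spec a [populationSpec()].
#' @return A \linkS4class{MultiSubjectDataset}; same seed, same bytes.
#' @export
simulatePopulation <- function(spec) {
  n <- spec$nSubjects
  counts <- floor(spec$mixture * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- spec$mixture * n - counts
    counts[order(-frac)[seq_len(rem)]] <- counts[order(-frac)[seq_len(rem)]] + 1
  }
  ranges <- list(good = spec$erdGood, poor = spec$erdPoor,
                 ipsilateral = spec$erdIpsi)
  profiles <- withSeed(spec$seed, {
    types <- sample(rep(names(counts), counts))
    data.frame(
      subject_id = sprintf("s%02d", seq_len(n)),
      type = types,
      erdDepth = vapply(types, function(ty)
        stats::runif(1, ranges[[ty]][1], ranges[[ty]][2]), numeric(1)),
      erraticDepth = ifelse(types == "poor", stats::runif(n, 0.3, 0.6),
                            stats::runif(n, 0.1, 0.3)),
      muScale = stats::runif(n, 0.8, 1.2),
      bgScale = ifelse(types == "poor", stats::runif(n, 4, 6),
                       stats::runif(n, 0.8, 1.2)),
      driftScale = stats::runif(n, 0.3, 0.8),
      laterality = ifelse(types == "ipsilateral", "ipsilateral",
                          "contralateral"),
      alphaPeakHz = stats::runif(n, 8.5, 12.5),
      noiseSd = spec$noiseSd,
      seed = (spec$seed * 7919 + seq_len(n) * 104729) %% 2147483647,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  subs <- lapply(seq_len(n), function(i) {
    p <- subjectProfile(profiles$erdDepth[i], profiles$laterality[i],
                        profiles$noiseSd[i], profiles$alphaPeakHz[i],
                        profiles$erraticDepth[i], profiles$muScale[i],
                        profiles$bgScale[i], profiles$driftScale[i],
                        profiles$seed[i])
    simulateSubject(p, spec$nTrialsPerClass, spec$fs, spec$montage,
                    spec$window)
  })
  names(subs) <- profiles$subject_id
  d <- multiSubjectDataset(subs, name = sprintf("synthetic-%d", spec$seed),
                           montage = spec$montage)
  attr(d, "profiles") <- profiles
  d
}
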