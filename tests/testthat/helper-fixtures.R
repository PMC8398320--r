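# shared fixture builders: everything is generated in code at test time

# white-noise epochs with balanced labels
noiseEpochs <- function(T = 64, C = 3, N = 8, fs = 64, seed = 1,
                        channels = paste0("ch", seq_len(C)),
                        labels = rep(c(1L, 2L), length.out = N), t0 = 0) {
  set.seed(seed)
  Epochs(array(rnorm(T * C * N), c(T, C, N)), labels, fs, channels, t0)
}

# gaussian trials with prescribed per-class channel covariances
covEpochs <- function(Sigma1, Sigma2, nPerClass = 10, T = 500, fs = 100,
                      seed = 1) {
  C <- nrow(Sigma1)
  set.seed(seed)
  R1 <- chol(Sigma1); R2 <- chol(Sigma2)
  N <- 2 * nPerClass
  dat <- array(0, c(T, C, N))
  labels <- rep(c(1L, 2L), each = nPerClass)
  for (i in seq_len(N)) {
    R <- if (labels[i] == 1L) R1 else R2
    dat[, , i] <- matrix(rnorm(T * C), T, C) %*% R
  }
  Epochs(dat, labels, fs, paste0("ch", seq_len(C)))
}

# small multi-subject dataset of white-noise subjects (structural tests)
noiseDataset <- function(nSubj = 3, T = 64, C = 3, N = 8, fs = 64,
                         seed = 1) {
  subs <- lapply(seq_len(nSubj), function(i)
    list(train = noiseEpochs(T, C, N, fs, seed = seed + 2 * i),
         test = noiseEpochs(T, C, N, fs, seed = seed + 2 * i + 1)))
  names(subs) <- sprintf("s%02d", seq_len(nSubj))
  multiSubjectDataset(subs, name = "noise")
}

# compact synthetic montage around the motor strip (keeps C3/C4)
smallMontage <- function() c("C5", "C3", "C1", "C2", "C4", "C6")

# independent re-derivation of pair-wise MI feature selection: repeatedly
# pick the best-ranked uncovered feature and claim its mirrored partner
bruteMibifs <- function(X, lab, k, bins = NULL) {
  mi <- vapply(seq_len(ncol(X)), function(j)
    mutualInformation(X[, j], lab, bins = bins), numeric(1))
  comp <- function(j) {
    band <- (j - 1) %/% 4
    pos <- (j - 1) %% 4 + 1
    as.integer(band * 4 + (5 - pos))
  }
  remaining <- seq_len(ncol(X))
  sel <- integer(0)
  for (i in seq_len(k)) {
    byRank <- remaining[order(-mi[remaining], remaining)]
    best <- byRank[1]
    sel <- c(sel, best, comp(best))
    remaining <- setdiff(remaining, c(best, comp(best)))
  }
  sort(unique(sel))
}

# one simulated subject wrapped as a single-subject dataset
subjectDataset <- function(erd, seed, nPerClass = 50,
                           montage = smallMontage(), ...) {
  s <- simulateSubject(subjectProfile(erd, seed = seed, ...),
                       nTrialsPerClass = nPerClass, montage = montage)
  multiSubjectDataset(list(s01 = s), name = "single")
}
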