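test_that("classCovariance behaves like a trial-concatenated sample covariance", {
  # white noise, long T: covariance approaches sigma^2 I
  e <- noiseEpochs(T = 50000, C = 3, N = 2, seed = 10)
  S <- classCovariance(e, 1L)
  expect_equal(diag(S), rep(1, 3), tolerance = 0.05)
  expect_lt(max(abs(S[upper.tri(S)])), 0.05)
  # constant channel: zero row and column
  e2 <- noiseEpochs(T = 100, C = 3, N = 2)
  e2@data[, 2, ] <- 5
  S2 <- classCovariance(e2, 1L)
  expect_equal(S2[2, ], rep(0, 3))
  expect_equal(S2[, 2], rep(0, 3))
  # duplicating all trials leaves the covariance (nearly) unchanged:
  # only the -1 in the denominator differs
  e3 <- noiseEpochs(T = 200, C = 3, N = 4)
  dup <- Epochs(array(c(e3@data, e3@data), c(200, 3, 8)),
                c(e3@labels, e3@labels), e3@fs, e3@channels)
  expect_equal(classCovariance(dup, 1L), classCovariance(e3, 1L),
               tolerance = 1e-2)
  expect_error(classCovariance(e3, 7L), "no trials")
})

test_that("fitCSP solves the generalized eigenproblem with its normalizations", {
  # planted diagonal instance: d -> (2/3, 1/3), filters on the axes
  e <- covEpochs(diag(c(2, 1)), diag(c(1, 2)), nPerClass = 20, T = 2000)
  m <- fitCSP(e)
  expect_equal(m@d, c(2 / 3, 1 / 3), tolerance = 0.02)
  W <- apply(abs(m@W), 2, function(w) w / max(w))
  expect_equal(sort(diag(W), decreasing = TRUE), c(1, 1), tolerance = 0.05)
  # identical classes: no discriminative direction, all d = 0.5
  e2 <- covEpochs(diag(3), diag(3), nPerClass = 30, T = 3000, seed = 5)
  expect_equal(fitCSP(e2)@d, rep(0.5, 3), tolerance = 0.03)
  # exact identities on a random 6-channel instance
  set.seed(8)
  A <- matrix(rnorm(36), 6); B <- matrix(rnorm(36), 6)
  e3 <- covEpochs(crossprod(A) + diag(6), crossprod(B) + diag(6),
                  nPerClass = 8, T = 300, seed = 9)
  m3 <- fitCSP(e3)
  S1 <- classCovariance(e3, 1L); S2 <- classCovariance(e3, 2L)
  expect_equal(crossprod(m3@W, (S1 + S2) %*% m3@W), diag(6),
               tolerance = 1e-8, ignore_attr = TRUE)
  P <- crossprod(m3@W, S1 %*% m3@W)
  expect_equal(P, diag(m3@d), tolerance = 1e-8, ignore_attr = TRUE)
  expect_false(is.unsorted(rev(m3@d)))
})

test_that("swapping class labels mirrors the decomposition", {
  e <- covEpochs(diag(c(3, 1, 1)), diag(c(1, 1, 3)), nPerClass = 10, T = 800,
                 seed = 11)
  m <- fitCSP(e)
  sw <- Epochs(e@data, 3L - e@labels, e@fs, e@channels)
  msw <- fitCSP(sw)
  expect_equal(msw@d, rev(1 - m@d), tolerance = 1e-10)
  # filters appear in reversed column order (sign-normalized)
  expect_equal(abs(msw@W), abs(m@W[, ncol(m@W):1]), tolerance = 1e-8)
})

test_that("rank-deficient composite covariance errors unless ridged", {
  e <- noiseEpochs(T = 100, C = 3, N = 4)
  e@data[, 3, ] <- e@data[, 2, ]   # duplicated channel
  expect_error(fitCSP(e), "rank-deficient")
  m <- fitCSP(e, ridge = 1e-9)
  expect_s4_class(m, "CSPModel")
})

test_that("selectFilters takes the outer columns", {
  e <- covEpochs(diag(6) + 0.1, diag(6), nPerClass = 8, T = 300, seed = 12)
  m <- fitCSP(e)
  expect_equal(ncol(selectFilters(m, 2)@filters), 4)
  expect_equal(ncol(selectFilters(m, 3)@filters), 6)
  all6 <- selectFilters(m, 3)
  expect_identical(all6@filters, m@W[, c(1, 2, 3, 4, 5, 6)])
  f2 <- selectFilters(m, 2)
  expect_identical(f2@filters, m@W[, c(1, 2, 5, 6)])
  expect_error(selectFilters(m, 4), "exceeds")
})

test_that("cspFeatures are normalized, scale-invariant log band powers", {
  e <- covEpochs(diag(c(2, 1, 1, 1)), diag(c(1, 1, 1, 2)), nPerClass = 6,
                 T = 400, seed = 13)
  m <- fitCSP(e)
  fset <- selectFilters(m, 2)
  X <- cspFeatures(fset, e)
  expect_equal(dim(X), c(12, 4))
  # conservation: exp(features) sums to 1 per trial
  expect_equal(rowSums(exp(X)), rep(1, 12), tolerance = 1e-12)
  # per-trial amplitude scaling cancels
  es <- e; es@data[, , 3] <- es@data[, , 3] * 10
  expect_equal(cspFeatures(fset, es)[3, ], X[3, ], tolerance = 1e-12)
  # a trial with (almost) all power along the first filter direction
  a <- m@patterns[, 1]
  s <- sin(2 * pi * 10 * (seq_len(400) - 1) / 100)
  er1 <- e
  er1@data[, , 1] <- outer(s, a) + 1e-6 * matrix(rnorm(1600), 400, 4)
  f1 <- cspFeatures(fset, er1)[1, ]
  expect_equal(which.max(f1), 1L)
  expect_gt(exp(f1[1]), 0.999)   # log of ~1
})

test_that("fitCSP agrees with a direct generalized-eigendecomposition oracle", {
  set.seed(20)
  for (rep in 1:10) {
    C <- sample(4:8, 1)
    A <- matrix(rnorm(C * C), C); B <- matrix(rnorm(C * C), C)
    e <- covEpochs(crossprod(A) / C + diag(C), crossprod(B) / C + diag(C),
                   nPerClass = 6, T = 40 * C, seed = 100 + rep)
    m <- fitCSP(e)
    S1 <- classCovariance(e, 1L); Sc <- S1 + classCovariance(e, 2L)
    # independent oracle: plain (non-symmetric) eigensolve of Sc^-1 S1
    eg <- eigen(solve(Sc, S1))
    ord <- order(Re(eg$values), decreasing = TRUE)
    expect_equal(m@d, Re(eg$values)[ord], tolerance = 1e-6)
    V <- Re(eg$vectors[, ord])
    for (j in seq_len(C)) {
      cosang <- abs(sum(V[, j] * m@W[, j])) /
        sqrt(sum(V[, j]^2) * sum(m@W[, j]^2))
      expect_equal(cosang, 1, tolerance = 1e-6)
    }
  }
})

test_that("exportPatterns zero-pads to a larger montage", {
  e <- covEpochs(diag(2), diag(c(1, 2)), nPerClass = 6, T = 200, seed = 14)
  e@channels <- c("C3", "C4")
  m <- fitCSP(e)
  tab <- exportPatterns(m, montage = c("FC1", "C3", "Cz", "C4"))
  expect_equal(tab$channel, c("FC1", "C3", "Cz", "C4"))
  expect_equal(unlist(tab[tab$channel == "FC1", -1], use.names = FALSE),
               c(0, 0))
  expect_equal(unlist(tab[tab$channel == "C3", -1], use.names = FALSE),
               m@W[1, ])
})
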