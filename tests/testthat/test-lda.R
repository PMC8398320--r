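test_that("shrinkageGamma tracks sample size and dimensionality", {
  set.seed(40)
  # huge well-conditioned sample: little shrinkage needed
  X <- matrix(rnorm(1e4 * 4), ncol = 4) %*% chol(diag(4) + 0.3)
  expect_lt(shrinkageGamma(X), 0.1)
  # a handful of samples in 60 dimensions: shrink more than halfway
  X2 <- matrix(rnorm(4 * 60), 4, 60)
  expect_gt(shrinkageGamma(X2), 0.5)
  # n = 2 is degenerate: the two centered samples are mirror images, so
  # every cross-product variance (the estimator's numerator) vanishes
  expect_equal(shrinkageGamma(matrix(rnorm(120), 2, 60)), 0)
  expect_error(shrinkageGamma(X2[1, , drop = FALSE]), "2 samples")
  # shrinkage moves the estimate toward nu*I when the population is nu*I
  X3 <- matrix(rnorm(30 * 10, sd = 2), 30, 10)
  S <- cov(X3)
  nu <- mean(diag(S))
  g <- shrinkageGamma(X3)
  St <- (1 - g) * S + g * nu * diag(10)
  expect_lt(norm(St - 4 * diag(10), "F"), norm(S - 4 * diag(10), "F"))
})

test_that("fitSLDA separates what is separable and stays at chance otherwise", {
  set.seed(41)
  X <- matrix(c(rnorm(100, -5), rnorm(100, 5)), ncol = 1)
  lab <- rep(c(1L, 2L), each = 100)
  m <- fitSLDA(X, lab)
  expect_gte(accuracy(predict(m, X), lab), 0.99)
  # identical class distributions: near chance
  accs <- vapply(1:10, function(s) {
    set.seed(100 + s)
    Xn <- matrix(rnorm(200 * 3), ncol = 3)
    mn <- fitSLDA(Xn, lab[1:200])
    accuracy(predict(mn, matrix(rnorm(200 * 3), ncol = 3)), lab[1:200])
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
  expect_error(fitSLDA(X, rep(1L, 200)), "both classes")
})

test_that("gamma = 0 reproduces a plain pooled-covariance LDA oracle", {
  skip_if_not_installed("MASS")
  set.seed(42)
  n <- 200
  X <- rbind(matrix(rnorm(n * 4), ncol = 4),
             matrix(rnorm(n * 4, mean = 0.8), ncol = 4))
  lab <- rep(c(1L, 2L), each = n)
  m0 <- fitSLDA(X, lab, gamma = 0)
  expect_equal(m0@gamma, 0)
  or <- MASS::lda(X, grouping = lab)
  Xnew <- matrix(rnorm(300 * 4, mean = 0.4), ncol = 4)
  expect_identical(predict(m0, Xnew),
                   as.integer(as.character(predict(or, Xnew)$class)))
})

test_that("predict applies the documented tie-break and invariances", {
  set.seed(43)
  X <- rbind(matrix(rnorm(40 * 2, -2), ncol = 2),
             matrix(rnorm(40 * 2, 2), ncol = 2))
  lab <- rep(c(1L, 2L), each = 40)
  m <- fitSLDA(X, lab)
  # a point exactly on the boundary goes to class 1
  mb <- new("LDAModel", w = c(1, 0), b = 0, gamma = 0.5,
            classOrder = c(1L, 2L))
  expect_equal(predict(mb, matrix(c(0, 7), 1)), 1L)
  expect_equal(predict(mb, matrix(c(1e-12, 7), 1)), 2L)
  # translating all features and refitting leaves predictions unchanged
  shift <- c(100, -50)
  m2 <- fitSLDA(sweep(X, 2, shift, "+"), lab)
  Xnew <- matrix(rnorm(100 * 2), ncol = 2)
  expect_identical(predict(m2, sweep(Xnew, 2, shift, "+")),
                   predict(m, Xnew))
  # feature permutation commutes with fitting
  perm <- c(2, 1)
  mp <- fitSLDA(X[, perm], lab)
  expect_identical(predict(mp, Xnew[, perm]), predict(m, Xnew))
  expect_error(predict(m, Xnew[, 1, drop = FALSE]), "width")
})

test_that("accuracy scores agreement and rejects degenerate input", {
  expect_equal(accuracy(c(1, 2, 1), c(1, 2, 1)), 1.0)
  expect_equal(accuracy(c(1, 2), c(2, 1)), 0.0)
  expect_equal(accuracy(rep(c(1, 2), 50), rep(c(1, 1), 50)), 0.5)
  expect_error(accuracy(integer(0), integer(0)), "empty")
  expect_error(accuracy(1, c(1, 2)), "mismatch")
})

test_that("accuracy grows with class separation in simulation", {
  set.seed(44)
  lab <- rep(c(1L, 2L), each = 150)
  accs <- vapply(c(0, 0.5, 1.5, 3), function(delta) {
    X <- rbind(matrix(rnorm(150 * 2), ncol = 2),
               matrix(rnorm(150 * 2, mean = delta), ncol = 2))
    Xt <- rbind(matrix(rnorm(150 * 2), ncol = 2),
                matrix(rnorm(150 * 2, mean = delta), ncol = 2))
    accuracy(predict(fitSLDA(X, lab), Xt), lab)
  }, numeric(1))
  expect_true(all(diff(accs) > -0.05))
  expect_gt(accs[4], 0.95)
})
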