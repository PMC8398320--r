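# mu-band power at one channel, per trial
bandPower <- function(e, channel, band = bandSpec(8, 13)) {
  eb <- bandpass(e, band)
  idx <- match(channel, e@channels)
  apply(eb@data[, idx, , drop = FALSE], 3, var)
}

test_that("the generator is deterministic and montage-checked", {
  p <- subjectProfile(0.6, seed = 70)
  s1 <- simulateSubject(p, nTrialsPerClass = 5, montage = smallMontage())
  s2 <- simulateSubject(p, nTrialsPerClass = 5, montage = smallMontage())
  expect_identical(s1$train@data, s2$train@data)
  expect_identical(s1$test@data, s2$test@data)
  expect_error(simulateSubject(p, montage = c("FC1", "FC2")), "C3")
  expect_error(subjectProfile(1.2), "erdDepth")
  expect_error(subjectProfile(0.5, alphaPeakHz = 14), "alphaPeakHz")
})

test_that("ERD appears contralaterally and scales with depth", {
  # zero depth: left/right band powers indistinguishable
  s0 <- simulateSubject(subjectProfile(0, seed = 71), nTrialsPerClass = 100,
                        montage = smallMontage())
  e0 <- s0$train
  pw <- bandPower(e0, "C3")
  pv <- t.test(pw[e0@labels == 1], pw[e0@labels == 2])$p.value
  expect_gt(pv, 0.01)
  # strong contralateral depth: C3 power drops on right-hand (class 2) trials
  s8 <- simulateSubject(subjectProfile(0.8, seed = 72), nTrialsPerClass = 50,
                        montage = smallMontage())
  e8 <- s8$train
  d3 <- mean(bandPower(e8, "C3")[e8@labels == 1]) -
    mean(bandPower(e8, "C3")[e8@labels == 2])
  expect_gt(d3, 0)
  d4 <- mean(bandPower(e8, "C4")[e8@labels == 1]) -
    mean(bandPower(e8, "C4")[e8@labels == 2])
  expect_lt(d4, 0)
  # ipsilateral profile reverses the sign of the C3 contrast
  si <- simulateSubject(subjectProfile(0.8, "ipsilateral", seed = 72),
                        nTrialsPerClass = 50, montage = smallMontage())
  ei <- si$train
  d3i <- mean(bandPower(ei, "C3")[ei@labels == 1]) -
    mean(bandPower(ei, "C3")[ei@labels == 2])
  expect_lt(d3i, 0)
})

test_that("subject-specific accuracy is monotone in ERD depth", {
  grid <- c(0, 0.2, 0.4, 0.6, 0.8)
  means <- vapply(grid, function(erd) {
    mean(vapply(1:5, function(s)
      subjectSpecificEval(subjectDataset(erd, seed = 700 + 13 * s,
                                         nPerClass = 20))@perSubject,
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > -0.03))
  expect_lt(means[1], 0.65)
  expect_gt(means[5], 0.9)
})

test_that("pooled CSP on good subjects localizes to the motor cortices", {
  spec <- populationSpec(4, mixture = c(good = 1, poor = 0, ipsilateral = 0),
                         erdGood = c(0.7, 0.9), nTrialsPerClass = 20,
                         seed = 73)
  d <- simulatePopulation(spec)
  pipe <- pooledTrain(d, subjectIds(d), config = miConfig())
  W <- pipe@csp@filters
  first <- abs(W[, 1]); last <- abs(W[, ncol(W)])
  expect_true(which.max(first) %in% match(c("C3", "C4"), d@montage))
  expect_true(which.max(last) %in% match(c("C3", "C4"), d@montage))
})

test_that("simulatePopulation emits a valid dataset with ground truth attached", {
  spec <- populationSpec(5, nTrialsPerClass = 6, montage = motorMontage21(),
                         seed = 74)
  d <- simulatePopulation(spec)
  expect_true(validObject(d))
  expect_length(d@subjects, 5)
  prof <- attr(d, "profiles")
  expect_identical(prof$subject_id, subjectIds(d))
  expect_true(all(prof$type %in% c("good", "poor", "ipsilateral")))
  # mixture counts follow largest remainders: 0.7/0.2/0.1 of 5 -> 4/1/0
  expect_equal(as.integer(table(factor(prof$type,
                                       c("good", "poor", "ipsilateral")))),
               c(4L, 1L, 0L))
  # epoch geometry matches the public-dataset shape after standard cropping
  tr <- getSubject(d, "s01")$train
  expect_equal(nChannels(tr), 21)
  expect_equal(nSamples(cropEpochs(tr, 1.0, 3.5)), 320)
  # identical seeds give identical bytes end to end
  d2 <- simulatePopulation(spec)
  expect_identical(getSubject(d2, "s03")$test@data,
                   getSubject(d, "s03")$test@data)
  expect_error(populationSpec(1), "at least 2")
  expect_error(populationSpec(5, mixture = c(good = 0.5, poor = 0.2,
                                             ipsilateral = 0.1)), "sum to 1")
})
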