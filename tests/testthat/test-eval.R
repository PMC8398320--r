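test_that("subjectSpecificEval is deterministic and decodes strong ERD", {
  d <- subjectDataset(erd = 0.8, seed = 60)
  ss1 <- subjectSpecificEval(d)
  ss2 <- subjectSpecificEval(d)
  expect_identical(ss1@perSubject, ss2@perSubject)
  expect_gt(ss1@perSubject[["s01"]], 0.85)
  rec <- ssRecords(ss1)
  expect_equal(rec$n_test_trials, 100)
  expect_error(subjectSpecificEval(d, subjects = "nope"), "unknown subject")
})

test_that("a zero-ERD subject stays inside the chance limits most of the time", {
  cl <- chanceLimits(0.5, 100, 0.05)
  inside <- vapply(1:25, function(s) {
    acc <- subjectSpecificEval(subjectDataset(0, seed = 600 + s))@perSubject
    acc > cl[["lower"]] && acc < cl[["upper"]]
  }, logical(1))
  expect_gte(mean(inside), 0.8)
})

test_that("losocv audits exclusion and honors the pooling strategy", {
  spec <- populationSpec(4, mixture = c(good = 1, poor = 0, ipsilateral = 0),
                         nTrialsPerClass = 15, montage = smallMontage(),
                         seed = 61)
  d <- simulatePopulation(spec)
  tab <- losocv(d, strategy = "all")
  expect_s4_class(tab, "EvalTable")
  for (id in subjectIds(d)) {
    expect_length(tab@config$audit[[id]], 3)          # trained on the rest
    expect_false(id %in% tab@config$audit[[id]])      # never on itself
  }
  expect_equal(tab@mean, mean(tab@perSubject), tolerance = 1e-12)
  # every subject decodable -> alpha strategy falls back to the full pool
  tabA <- losocv(d, strategy = 0.05)
  if (setequal(tabA@config$pool, subjectIds(d)))
    expect_equal(tabA@perSubject, tab@perSubject)
  expect_error(losocv(d, strategy = 2), "alpha")
})

test_that("pooledTrain matches the losocv engine and conserves trials", {
  spec <- populationSpec(3, mixture = c(good = 1, poor = 0, ipsilateral = 0),
                         nTrialsPerClass = 12, montage = smallMontage(),
                         seed = 62)
  d <- simulatePopulation(spec)
  cfg <- miConfig()
  tab <- losocv(d, cfg, strategy = "all")
  pipe <- pooledTrain(d, subjectIds(d), exclude = "s02", config = cfg)
  expect_identical(sort(pipe@trainedOn), c("s01", "s03"))
  acc <- evaluatePipeline(pipe, getSubject(d, "s02")$test)
  expect_equal(acc, tab@perSubject[["s02"]], tolerance = 1e-10)
  # degenerate pool
  expect_error(pooledTrain(d, "s02", exclude = "s02", config = cfg),
               "no source subjects")
  expect_error(pooledTrain(d, c("s01", "zz"), config = cfg), "not in dataset")
})

test_that("the fbcsp strategy runs through losocv on a small population", {
  spec <- populationSpec(3, mixture = c(good = 1, poor = 0, ipsilateral = 0),
                         nTrialsPerClass = 12, montage = smallMontage(),
                         seed = 63)
  d <- simulatePopulation(spec)
  tab <- losocv(d, miConfig("fbcsp", kPairs = 6), strategy = "all")
  expect_length(tab@perSubject, 3)
  expect_true(all(tab@perSubject >= 0 & tab@perSubject <= 1))
})

test_that("crossDatasetEval requires harmonized montages and scores per subject", {
  spec1 <- populationSpec(3, mixture = c(good = 1, poor = 0, ipsilateral = 0),
                          nTrialsPerClass = 12, montage = smallMontage(),
                          seed = 64)
  spec2 <- populationSpec(3, mixture = c(good = 1, poor = 0, ipsilateral = 0),
                          nTrialsPerClass = 12, montage = smallMontage(),
                          noiseSd = 1.4, seed = 65)
  d1 <- simulatePopulation(spec1)
  d2 <- simulatePopulation(spec2)
  tab <- crossDatasetEval(d1, d2, strategy = "all")
  expect_length(tab@perSubject, 3)
  expect_identical(tab@config$pool, subjectIds(d1))
  # montage harmonization: channel order must match exactly
  d2r <- selectChannels(d2, rev(smallMontage()))
  expect_error(crossDatasetEval(d1, d2r, strategy = "all"), "montage")
  # a genuinely missing channel is named
  d2m <- selectChannels(d2, setdiff(smallMontage(), "C6"))
  expect_error(crossDatasetEval(d1, d2m, strategy = "all"), "C6")
})

test_that("subsampleTrials draws balanced, reproducible, order-preserving subsets", {
  e <- noiseEpochs(T = 32, C = 2, N = 20)
  s1 <- subsampleTrials(e, 10, seed = 7)
  s2 <- subsampleTrials(e, 10, seed = 7)
  expect_identical(s1@data, s2@data)
  expect_equal(as.integer(table(classLabels(s1))), c(5L, 5L))
  # full draw keeps everything in order
  full <- subsampleTrials(e, 20, seed = 7)
  expect_identical(full@data, e@data)
  expect_identical(full@labels, e@labels)
  expect_error(subsampleTrials(e, 7, seed = 1), "even")
  expect_error(subsampleTrials(e, 22, seed = 1), "exceeds")
  # drawing must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(subsampleTrials(e, 10, seed = 3)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("losocvSubtrials averages repeated draws per subject", {
  spec <- populationSpec(3, mixture = c(good = 1, poor = 0, ipsilateral = 0),
                         nTrialsPerClass = 12, montage = smallMontage(),
                         seed = 66)
  d <- simulatePopulation(spec)
  tab <- losocvSubtrials(d, nSub = 16, strategy = "all", repeats = 2, seed = 5)
  expect_length(tab@perSubject, 3)
  reps <- tab@config$perRepeat
  expect_length(reps, 2)
  manual <- colMeans(rbind(reps[[1]]@perSubject, reps[[2]]@perSubject))
  expect_equal(tab@perSubject, manual)
})

test_that("compareStrategies shares one preprocessing pass across strategies", {
  spec <- populationSpec(3, mixture = c(good = 1, poor = 0, ipsilateral = 0),
                         nTrialsPerClass = 12, montage = smallMontage(),
                         seed = 67)
  d <- simulatePopulation(spec)
  cmp <- compareStrategies(d, strategies = list("all", 0.05))
  expect_named(cmp, c("SS", "all", "0.05"))
  expect_identical(cmp$all@perSubject, losocv(d, strategy = "all")@perSubject)
  expect_identical(cmp$SS@perSubject, subjectSpecificEval(d)@perSubject)
})
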