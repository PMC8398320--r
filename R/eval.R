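#' @include pipeline.R chance.R
NULL

# ---- internal evaluation engine -------------------------------------------
#
# LOSOCV refits spatial filters for every held-out subject. Rather than
# re-filtering and re-concatenating raw trials per fold, each subject is
# preprocessed once per band into (i) a per-trial covariance matrix row
# [N x C^2] and (ii) its class-wise sums. A fold's trial-concatenated class
# covariance is then a weighted sum over pool members, and the log-variance
# feature of trial t under filter w is log-normalized w' Cov_t w, a single
# BLAS product per fold. This is algebraically identical to the plain
# trainPipeline() path (asserted in the tests).

prepSplit <- function(e, bands, window) {
  perBand <- lapply(bands, function(b) {
    eb <- cropEpochs(bandpass(e, b), window[1], window[2])
    N <- nTrials(eb); C <- nChannels(eb); Tn <- nSamples(eb)
    Fm <- matrix(0, N, C * C)
    for (tr in seq_len(N)) {
      X <- eb@data[, , tr]
      X <- sweep(X, 2L, colMeans(X))
      Fm[tr, ] <- crossprod(X) / (Tn - 1)
    }
    list(F = Fm, T = Tn)
  })
  list(bands = perBand, labels = e@labels, C = nChannels(e))
}

prepCache <- function(d, config) {
  bands <- configBands(config)
  lapply(d@subjects, function(s)
    list(train = prepSplit(s$train, bands, config$window),
         test = prepSplit(s$test, bands, config$window)))
}

# variances of the filtered trials from cached covariances, then the
# log of the sum-normalized variance (same transform as cspFeatures)
featuresFromCov <- function(Fm, filters) {
  WV <- apply(filters, 2L, function(w) as.vector(tcrossprod(w)))
  V <- Fm %*% WV
  log(V / rowSums(V))
}

pooledClassCov <- function(cache, members, band, label) {
  C <- cache[[members[1]]]$train$C
  S <- matrix(0, C, C)
  n <- 0
  for (id in members) {
    sp <- cache[[id]]$train
    rows <- sp$labels == label
    Tn <- sp$bands[[band]]$T
    S <- S + matrix(colSums(sp$bands[[band]]$F[rows, , drop = FALSE]) *
                      (Tn - 1), C, C)
    n <- n + Tn * sum(rows)
  }
  S / (n - 1)
}

fitPooled <- function(cache, members, config, mPairs) {
  bands <- configBands(config)
  nb <- length(bands)
  filterSets <- vector("list", nb)
  for (b in seq_len(nb)) {
    S1 <- pooledClassCov(cache, members, b, 1L)
    S2 <- pooledClassCov(cache, members, b, 2L)
    m <- if (config$feature == "csp") mPairs else 2L
    filterSets[[b]] <- selectFilters(fitCSPFromCov(S1, S2), m)
  }
  feats <- do.call(rbind, lapply(members, function(id) {
    sp <- cache[[id]]$train
    do.call(cbind, lapply(seq_len(nb), function(b)
      featuresFromCov(sp$bands[[b]]$F, filterSets[[b]]@filters)))
  }))
  labels <- unlist(lapply(members, function(id) cache[[id]]$train$labels))
  sel <- NULL
  if (config$feature == "fbcsp") {
    sel <- mibifsSelect(feats, labels, config$kPairs, bins = config$bins)
    feats <- feats[, sel, drop = FALSE]
  }
  lda <- fitSLDA(feats, labels, gamma = config$gamma)
  list(filterSets = filterSets, selected = sel, lda = lda, members = members)
}

predictPooled <- function(model, split) {
  feats <- do.call(cbind, lapply(seq_along(model$filterSets), function(b)
    featuresFromCov(split$bands[[b]]$F, model$filterSets[[b]]@filters)))
  if (!is.null(model$selected))
    feats <- feats[, model$selected, drop = FALSE]
  predict(model$lda, feats)
}

ssFromCache <- function(cache, config) {
  ids <- names(cache)
  acc <- vapply(ids, function(id) {
    model <- fitPooled(cache, id, config, mPairs = config$mPairsSS)
    accuracy(predictPooled(model, cache[[id]]$test), cache[[id]]$test$labels)
  }, numeric(1))
  data.frame(subject_id = ids, ss_accuracy = unname(acc),
             n_test_trials = vapply(ids, function(id)
               length(cache[[id]]$test$labels), integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

evalTable <- function(strategy, perSubject, config = list()) {
  ok <- perSubject[!is.na(perSubject)]
  new("EvalTable", strategy = strategy, perSubject = perSubject,
      mean = if (length(ok)) mean(ok) else NA_real_, config = config)
}

# ---- exported evaluation protocols ----------------------------------------

#' Subject-specific (SS) evaluation
#'
#' For every subject: train the pipeline on the subject's own training
#' split (m = \code{config$mPairsSS} CSP pairs) and score it on the
#' subject's own test split. Fully deterministic given the data.
#'
#' @param d a \linkS4class{MultiSubjectDataset}.
#' @param config a [miConfig()] list.
#' @param subjects subject ids to evaluate (default: all).
#' @return An \linkS4class{EvalTable} (strategy "SS") whose config carries
#'   the per-subject records (\code{subject_id}, \code{ss_accuracy},
#'   \code{n_test_trials}) used for pool construction.
#' @export
subjectSpecificEval <- function(d, config = miConfig(),
                                subjects = subjectIds(d)) {
  stopifnot(is(d, "MultiSubjectDataset"))
  bad <- setdiff(subjects, subjectIds(d))
  if (length(bad)) stop("unknown subject id(s): ", paste(bad, collapse = ", "))
  cache <- prepCache(
    multiSubjectDataset(d@subjects[subjects], d@name, d@montage), config)
  records <- ssFromCache(cache, config)
  acc <- stats::setNames(records$ss_accuracy, records$subject_id)
  evalTable("SS", acc, config = list(config = config, records = records))
}

#' Per-subject records from an SS evaluation
#'
#' @param ss an \linkS4class{EvalTable} returned by [subjectSpecificEval()].
#' @return data.frame with columns subject_id, ss_accuracy, n_test_trials.
#' @export
ssRecords <- function(ss) {
  stopifnot(is(ss, "EvalTable"), !is.null(ss@config$records))
  ss@config$records
}

#' Train a pooled (subject-independent) pipeline
#'
#' Concatenates the training trials of all pool members except the
#' excluded subject and trains the pipeline with
#' \code{config$mPairsSI} CSP pairs on the concatenation.
#'
#' @param d a \linkS4class{MultiSubjectDataset}.
#' @param pool a \linkS4class{SubjectPool} or character vector of member
#'   ids.
#' @param exclude subject id to remove from the pool (the current test
#'   subject), or NULL for none.
#' @param config a [miConfig()] list.
#' @return An \linkS4class{MIPipeline}; \code{@trainedOn} records the
#'   source subjects.
#' @export
pooledTrain <- function(d, pool, exclude = NULL, config = miConfig()) {
  members <- if (is(pool, "SubjectPool")) pool@memberIds else as.character(pool)
  members <- setdiff(members, exclude)
  if (!length(members))
    stop("no source subjects: pool is empty after excluding '", exclude, "'")
  bad <- setdiff(members, subjectIds(d))
  if (length(bad)) stop("pool members not in dataset: ",
                        paste(bad, collapse = ", "))
  e <- concatEpochs(lapply(members, function(id) d@subjects[[id]]$train))
  trainPipeline(e, config, mPairs = config$mPairsSI, trainedOn = members)
}

#' Leave-one-subject-out (SI) evaluation
#'
#' For every subject, trains the pooled pipeline on the other subjects'
#' training trials and scores it on the held-out subject's test split.
#' With \code{strategy = "all"} the pool is every subject; with a numeric
#' significance level, the pool is the selective subject pool built from
#' the subject-specific accuracies at that alpha (computed once, with the
#' current subject removed per fold). An audit log of every fold's
#' training subjects is kept in the result.
#'
#' @param d a \linkS4class{MultiSubjectDataset} with >= 2 subjects.
#' @param config a [miConfig()] list.
#' @param strategy "all", or a significance level in (0, 1).
#' @return An \linkS4class{EvalTable} (strategy "SI-All" or "SI-alpha").
#'   Folds with an empty effective pool get NA accuracy (with a warning)
#'   and are excluded from the mean. \code{@config$audit} maps each subject
#'   to the ids its model was trained on.
#' @export
losocv <- function(d, config = miConfig(), strategy = "all") {
  stopifnot(is(d, "MultiSubjectDataset"))
  if (length(subjectIds(d)) < 2L) stop("LOSOCV needs at least 2 subjects")
  losocvFromCache(prepCache(d, config), config, strategy)
}

losocvFromCache <- function(cache, config, strategy, records = NULL) {
  ids <- names(cache)
  if (identical(strategy, "all")) {
    poolIds <- ids
    label <- "SI-All"
    alpha <- NA_real_
  } else {
    alpha <- as.numeric(strategy)
    if (!(alpha > 0 && alpha < 1)) stop("strategy must be \"all\" or an alpha in (0, 1)")
    if (is.null(records)) records <- ssFromCache(cache, config)
    poolIds <- buildPool(records, alpha)@memberIds
    label <- "SI-alpha"
  }
  audit <- list()
  acc <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (id in ids) {
    members <- setdiff(poolIds, id)
    audit[[id]] <- members
    if (!length(members)) {
      warning("subject ", id, ": empty effective pool; accuracy recorded as NA")
      next
    }
    stopifnot(!(id %in% members))  # never train on the evaluated subject
    model <- fitPooled(cache, members, config, mPairs = config$mPairsSI)
    acc[id] <- accuracy(predictPooled(model, cache[[id]]$test),
                        cache[[id]]$test$labels)
  }
  evalTable(label, acc,
            config = list(config = config, strategy = strategy, alpha = alpha,
                          pool = poolIds, ssRecords = records, audit = audit))
}

#' Compare pooling strategies on one dataset
#'
#' Runs [losocv()] under several strategies ("all" and/or significance
#' levels) while preprocessing every subject only once, and also returns
#' the subject-specific table. This is the package's central comparison:
#' does selective pooling beat training on everyone?
#'
#' @param d a \linkS4class{MultiSubjectDataset}.
#' @param config a [miConfig()] list.
#' @param strategies list/vector of strategies as accepted by [losocv()].
#' @return Named list of \linkS4class{EvalTable}s: one "SS" entry plus one
#'   entry per strategy (named "all" or the alpha value).
#' @export
compareStrategies <- function(d, config = miConfig(),
                              strategies = list("all", 0.05)) {
  stopifnot(is(d, "MultiSubjectDataset"))
  cache <- prepCache(d, config)
  records <- ssFromCache(cache, config)
  out <- list(SS = evalTable("SS",
                             stats::setNames(records$ss_accuracy,
                                             records$subject_id),
                             config = list(config = config,
                                           records = records)))
  for (s in strategies) {
    nm <- if (identical(s, "all")) "all" else as.character(s)
    out[[nm]] <- losocvFromCache(cache, config, s, records = records)
  }
  out
}

#' Cross-dataset evaluation
#'
#' Trains one pooled pipeline on the training dataset (pool = all subjects
#' or the selective pool at a significance level) and scores it on every
#' subject of the test dataset. No per-fold exclusion is needed because the
#' datasets share no subjects; both must be harmonized to the same montage
#' first (see [selectChannels()]).
#'
#' @param trainD,testD \linkS4class{MultiSubjectDataset}s on an identical
#'   montage.
#' @param config a [miConfig()] list.
#' @param strategy "all", or a significance level in (0, 1).
#' @return An \linkS4class{EvalTable} (strategy "CROSS-All" or
#'   "CROSS-alpha").
#' @export
crossDatasetEval <- function(trainD, testD, config = miConfig(),
                             strategy = "all") {
  stopifnot(is(trainD, "MultiSubjectDataset"), is(testD, "MultiSubjectDataset"))
  if (!identical(trainD@montage, testD@montage)) {
    bad <- c(setdiff(trainD@montage, testD@montage),
             setdiff(testD@montage, trainD@montage))
    if (!length(bad)) bad <- "(same channels, different order)"
    stop("montage mismatch between datasets: ", paste(unique(bad), collapse = ", "))
  }
  records <- NULL
  if (identical(strategy, "all")) {
    pool <- subjectIds(trainD)
    label <- "CROSS-All"
    alpha <- NA_real_
  } else {
    alpha <- as.numeric(strategy)
    records <- ssRecords(subjectSpecificEval(trainD, config))
    pool <- buildPool(records, alpha)@memberIds
    label <- "CROSS-alpha"
    if (!length(pool)) stop("no source subjects: selective pool is empty")
  }
  pipe <- pooledTrain(trainD, pool, exclude = NULL, config = config)
  acc <- vapply(subjectIds(testD), function(id)
    evaluatePipeline(pipe, testD@subjects[[id]]$test), numeric(1))
  evalTable(label, acc,
            config = list(config = config, strategy = strategy, alpha = alpha,
                          pool = pool, ssRecords = records))
}

# run expr under a fixed seed without disturbing the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  }
  set.seed(seed)
  force(expr)
}

#' Balanced random sub-trial selection
#'
#' Draws \code{nSub / 2} trials per class uniformly without replacement,
#' keeping the original trial order. Used to compare pooling strategies
#' across trial counts; the matching chance threshold then uses
#' \code{n = nSub}.
#'
#' @param e an \linkS4class{Epochs} object.
#' @param nSub total number of trials to keep; even, at most
#'   \code{nTrials(e)}.
#' @param seed integer seed; the same seed always selects the same subset.
#' @return Subsampled \linkS4class{Epochs}.
#' @export
subsampleTrials <- function(e, nSub, seed) {
  stopifnot(is(e, "Epochs"))
  nSub <- as.integer(nSub)
  if (nSub %% 2L != 0L) stop("nSub must be even (balanced classes)")
  if (nSub > nTrials(e)) stop("nSub exceeds the number of trials")
  perClass <- nSub %/% 2L
  keep <- withSeed(seed, {
    unlist(lapply(c(1L, 2L), function(cl) {
      idx <- which(e@labels == cl)
      if (length(idx) < perClass)
        stop("class ", cl, " has fewer than ", perClass, " trials")
      sort(sample(idx, perClass))
    }))
  })
  keep <- sort(keep)
  Epochs(e@data[, , keep, drop = FALSE], e@labels[keep], e@fs, e@channels,
         e@t0)
}

#' Subsample every subject of a dataset to a fixed trial count
#'
#' Applies [subsampleTrials()] to the train and test splits of every
#' subject with per-subject seeds derived deterministically from
#' \code{seed}.
#'
#' @param d a \linkS4class{MultiSubjectDataset}.
#' @param nSub total trials per split after subsampling.
#' @param seed integer base seed.
#' @return A \linkS4class{MultiSubjectDataset}.
#' @export
subsampleDataset <- function(d, nSub, seed) {
  ids <- subjectIds(d)
  subs <- lapply(seq_along(ids), function(i) {
    s <- d@subjects[[ids[i]]]
    list(train = subsampleTrials(s$train, nSub, (seed * 131L + 2L * i) %% 2147483647L),
         test = subsampleTrials(s$test, nSub, (seed * 131L + 2L * i + 1L) %% 2147483647L))
  })
  names(subs) <- ids
  multiSubjectDataset(subs, name = d@name, montage = d@montage)
}

#' LOSOCV over repeated random sub-trial draws
#'
#' Draws balanced sub-trials \code{repeats} times (seeds \code{seed + r}),
#' runs [losocv()] on each draw, and reports the per-subject mean accuracy;
#' the per-repeat tables are retained in the result's config.
#'
#' @param d a \linkS4class{MultiSubjectDataset}.
#' @param nSub total trials per split in each draw.
#' @param config a [miConfig()] list.
#' @param strategy "all" or a significance level, as in [losocv()].
#' @param repeats number of random draws (default 3).
#' @param seed integer base seed.
#' @return An \linkS4class{EvalTable} of per-subject mean accuracies.
#' @export
losocvSubtrials <- function(d, nSub, config = miConfig(), strategy = "all",
                            repeats = 3L, seed = 1L) {
  tabs <- lapply(seq_len(repeats), function(r)
    losocv(subsampleDataset(d, nSub, seed + r), config, strategy))
  accs <- do.call(rbind, lapply(tabs, function(tb) tb@perSubject))
  evalTable(tabs[[1L]]@strategy, colMeans(accs),
            config = list(config = config, strategy = strategy, nSub = nSub,
                          repeats = repeats, seed = seed, perRepeat = tabs))
}
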