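test_that("identical config and seed give bit-identical trials", {
  cfg <- quickConfig()
  a <- simulateTrial(cfg, seed = 7)
  b <- simulateTrial(cfg, seed = 7)
  expect_identical(a, b)
  ts1 <- runExperiment(cfg, nTrials = 3, seed = 5)
  ts2 <- runExperiment(cfg, nTrials = 3, seed = 5)
  expect_identical(ts1@networks, ts2@networks)
})

test_that("rates are non-negative and finite under the default config", {
  tr <- simulateTrial(defaultNetworkConfig(), seed = 3)
  expect_true(all(is.finite(tr$rates)))
  expect_true(all(tr$rates >= 0))
  expect_identical(rownames(tr$rates), populationNames())
})

test_that("no stimulus and sub-threshold baselines give a timeout", {
  cfg <- quickConfig(stimulusAmplitude = c(left = 0, right = 0))
  tr <- simulateTrial(cfg, seed = 1)
  expect_identical(tr$choice, "none")
  expect_true(is.na(tr$decisionTime))
})

test_that("a single-trial experiment reproduces simulateTrial on the derived sub-seed", {
  cfg <- quickConfig()
  ts <- runExperiment(cfg, nTrials = 1, seed = 9)
  direct <- simulateTrial(cfg, trialSeed(9, 1))
  expect_identical(networkTrials(ts, 1)[[1]], direct)
})

test_that("symmetric configurations choose each side about equally often", {
  cfg <- quickConfig()
  ts <- runExperiment(cfg, nTrials = 400, seed = 21)
  beh <- behaviorTable(ts)
  pLeft <- mean(beh$choice == "left")
  expect_lt(abs(pLeft - 0.5), 3 * sqrt(0.25 / 400))
  expect_lt(mean(beh$choice == "none"), 0.01)
})

test_that("a much stronger left stimulus wins the overwhelming majority of trials", {
  cfg <- quickConfig(stimulusAmplitude = c(left = 15, right = 3))
  ts <- runExperiment(cfg, nTrials = 60, seed = 13)
  beh <- behaviorTable(ts)
  decided <- beh$choice != "none"
  expect_gt(mean(beh$choice[decided] == "left"), 0.9)
})

test_that("the decision time marks the first thalamic threshold crossing", {
  cfg <- quickConfig()
  for (s in 1:5) {
    tr <- simulateTrial(cfg, seed = s)
    if (tr$choice == "none") next
    on <- tr$phaseMarks[["stimOnset"]]
    db <- tr$phaseMarks[["decision"]]
    th <- tr$rates[c("Th-L", "Th-R"), , drop = FALSE]
    expect_true(any(th[, db] >= cfg@decisionThreshold))
    if (db > on + 1)
      expect_true(all(apply(th[, (on + 1):(db - 1), drop = FALSE], 2, max) <
                        cfg@decisionThreshold))
    expect_equal(tr$decisionTime, (db - on) * cfg@binWidth)
  }
})

test_that("invalid configurations are rejected by the sign table", {
  expect_error(defaultNetworkConfig(weights = c("dSPN->GPi" = 2)),
               "sign")
  expect_error(defaultNetworkConfig(weights = c("nonsense" = 1)),
               "unknown weight")
})

test_that("feasibility evaluation accepts the default network", {
  ev <- evaluateConfig(defaultNetworkConfig(), nTrials = 8, seed = 2)
  expect_true(ev$feasible)
  expect_lt(ev$timeoutFraction, 0.01)
  expect_gt(ev$corCxStriatum, 0)
})

test_that("a degenerate point search returns that config when feasible", {
  keys <- searchableWeights()
  w0 <- connectivityTable()
  defaults <- defaultNetworkConfig()@weights[keys]
  bounds <- lapply(setNames(keys, keys), function(k) rep(defaults[[k]], 2))
  res <- geneticSearch(bounds, popSize = 4L, generations = 1L, nKeep = 2L,
                       seed = 3L, nEvalTrials = 6L)
  expect_gt(length(res), 0)
  for (cfg in res)
    expect_equal(unname(cfg@weights[keys]), unname(defaults))
})

test_that("vacuous targets make every candidate feasible", {
  keys <- searchableWeights()
  defaults <- defaultNetworkConfig()@weights[keys]
  bounds <- lapply(setNames(keys, keys), function(k)
    sort(c(0.8, 1.2) * defaults[[k]]))
  wide <- lapply(defaultRateTargets(), function(x) c(0, Inf))
  evals <- list()
  ev <- function(w, s) {
    cfg <- defaultNetworkConfig(weights = w)
    e <- evaluateConfig(cfg, wide, nTrials = 10L, seed = s)
    e$config <- cfg
    evals[[length(evals) + 1L]] <<- e
    e
  }
  res <- geneticSearch(bounds, targets = wide, popSize = 4L,
                       generations = 2L, nKeep = 8L, seed = 3L,
                       evalFun = ev)
  # with vacuous rate targets, feasibility is decided only by the timeout
  # and cortex-striatum correlation predicates: no candidate may be
  # rejected by a rate range, and everything passing those two predicates
  # is returned
  rangeOk <- vapply(evals, function(e) {
    rates <- e$meanRates
    all(rates >= 0)  # the [0, Inf) target is satisfied by every rate
  }, logical(1))
  expect_true(all(rangeOk))
  otherOk <- vapply(evals, function(e)
    e$timeoutFraction < 0.01 && e$corCxStriatum > 0, logical(1))
  expect_equal(length(res), sum(otherOk))
  expect_equal(vapply(evals, function(e) isTRUE(e$feasible), logical(1)),
               otherOk)
})

test_that("the genetic search approaches a brute-force grid optimum on a toy fitness", {
  fit <- function(w, s) {
    f <- exp(-((w[1] - 0.3)^2 + (w[2] + 0.5)^2) / 0.1)
    list(feasible = TRUE, fitness = f)
  }
  bounds <- list(w1 = c(-1, 1), w2 = c(-1, 1))
  grid <- expand.grid(w1 = seq(-1, 1, length.out = 20),
                      w2 = seq(-1, 1, length.out = 20))
  gridBest <- max(apply(grid, 1, function(w) fit(w, 0)$fitness))
  res <- geneticSearch(bounds, popSize = 24L, generations = 8L, nKeep = 1L,
                       seed = 4L, evalFun = fit)
  gaBest <- attr(res, "fitness")[1]
  expect_gte(gaBest, 0.95 * gridBest)
})

test_that("scripted traces binarize back to the script exactly", {
  script <- list(list(pattern = 60, dwell = 3), list(pattern = 63, dwell = 2))
  ts <- scriptedTraceSet(list(script))
  bin <- binarizeTraces(ts, thresholds = flatThresholds())
  seqs <- extractSequences(bin)
  expect_identical(seqs[[1]]$labels, c(60L, 60L, 60L, 63L, 63L))

  single <- scriptedTraceSet(list(list(list(pattern = 575, dwell = 4))))
  sbin <- binarizeTraces(single, thresholds = flatThresholds())
  expect_identical(extractSequences(sbin)[[1]]$labels, rep(575L, 4L))

  expect_error(generateScriptedTraces(list()), "at least one")
})

test_that("a scripted deliberation loop yields exactly the scripted transition counts", {
  loop <- c(63, 55, 183, 191, 63)
  script <- lapply(loop, function(s) list(pattern = s, dwell = 2))
  ts <- scriptedTraceSet(list(script))
  bin <- binarizeTraces(ts, thresholds = flatThresholds())
  raw <- estimateTransitions(extractSequences(bin), mode = "per_change")
  expect_equal(nrow(raw$edges), 4L)
  for (k in seq_len(4)) {
    e <- raw$edges[raw$edges$from == loop[k] & raw$edges$to == loop[k + 1], ]
    expect_equal(e$count, 1L)
  }
  expect_equal(raw$ends$state, 63L)
  expect_equal(raw$ends$probability, 0.5)  # 63 once mid-loop, once at end
})
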