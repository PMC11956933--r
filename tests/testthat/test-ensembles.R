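# Build a trace set with hand-specified per-population constant rates per
# trial (one bin block), for feature arithmetic checks.
constTrial <- function(rates, nBins = 6L) {
  pops <- populationNames()
  m <- matrix(rates[pops], length(pops), nBins,
              dimnames = list(pops, NULL))
  list(rates = m, decisionTime = (nBins - 1L) * 10, choice = "left",
       phaseMarks = c(stimOnset = 1L, decision = nBins,
                      consolidationEnd = nBins), seed = 1L)
}

flatRates <- function(value = 10) {
  setNames(rep(value, 18), populationNames())
}

test_that("feature columns follow the sum/diff construction", {
  r1 <- flatRates(10)                 # equal channels -> all diffs zero
  r2 <- flatRates(10)
  r2[c("Th-L", "Th-R")] <- c(30, 14)  # Th_sum 44, Th_diff 16
  ts <- rateTraceSet(list(
    list(config = defaultNetworkConfig(), trials = list(constTrial(r1))),
    list(config = defaultNetworkConfig(), trials = list(constTrial(r2)))),
    binWidth = 10)
  F <- buildFeatureMatrix(ts)
  expect_identical(colnames(F), featureNames())
  expect_true(all(F[1, grepl("_diff$", colnames(F))] == 0))
  expect_equal(unname(F[1, "Cx_sum"]), 20)
  expect_equal(unname(F[2, "Th_sum"]), 44)
  expect_equal(unname(F[2, "Th_diff"]), 16)
  expect_equal(unname(F[2, "CxI"]), 10)

  # doubling both channels doubles the sum and keeps the diff fixed
  r3 <- r2; r3[c("Th-L", "Th-R")] <- 2 * r2[c("Th-L", "Th-R")] - c(0, 14 * 1)
  r3[c("Th-L", "Th-R")] <- c(60, 28)
  ts3 <- rateTraceSet(list(config = defaultNetworkConfig(),
                           trials = list(constTrial(r3))), binWidth = 10)
  F3 <- buildFeatureMatrix(ts3)
  expect_equal(unname(F3[1, "Th_sum"]), unname(2 * F[2, "Th_sum"]))
  expect_equal(unname(F3[1, "Th_diff"]), unname(2 * F[2, "Th_diff"]))
})

test_that("channel swap fixes sums and negates differences exactly", {
  ts <- smallTraces()
  F <- buildFeatureMatrix(ts)
  Fs <- buildFeatureMatrix(swapTraceChannels(ts))
  sums <- !grepl("_diff$", colnames(F))
  expect_equal(Fs[, sums], F[, sums])
  expect_equal(Fs[, !sums], -F[, !sums])
})

test_that("an exact linear activity-to-parameter map yields unit canonical correlations", {
  set.seed(41)
  F <- matrix(rnorm(60 * 18), 60, 18, dimnames = list(NULL, featureNames()))
  B <- matrix(rnorm(18 * 4), 18, 4)
  D <- F %*% B
  colnames(D) <- c("a", "v", "t", "z")
  m <- fitCca(F, D)
  expect_true(all(abs(m@cors - 1) < 1e-6))
})

test_that("a planted correlated factor is recovered at its strength", {
  set.seed(43)
  n <- 200
  shared <- rnorm(n)
  rho <- 0.8
  F <- matrix(rnorm(n * 18), n, 18, dimnames = list(NULL, featureNames()))
  F[, 1] <- sqrt(rho) * shared + sqrt(1 - rho) * rnorm(n)
  D <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, c("a", "v", "t", "z")))
  D[, 1] <- sqrt(rho) * shared + sqrt(1 - rho) * rnorm(n)
  m <- fitCca(F, D)
  expect_lt(abs(m@cors[1] - rho), 0.05)
})

test_that("the CCA agrees with brute-force and reference solutions on a 5-feature toy", {
  set.seed(47)
  n <- 120
  F <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, c("A_sum", "A_diff", "B_sum", "B_diff",
                                      "C")))
  D <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "v", "t")))
  D[, 2] <- D[, 2] + 0.9 * F[, 2]
  m <- fitCca(F, D, k = 3)
  bf <- bruteForceCca(F, D)
  expect_equal(m@cors, bf$cors[1:3], tolerance = 1e-6)
  cc <- cancor(scale(F), scale(D))
  expect_equal(m@cors, cc$cor[1:3], tolerance = 1e-6)
  # loadings agree with the brute-force eigenvectors up to sign and scale
  for (j in 1:3) {
    u <- m@U[, j]; ub <- bf$U[, j]
    expect_gt(abs(cor(u, ub)), 1 - 1e-6)
  }
})

test_that("CCA correlations are invariant to affine rescaling of input columns", {
  set.seed(53)
  F <- matrix(rnorm(80 * 18), 80, 18, dimnames = list(NULL, featureNames()))
  D <- matrix(rnorm(80 * 4), 80, 4, dimnames = list(NULL, c("a", "v", "t", "z")))
  D[, 1] <- D[, 1] + 0.5 * F[, 3]
  m1 <- fitCca(F, D)
  F2 <- F; F2[, 3] <- 100 * F[, 3] - 7
  D2 <- D; D2[, 1] <- -2 * D[, 1] + 11
  m2 <- fitCca(F2, D2)
  expect_equal(m1@cors, m2@cors, tolerance = 1e-8)
})

test_that("planted loading patterns receive the right ensemble labels", {
  U <- matrix(0.01, 18, 3, dimnames = list(featureNames(), NULL))
  V <- matrix(0.01, 4, 3, dimnames = list(c("a", "v", "t", "z"), NULL))
  U[grepl("_diff$", rownames(U)), 1] <- 1        # choice: diff mass
  V["v", 1] <- 1.5
  U[c("Th_sum", "dSPN_sum", "Cx_sum"), 2] <- 1   # responsiveness
  V["a", 2] <- -0.8; V["t", 2] <- -0.5           # a, t same sign
  U[c("iSPN_sum", "STN_sum", "GPeA_sum"), 3] <- 1  # pliancy
  V["a", 3] <- 0.8; V["t", 3] <- -0.5            # a, t opposite signs
  mk <- function(U, V) new("EnsembleModel", U = U, V = V,
                           cors = c(0.9, 0.8, 0.7),
                           labels = rep(NA_character_, 3),
                           lowConfidence = FALSE,
                           featureCenter = setNames(rep(0, 18), featureNames()),
                           featureScale = setNames(rep(1, 18), featureNames()),
                           ddmCenter = setNames(rep(0, 4), rownames(V)),
                           ddmScale = setNames(rep(1, 4), rownames(V)))
  m <- labelComponents(mk(U, V))
  expect_identical(m@labels, c("choice", "responsiveness", "pliancy"))
  expect_false(m@lowConfidence)

  # permuting the components permutes but does not change the labels
  perm <- c(3, 1, 2)
  mp <- labelComponents(mk(U[, perm], V[, perm]))
  expect_identical(mp@labels, c("pliancy", "choice", "responsiveness"))

  # flipping a component's sign leaves its label unchanged
  U2 <- U; V2 <- V; U2[, 2] <- -U2[, 2]; V2[, 2] <- -V2[, 2]
  mf <- labelComponents(mk(U2, V2))
  expect_identical(mf@labels, m@labels)
})

test_that("drives are zero for constant rates and reproduce selector projections", {
  r <- flatRates(10)
  ts <- rateTraceSet(list(config = defaultNetworkConfig(),
                          trials = list(constTrial(r))), binWidth = 10)
  U <- matrix(0, 18, 3, dimnames = list(featureNames(), NULL))
  U[1, 1] <- 1; U[3, 2] <- 1; U[5, 3] <- 1
  model <- new("EnsembleModel", U = U,
               V = matrix(0, 4, 3, dimnames = list(c("a", "v", "t", "z"),
                                                   NULL)),
               cors = c(1, 1, 1), labels = c("choice", "responsiveness",
                                             "pliancy"),
               lowConfidence = FALSE,
               featureCenter = setNames(rep(0, 18), featureNames()),
               featureScale = setNames(rep(1, 18), featureNames()),
               ddmCenter = setNames(rep(0, 4), c("a", "v", "t", "z")),
               ddmScale = setNames(rep(1, 4), c("a", "v", "t", "z")))
  dr <- driveTimeseries(ts, model)
  expect_true(all(vapply(dr$trials, function(x) all(x$W == 0), logical(1))))

  # a selector column reproduces the raw increment of the selected feature
  pops <- populationNames()
  m <- matrix(10, 18, 4, dimnames = list(pops, NULL))
  m["Cx-L", ] <- c(10, 12, 15, 19)   # Cx_sum increments: 2, 3, 4
  tr <- list(rates = m, decisionTime = 30, choice = "left",
             phaseMarks = c(stimOnset = 1L, decision = 4L,
                            consolidationEnd = 4L), seed = 1L)
  ts2 <- rateTraceSet(list(config = defaultNetworkConfig(),
                           trials = list(tr)), binWidth = 10)
  dr2 <- driveTimeseries(ts2, model)
  W <- dr2$trials[[1]]$W
  expect_equal(unname(W[, "choice"]), c(0, 2, 3, 4))  # Cx_sum selector
})

test_that("a hand-built three-bin trial projects by plain matrix arithmetic", {
  pops <- populationNames()
  m <- matrix(5, 18, 3, dimnames = list(pops, NULL))
  m["Th-L", ] <- c(10, 20, 40)
  m["Th-R", ] <- c(10, 15, 20)
  tr <- list(rates = m, decisionTime = 20, choice = "left",
             phaseMarks = c(stimOnset = 1L, decision = 3L,
                            consolidationEnd = 3L), seed = 1L)
  ts <- rateTraceSet(list(config = defaultNetworkConfig(),
                          trials = list(tr)), binWidth = 10)
  U <- matrix(0, 18, 3, dimnames = list(featureNames(), NULL))
  U["Th_sum", 1] <- 2; U["Th_diff", 2] <- -1; U["Th_sum", 3] <- 1
  U["Th_diff", 3] <- 1
  model <- new("EnsembleModel", U = U,
               V = matrix(0, 4, 3, dimnames = list(c("a", "v", "t", "z"),
                                                   NULL)),
               cors = c(1, 1, 1),
               labels = c("choice", "responsiveness", "pliancy"),
               lowConfidence = FALSE,
               featureCenter = setNames(rep(0, 18), featureNames()),
               featureScale = setNames(rep(1, 18), featureNames()),
               ddmCenter = setNames(rep(0, 4), c("a", "v", "t", "z")),
               ddmScale = setNames(rep(1, 4), c("a", "v", "t", "z")))
  W <- driveTimeseries(ts, model)$trials[[1]]$W
  # Th_sum: 20, 35, 60 -> increments 0, 15, 25; Th_diff: 0, 5, 20 ->
  # increments 0, 5, 15
  expect_equal(unname(W[, 1]), c(0, 30, 50))
  expect_equal(unname(W[, 2]), c(0, -5, -15))
  expect_equal(unname(W[, 3]), c(0, 20, 40))
})

test_that("zone projection is linear and vanishes for zero activity change", {
  report <- deskReport()
  zp <- report$zoneProjection
  expect_true(all(c("parameters", "drives", "pairs") %in% names(zp)))
  pr <- zp$pairs[[1]]
  # P = W V^T exactly, and dF = 0 implies P = 0
  expect_equal(pr$P, pr$W %*% t(report$model@V), tolerance = 1e-12)
  zeroP <- (matrix(0, 1, 18) %*% report$model@U) %*% t(report$model@V)
  expect_true(all(zeroP == 0))
  # toy double product with known entries
  U <- matrix(c(1, 2), 2, 1); V <- matrix(c(3, 4), 2, 1)
  dF <- matrix(c(5, 6), 1, 2)
  expect_equal((dF %*% U) %*% t(V), matrix(c(51, 68), 1, 2))
})

test_that("mirrored traces flip the drift-rate sign of mirrored zone transitions", {
  report <- deskReport()
  p <- report$zoneProjection$parameters
  vIIII <- p[p$zone_from == "I" & p$zone_to == "III" & p$parameter == "v", ]
  vIIV <- p[p$zone_from == "I" & p$zone_to == "IV" & p$parameter == "v", ]
  expect_gt(nrow(vIIII), 0)
  expect_gt(nrow(vIIV), 0)
  expect_lt(sign(vIIII$median_change) * sign(vIIV$median_change), 0)
})
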