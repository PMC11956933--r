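# 32-bit helpers on doubles (16-bit limb arithmetic keeps every product
# inside exact double range).
.xor32 <- function(a, b) {
  bitwXor(a %% 65536, b %% 65536) +
    bitwXor(a %/% 65536, b %/% 65536) * 65536
}
.mul32 <- function(a, b) {
  al <- a %% 65536; ah <- a %/% 65536
  (al * b + ((ah * (b %% 65536)) %% 65536) * 65536 +
     ((ah * (b %/% 65536)) %% 1) ) %% 4294967296
}
# splitmix-style avalanche finalizer: nearby inputs map to well-scattered
# outputs, so derived sub-seeds behave like arbitrary independent seeds.
.mix32 <- function(x) {
  z <- (x + 2654435769) %% 4294967296
  z <- .mul32(.xor32(z, z %/% 65536), 569420461)
  z <- .mul32(.xor32(z, z %/% 32768), 1935289751)
  .xor32(z, z %/% 32768)
}

# Deterministic seed derivation for named substreams.  A plain polynomial
# accumulator would hand consecutive indices consecutive seeds, whose
# generator streams are correlated in their first draws; the avalanche mix
# removes that structure.
.deriveSeed <- function(seed, ...) {
  h <- as.numeric(seed) %% 4294967296
  for (tok in list(...)) {
    tok <- if (is.character(tok)) sum(utf8ToInt(tok)) else as.numeric(tok)
    h <- .mix32((h + tok) %% 4294967296)
  }
  as.integer(.mix32(h) %% 2147483647)
}

# Saturating non-negative transfer function.
.phi <- function(x, rmax) pmin(pmax(x, 0), rmax)

#' Simulate a single two-choice trial
#'
#' Integrates the noisy leaky rate equations
#' \deqn{r_i(t + dt) = r_i(t) + (dt/\tau_i)(-r_i + \phi(\sum_j W_{ij} r_j +
#' I_i)) + \sigma_i \sqrt{dt}\,\xi} with \eqn{\phi} a non-negative
#' saturating transfer, from the pre-stimulus baseline through the decision
#' phase and, after a choice, a consolidation phase (partial cortical input
#' sustained to the selected channel) and an inter-trial interval.  A choice
#' is made when the binned rate of a thalamic population first reaches the
#' decision threshold; if neither channel crosses within the timeout the
#' trial is a timeout (\code{choice = "none"}).
#'
#' @param config A \linkS4class{NetworkConfig}.
#' @param seed Integer seed; identical (config, seed) give bit-identical
#'   trials.
#' @return A trial record (see \linkS4class{RateTraceSet}).
#' @examples
#' tr <- simulateTrial(defaultNetworkConfig(), seed = 1)
#' tr$decisionTime; tr$choice
#' @export
simulateTrial <- function(config, seed = config@seed) {
  validObject(config)
  set.seed(as.integer(seed))
  pops <- populationNames()
  n <- length(pops)
  W <- .weightMatrix(config)
  I0 <- .baselineInputs(config, W)
  dt <- config@dtSim
  stepsPerBin <- as.integer(config@binWidth / dt)
  tauFac <- dt / config@tau
  noiseFac <- config@noiseSd * sqrt(dt)
  rmax <- config@rmax

  onsetBins <- as.integer(ceiling(config@stimulus$onset / config@binWidth))
  maxDecBins <- as.integer(ceiling(config@timeout / config@binWidth))
  consBins <- as.integer(ceiling(config@consolidation / config@binWidth))
  itiBins <- as.integer(ceiling(config@iti / config@binWidth))

  stimVec <- function(phase, winner = NULL) {
    s <- numeric(n)
    amp <- config@stimulus$amplitude
    if (phase == "decision") {
      s[match(c("Cx-L", "Cx-R"), pops)] <- c(amp[["left"]], amp[["right"]])
    } else if (phase == "consolidation" && !is.null(winner)) {
      key <- if (winner == "left") "Cx-L" else "Cx-R"
      s[match(key, pops)] <- config@consolidationGain *
        amp[[if (winner == "left") "left" else "right"]]
    }
    s
  }

  r <- config@baselineRates
  thIdx <- match(c("Th-L", "Th-R"), pops)
  totalBins <- onsetBins + maxDecBins + consBins + itiBins
  rates <- matrix(NA_real_, n, totalBins, dimnames = list(pops, NULL))

  runBin <- function(r, I, bin) {
    acc <- numeric(n)
    noise <- matrix(stats::rnorm(n * stepsPerBin), n, stepsPerBin) * noiseFac
    for (s in seq_len(stepsPerBin)) {
      drive <- .phi(drop(W %*% r) + I, rmax)
      r <- r + tauFac * (drive - r) + noise[, s]
      r <- pmin(pmax(r, 0), rmax)
      acc <- acc + r
    }
    m <- acc / stepsPerBin
    if (any(!is.finite(m))) {
      bad <- pops[which(!is.finite(m))[1]]
      stop(sprintf("integration failure: non-finite rate in %s at bin %d",
                   bad, bin))
    }
    list(r = r, mean = m)
  }

  bin <- 0L
  for (b in seq_len(onsetBins)) {
    bin <- bin + 1L
    st <- runBin(r, I0, bin); r <- st$r; rates[, bin] <- st$mean
  }

  Idec <- I0 + stimVec("decision")
  decisionBin <- NA_integer_; choice <- "none"; decisionTime <- NA_real_
  for (b in seq_len(maxDecBins)) {
    bin <- bin + 1L
    st <- runBin(r, Idec, bin); r <- st$r; rates[, bin] <- st$mean
    th <- st$mean[thIdx]
    if (any(th >= config@decisionThreshold)) {
      decisionBin <- bin
      choice <- if (th[1] >= th[2]) "left" else "right"
      decisionTime <- b * config@binWidth
      break
    }
  }

  if (!is.na(decisionBin)) {
    Icons <- I0 + stimVec("consolidation", choice)
    for (b in seq_len(consBins)) {
      bin <- bin + 1L
      st <- runBin(r, Icons, bin); r <- st$r; rates[, bin] <- st$mean
    }
  }
  for (b in seq_len(itiBins)) {
    bin <- bin + 1L
    st <- runBin(r, I0, bin); r <- st$r; rates[, bin] <- st$mean
  }

  list(rates = rates[, seq_len(bin), drop = FALSE],
       decisionTime = decisionTime,
       choice = choice,
       phaseMarks = c(stimOnset = onsetBins,
                      decision = ifelse(is.na(decisionBin), 0L, decisionBin),
                      consolidationEnd = ifelse(is.na(decisionBin), 0L,
                                                decisionBin + consBins)),
       seed = as.integer(seed))
}

#' Simulate a batch of trials for one network
#'
#' Runs \code{\link{simulateTrial}} \code{nTrials} times with per-trial
#' sub-seeds derived deterministically from \code{seed}, so the same
#' (config, nTrials, seed) always yields bit-identical output and trial
#' \code{i} can be reproduced in isolation via
#' \code{simulateTrial(config, trialSeed(seed, i))}.
#'
#' @param config A \linkS4class{NetworkConfig}.
#' @param nTrials Number of trials (>= 1); the study default is 50 per
#'   network.
#' @param seed Integer master seed.
#' @return A \linkS4class{RateTraceSet} with one network entry.
#' @export
runExperiment <- function(config, nTrials = 50, seed = config@seed) {
  if (nTrials < 1) stop("nTrials must be >= 1")
  trials <- vector("list", nTrials)
  for (i in seq_len(nTrials)) {
    trials[[i]] <- tryCatch(
      simulateTrial(config, trialSeed(seed, i)),
      error = function(e) stop(sprintf("trial %d: %s", i, conditionMessage(e)),
                               call. = FALSE))
  }
  rateTraceSet(list(config = config, trials = trials),
               binWidth = config@binWidth)
}

#' Per-trial sub-seed used by \code{\link{runExperiment}}
#' @param seed Master seed.
#' @param i Trial index.
#' @return Integer sub-seed.
#' @export
trialSeed <- function(seed, i) .deriveSeed(seed, "trial", i)

#' Sample network configurations around the default
#'
#' Draws configurations by jittering the 13 searchable synaptic weights
#' multiplicatively (uniform in \code{1 +/- jitter}), preserving signs, and
#' optionally keeps only configurations passing the feasibility screen used
#' by the genetic search (population mean rates within target ranges, no
#' timeouts in the screening trials, positive cortex-striatum correlation).
#'
#' @param n Number of configurations to return.
#' @param seed Integer seed.
#' @param jitter Relative weight jitter (default 0.12).
#' @param screen Logical; apply the feasibility screen.
#' @param nScreenTrials Trials per screening evaluation.
#' @param targets Rate target ranges (see \code{\link{defaultRateTargets}}).
#' @param maxDraws Maximum candidate draws before giving up.
#' @return List of \code{n} \linkS4class{NetworkConfig} objects.
#' @export
sampleNetworks <- function(n, seed = 1L, jitter = 0.12, screen = TRUE,
                           nScreenTrials = 10L,
                           targets = defaultRateTargets(),
                           maxDraws = 10L * n) {
  out <- vector("list", n)
  kept <- 0L; draws <- 0L
  while (kept < n && draws < maxDraws) {
    draws <- draws + 1L
    set.seed(.deriveSeed(seed, "network", draws))
    fac <- stats::runif(length(.searchableKeys), 1 - jitter, 1 + jitter)
    w <- .defaultWeights()[.searchableKeys] * fac
    cfg <- defaultNetworkConfig(weights = w,
                                seed = .deriveSeed(seed, "netseed", draws))
    ok <- TRUE
    if (screen) {
      ev <- evaluateConfig(cfg, targets, nTrials = nScreenTrials,
                           seed = .deriveSeed(seed, "screen", draws))
      ok <- ev$feasible
    }
    if (ok) {
      kept <- kept + 1L
      out[[kept]] <- cfg
    }
  }
  if (kept < n)
    stop(sprintf("only %d of %d feasible configurations found in %d draws",
                 kept, n, draws))
  out
}
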