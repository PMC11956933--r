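#' Default target firing-rate ranges for the feasibility screen
#'
#' Acceptable ranges (Hz) for the per-population mean firing rate over the
#' analysis window (trial start to decision).  Pallidal output populations
#' (GPeP, GPi) must sit high, striatal and arkypallidal populations low,
#' matching the resting regimes of the circuit.
#'
#' @return Named list of length-2 numeric ranges keyed by region.
#' @export
defaultRateTargets <- function() {
  list(Cx = c(2, 40), CxI = c(2, 40), FSI = c(2, 40),
       dSPN = c(0.5, 30), iSPN = c(0.5, 30),
       GPeP = c(30, 90), GPeA = c(0.5, 30),
       STN = c(5, 45), GPi = c(30, 95), Th = c(3, 35))
}

#' Evaluate a configuration against the feasibility constraints
#'
#' Simulates \code{nTrials} trials and checks the three feasibility
#' predicates used to admit a network into the study set: every
#' population's mean rate (over bins up to the decision) inside its target
#' range, timeout fraction below 1\%, and positive correlation between
#' trial-mean cortical and trial-mean striatal (dSPN + iSPN) activity.
#'
#' @param config A \linkS4class{NetworkConfig}.
#' @param targets Target ranges as from \code{\link{defaultRateTargets}}.
#' @param nTrials Number of evaluation trials.
#' @param seed Integer seed.
#' @return List with elements \code{feasible}, \code{fitness} (0 at the
#'   range midpoints, more negative with violations), \code{meanRates},
#'   \code{timeoutFraction}, \code{corCxStriatum}, \code{violations}.
#' @export
evaluateConfig <- function(config, targets = defaultRateTargets(),
                           nTrials = 10L, seed = 1L) {
  ts <- runExperiment(config, nTrials = nTrials, seed = seed)
  trials <- networkTrials(ts, 1L)
  pops <- cbgtPopulations()

  perTrialMeans <- vapply(trials, function(tr) {
    bins <- .analysisBins(tr)
    if (is.null(bins)) bins <- seq_len(ncol(tr$rates))
    rowMeans(tr$rates[, bins, drop = FALSE])
  }, numeric(nrow(pops)))
  meanRates <- rowMeans(perTrialMeans)

  timeoutFraction <- mean(vapply(trials, function(tr) tr$choice == "none",
                                 logical(1)))
  cxIdx <- pops$region == "Cx"
  strIdx <- pops$region %in% c("dSPN", "iSPN")
  cxTrial <- colMeans(perTrialMeans[cxIdx, , drop = FALSE])
  strTrial <- colMeans(perTrialMeans[strIdx, , drop = FALSE])
  corCxStr <- if (stats::sd(cxTrial) > 0 && stats::sd(strTrial) > 0)
    stats::cor(cxTrial, strTrial) else 0

  violations <- 0L; dist <- 0
  for (i in seq_len(nrow(pops))) {
    rng <- targets[[pops$region[i]]]
    m <- meanRates[i]
    if (m < rng[1] || m > rng[2]) violations <- violations + 1L
    mid <- mean(rng); half <- diff(rng) / 2
    if (is.finite(half) && half > 0) dist <- dist + abs(m - mid) / half
  }
  if (timeoutFraction >= 0.01) violations <- violations + 1L
  if (!(corCxStr > 0)) violations <- violations + 1L

  list(feasible = violations == 0L,
       fitness = -(violations * 1000 + dist),
       meanRates = meanRates,
       timeoutFraction = timeoutFraction,
       corCxStriatum = corCxStr,
       violations = violations)
}

#' Genetic search over the 13 searchable synaptic weights
#'
#' A simple generational genetic algorithm (tournament selection, uniform
#' crossover, Gaussian mutation clipped to bounds) over the searchable
#' weight keys, maximizing the feasibility fitness of
#' \code{\link{evaluateConfig}}.  All evaluated candidates are pooled and
#' the best \code{nKeep} feasible configurations are returned, sorted by
#' fitness.
#'
#' @param bounds Named list over \code{\link{searchableWeights}} keys (or a
#'   subset, for toy searches) of length-2 numeric (lo, hi) intervals.
#' @param targets Rate targets passed to the evaluator.
#' @param popSize Individuals per generation.
#' @param generations Number of generations.
#' @param nKeep Maximum number of configurations to return.
#' @param seed Integer seed.
#' @param evalFun Optional evaluator \code{function(weights, seed)}
#'   returning \code{list(feasible, fitness)}; defaults to building a
#'   \linkS4class{NetworkConfig} with the candidate weights and running
#'   \code{evaluateConfig}.  A custom evaluator also permits searches over
#'   fewer than 13 weights.
#' @param nEvalTrials Trials per default evaluation.
#' @param mutationSd Mutation scale as a fraction of each bound width.
#' @return List of \linkS4class{NetworkConfig} (or, under a custom
#'   \code{evalFun}, of weight vectors) sorted by decreasing fitness, with
#'   fitness attached as attribute \code{"fitness"}.  If no candidate is
#'   feasible, an empty list with attribute \code{"report"} describing the
#'   best infeasible candidate.
#' @export
geneticSearch <- function(bounds, targets = defaultRateTargets(),
                          popSize = 16L, generations = 4L, nKeep = 10L,
                          seed = 1L, evalFun = NULL, nEvalTrials = 8L,
                          mutationSd = 0.15) {
  keys <- names(bounds)
  customEval <- !is.null(evalFun)
  if (!customEval && !setequal(keys, .searchableKeys))
    stop("bounds must cover exactly the 13 searchable weights")
  if (nKeep > popSize * generations)
    stop("nKeep must not exceed popSize * generations")
  lo <- vapply(bounds, `[`, numeric(1), 1L)
  hi <- vapply(bounds, `[`, numeric(1), 2L)
  if (any(hi < lo)) stop("bounds must satisfy lo <= hi")

  if (is.null(evalFun)) {
    evalFun <- function(weights, s) {
      cfg <- defaultNetworkConfig(weights = weights)
      ev <- evaluateConfig(cfg, targets, nTrials = nEvalTrials, seed = s)
      ev$config <- cfg
      ev
    }
  }

  set.seed(.deriveSeed(seed, "ga-init"))
  pop <- lapply(seq_len(popSize), function(i)
    setNames(stats::runif(length(keys), lo, hi), keys))

  archive <- list()
  evalCount <- 0L
  evalAll <- function(pop) {
    lapply(pop, function(w) {
      evalCount <<- evalCount + 1L
      ev <- evalFun(w, .deriveSeed(seed, "ga-eval", evalCount))
      ev$weights <- w
      archive[[length(archive) + 1L]] <<- ev
      ev
    })
  }

  evals <- evalAll(pop)
  for (g in seq_len(generations - 1L)) {
    set.seed(.deriveSeed(seed, "ga-gen", g))
    fit <- vapply(evals, function(e) e$fitness, numeric(1))
    tournament <- function() {
      cand <- sample.int(popSize, 2L)
      pop[[cand[which.max(fit[cand])]]]
    }
    newPop <- lapply(seq_len(popSize), function(i) {
      p1 <- tournament(); p2 <- tournament()
      mask <- stats::runif(length(keys)) < 0.5
      child <- ifelse(mask, p1, p2)
      child <- child + stats::rnorm(length(keys), 0, mutationSd * (hi - lo))
      setNames(pmin(pmax(child, lo), hi), keys)
    })
    pop <- newPop
    evals <- evalAll(pop)
  }

  fitAll <- vapply(archive, function(e) e$fitness, numeric(1))
  feas <- vapply(archive, function(e) isTRUE(e$feasible), logical(1))
  if (!any(feas)) {
    best <- archive[[which.max(fitAll)]]
    out <- list()
    attr(out, "report") <- best
    return(out)
  }
  ord <- order(fitAll, decreasing = TRUE)
  ord <- ord[feas[ord]][seq_len(min(nKeep, sum(feas)))]
  out <- lapply(archive[ord], function(e)
    if (!is.null(e$config)) e$config else e$weights)
  attr(out, "fitness") <- fitAll[ord]
  out
}
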