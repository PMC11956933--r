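# Shared fixtures and independent oracles for the test suite.  The larger
# simulated sets are memoized so several test files can share one run.

.fixtureCache <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# A small multi-network simulated set for module-level tests.
smallTraces <- function() memoize("smallTraces", {
  cfgs <- sampleNetworks(4, seed = 11, screen = FALSE)
  combineTraceSets(lapply(seq_along(cfgs), function(i)
    runExperiment(cfgs[[i]], nTrials = 12, seed = 300 + i)))
})

# Desk-scale end-to-end run shared by the acceptance checks.
deskReport <- function() memoize("deskReport", {
  runPipeline(pipelineConfig(nNetworks = 30, nTrials = 50, seed = 42,
                             outDir = NULL))
})

# Fast config for behavioural statistics: no post-decision phases.
quickConfig <- function(...) {
  defaultNetworkConfig(consolidation = 0, iti = 0, ...)
}

# Uniform thresholds matching the scripted-trace generator defaults.
flatThresholds <- function(value = 20) {
  new("BinarizationThresholds",
      table = data.frame(population = populationNames(),
                         threshold_hz = value, rule = "high90",
                         stringsAsFactors = FALSE),
      network = 1L)
}

# Independent pair-count oracle for transition estimation (loops, no rle).
bruteForceTransitions <- function(labelLists, mode) {
  trans <- list(); ends <- list()
  bump <- function(env, key) {
    cur <- if (is.null(env[[key]])) 0L else env[[key]]
    env[[key]] <- cur + 1L
  }
  tEnv <- new.env(); eEnv <- new.env()
  for (lab in labelLists) {
    if (mode == "per_change") {
      collapsed <- lab[1]
      for (k in seq_along(lab)[-1])
        if (lab[k] != collapsed[length(collapsed)])
          collapsed <- c(collapsed, lab[k])
      lab <- collapsed
    }
    if (length(lab) > 1L)
      for (k in seq_len(length(lab) - 1L))
        bump(tEnv, paste(lab[k], lab[k + 1L]))
    bump(eEnv, as.character(lab[length(lab)]))
  }
  tKeys <- ls(tEnv)
  edges <- if (length(tKeys)) {
    parts <- strsplit(tKeys, " ")
    data.frame(from = as.integer(vapply(parts, `[`, "", 1)),
               to = as.integer(vapply(parts, `[`, "", 2)),
               count = vapply(tKeys, function(k) tEnv[[k]], integer(1)))
  } else data.frame(from = integer(0), to = integer(0), count = integer(0))
  eKeys <- ls(eEnv)
  ends <- data.frame(state = as.integer(eKeys),
                     count = vapply(eKeys, function(k) eEnv[[k]], integer(1)))
  tot <- function(st) {
    o <- sum(edges$count[edges$from == st])
    e <- sum(ends$count[ends$state == st])
    o + e
  }
  edges$probability <- mapply(function(f, c) c / tot(f), edges$from,
                              edges$count)
  ends$probability <- mapply(function(s, c) c / tot(s), ends$state,
                             ends$count)
  list(edges = edges[order(edges$from, edges$to), ],
       ends = ends[order(ends$state), ])
}

# Wrap raw label vectors as sequence records.
asSequences <- function(labelLists, choice = "left", dt = 100) {
  lapply(seq_along(labelLists), function(i)
    list(network = 1L, trial = i, labels = as.integer(labelLists[[i]]),
         aux = matrix(0L, 4, length(labelLists[[i]]),
                      dimnames = list(auxPopulations(), NULL)),
         choice = choice, decisionTime = dt))
}

# Brute-force CCA oracle: generalized eigensolution of the whitened
# cross-covariance, built from plain solve()/eigen() calls.
bruteForceCca <- function(F, D) {
  X <- scale(F); Y <- scale(D)
  n <- nrow(X)
  Sxx <- crossprod(X) / (n - 1); Syy <- crossprod(Y) / (n - 1)
  Sxy <- crossprod(X, Y) / (n - 1)
  M <- solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy)
  ev <- eigen(M)
  cors <- sqrt(pmax(Re(ev$values), 0))
  list(cors = cors, U = Re(ev$vectors))
}
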