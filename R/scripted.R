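#' Generate a trial whose binarization is known by construction
#'
#' Emits a rate trace in which each encoded population sits a fixed margin
#' above (bit 1) or below (bit 0) its binarization threshold according to a
#' script of state patterns with dwell times, so that thresholding recovers
#' the scripted Boolean sequence exactly.  In the final bin the active
#' thalamic population is raised to at least the decision threshold (30 Hz)
#' so the trial closes.
#'
#' @param script List of steps, each \code{list(pattern, dwell)} where
#'   \code{pattern} is either an integer state label or a named 0/1 vector
#'   over \code{\link{encodedPopulations}}, and \code{dwell} is the number
#'   of 10 ms bins (>= 1) the pattern is held.
#' @param thresholds Named numeric of per-population binarization
#'   thresholds (Hz); defaults to 20 Hz for every population.
#' @param margin Distance (Hz) of emitted rates from the threshold.
#' @param auxPattern Optional named 0/1 vector over
#'   \code{\link{auxPopulations}} applied to every bin.
#' @param choice Optional choice override; by default taken from the
#'   thalamic bits of the final pattern (left wins ties).
#' @return A trial record as in \linkS4class{RateTraceSet}.
#' @examples
#' tr <- generateScriptedTraces(list(list(pattern = 60, dwell = 3),
#'                                   list(pattern = 63, dwell = 2)))
#' @export
generateScriptedTraces <- function(script,
                                   thresholds = NULL,
                                   margin = 5,
                                   auxPattern = NULL,
                                   choice = NULL) {
  if (length(script) == 0L) stop("script must contain at least one step")
  pops <- populationNames()
  if (is.null(thresholds)) thresholds <- setNames(rep(20, length(pops)), pops)
  missingThr <- setdiff(pops, names(thresholds))
  thr <- setNames(rep(20, length(pops)), pops)
  thr[names(thresholds)] <- thresholds

  patterns <- lapply(script, function(step) {
    p <- step$pattern
    if (is.numeric(p) && length(p) == 1L) p <- decodeState(p)
    if (!is.null(names(p))) p <- p[encodedPopulations()]
    if (length(p) != 10L || anyNA(p))
      stop("each pattern must cover the 10 encoded populations")
    as.integer(as.logical(p))
  })
  dwells <- vapply(script, function(step) as.integer(step$dwell), integer(1))
  if (any(dwells < 1L)) stop("dwell bins must be >= 1")

  nbins <- sum(dwells)
  rates <- matrix(0, length(pops), nbins, dimnames = list(pops, NULL))
  for (p in pops) rates[p, ] <- max(thr[[p]] - margin, 0)
  if (!is.null(auxPattern)) {
    for (a in names(auxPattern)) if (auxPattern[[a]] == 1)
      rates[a, ] <- thr[[a]] + margin
  }

  bin <- 0L
  for (k in seq_along(patterns)) {
    pat <- setNames(patterns[[k]], encodedPopulations())
    for (b in seq_len(dwells[k])) {
      bin <- bin + 1L
      for (p in encodedPopulations()) {
        rates[p, bin] <- if (pat[[p]] == 1) thr[[p]] + margin
                         else max(thr[[p]] - margin, 0)
      }
    }
  }

  finalPat <- setNames(patterns[[length(patterns)]], encodedPopulations())
  for (p in c("Th-L", "Th-R")) if (finalPat[[p]] == 1)
    rates[p, nbins] <- max(thr[[p]] + margin, 30 + margin)

  if (is.null(choice)) {
    choice <- if (finalPat[["Th-L"]] == 1) "left"
              else if (finalPat[["Th-R"]] == 1) "right" else "none"
  }

  list(rates = rates,
       decisionTime = nbins * 10,
       choice = choice,
       phaseMarks = c(stimOnset = 0L, decision = nbins,
                      consolidationEnd = nbins),
       seed = NA_integer_)
}

#' Wrap scripted trials into a RateTraceSet
#'
#' @param scripts List of scripts (each as in
#'   \code{\link{generateScriptedTraces}}).
#' @param thresholds,margin,auxPattern Passed through to the generator.
#' @param config Carrier configuration (defaults to
#'   \code{defaultNetworkConfig()}).
#' @return A single-network \linkS4class{RateTraceSet}.
#' @export
scriptedTraceSet <- function(scripts, thresholds = NULL, margin = 5,
                             auxPattern = NULL,
                             config = defaultNetworkConfig()) {
  trials <- lapply(scripts, generateScriptedTraces, thresholds = thresholds,
                   margin = margin, auxPattern = auxPattern)
  rateTraceSet(list(config = config, trials = trials), binWidth = 10)
}
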