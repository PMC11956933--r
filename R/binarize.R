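#' Pooled firing-rate histograms per population
#'
#' Pools one network's binned rates over all non-timeout trials, using only
#' bins up to each trial's decision, and builds one histogram per
#' population with Freedman-Diaconis bin widths (floored at 1 Hz).  Each
#' histogram also records the population's baseline rate (mean over
#' pre-stimulus bins), its rate close to decision times (mean over the last
#' \code{kNear} bins before the decision) and a modality call (unimodal or
#' bimodal) from smoothed counts.
#'
#' @param traces A \linkS4class{RateTraceSet}.
#' @param network Network index to pool (thresholds are estimated per
#'   network).
#' @param kNear Number of pre-decision bins in the near-decision window.
#' @param smoothWidth Moving-average window (bins) for modality detection.
#' @param prominence Minimum peak prominence as a fraction of the tallest
#'   smoothed count.
#' @return Named list (one element per population) of rate histogram
#'   records: \code{population}, \code{breaks}, \code{counts}, \code{mids},
#'   \code{modality}, \code{peaks} (locations of the detected peaks, Hz),
#'   \code{baselineRate}, \code{nearDtRate}.
#' @export
buildHistograms <- function(traces, network = 1L, kNear = 3L,
                            smoothWidth = 5L, prominence = 0.1) {
  trials <- networkTrials(traces, network)
  keep <- vapply(trials, function(tr) tr$choice != "none", logical(1))
  if (!any(keep)) stop("all trials timed out; no histogram can be built")
  trials <- trials[keep]
  pops <- populationNames()

  pooled <- lapply(trials, function(tr)
    tr$rates[, .analysisBins(tr), drop = FALSE])
  baseline <- lapply(trials, function(tr) {
    on <- tr$phaseMarks[["stimOnset"]]
    if (on >= 1) tr$rates[, seq_len(on), drop = FALSE]
    else tr$rates[, 1L, drop = FALSE]
  })
  nearDt <- lapply(trials, function(tr) {
    db <- tr$phaseMarks[["decision"]]
    tr$rates[, seq(max(1L, db - kNear + 1L), db), drop = FALSE]
  })

  out <- lapply(seq_along(pops), function(i) {
    x <- unlist(lapply(pooled, function(m) m[i, ]), use.names = FALSE)
    h <- .rateHistogram(x, smoothWidth, prominence)
    h$population <- pops[i]
    h$baselineRate <- mean(unlist(lapply(baseline, function(m) m[i, ])))
    h$nearDtRate <- mean(unlist(lapply(nearDt, function(m) m[i, ])))
    h
  })
  names(out) <- pops
  out
}

.rateHistogram <- function(x, smoothWidth = 5L, prominence = 0.1) {
  stopifnot(length(x) > 0)
  if (length(unique(x)) == 1L) {
    return(list(breaks = c(x[1] - 0.5, x[1] + 0.5), counts = length(x),
                mids = x[1], modality = "unimodal", peaks = x[1],
                degenerate = TRUE))
  }
  bw <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  # cap so well-separated modes keep enough bins to be resolved
  bw <- min(bw, diff(range(x)) / 15)
  bw <- max(bw, 1)
  breaks <- seq(floor(min(x)), max(x) + bw, by = bw)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  sm <- .movingAverage(h$counts, smoothWidth)
  pk <- .findPeaks(sm, prominence * max(sm))
  list(breaks = h$breaks, counts = h$counts, mids = h$mids,
       modality = if (length(pk) == 2L) "bimodal" else "unimodal",
       peaks = h$mids[pk], degenerate = FALSE)
}

.movingAverage <- function(y, width) {
  if (width <= 1L) return(y)
  k <- rep(1 / width, width)
  as.numeric(stats::filter(y, k, sides = 2, circular = FALSE)) ->
    sm
  # shrink the window at the edges instead of dropping them
  n <- length(y)
  half <- (width - 1L) %/% 2L
  for (i in which(is.na(sm))) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    sm[i] <- mean(y[lo:hi])
  }
  sm
}

# Local maxima of a non-negative series with a simple prominence rule: a
# peak's prominence is its height minus the highest minimum separating it
# from a higher peak (or minus the global minimum for the tallest peak).
.findPeaks <- function(y, minProminence) {
  n <- length(y)
  if (n < 3L) return(which.max(y))
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  if (y[1] > y[2]) cand <- c(1L, cand)
  if (y[n] > y[n - 1L]) cand <- c(cand, n)
  if (!length(cand)) return(which.max(y))
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    higher <- cand[y[cand] > y[i]]
    if (!length(higher)) {
      prom <- y[i] - min(y)
    } else {
      j <- higher[which.min(abs(higher - i))]
      saddle <- min(y[seq(min(i, j), max(i, j))])
      prom <- y[i] - saddle
    }
    keep[k] <- prom >= minProminence
  }
  res <- cand[keep]
  if (!length(res)) res <- cand[which.max(y[cand])]
  # order by height, keep at most the two most salient, report in position order
  if (length(res) > 2L) res <- res[order(y[res], decreasing = TRUE)][1:2]
  sort(res)
}

#' Select the binarization threshold for one population
#'
#' Applies the histogram rule: for a unimodal histogram whose baseline rate
#' exceeds its near-decision rate (populations that dip under drive, such
#' as GPeP and GPi) the threshold sits where the cumulative counts first
#' reach 10\% of the total (\code{low10}); for a unimodal histogram whose
#' activity rises toward the decision (dSPN, iSPN, GPeA) it sits at 90\%
#' (\code{high90}); for a bimodal histogram it is the midpoint between the
#' two detected peaks (\code{bimodal_midpoint}).  Rates above the threshold
#' binarize to 1.
#'
#' @param hist One histogram record from \code{\link{buildHistograms}}.
#' @return list(population, threshold, rule).
#' @export
selectThreshold <- function(hist) {
  if (isTRUE(hist$degenerate)) {
    warning("degenerate histogram (single value) for ",
            hist$population %||% "population", "; threshold set to that value")
    return(list(population = hist$population, threshold = hist$mids[1],
                rule = "degenerate"))
  }
  if (hist$modality == "bimodal" && length(hist$peaks) == 2L) {
    return(list(population = hist$population,
                threshold = mean(hist$peaks), rule = "bimodal_midpoint"))
  }
  frac <- if (hist$baselineRate > hist$nearDtRate) 0.10 else 0.90
  rule <- if (frac == 0.10) "low10" else "high90"
  list(population = hist$population,
       threshold = .cumulativeCut(hist, frac), rule = rule)
}

# Rate at which the cumulative histogram counts first reach frac * total,
# linearly interpolated inside the crossing bin.
.cumulativeCut <- function(hist, frac) {
  total <- sum(hist$counts)
  target <- frac * total
  cum <- cumsum(hist$counts)
  i <- which(cum >= target)[1]
  prev <- if (i > 1L) cum[i - 1L] else 0
  lo <- hist$breaks[i]
  w <- hist$breaks[i + 1L] - hist$breaks[i]
  if (hist$counts[i] == 0) return(lo)
  lo + w * (target - prev) / hist$counts[i]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binarization thresholds for every population of a network
#'
#' @slot table data.frame(population, threshold_hz, rule).
#' @slot network Network index the thresholds were estimated from.
#' @export
setClass("BinarizationThresholds",
         representation(table = "data.frame", network = "integer"))

setValidity("BinarizationThresholds", function(object) {
  tab <- object@table
  if (!all(c("population", "threshold_hz", "rule") %in% names(tab)))
    return("table must have columns population, threshold_hz, rule")
  if (anyDuplicated(tab$population))
    return("each population must have exactly one threshold")
  if (any(!is.finite(tab$threshold_hz)) || any(tab$threshold_hz < 0))
    return("thresholds must be finite and >= 0")
  TRUE
})

setMethod("show", "BinarizationThresholds", function(object) {
  cat("BinarizationThresholds for network", object@network, "\n")
  print(object@table, row.names = FALSE)
})

#' Estimate thresholds for one network
#'
#' Convenience wrapper: build histograms and apply
#' \code{\link{selectThreshold}} to each.
#'
#' @inheritParams buildHistograms
#' @return A \linkS4class{BinarizationThresholds}.
#' @export
estimateThresholds <- function(traces, network = 1L, kNear = 3L) {
  hists <- buildHistograms(traces, network = network, kNear = kNear)
  rows <- lapply(hists, selectThreshold)
  tab <- data.frame(population = vapply(rows, `[[`, character(1), "population"),
                    threshold_hz = vapply(rows, `[[`, numeric(1), "threshold"),
                    rule = vapply(rows, `[[`, character(1), "rule"),
                    stringsAsFactors = FALSE)
  new("BinarizationThresholds", table = tab, network = as.integer(network))
}

#' Boolean trace container
#'
#' Per network and non-timeout trial, the Boolean activity matrix (18
#' populations x bins up to the decision), obtained by strict comparison of
#' each binned rate against its population's threshold (rate > threshold
#' gives 1; a rate exactly at threshold gives 0).
#'
#' @slot networks List; each element
#'   \code{list(thresholds, trials, nTimeouts)}, with each trial
#'   \code{list(bits, choice, decisionTime, phaseMarks)}.
#' @slot binWidth Bin width (ms).
#' @export
setClass("BinaryTraceSet", representation(networks = "list",
                                          binWidth = "numeric"))

setMethod("show", "BinaryTraceSet", function(object) {
  nt <- vapply(object@networks, function(nw) length(nw$trials), integer(1))
  cat("BinaryTraceSet:", length(object@networks), "network(s),",
      sum(nt), "binarized trials\n")
})

#' Binarize a trace set
#'
#' @param traces A \linkS4class{RateTraceSet}.
#' @param thresholds Optional \linkS4class{BinarizationThresholds} or list
#'   of them (one per network); estimated per network when omitted.
#' @param kNear Passed to \code{\link{estimateThresholds}} when estimating.
#' @return A \linkS4class{BinaryTraceSet}.  Timeout trials are excluded
#'   (their count is kept per network).
#' @export
binarizeTraces <- function(traces, thresholds = NULL, kNear = 3L) {
  nets <- lapply(seq_len(nNetworks(traces)), function(i) {
    thr <- if (is.null(thresholds)) estimateThresholds(traces, i, kNear)
           else if (is(thresholds, "BinarizationThresholds")) thresholds
           else thresholds[[i]]
    tab <- thr@table
    trials <- networkTrials(traces, i)
    keep <- vapply(trials, function(tr) tr$choice != "none", logical(1))
    btrials <- lapply(which(keep), function(j) {
      tr <- trials[[j]]
      bins <- .analysisBins(tr)
      m <- tr$rates[, bins, drop = FALSE]
      missing <- setdiff(rownames(m), tab$population)
      if (length(missing))
        stop("missing threshold for population(s): ",
             paste(missing, collapse = ", "))
      thrVec <- tab$threshold_hz[match(rownames(m), tab$population)]
      list(bits = m > thrVec, trial = j,
           choice = tr$choice, decisionTime = tr$decisionTime,
           phaseMarks = tr$phaseMarks)
    })
    list(thresholds = thr, trials = btrials, nTimeouts = sum(!keep))
  })
  new("BinaryTraceSet", networks = nets, binWidth = traces@binWidth)
}
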