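#' Container for simulated firing-rate trials
#'
#' A \code{RateTraceSet} holds, per network, a \linkS4class{NetworkConfig}
#' and a list of trial records.  Each trial record is a list with elements
#' \describe{
#'   \item{rates}{18 x bins matrix of binned firing rates (Hz), rows named
#'     by \code{\link{populationNames}}.}
#'   \item{decisionTime}{Decision time in ms from stimulus onset, or
#'     \code{NA} for a timeout.}
#'   \item{choice}{\code{"left"}, \code{"right"} or \code{"none"}.}
#'   \item{phaseMarks}{Named integer bin indices: \code{stimOnset} (last
#'     pre-stimulus bin), \code{decision} (bin whose rate closed the trial,
#'     0 if timeout), \code{consolidationEnd}.}
#' }
#' All analysis downstream of simulation uses bins 1..decision only; the
#' consolidation and inter-trial bins exist for inspection of the full trial
#' time course.
#'
#' @slot networks List; each element is \code{list(config, trials)}.
#' @slot binWidth Bin width in ms (common to all networks).
#' @export
setClass("RateTraceSet", representation(networks = "list",
                                        binWidth = "numeric"))

setValidity("RateTraceSet", function(object) {
  msgs <- character(0)
  pops <- populationNames()
  for (i in seq_along(object@networks)) {
    nw <- object@networks[[i]]
    if (!is(nw$config, "NetworkConfig"))
      msgs <- c(msgs, sprintf("network %d: missing NetworkConfig", i))
    for (tr in nw$trials) {
      if (!identical(rownames(tr$rates), pops)) {
        msgs <- c(msgs, sprintf("network %d: trial rate matrix rows must be %s",
                                i, "the 18 canonical populations"))
        break
      }
      if (any(tr$rates < 0) || any(!is.finite(tr$rates))) {
        msgs <- c(msgs, sprintf("network %d: negative or non-finite rates", i))
        break
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "RateTraceSet", function(object) {
  nt <- vapply(object@networks, function(nw) length(nw$trials), integer(1))
  cat("RateTraceSet:", length(object@networks), "network(s),",
      sum(nt), "trials,", object@binWidth, "ms bins\n")
  if (length(nt)) {
    beh <- behaviorTable(object)
    to <- mean(beh$choice == "none")
    cat(sprintf("  decisions: %.0f%% left, %.0f%% right, %.2f%% timeouts\n",
                100 * mean(beh$choice == "left"),
                100 * mean(beh$choice == "right"), 100 * to))
  }
})

#' Construct a RateTraceSet from network entries
#' @param entries List of \code{list(config, trials)} entries (or a single
#'   entry).
#' @param binWidth Bin width in ms.
#' @return A \linkS4class{RateTraceSet}.
#' @export
rateTraceSet <- function(entries, binWidth = 10) {
  if (!is.null(entries$config)) entries <- list(entries)
  new("RateTraceSet", networks = entries, binWidth = binWidth)
}

#' Number of networks in a trace set
#' @param x A \linkS4class{RateTraceSet}.
#' @return Integer.
#' @export
nNetworks <- function(x) length(x@networks)

#' Trials of one network
#' @param x A \linkS4class{RateTraceSet}.
#' @param i Network index.
#' @return List of trial records.
#' @export
networkTrials <- function(x, i = 1L) x@networks[[i]]$trials

#' Configuration of one network
#' @param x A \linkS4class{RateTraceSet}.
#' @param i Network index.
#' @return The \linkS4class{NetworkConfig} of network \code{i}.
#' @export
networkConfig <- function(x, i = 1L) x@networks[[i]]$config

#' Merge several trace sets into one
#' @param ... \linkS4class{RateTraceSet} objects with equal bin widths.
#' @return A combined \linkS4class{RateTraceSet}.
#' @export
combineTraceSets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is(sets[[1]], "RateTraceSet"))
    sets <- sets[[1]]
  bw <- unique(vapply(sets, function(s) s@binWidth, numeric(1)))
  if (length(bw) != 1L) stop("bin widths differ across sets")
  new("RateTraceSet", networks = do.call(c, lapply(sets, slot, "networks")),
      binWidth = bw)
}

#' Behavioural summary of all trials
#'
#' @param x A \linkS4class{RateTraceSet}.
#' @return data.frame with columns network, trial, decision_time_ms, choice.
#' @export
behaviorTable <- function(x) {
  out <- lapply(seq_along(x@networks), function(i) {
    tr <- x@networks[[i]]$trials
    data.frame(network = i, trial = seq_along(tr),
               decision_time_ms = vapply(tr, function(t)
                 ifelse(is.na(t$decisionTime), NA_real_, t$decisionTime),
                 numeric(1)),
               choice = vapply(tr, function(t) t$choice, character(1)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Bins of a trial entering the analysis: trial start up to and including the
# decision bin.  NULL for timeouts.
.analysisBins <- function(trial) {
  db <- trial$phaseMarks[["decision"]]
  if (is.na(db) || db < 1L) return(NULL)
  seq_len(db)
}
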