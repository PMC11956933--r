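# Region-level connectivity of the model circuit.  scope:
#   ipsi    - within action channel (left source -> left target, etc.)
#   shared  - source and/or target is a channel-shared population; a shared
#             source projects to both channels, a shared target pools both.
#   diffuse - source projects to both channels' targets (STN -> GPi; the
#             subthalamic projection to the output nucleus is broad, and this
#             coupling is what lets one channel's rise delay the other's).
.edgeTable <- function() {
  e <- rbind(
    c("Cx",   "dSPN", +1, "ipsi"),
    c("Cx",   "iSPN", +1, "ipsi"),
    c("Cx",   "STN",  +1, "ipsi"),
    c("Cx",   "FSI",  +1, "shared"),
    c("Cx",   "CxI",  +1, "shared"),
    c("CxI",  "Cx",   -1, "shared"),
    c("FSI",  "dSPN", -1, "shared"),
    c("FSI",  "iSPN", -1, "shared"),
    c("Th",   "Cx",   +1, "ipsi"),
    c("Th",   "dSPN", +1, "ipsi"),
    c("Th",   "iSPN", +1, "ipsi"),
    c("dSPN", "GPi",  -1, "ipsi"),
    c("iSPN", "GPeP", -1, "ipsi"),
    c("GPeP", "STN",  -1, "ipsi"),
    c("GPeP", "GPi",  -1, "ipsi"),
    c("GPeP", "GPeA", -1, "ipsi"),
    c("GPeA", "dSPN", -1, "ipsi"),
    c("GPeA", "iSPN", -1, "ipsi"),
    c("GPeA", "FSI",  -1, "shared"),
    c("STN",  "GPeP", +1, "ipsi"),
    c("STN",  "GPeA", +1, "ipsi"),
    c("STN",  "GPi",  +1, "diffuse"),
    c("GPi",  "Th",   -1, "ipsi"))
  data.frame(from = e[, 1], to = e[, 2], sign = as.numeric(e[, 3]),
             scope = e[, 4], stringsAsFactors = FALSE)
}

#' Connectivity sign table of the CBGT model
#'
#' One row per region-level projection, with its sign (+1 excitatory, -1
#' inhibitory) and scope (within-channel, channel-shared, or diffuse across
#' channels).  Connection weights in a \linkS4class{NetworkConfig} are keyed
#' as \code{"from->to"} and must carry the sign listed here.
#'
#' @return data.frame with columns from, to, sign, scope.
#' @export
connectivityTable <- function() .edgeTable()

# The 13 synaptic weights exposed to the genetic search; they span the
# direct, indirect and pallidostriatal pathways.
.searchableKeys <- c("Cx->dSPN", "Cx->iSPN", "Cx->STN",
                     "dSPN->GPi", "iSPN->GPeP",
                     "GPeP->STN", "STN->GPeP", "GPeP->GPi", "STN->GPi",
                     "GPi->Th", "GPeA->dSPN", "GPeA->iSPN", "STN->GPeA")

#' Keys of the 13 searchable synaptic weights
#' @return Character vector of length 13 of \code{"from->to"} keys.
#' @export
searchableWeights <- function() .searchableKeys

#' Network configuration container
#'
#' Holds everything needed to simulate one CBGT network: signed synaptic
#' weights (region level, shared across the two action channels), target
#' baseline rates from which tonic inputs are derived, noise scales, time
#' constants, the stimulus protocol and trial timing.
#'
#' @slot weights Named numeric; signed weight per \code{"from->to"} key of
#'   \code{\link{connectivityTable}}.
#' @slot baselineRates Named numeric(18); pre-stimulus target rate (Hz) per
#'   population.  Tonic inputs are set so these are the noise-free fixed
#'   point of the rate equations.
#' @slot noiseSd Named numeric(18); diffusion scale (Hz per sqrt(ms)).
#' @slot tau Named numeric(18); population time constants (ms).
#' @slot rmax Saturation of the transfer function (Hz).
#' @slot stimulus list(onset (ms from trial start), amplitude (named numeric,
#'   left/right drive to cortex in Hz-equivalent input units)).
#' @slot decisionThreshold Thalamic rate (Hz) that closes a trial.
#' @slot timeout Maximum decision phase duration (ms).
#' @slot consolidation,iti Post-decision phase durations (ms); the selected
#'   channel keeps \code{consolidationGain} of its stimulus during
#'   consolidation.
#' @slot consolidationGain Fraction of the stimulus sustained after decision.
#' @slot dtSim Euler integration step (ms).
#' @slot binWidth Rate binning width (ms).
#' @slot seed Default RNG seed used when an operation is not given one.
#' @export
setClass("NetworkConfig", representation(
  weights = "numeric",
  baselineRates = "numeric",
  noiseSd = "numeric",
  tau = "numeric",
  rmax = "numeric",
  stimulus = "list",
  decisionThreshold = "numeric",
  timeout = "numeric",
  consolidation = "numeric",
  iti = "numeric",
  consolidationGain = "numeric",
  dtSim = "numeric",
  binWidth = "numeric",
  seed = "integer"))

setValidity("NetworkConfig", function(object) {
  et <- .edgeTable()
  keys <- paste0(et$from, "->", et$to)
  msgs <- character(0)
  if (!setequal(names(object@weights), keys))
    msgs <- c(msgs, "weights must cover exactly the connectivity table keys")
  else {
    w <- object@weights[keys]
    bad <- sign(w) != 0 & sign(w) != et$sign
    if (any(bad))
      msgs <- c(msgs, paste0("weight sign violates connectivity table for: ",
                             paste(keys[bad], collapse = ", ")))
  }
  pops <- populationNames()
  for (s in c("baselineRates", "noiseSd", "tau")) {
    v <- slot(object, s)
    if (!identical(names(v), pops))
      msgs <- c(msgs, paste0(s, " must be named by the 18 populations in ",
                             "canonical order"))
  }
  if (object@decisionThreshold <= 0) msgs <- c(msgs, "decisionThreshold must be > 0")
  if (object@timeout <= 0) msgs <- c(msgs, "timeout must be > 0")
  if (object@binWidth %% object@dtSim != 0)
    msgs <- c(msgs, "binWidth must be a multiple of dtSim")
  if (!setequal(names(object@stimulus$amplitude), c("left", "right")))
    msgs <- c(msgs, "stimulus$amplitude must have entries 'left' and 'right'")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "NetworkConfig", function(object) {
  cat("NetworkConfig: 18 populations,", length(object@weights), "weights\n")
  cat("  stimulus onset", object@stimulus$onset, "ms, amplitude L/R =",
      paste(round(object@stimulus$amplitude, 2), collapse = "/"), "\n")
  cat("  decision threshold", object@decisionThreshold,
      "Hz, timeout", object@timeout, "ms\n")
})

.defaultWeights <- function() {
  w <- c("Cx->dSPN"   = 0.65,
         "Cx->iSPN"   = 0.58,
         "Cx->STN"    = 0.25,
         "Cx->FSI"    = 0.20,
         "Cx->CxI"    = 0.30,
         "CxI->Cx"    = -0.40,
         "FSI->dSPN"  = -0.20,
         "FSI->iSPN"  = -0.20,
         "Th->Cx"     = 0.25,
         "Th->dSPN"   = 0.25,
         "Th->iSPN"   = 0.20,
         "dSPN->GPi"  = -3.00,
         "iSPN->GPeP" = -2.80,
         "GPeP->STN"  = -0.25,
         "GPeP->GPi"  = -0.15,
         "GPeP->GPeA" = -0.15,
         "GPeA->dSPN" = -0.20,
         "GPeA->iSPN" = -0.20,
         "GPeA->FSI"  = -0.20,
         "STN->GPeP"  = 0.35,
         "STN->GPeA"  = 0.50,
         "STN->GPi"   = 0.20,
         "GPi->Th"    = -0.80)
  et <- .edgeTable()
  w[paste0(et$from, "->", et$to)]
}

.defaultBaselines <- function() {
  pops <- cbgtPopulations()
  base <- c(Cx = 5, CxI = 8, FSI = 10, dSPN = 2, iSPN = 2,
            GPeP = 60, GPeA = 4, STN = 15, GPi = 70, Th = 10)
  setNames(base[pops$region], pops$name)
}

.defaultNoise <- function() {
  pops <- cbgtPopulations()
  ns <- c(Cx = 1.0, CxI = 0.4, FSI = 0.4, dSPN = 0.5, iSPN = 0.5,
          GPeP = 0.8, GPeA = 0.4, STN = 0.6, GPi = 0.8, Th = 0.5)
  setNames(ns[pops$region], pops$name)
}

.defaultTau <- function() {
  pops <- cbgtPopulations()
  tau <- c(Cx = 20, CxI = 10, FSI = 10, dSPN = 20, iSPN = 20,
           GPeP = 20, GPeA = 20, STN = 15, GPi = 15, Th = 25)
  setNames(tau[pops$region], pops$name)
}

#' Default CBGT network configuration
#'
#' The shipped configuration is tuned so that the noise-free fixed point
#' before the stimulus has high pallidal output (GPeP/GPi around 60-70 Hz)
#' and low striatal/arkypallidal activity, and so that the post-stimulus
#' cascade (cortex up, striatum up, GPeP dips, GPi dips, thalamus ramps)
#' reliably drives a thalamic channel over the 30 Hz decision threshold well
#' inside the 1000 ms timeout.
#'
#' @param weights Optional named numeric of weight overrides (subset of the
#'   connectivity keys).
#' @param stimulusAmplitude Length-2 numeric (left, right) stimulus drive.
#' @param seed Default seed stored in the config.
#' @param ... Further slot overrides (\code{decisionThreshold},
#'   \code{timeout}, \code{noiseSd}, ...).
#' @return A validated \linkS4class{NetworkConfig}.
#' @examples
#' cfg <- defaultNetworkConfig()
#' @export
defaultNetworkConfig <- function(weights = NULL,
                                 stimulusAmplitude = c(left = 10, right = 10),
                                 seed = 1L, ...) {
  w <- .defaultWeights()
  if (!is.null(weights)) {
    unknown <- setdiff(names(weights), names(w))
    if (length(unknown))
      stop("unknown weight keys: ", paste(unknown, collapse = ", "))
    w[names(weights)] <- weights
  }
  if (is.null(names(stimulusAmplitude)))
    names(stimulusAmplitude) <- c("left", "right")
  obj <- new("NetworkConfig",
             weights = w,
             baselineRates = .defaultBaselines(),
             noiseSd = .defaultNoise(),
             tau = .defaultTau(),
             rmax = 200,
             stimulus = list(onset = 200,
                             amplitude = stimulusAmplitude[c("left", "right")]),
             decisionThreshold = 30,
             timeout = 1000,
             consolidation = 150,
             iti = 150,
             consolidationGain = 0.5,
             dtSim = 1,
             binWidth = 10,
             seed = as.integer(seed))
  extra <- list(...)
  for (nm in names(extra)) slot(obj, nm) <- extra[[nm]]
  validObject(obj)
  obj
}

# Expand region-level weights into the 18 x 18 instance matrix W, with
# W[i, j] the signed weight from population j onto population i.
.weightMatrix <- function(config) {
  pops <- cbgtPopulations()
  n <- nrow(pops)
  W <- matrix(0, n, n, dimnames = list(pops$name, pops$name))
  et <- .edgeTable()
  for (k in seq_len(nrow(et))) {
    w <- config@weights[paste0(et$from[k], "->", et$to[k])]
    src <- which(pops$region == et$from[k])
    tgt <- which(pops$region == et$to[k])
    for (i in tgt) for (j in src) {
      if (et$scope[k] == "ipsi" &&
          pops$channel[i] != "shared" && pops$channel[j] != "shared" &&
          pops$channel[i] != pops$channel[j]) next
      W[i, j] <- w
    }
  }
  W
}

# Tonic inputs making baselineRates the noise-free fixed point (transfer
# function is identity on [0, rmax], so I = r* - W r* as long as r* stays in
# the linear range).
.baselineInputs <- function(config, W = .weightMatrix(config)) {
  r <- config@baselineRates
  drop(r - W %*% r)
}
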