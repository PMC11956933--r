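#' Extract integer state sequences from binarized trials
#'
#' Converts each non-timeout trial's Boolean matrix into a sequence of
#' integer state labels over the ten encoded populations (one label per
#' 10 ms bin, up to and including the decision bin).  STN and GPeA bits do
#' not enter the label but are carried along for the per-state activation
#' statistics.
#'
#' @param binary A \linkS4class{BinaryTraceSet}.
#' @return List of state sequence records: \code{network}, \code{trial},
#'   \code{labels} (integer vector), \code{aux} (4 x bins 0/1 matrix over
#'   \code{\link{auxPopulations}}), \code{choice}, \code{decisionTime}.
#' @export
extractSequences <- function(binary) {
  enc <- encodedPopulations()
  aux <- auxPopulations()
  pow <- 2L^(9:0)
  out <- list()
  for (i in seq_along(binary@networks)) {
    nw <- binary@networks[[i]]
    for (j in seq_along(nw$trials)) {
      tr <- nw$trials[[j]]
      if (ncol(tr$bits) == 0L) {
        warning(sprintf("network %d trial %d: empty trace skipped", i, j))
        next
      }
      labels <- as.integer(colSums(tr$bits[enc, , drop = FALSE] * pow))
      origTrial <- if (is.null(tr$trial)) j else tr$trial
      out[[length(out) + 1L]] <-
        list(network = i, trial = origTrial, labels = labels,
             aux = tr$bits[aux, , drop = FALSE] * 1L,
             choice = tr$choice, decisionTime = tr$decisionTime)
    }
  }
  out
}

#' Estimate the raw state-transition structure
#'
#' Aggregates all state sequences into transition and end counts.  In mode
#' \code{per_change} (the default) a transition is counted whenever the
#' label changes, with dwell repetitions collapsed, so the resulting chain
#' connects distinct states.  In mode \code{per_bin} every consecutive bin
#' pair is counted, including self-transitions.  A state's end count
#' increments whenever it is a trial's final label.  Probabilities are
#' normalized per source state over outgoing transitions plus ends.
#'
#' @param sequences List of sequence records from
#'   \code{\link{extractSequences}}.
#' @param mode \code{"per_change"} or \code{"per_bin"}.
#' @return list with \code{edges} data.frame(from, to, count, probability),
#'   \code{ends} data.frame(state, count, probability), \code{mode},
#'   \code{nSequences}.
#' @export
estimateTransitions <- function(sequences, mode = c("per_change", "per_bin")) {
  mode <- match.arg(mode)
  if (length(sequences) == 0L) stop("at least one sequence is required")
  fromAll <- integer(0); toAll <- integer(0); endAll <- integer(0)
  for (s in sequences) {
    lab <- s$labels
    if (mode == "per_change") lab <- rle(lab)$values
    n <- length(lab)
    if (n > 1L) {
      fromAll <- c(fromAll, lab[-n])
      toAll <- c(toAll, lab[-1L])
    }
    endAll <- c(endAll, lab[n])
  }
  edges <- if (length(fromAll)) {
    agg <- stats::aggregate(list(count = rep(1L, length(fromAll))),
                            by = list(from = fromAll, to = toAll), FUN = sum)
    agg[order(agg$from, agg$to), ]
  } else data.frame(from = integer(0), to = integer(0), count = integer(0))
  endsTab <- as.data.frame(table(state = endAll), stringsAsFactors = FALSE)
  ends <- data.frame(state = as.integer(endsTab$state),
                     count = as.integer(endsTab$Freq))

  outTotal <- tapply(edges$count, edges$from, sum)
  total <- function(st) {
    o <- outTotal[as.character(st)]; o[is.na(o)] <- 0
    e <- ends$count[match(st, ends$state)]; e[is.na(e)] <- 0
    as.numeric(o + e)
  }
  edges$probability <- edges$count / total(edges$from)
  ends$probability <- ends$count / total(ends$state)
  rownames(edges) <- NULL
  list(edges = edges, ends = ends, mode = mode,
       nSequences = length(sequences))
}

#' Pruned state-transition graph of the decision process
#'
#' @slot edges data.frame(from, to, count, probability, retained).
#' @slot ends data.frame(state, count, probability).
#' @slot stats data.frame of per-state statistics (may be empty; see
#'   \code{\link{computeStateStats}}).
#' @slot mode Transition counting mode used.
#' @slot gap Relative pruning gap.
#' @export
setClass("ClawGraph", representation(edges = "data.frame",
                                     ends = "data.frame",
                                     stats = "data.frame",
                                     mode = "character",
                                     gap = "numeric"))

setValidity("ClawGraph", function(object) {
  p <- c(object@edges$probability, object@ends$probability)
  if (length(p) && (any(p < 0) || any(p > 1 + 1e-9)))
    return("probabilities must lie in [0, 1]")
  for (st in unique(object@edges$from)) {
    keep <- object@edges$from == st & object@edges$retained
    mass <- sum(object@edges$probability[keep]) +
      sum(object@ends$probability[object@ends$state == st])
    if (mass > 1 + 1e-9)
      return(sprintf("retained + end probability exceeds 1 for state %d", st))
  }
  TRUE
})

setMethod("show", "ClawGraph", function(object) {
  cat("ClawGraph: ", length(clawStates(object)), " states, ",
      sum(object@edges$retained), " retained / ", nrow(object@edges),
      " raw edges (mode ", object@mode, ", gap ", object@gap, ")\n",
      sep = "")
})

#' States present in a CLAW graph
#' @param graph A \linkS4class{ClawGraph}.
#' @return Sorted integer vector of state labels.
#' @export
clawStates <- function(graph)
  sort(unique(c(graph@edges$from, graph@edges$to, graph@ends$state)))

#' Retained edges of a CLAW graph
#' @param graph A \linkS4class{ClawGraph}.
#' @return data.frame of retained edges.
#' @export
clawEdges <- function(graph) graph@edges[graph@edges$retained, , drop = FALSE]

#' End (pre-decision) probabilities of a CLAW graph
#' @param graph A \linkS4class{ClawGraph}.
#' @return data.frame(state, count, probability).
#' @export
clawEnds <- function(graph) graph@ends

#' Prune the raw transition table into a CLAW graph
#'
#' Per source state, outgoing probabilities are sorted in decreasing order
#' and edges 1..p are retained for the smallest p at which the relative
#' drop to the next edge, \eqn{(p_p - p_{p+1})/p_p}, reaches the gap
#' (default 25\%); if no drop qualifies, all edges are retained.  End
#' probabilities are never pruned.
#'
#' @param raw Output of \code{\link{estimateTransitions}}.
#' @param gap Relative gap threshold in [0, 1].
#' @param stats Optional per-state statistics to attach.
#' @return A \linkS4class{ClawGraph}.
#' @export
pruneGraph <- function(raw, gap = 0.25, stats = NULL) {
  edges <- raw$edges
  edges$retained <- TRUE
  for (st in unique(edges$from)) {
    idx <- which(edges$from == st)
    p <- edges$probability[idx]
    ord <- order(p, decreasing = TRUE)
    ps <- p[ord]
    keepN <- length(ps)
    if (length(ps) > 1L) {
      gaps <- (ps[-length(ps)] - ps[-1L]) / ps[-length(ps)]
      hit <- which(gaps >= gap)
      if (length(hit)) keepN <- hit[1]
    }
    edges$retained[idx[ord][-seq_len(keepN)]] <- FALSE
    if (keepN == length(ps)) edges$retained[idx] <- TRUE
  }
  new("ClawGraph", edges = edges, ends = raw$ends,
      stats = if (is.null(stats)) data.frame() else stats,
      mode = raw$mode, gap = gap)
}

#' Kullback-Leibler divergence between two discrete distributions
#'
#' \eqn{KL(P||Q) = \sum_i p_i \log(p_i / q_i)} in nats; terms with
#' \eqn{p_i = 0} contribute zero.
#'
#' @param p,q Non-negative vectors of equal length (normalized internally).
#' @param symmetrized If TRUE, return the Jensen-Shannon divergence
#'   (average of the two KLs against the mixture).
#' @return Divergence in nats (non-negative; Inf if q has a zero where p
#'   does not and no smoothing was applied by the caller).
#' @examples
#' klDivergence(c(0.5, 0.5), c(0.9, 0.1))  # 0.5108 nats
#' @export
klDivergence <- function(p, q, symmetrized = FALSE) {
  stopifnot(length(p) == length(q))
  p <- p / sum(p); q <- q / sum(q)
  if (symmetrized) {
    m <- (p + q) / 2
    return((klDivergence(p, m) + klDivergence(q, m)) / 2)
  }
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

#' Per-state statistics of the decision process
#'
#' For each state: the mean decision time over the trials that visit it,
#' the left/right choice counts of those trials, the KL divergence between
#' the decision-time histograms of left- and right-choosing visiting trials
#' (shared bin edges, additive smoothing of 1/total-count, natural log),
#' and the activation probability of the STN and GPeA bits over the bins in
#' which the state is occupied.
#'
#' @param sequences Sequence records from \code{\link{extractSequences}}.
#' @param behavior Optional data.frame(network, trial, decision_time_ms,
#'   choice); taken from the sequence records when omitted.
#' @param nBreaks Number of shared histogram bins for the KL computation.
#' @param symmetrized Use the Jensen-Shannon variant instead of
#'   KL(left || right).
#' @return data.frame with one row per state: state, n_trials, mean_dt_ms,
#'   n_left, n_right, kl_nats (NA when only one choice class visits, with
#'   kl_defined FALSE), p_stn_l, p_stn_r, p_gpea_l, p_gpea_r, occupancy.
#' @export
computeStateStats <- function(sequences, behavior = NULL, nBreaks = 10L,
                              symmetrized = FALSE) {
  if (is.null(behavior)) {
    behavior <- data.frame(
      network = vapply(sequences, `[[`, numeric(1), "network"),
      trial = vapply(sequences, `[[`, numeric(1), "trial"),
      decision_time_ms = vapply(sequences, `[[`, numeric(1), "decisionTime"),
      choice = vapply(sequences, `[[`, character(1), "choice"))
  }
  key <- function(nw, tr) paste(nw, tr, sep = ":")
  behKey <- key(behavior$network, behavior$trial)

  states <- sort(unique(unlist(lapply(sequences, `[[`, "labels"))))
  visits <- lapply(setNames(states, states), function(s) list(
    trials = character(0), binAux = matrix(0L, 4, 0), bins = 0L))
  for (sq in sequences) {
    k <- key(sq$network, sq$trial)
    for (s in unique(sq$labels)) {
      ss <- as.character(s)
      visits[[ss]]$trials <- c(visits[[ss]]$trials, k)
      occ <- sq$labels == s
      visits[[ss]]$binAux <- cbind(visits[[ss]]$binAux,
                                   sq$aux[, occ, drop = FALSE])
      visits[[ss]]$bins <- visits[[ss]]$bins + sum(occ)
    }
  }

  rows <- lapply(as.character(states), function(ss) {
    v <- visits[[ss]]
    idx <- match(v$trials, behKey)
    dt <- behavior$decision_time_ms[idx]
    ch <- behavior$choice[idx]
    nL <- sum(ch == "left"); nR <- sum(ch == "right")
    klDef <- nL > 0 && nR > 0
    kl <- NA_real_
    if (klDef) {
      breaks <- seq(min(dt), max(dt), length.out = nBreaks + 1L)
      if (breaks[1] == breaks[length(breaks)])
        breaks <- breaks[1] + c(-0.5, 0.5)
      cL <- graphics::hist(dt[ch == "left"], breaks = breaks,
                           plot = FALSE)$counts
      cR <- graphics::hist(dt[ch == "right"], breaks = breaks,
                           plot = FALSE)$counts
      eps <- 1 / length(dt)
      kl <- klDivergence(cL / sum(cL) + eps, cR / sum(cR) + eps,
                         symmetrized = symmetrized)
    }
    pAux <- rowMeans(v$binAux)
    data.frame(state = as.integer(ss), n_trials = length(idx),
               mean_dt_ms = mean(dt), n_left = nL, n_right = nR,
               kl_nats = kl, kl_defined = klDef,
               p_stn_l = pAux[["STN-L"]], p_stn_r = pAux[["STN-R"]],
               p_gpea_l = pAux[["GPeA-L"]], p_gpea_r = pAux[["GPeA-R"]],
               occupancy = v$bins)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Equal-mass decision-time tertiles
#'
#' Cut points at the empirical 1/3 and 2/3 quantiles of the pooled decision
#' times, classing each trial as fast, intermediate or slow.
#'
#' @param decisionTimes Numeric vector (ms), length >= 3, NAs dropped.
#' @return list(cuts = numeric(2), class = factor over fast / intermediate
#'   / slow aligned with the input).
#' @export
dtTertiles <- function(decisionTimes) {
  dt <- decisionTimes[!is.na(decisionTimes)]
  if (length(dt) < 3L) stop("at least 3 decision times are required")
  cuts <- stats::quantile(dt, c(1, 2) / 3, type = 1, names = FALSE)
  lv <- c("fast", "intermediate", "slow")
  if (cuts[1] == cuts[2]) {
    warning("tied decision times: tertile classes are degenerate")
    cls <- factor(ifelse(is.na(decisionTimes), NA,
                         ifelse(decisionTimes <= cuts[1], "fast", "slow")),
                  levels = lv)
  } else {
    cls <- cut(decisionTimes, breaks = c(-Inf, cuts, Inf), labels = lv,
               right = TRUE)
  }
  list(cuts = cuts, class = cls)
}
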