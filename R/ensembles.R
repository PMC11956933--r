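# Regions contributing sum/diff feature pairs, in fixed column order.
.lateralRegions <- c("Cx", "dSPN", "iSPN", "GPeP", "GPeA", "STN", "GPi", "Th")

#' Names of the 18 activity features
#'
#' For each of the eight lateralized regions, the across-channel sum and
#' the left-minus-right difference of its firing rate; plus the rates of
#' the two shared populations (CxI, FSI).
#'
#' @return Character vector of length 18.
#' @export
featureNames <- function() {
  c(as.vector(rbind(paste0(.lateralRegions, "_sum"),
                    paste0(.lateralRegions, "_diff"))),
    "CxI", "FSI")
}

# 18-feature vector(s) from an 18-population rate matrix (populations x
# bins): returns features x bins.
.featureTransform <- function(rates) {
  pops <- cbgtPopulations()
  out <- matrix(NA_real_, 18, ncol(rates),
                dimnames = list(featureNames(), NULL))
  for (rg in .lateralRegions) {
    l <- rates[paste0(rg, "-L"), , drop = FALSE]
    r <- rates[paste0(rg, "-R"), , drop = FALSE]
    out[paste0(rg, "_sum"), ] <- l + r
    out[paste0(rg, "_diff"), ] <- l - r
  }
  out["CxI", ] <- rates["CxI", ]
  out["FSI", ] <- rates["FSI", ]
  out
}

#' Per-network trial-averaged activity features
#'
#' One row per network: the 18 activity features (sums, left-minus-right
#' differences, shared-population rates) of the trial-averaged firing rates
#' over bins up to each trial's decision, averaged across non-timeout
#' trials.
#'
#' @param traces A \linkS4class{RateTraceSet}.
#' @return n_networks x 18 matrix with \code{\link{featureNames}} columns.
#' @export
buildFeatureMatrix <- function(traces) {
  rows <- lapply(seq_len(nNetworks(traces)), function(i) {
    trials <- networkTrials(traces, i)
    trials <- Filter(function(tr) tr$choice != "none", trials)
    if (!length(trials)) stop("network ", i, " has no non-timeout trials")
    m <- vapply(trials, function(tr)
      rowMeans(tr$rates[, .analysisBins(tr), drop = FALSE]),
      numeric(18))
    drop(.featureTransform(as.matrix(rowMeans(m))))
  })
  F <- do.call(rbind, rows)
  colnames(F) <- featureNames()
  F
}

#' Per-network fitted DDM parameter matrix
#'
#' Fits the drift-diffusion model to each network's choices and decision
#' times (seconds) and stacks the point estimates.
#'
#' @param traces A \linkS4class{RateTraceSet}.
#' @param fixZ Optional fixed starting bias passed to \code{\link{fitDdm}}.
#' @return list(D = n x 4 matrix with columns a, v, t, z; fits = list of
#'   \code{DdmFit}).
#' @export
buildDdmMatrix <- function(traces, fixZ = NULL) {
  fits <- lapply(seq_len(nNetworks(traces)), function(i) {
    beh <- behaviorTable(traces)
    beh <- beh[beh$network == i & beh$choice != "none", ]
    fitDdm(beh$choice, beh$decision_time_ms / 1000, fixZ = fixZ)
  })
  D <- t(vapply(fits, function(f) ddmVector(f@params), numeric(4)))
  colnames(D) <- c("a", "v", "t", "z")
  list(D = D, fits = fits)
}

#' Canonical-correlation model of the three control ensembles
#'
#' @slot U 18 x k activity-side loadings (standardized units).
#' @slot V 4 x k DDM-side loadings (standardized units).
#' @slot cors Canonical correlations, non-increasing in [0, 1].
#' @slot labels Character k; one of choice / responsiveness / pliancy after
#'   \code{\link{labelComponents}}.
#' @slot lowConfidence Logical flag from labeling.
#' @slot featureCenter,featureScale,ddmCenter,ddmScale Standardization
#'   parameters of the training data.
#' @export
setClass("EnsembleModel", representation(
  U = "matrix", V = "matrix", cors = "numeric", labels = "character",
  lowConfidence = "logical",
  featureCenter = "numeric", featureScale = "numeric",
  ddmCenter = "numeric", ddmScale = "numeric"))

setValidity("EnsembleModel", function(object) {
  msgs <- character(0)
  if (any(object@cors < -1e-9) || any(object@cors > 1 + 1e-9))
    msgs <- c(msgs, "canonical correlations must lie in [0, 1]")
  if (is.unsorted(rev(object@cors), strictly = FALSE))
    msgs <- c(msgs, "canonical correlations must be non-increasing")
  if (ncol(object@U) != ncol(object@V))
    msgs <- c(msgs, "U and V must have the same number of components")
  labs <- object@labels[!is.na(object@labels)]
  if (anyDuplicated(labs)) msgs <- c(msgs, "labels must be distinct")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "EnsembleModel", function(object) {
  cat("EnsembleModel:", ncol(object@U), "components, correlations",
      paste(round(object@cors, 3), collapse = ", "), "\n")
  if (!all(is.na(object@labels)))
    cat("  labels:", paste(object@labels, collapse = ", "),
        if (object@lowConfidence) "(low confidence)" else "", "\n")
})

#' Canonical correlation analysis between activity features and DDM
#' parameters
#'
#' Columns of both matrices are standardized; the whitened cross-covariance
#' is decomposed by SVD with a small ridge on each covariance for
#' conditioning.  Loadings are expressed in standardized units and each
#' component is sign-fixed so its largest-magnitude activity loading is
#' positive.
#'
#' @param F n x 18 feature matrix (\code{\link{buildFeatureMatrix}}).
#' @param D n x 4 DDM parameter matrix.
#' @param k Number of canonical pairs to keep (default 3).
#' @param ridge Ridge added to the standardized covariances.
#' @return An \linkS4class{EnsembleModel} (unlabeled).
#' @export
fitCca <- function(F, D, k = 3L, ridge = 1e-8) {
  n <- nrow(F)
  if (nrow(D) != n) stop("F and D must have the same number of rows")
  if (n <= ncol(F) + ncol(D))
    stop("need more networks than total variables (", ncol(F) + ncol(D), ")")
  fc <- colMeans(F); dc <- colMeans(D)
  fs <- apply(F, 2, stats::sd); ds <- apply(D, 2, stats::sd)
  if (any(fs == 0) || any(ds == 0)) {
    warning("constant column(s); regularized standardization applied")
    fs[fs == 0] <- 1; ds[ds == 0] <- 1
  }
  X <- scale(F, fc, fs); Y <- scale(D, dc, ds)
  Sxx <- crossprod(X) / (n - 1) + ridge * diag(ncol(X))
  Syy <- crossprod(Y) / (n - 1) + ridge * diag(ncol(Y))
  Sxy <- crossprod(X, Y) / (n - 1)
  invSqrt <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    vals <- pmax(e$values, ridge)
    e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
  }
  Wx <- invSqrt(Sxx); Wy <- invSqrt(Syy)
  sv <- svd(Wx %*% Sxy %*% Wy)
  k <- min(k, length(sv$d))
  U <- Wx %*% sv$u[, seq_len(k), drop = FALSE]
  V <- Wy %*% sv$v[, seq_len(k), drop = FALSE]
  cors <- pmin(pmax(sv$d[seq_len(k)], 0), 1)
  for (j in seq_len(k)) {
    s <- sign(U[which.max(abs(U[, j])), j])
    if (s < 0) { U[, j] <- -U[, j]; V[, j] <- -V[, j] }
  }
  rownames(U) <- colnames(F); rownames(V) <- colnames(D)
  new("EnsembleModel", U = U, V = V, cors = cors,
      labels = rep(NA_character_, k), lowConfidence = FALSE,
      featureCenter = fc, featureScale = fs, ddmCenter = dc, ddmScale = ds)
}

#' Fit the control ensembles with channel-symmetry augmentation
#'
#' The two action channels share all connectivity parameters, so the
#' network family is statistically invariant under the channel swap, which
#' fixes sum features, boundary height and onset time while negating
#' difference features, the drift rate and the centred starting bias.  This
#' function enforces that symmetry on the canonical correlation analysis by
#' augmenting the training set with its channel-swapped image before
#' calling \code{\link{fitCca}}: cross-covariances between the
#' swap-even and swap-odd sectors, which are pure sampling noise at modest
#' network counts, then vanish exactly, and each canonical component is
#' purely even (responsiveness / pliancy) or purely odd (choice).
#'
#' @param F n x 18 feature matrix.
#' @param D n x 4 DDM parameter matrix (columns a, v, t, z).
#' @param k Number of canonical pairs.
#' @param symmetrize Apply the augmentation (default TRUE).
#' @param ... Passed to \code{\link{fitCca}}.
#' @return An \linkS4class{EnsembleModel} (unlabeled).
#' @export
fitControlEnsembles <- function(F, D, k = 3L, symmetrize = TRUE, ...) {
  if (!symmetrize) return(fitCca(F, D, k = k, ...))
  Fs <- F
  diffCols <- grepl("_diff$", colnames(F))
  Fs[, diffCols] <- -F[, diffCols]
  Ds <- D
  Ds[, "v"] <- -D[, "v"]
  Ds[, "z"] <- 1 - D[, "z"]
  fitCca(rbind(F, Fs), rbind(D, Ds), k = k, ...)
}

#' Label the canonical components as choice, responsiveness and pliancy
#'
#' The choice ensemble is the component with the largest combined loading
#' mass on between-channel difference features and on the drift rate; of
#' the remaining two, the component whose boundary-height (a) and
#' onset-time (t) loadings share a sign is responsiveness, the one whose a
#' and t loadings oppose is pliancy.  If the two remaining components do
#' not split that way the assignment falls back to the relative sign
#' product of a and t and the model is flagged low-confidence.
#'
#' @param model An \linkS4class{EnsembleModel} with 3 components.
#' @return The model with \code{labels} (and possibly
#'   \code{lowConfidence}) set.
#' @export
labelComponents <- function(model) {
  if (ncol(model@U) != 3L) stop("labeling expects exactly 3 components")
  diffRows <- grepl("_diff$", rownames(model@U))
  diffMass <- colSums(abs(model@U[diffRows, , drop = FALSE])) /
    colSums(abs(model@U))
  vMass <- abs(model@V["v", ]) / colSums(abs(model@V))
  choiceIdx <- which.max(diffMass + vMass)
  rest <- setdiff(1:3, choiceIdx)
  at <- model@V["a", rest] * model@V["t", rest]
  labels <- rep(NA_character_, 3)
  labels[choiceIdx] <- "choice"
  low <- FALSE
  if (sum(at > 0) == 1L) {
    labels[rest[at > 0]] <- "responsiveness"
    labels[rest[at <= 0]] <- "pliancy"
  } else {
    # ambiguous: the more positively aligned a*t gets responsiveness
    ord <- order(at, decreasing = TRUE)
    labels[rest[ord[1]]] <- "responsiveness"
    labels[rest[ord[2]]] <- "pliancy"
    low <- TRUE
  }
  model@labels <- labels
  model@lowConfidence <- low
  validObject(model)
  model
}

#' Component index by ensemble label
#' @param model A labeled \linkS4class{EnsembleModel}.
#' @param label "choice", "responsiveness" or "pliancy".
#' @return Integer column index.
#' @export
ensembleIndex <- function(model, label) {
  i <- match(label, model@labels)
  if (is.na(i)) stop("model has no component labeled ", label)
  i
}

#' Swap the action channels of every trial in a trace set
#'
#' Exchanges the left and right rows of each rate matrix and relabels the
#' choices; sum features are invariant and difference features change
#' sign under this map.
#'
#' @param traces A \linkS4class{RateTraceSet}.
#' @return The channel-swapped \linkS4class{RateTraceSet}.
#' @export
swapTraceChannels <- function(traces) {
  pops <- populationNames()
  perm <- match(pops, swapChannels(pops))
  nets <- lapply(traces@networks, function(nw) {
    nw$trials <- lapply(nw$trials, function(tr) {
      m <- tr$rates[perm, , drop = FALSE]
      rownames(m) <- pops
      tr$rates <- m
      tr$choice <- switch(tr$choice, left = "right", right = "left", tr$choice)
      tr
    })
    nw
  })
  new("RateTraceSet", networks = nets, binWidth = traces@binWidth)
}

#' Control-ensemble drive time series
#'
#' For each non-timeout trial, the bin-to-bin change of the standardized
#' 18-feature vector from stimulus onset to the decision is projected onto
#' the three ensemble components: \eqn{W_k = \Delta F_k^T U}, with
#' \eqn{\Delta F_0 = 0} at the onset bin.  Trials are grouped into fast /
#' slow (decision-time tertiles pooled over the whole set) crossed with
#' left / right, and group summaries are aligned backward from the
#' decision bin (aligned bin 0 = decision).  The cumulative drive is also
#' expressed as a percentage of the group's mean pre-stimulus standardized
#' feature magnitude.
#'
#' @param traces A \linkS4class{RateTraceSet}.
#' @param model A labeled \linkS4class{EnsembleModel}.
#' @param minBins Trials with fewer analysis bins after onset are excluded
#'   (with a warning).
#' @return list with \code{summary} (data.frame: group, aligned_bin,
#'   ensemble, mean, sd, n, cum_mean, pct_change) and \code{trials} (list
#'   of per-trial records: group, alignedBins, W matrix bins x 3).
#' @export
driveTimeseries <- function(traces, model, minBins = 2L) {
  labels <- model@labels
  if (all(is.na(labels))) labels <- paste0("component", seq_len(ncol(model@U)))
  beh <- behaviorTable(traces)
  ok <- beh$choice != "none"
  speed <- if (sum(ok) >= 3L) {
    as.character(dtTertiles(ifelse(ok, beh$decision_time_ms, NA))$class)
  } else rep("intermediate", nrow(beh))

  perTrial <- list()
  dropped <- 0L
  for (i in seq_len(nNetworks(traces))) {
    trials <- networkTrials(traces, i)
    for (j in seq_along(trials)) {
      tr <- trials[[j]]
      if (tr$choice == "none") next
      row <- which(beh$network == i & beh$trial == j)
      on <- tr$phaseMarks[["stimOnset"]]
      db <- tr$phaseMarks[["decision"]]
      bins <- seq(max(on, 1L), db)
      if (length(bins) < minBins) { dropped <- dropped + 1L; next }
      feats <- .featureTransform(tr$rates[, bins, drop = FALSE])
      feats <- (feats - model@featureCenter) / model@featureScale
      dF <- cbind(0, feats[, -1, drop = FALSE] - feats[, -ncol(feats), drop = FALSE])
      W <- t(dF) %*% model@U        # bins x 3
      colnames(W) <- labels
      pre <- if (on >= 1L) {
        pf <- .featureTransform(tr$rates[, seq_len(on), drop = FALSE])
        pf <- (pf - model@featureCenter) / model@featureScale
        sqrt(sum(rowMeans(pf)^2))
      } else NA_real_
      perTrial[[length(perTrial) + 1L]] <- list(
        network = i, trial = j,
        group = paste(speed[row], tr$choice, sep = "_"),
        alignedBins = seq_along(bins) - length(bins),  # 0 at decision
        W = W, preMagnitude = pre)
    }
  }
  if (dropped > 0L)
    warning(dropped, " trial(s) shorter than ", minBins, " bins excluded")

  groups <- c("fast_left", "fast_right", "slow_left", "slow_right")
  rows <- list()
  for (g in groups) {
    sel <- Filter(function(x) x$group == g, perTrial)
    if (!length(sel)) next
    preMag <- mean(vapply(sel, function(x) x$preMagnitude, numeric(1)),
                   na.rm = TRUE)
    allBins <- sort(unique(unlist(lapply(sel, `[[`, "alignedBins"))))
    for (ens in labels) {
      cums <- lapply(sel, function(x)
        stats::setNames(cumsum(x$W[, ens]), x$alignedBins))
      incs <- lapply(sel, function(x)
        stats::setNames(x$W[, ens], x$alignedBins))
      for (b in allBins) {
        vals <- unlist(lapply(incs, function(v) v[as.character(b)]))
        vals <- vals[!is.na(vals)]
        cvals <- unlist(lapply(cums, function(v) v[as.character(b)]))
        cvals <- cvals[!is.na(cvals)]
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, aligned_bin = b, ensemble = ens,
          mean = mean(vals), sd = stats::sd(vals), n = length(vals),
          cum_mean = mean(cvals),
          pct_change = 100 * mean(cvals) / preMag)
      }
    }
  }
  summary <- if (length(rows)) do.call(rbind, rows)
             else data.frame(group = character(0), aligned_bin = integer(0),
                             ensemble = character(0), mean = numeric(0),
                             sd = numeric(0), n = integer(0),
                             cum_mean = numeric(0), pct_change = numeric(0))
  rownames(summary) <- NULL
  list(summary = summary, trials = perTrial)
}

#' Onset bin of each group-mean drive
#'
#' The aligned bin at which the absolute cumulative group-mean drive first
#' reaches a fraction (default half) of its peak deviation from baseline;
#' used to compare when the choice versus responsiveness/pliancy ensembles
#' engage.  The peak rather than the value at decision anchors the
#' normalization because a drive can return toward baseline as the network
#' passes through commitment.
#'
#' @param drives Output of \code{\link{driveTimeseries}}.
#' @param frac Fraction of the peak |cumulative drive| (default 0.5).
#' @return data.frame(group, ensemble, onset_bin).
#' @export
driveOnsets <- function(drives, frac = 0.5) {
  s <- drives$summary
  out <- list()
  for (g in unique(s$group)) for (e in unique(s$ensemble)) {
    ss <- s[s$group == g & s$ensemble == e, ]
    ss <- ss[order(ss$aligned_bin), ]
    if (!nrow(ss)) next
    peak <- max(abs(ss$cum_mean))
    hit <- which(abs(ss$cum_mean) >= frac * peak)
    out[[paste(g, e)]] <- data.frame(
      group = g, ensemble = e,
      onset_bin = if (length(hit)) ss$aligned_bin[hit[1]] else NA_integer_)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Project zone-to-zone activity changes into DDM parameter changes
#'
#' For every ordered zone pair (i, j) with a direct transition in at least
#' one network, the change in zone-mean standardized features
#' \eqn{\Delta F_{ij}} (zone j mean minus zone i mean, one row per network
#' exhibiting the transition) is projected onto the ensemble space,
#' \eqn{W_{ij} = \Delta F_{ij} U}, and onward to the DDM space,
#' \eqn{P_{ij} = W_{ij} V^T}.  Column medians summarize each pair;
#' percentage changes are relative to each network's fitted static DDM
#' parameters.
#'
#' @param traces A \linkS4class{RateTraceSet}.
#' @param partition A \linkS4class{ZonePartition}.
#' @param model A labeled \linkS4class{EnsembleModel}.
#' @param ddm Optional n_networks x 4 matrix of fitted DDM parameters (from
#'   \code{\link{buildDdmMatrix}}) for the percentage changes.
#' @param sequences Optional precomputed sequences (recomputed from
#'   \code{traces} when NULL).
#' @return list with \code{parameters} (data.frame: zone_from, zone_to,
#'   parameter, median_change, pct_change, n_networks), \code{drives}
#'   (data.frame: zone_from, zone_to, ensemble, median_drive, n_networks)
#'   and \code{pairs} (list of per-pair W and P matrices).
#' @export
zoneProjection <- function(traces, partition, model, ddm = NULL,
                           sequences = NULL) {
  if (is.null(sequences))
    sequences <- extractSequences(binarizeTraces(traces))
  labels <- model@labels
  if (all(is.na(labels))) labels <- paste0("component", seq_len(ncol(model@U)))

  nNet <- nNetworks(traces)
  zoneNames <- setdiff(unique(partition@map), "unassigned")
  # per network: zone-mean standardized features and observed transitions
  zoneMeans <- vector("list", nNet)
  zoneTrans <- vector("list", nNet)
  featAccum <- lapply(seq_len(nNet), function(i)
    lapply(setNames(zoneNames, zoneNames), function(z)
      list(sum = numeric(18), n = 0L)))
  for (sq in sequences) {
    i <- sq$network
    tr <- networkTrials(traces, i)[[sq$trial]]
    bins <- .analysisBins(tr)
    feats <- .featureTransform(tr$rates[, bins, drop = FALSE])
    feats <- (feats - model@featureCenter) / model@featureScale
    zs <- stateZone(partition, sq$labels)
    for (z in zoneNames) {
      occ <- zs == z
      if (any(occ)) {
        featAccum[[i]][[z]]$sum <- featAccum[[i]][[z]]$sum +
          rowSums(feats[, occ, drop = FALSE])
        featAccum[[i]][[z]]$n <- featAccum[[i]][[z]]$n + sum(occ)
      }
    }
    zseq <- rle(zs[zs != "unassigned"])$values
    if (length(zseq) > 1L)
      zoneTrans[[i]] <- unique(rbind(zoneTrans[[i]],
                                     cbind(zseq[-length(zseq)], zseq[-1L])))
  }
  zoneMeans <- lapply(featAccum, function(zl)
    lapply(zl, function(a) if (a$n > 0L) a$sum / a$n else NULL))

  pairKeys <- unique(do.call(rbind, zoneTrans))
  if (is.null(pairKeys) || nrow(pairKeys) == 0L)
    stop("no zone transitions observed")
  rowsP <- list(); rowsW <- list(); pairs <- list()
  for (r in seq_len(nrow(pairKeys))) {
    zi <- pairKeys[r, 1]; zj <- pairKeys[r, 2]
    nets <- which(vapply(seq_len(nNet), function(i) {
      tz <- zoneTrans[[i]]
      !is.null(tz) && any(tz[, 1] == zi & tz[, 2] == zj) &&
        !is.null(zoneMeans[[i]][[zi]]) && !is.null(zoneMeans[[i]][[zj]])
    }, logical(1)))
    if (!length(nets)) next
    dF <- t(vapply(nets, function(i)
      zoneMeans[[i]][[zj]] - zoneMeans[[i]][[zi]], numeric(18)))
    W <- dF %*% model@U
    P <- W %*% t(model@V)
    colnames(W) <- labels; colnames(P) <- rownames(model@V)
    key <- paste(zi, zj, sep = "->")
    pairs[[key]] <- list(networks = nets, dF = dF, W = W, P = P)
    for (ens in labels) {
      rowsW[[paste(key, ens)]] <- data.frame(
        zone_from = zi, zone_to = zj, ensemble = ens,
        median_drive = stats::median(W[, ens]), n_networks = length(nets))
    }
    for (pm in colnames(P)) {
      pcts <- if (!is.null(ddm)) {
        raw <- P[, pm] * model@ddmScale[pm]
        100 * raw / abs(ddm[nets, pm])
      } else NA_real_
      rowsP[[paste(key, pm)]] <- data.frame(
        zone_from = zi, zone_to = zj, parameter = pm,
        median_change = stats::median(P[, pm]),
        pct_change = stats::median(pcts),
        n_networks = length(nets))
    }
  }
  parameters <- do.call(rbind, rowsP); rownames(parameters) <- NULL
  drives <- do.call(rbind, rowsW); rownames(drives) <- NULL
  list(parameters = parameters, drives = drives, pairs = pairs)
}
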