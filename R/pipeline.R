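# Polynomial hash of the serialized analysis configuration (the output
# location is excluded); stamps output manifests so runs with differing
# configurations are never silently mixed.
.configHash <- function(x) {
  x$outDir <- NULL
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Assemble a pipeline configuration
#'
#' @param nNetworks Number of networks (desk-scale default 30; the full
#'   study scale is 300).
#' @param nTrials Trials per network (default 50).
#' @param seed Global seed; all stage randomness flows from it via named
#'   substreams.
#' @param outDir Output directory (NULL for no file output).
#' @param stages Character subset of
#'   c("simulate", "binarize", "claw", "ddm", "ensembles") to run; later
#'   stages require earlier ones.
#' @param mode Transition counting mode.
#' @param gap Pruning gap.
#' @param jitter Weight jitter for network sampling.
#' @param screen Feasibility-screen networks when sampling.
#' @return Named list (class \code{pipelineConfig}).
#' @export
pipelineConfig <- function(nNetworks = 30L, nTrials = 50L, seed = 1L,
                           outDir = NULL,
                           stages = c("simulate", "binarize", "claw", "ddm",
                                      "ensembles"),
                           mode = "per_change", gap = 0.25,
                           jitter = 0.12, screen = TRUE) {
  structure(list(nNetworks = as.integer(nNetworks),
                 nTrials = as.integer(nTrials), seed = as.integer(seed),
                 outDir = outDir, stages = stages, mode = mode, gap = gap,
                 jitter = jitter, screen = screen),
            class = "pipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: network sampling and trial simulation, binarization,
#' state-sequence extraction and graph construction with zone partition,
#' per-network DDM fitting, and the control-ensemble analysis (CCA,
#' labeling, drive time series, zone projection).  All tabular outputs are
#' written as CSV under \code{config$outDir} (when set) together with a
#' JSON manifest carrying the configuration hash, so identical
#' configurations yield byte-identical outputs.
#'
#' @param config A \code{\link{pipelineConfig}}.
#' @return Invisibly, a report list with elements traces, binary,
#'   sequences, graph, stats, partition, tertiles, ddm, model, drives,
#'   zoneProjection, manifest (stages not run are absent).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  stages <- config$stages
  report <- list()
  storedConfig <- unclass(config)
  storedConfig$outDir <- NULL
  manifest <- list(hash = .configHash(unclass(config)),
                   config = storedConfig,
                   seeds = list(global = config$seed))

  message("stage simulate: ", config$nNetworks, " networks x ",
          config$nTrials, " trials")
  cfgs <- withCallingHandlers(
    sampleNetworks(config$nNetworks, seed = .deriveSeed(config$seed, "network"),
                   jitter = config$jitter, screen = config$screen),
    error = function(e) stop("stage simulate (network sampling): ",
                             conditionMessage(e), call. = FALSE))
  sets <- lapply(seq_along(cfgs), function(i) {
    tryCatch(
      runExperiment(cfgs[[i]], nTrials = config$nTrials,
                    seed = .deriveSeed(config$seed, "trials", i)),
      error = function(e) stop(sprintf("stage simulate, network %d: %s", i,
                                       conditionMessage(e)), call. = FALSE))
  })
  traces <- combineTraceSets(sets)
  report$traces <- traces
  if (!"binarize" %in% stages) return(.finishPipeline(report, manifest, config))

  report$binary <- tryCatch(binarizeTraces(traces), error = function(e)
    stop("stage binarize: ", conditionMessage(e), call. = FALSE))
  if (!"claw" %in% stages) return(.finishPipeline(report, manifest, config))

  report$sequences <- extractSequences(report$binary)
  raw <- estimateTransitions(report$sequences, mode = config$mode)
  report$stats <- computeStateStats(report$sequences)
  report$graph <- pruneGraph(raw, gap = config$gap, stats = report$stats)
  report$partition <- partitionZones(report$graph)
  beh <- behaviorTable(traces)
  report$tertiles <- dtTertiles(ifelse(beh$choice == "none", NA,
                                       beh$decision_time_ms))
  if (!"ddm" %in% stages) return(.finishPipeline(report, manifest, config))

  report$ddm <- tryCatch(buildDdmMatrix(traces), error = function(e)
    stop("stage ddm: ", conditionMessage(e), call. = FALSE))
  if (!"ensembles" %in% stages) return(.finishPipeline(report, manifest, config))

  F <- buildFeatureMatrix(traces)
  model <- labelComponents(fitControlEnsembles(F, report$ddm$D))
  report$features <- F
  report$model <- model
  report$drives <- driveTimeseries(traces, model)
  report$zoneProjection <- zoneProjection(traces, report$partition, model,
                                          ddm = report$ddm$D,
                                          sequences = report$sequences)
  .finishPipeline(report, manifest, config)
}

.finishPipeline <- function(report, manifest, config) {
  report$manifest <- manifest
  if (!is.null(config$outDir)) .writePipelineOutputs(report, config)
  invisible(report)
}

.writePipelineOutputs <- function(report, config) {
  dir <- config$outDir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifestPath <- file.path(dir, "manifest.json")
  if (file.exists(manifestPath)) {
    old <- jsonlite::read_json(manifestPath)
    if (!identical(old$hash, report$manifest$hash))
      stop("output directory holds results from a different configuration (",
           old$hash, " vs ", report$manifest$hash, "); refusing to overwrite")
  }
  writeTraceSet(report$traces, dir)
  if (!is.null(report$binary)) {
    thr <- do.call(rbind, lapply(seq_along(report$binary@networks),
      function(i) cbind(network = i,
                        report$binary@networks[[i]]$thresholds@table)))
    utils::write.csv(thr, file.path(dir, "thresholds.csv"), row.names = FALSE)
  }
  if (!is.null(report$graph)) {
    exportGraph(report$graph, file.path(dir, "graph.json"), "json")
    exportGraph(report$graph, file.path(dir, "graph.graphml"), "graphml")
    exportGraph(report$graph, file.path(dir, "graph.dot"), "dot")
    utils::write.csv(report$stats, file.path(dir, "state_stats.csv"),
                     row.names = FALSE)
    zones <- data.frame(state = as.integer(names(report$partition@map)),
                        zone = unname(report$partition@map))
    utils::write.csv(zones, file.path(dir, "zones.csv"), row.names = FALSE)
  }
  if (!is.null(report$ddm)) {
    dd <- as.data.frame(report$ddm$D)
    dd <- cbind(network_id = seq_len(nrow(dd)), dd,
                loglik = vapply(report$ddm$fits, slot, numeric(1), "loglik"),
                converged = vapply(report$ddm$fits, slot, logical(1),
                                   "converged"))
    utils::write.csv(dd, file.path(dir, "ddm_params.csv"), row.names = FALSE)
  }
  if (!is.null(report$model)) {
    U <- report$model@U; V <- report$model@V
    loadings <- rbind(
      data.frame(side = "activity", name = rep(rownames(U), ncol(U)),
                 component = rep(report$model@labels, each = nrow(U)),
                 loading = as.vector(U)),
      data.frame(side = "ddm", name = rep(rownames(V), ncol(V)),
                 component = rep(report$model@labels, each = nrow(V)),
                 loading = as.vector(V)))
    utils::write.csv(loadings, file.path(dir, "loadings.csv"),
                     row.names = FALSE)
    utils::write.csv(report$drives$summary, file.path(dir, "drives.csv"),
                     row.names = FALSE)
    utils::write.csv(report$zoneProjection$parameters,
                     file.path(dir, "zone_projection.csv"), row.names = FALSE)
  }
  jsonlite::write_json(report$manifest, manifestPath, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  invisible(dir)
}

#' Write a trace set as per-network rate and behaviour CSV files
#'
#' @param traces A \linkS4class{RateTraceSet}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
writeTraceSet <- function(traces, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nNetworks(traces))) {
    trials <- networkTrials(traces, i)
    rows <- lapply(seq_along(trials), function(j) {
      m <- trials[[j]]$rates
      data.frame(trial = j,
                 bin_index = rep(seq_len(ncol(m)), each = nrow(m)),
                 population = rep(rownames(m), ncol(m)),
                 rate_hz = as.vector(m))
    })
    utils::write.csv(do.call(rbind, rows),
                     file.path(dir, sprintf("network%03d_rates.csv", i)),
                     row.names = FALSE)
  }
  beh <- behaviorTable(traces)
  utils::write.csv(beh, file.path(dir, "behavior.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read externally supplied rate and behaviour tables
#'
#' Accepts the CSV layout written by \code{\link{writeTraceSet}}: a rate
#' table with columns (trial, bin_index, population, rate_hz) and a
#' behaviour table with columns (trial, decision_time_ms, choice).  Rates
#' binned finer than 10 ms are rebinned to 10 ms by block means (with a
#' warning).  The returned set is usable by every downstream stage, which
#' is how experimental recordings can enter the analysis.
#'
#' @param rateCsv Path to the rate CSV.
#' @param behaviorCsv Path to the behaviour CSV.
#' @param binWidth Bin width of the input in ms (default 10); must divide
#'   10 when finer.
#' @param stimulusOnsetBin Last pre-stimulus bin index after rebinning
#'   (0 when recording starts at the stimulus).
#' @param config Carrier \linkS4class{NetworkConfig} for downstream
#'   defaults.
#' @return A single-network \linkS4class{RateTraceSet}.
#' @export
readExternalTables <- function(rateCsv, behaviorCsv, binWidth = 10,
                               stimulusOnsetBin = 0L,
                               config = defaultNetworkConfig()) {
  rates <- utils::read.csv(rateCsv, stringsAsFactors = FALSE)
  beh <- utils::read.csv(behaviorCsv, stringsAsFactors = FALSE)
  need <- c("trial", "bin_index", "population", "rate_hz")
  miss <- setdiff(need, names(rates))
  if (length(miss))
    stop("rate table is missing column(s): ", paste(miss, collapse = ", "))
  missB <- setdiff(c("trial", "decision_time_ms", "choice"), names(beh))
  if (length(missB))
    stop("behavior table is missing column(s): ", paste(missB, collapse = ", "))
  if (any(rates$rate_hz < 0)) stop("negative rates in rate table")
  if (!all(rates$population %in% populationNames()))
    stop("unknown population(s): ",
         paste(setdiff(unique(rates$population), populationNames()),
               collapse = ", "))

  factor <- 10 / binWidth
  if (binWidth != 10) {
    if (factor != round(factor) || factor < 1)
      stop("bin width must be 10 ms or divide it evenly, got ", binWidth)
    warning("rebinning ", binWidth, " ms bins to 10 ms by block means")
  }

  pops <- populationNames()
  trials <- lapply(sort(unique(rates$trial)), function(tid) {
    sub <- rates[rates$trial == tid, ]
    bins <- sort(unique(sub$bin_index))
    if (!identical(bins, seq_along(bins)))
      stop("trial ", tid, ": bin_index must be contiguous from 1 ",
           "(non-uniform binning?)")
    m <- matrix(NA_real_, length(pops), length(bins),
                dimnames = list(pops, NULL))
    idx <- cbind(match(sub$population, pops), sub$bin_index)
    m[idx] <- sub$rate_hz
    if (anyNA(m))
      stop("trial ", tid, ": incomplete population x bin coverage")
    if (factor > 1) {
      full <- (ncol(m) %/% factor) * factor
      m <- m[, seq_len(full), drop = FALSE]
      grp <- rep(seq_len(full / factor), each = factor)
      m <- t(apply(m, 1, function(x) tapply(x, grp, mean)))
      rownames(m) <- pops
    }
    b <- beh[beh$trial == tid, ]
    if (nrow(b) != 1L)
      stop("behavior table has no (or duplicated) row for trial ", tid)
    isTimeout <- b$choice == "none" || is.na(b$decision_time_ms)
    decBin <- if (isTimeout) 0L
              else as.integer(stimulusOnsetBin + ceiling(b$decision_time_ms / 10))
    if (!isTimeout && decBin > ncol(m))
      stop("trial ", tid, ": decision time exceeds trace length")
    list(rates = m,
         decisionTime = if (isTimeout) NA_real_ else b$decision_time_ms,
         choice = if (isTimeout) "none" else b$choice,
         phaseMarks = c(stimOnset = as.integer(stimulusOnsetBin),
                        decision = decBin,
                        consolidationEnd = decBin),
         seed = NA_integer_)
  })
  extra <- setdiff(beh$trial, rates$trial)
  if (length(extra))
    stop("behavior rows without matching rate trial id(s): ",
         paste(extra, collapse = ", "))
  rateTraceSet(list(config = config, trials = trials), binWidth = 10)
}
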