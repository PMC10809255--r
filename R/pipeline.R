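.pipelineTopKeys <- c("seed", "runs", "system", "simulate", "input",
                      "classifier", "dimer")

# validate a pipeline config list against the known schema; unknown keys are
# errors that name the key
validatePipelineConfig <- function(config) {
  unknown <- setdiff(names(config), .pipelineTopKeys)
  if (length(unknown))
    stop(sprintf("unknown config key: %s", paste(unknown, collapse = ", ")))
  if (!is.null(config$simulate)) {
    bad <- setdiff(names(config$simulate), methods::slotNames("SimConfig"))
    if (length(bad))
      stop(sprintf("unknown simulate key: %s", paste(bad, collapse = ", ")))
  }
  if (!is.null(config$classifier)) {
    bad <- setdiff(names(config$classifier),
                   methods::slotNames("ClassifierConfig"))
    if (length(bad))
      stop(sprintf("unknown classifier key: %s", paste(bad, collapse = ", ")))
  }
  if (!is.null(config$dimer)) {
    bad <- setdiff(names(config$dimer), methods::slotNames("DimerConfig"))
    if (length(bad))
      stop(sprintf("unknown dimer key: %s", paste(bad, collapse = ", ")))
  }
  if (is.null(config$simulate) && is.null(config$input))
    stop("config needs either a 'simulate' or an 'input' section")
  invisible(TRUE)
}

# static nanoparticle models for a simulated system
.simNpModels <- function(simCfg, nf) {
  nps <- list()
  for (k in seq_along(simCfg@np)) {
    np <- simCfg@np[[k]]
    nps[[paste0("SNP", k)]] <- new(
      "NanoparticleModel", group = paste0("SNP", k),
      centers = matrix(as.numeric(np$center), nf, 3, byrow = TRUE),
      radius = np$radius)
  }
  nps
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> per-frame geometric metrics -> state
#' classification -> dimer detection and classification -> summary tables,
#' writing every stage to \code{outDir} together with a JSON run manifest
#' (config snapshot, package version, seed, input digests, timestamp).
#' Reruns with an identical config and seed produce identical result tables.
#' On failure, partial outputs are removed.
#'
#' @param config a named list (see Details) or a path to a YAML file with
#'   the same structure. Top-level keys: \code{seed}; \code{runs} (number of
#'   repetitions, default 1); \code{simulate} ([SimConfig-class] fields) or
#'   \code{input} (\code{topology}, \code{sidecar}, \code{trajectory} paths
#'   plus \code{nanoparticles}, a list of \code{list(group, diameter)});
#'   optional \code{classifier} and \code{dimer} sections overriding
#'   [ClassifierConfig-class]/[DimerConfig-class] defaults; optional
#'   \code{system} label. Unknown keys anywhere are errors naming the key.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with \code{summaryStates}, \code{summaryDimers},
#'   per-run \code{segments}, \code{events}, \code{groundTruth}, and
#'   \code{outDir}.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  validatePipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(rows, name, schema) {
    p <- file.path(outDir, name)
    writeResultTable(rows, p, schema)
    written <<- c(written, p)
    p
  }
  ok <- FALSE
  on.exit({
    if (!ok && length(written)) unlink(written)
  })
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  nRuns <- if (is.null(config$runs)) 1L else as.integer(config$runs)
  systemName <- if (is.null(config$system)) "system" else config$system
  clsCfg <- do.call(classifierConfig, as.list(config$classifier))
  dimCfg <- do.call(dimerConfig, as.list(config$dimer))
  segmentsList <- list()
  eventsList <- list()
  gtList <- list()
  pct <- numeric(nRuns)
  inputDigests <- list()
  for (run in seq_len(nRuns)) {
    if (!is.null(config$simulate)) {
      simArgs <- config$simulate
      simArgs$scripted <- .normalizeScripted(simArgs$scripted)
      simCfg <- do.call(simConfig, simArgs)
      simCfg@seed <- subSeed(seed, run)
      sim <- simulateTrajectory(simCfg)
      traj <- sim$trajectory
      gtList[[run]] <- sim$groundTruth
      nps <- .simNpModels(simCfg, nFrames(traj))
    } else {
      top <- readTopology(config$input$topology,
                          sidecar = config$input$sidecar %||%
                            paste0(config$input$topology, ".tsv"))
      traj <- readTrajectory(config$input$trajectory, top)
      inputDigests <- lapply(
        c(topology = config$input$topology,
          trajectory = config$input$trajectory),
        function(p) unname(tools::md5sum(p)))
      nps <- list()
      for (npSpec in config$input$nanoparticles)
        nps[[npSpec$group]] <- nanoparticleModel(traj, npSpec$group,
                                                 diameter = npSpec$diameter)
    }
    dyes <- grep("^R6G_[0-9]+$", groupNames(traj), value = TRUE)
    metrics <- trajectoryMetrics(traj, dyes, nps)
    segments <- classifyStates(metrics, clsCfg)
    fd <- dimerFrameData(traj, dyes,
                         np = if (length(nps)) nps[[1]] else NULL)
    events <- detectDimers(fd, dimCfg)
    events <- classifyEvents(events, fd, segments, dimCfg)
    events$run <- rep(run, nrow(events))
    tlen <- max(metrics$time_ns) - min(metrics$time_ns)
    pct[run] <- adsorbedPercentage(segments, tlen)
    segmentsList[[run]] <- segments
    eventsList[[run]] <- events
    emit(metrics, sprintf("metrics_run%d.tsv", run), "metrics")
    emit(segments, sprintf("segments_run%d.tsv", run), "segments")
    emit(events[, c("dye_a", "dye_b", "start_ns", "end_ns", "location",
                    "end_reason")],
         sprintf("dimer_events_run%d.tsv", run), "dimer_events")
  }
  summaryStates <- data.frame(repetition = seq_len(nRuns))
  summaryStates[[systemName]] <- pct
  emit(summaryStates, "summary_states.tsv", "adsorption_summary")
  allEvents <- do.call(rbind, eventsList)
  summaryDimers <- cbind(system = systemName,
                         dimerStatistics(allEvents, runs = seq_len(nRuns)))
  names(summaryDimers) <- c("system", "mean_dimer_count", "total_time_ns",
                            "mean_lifetime_ns")
  emit(summaryDimers, "summary_dimers.tsv", "dimer_summary")
  manifest <- list(
    tool = "dyetraj",
    version = as.character(utils::packageVersion("dyetraj")),
    seed = seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    inputs = inputDigests
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  written <- c(written, file.path(outDir, "manifest.json"))
  ok <- TRUE
  invisible(list(summaryStates = summaryStates, summaryDimers = summaryDimers,
                 segments = segmentsList, events = eventsList,
                 groundTruth = gtList, adsorbedPct = pct, outDir = outDir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# YAML-friendly scripted blocks arrive as lists of records; coerce to the
# data.frames propagateScripted expects
.normalizeScripted <- function(scripted) {
  if (is.null(scripted) || length(scripted) == 0) return(list())
  coerce <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.data.frame(x)) return(x)
    do.call(rbind, lapply(x, function(rec) as.data.frame(rec)))
  }
  out <- list()
  if (!is.null(scripted$stateIntervals))
    out$stateIntervals <- coerce(scripted$stateIntervals)
  if (!is.null(scripted$dimerEvents))
    out$dimerEvents <- coerce(scripted$dimerEvents)
  out
}

#' Expected adsorbed percentage implied by a ground-truth script
#'
#' The union over dyes of scripted A/RA intervals as a percentage of the
#' spanned time; used to score a pipeline run against its generator script.
#'
#' @param groundTruth a [GroundTruth-class].
#' @param trajectoryLength ns.
#' @param countStates labels counted (default \code{c("A", "RA")}).
#' @return percent.
#' @export
groundTruthAdsorbedPercentage <- function(groundTruth, trajectoryLength,
                                          countStates = c("A", "RA")) {
  gi <- groundTruth@stateIntervals
  keep <- gi[gi$label %in% countStates, , drop = FALSE]
  100 * intervalUnionLength(keep$start_ns, keep$end_ns) / trajectoryLength
}
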