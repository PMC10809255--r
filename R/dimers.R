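#' Per-frame core geometry for dimer detection
#'
#' Extracts, for every dye and frame, the xanthene-core COM and core-plane
#' normal, plus (when a nanoparticle model is given) the per-dye surface
#' distance. This is the input of [detectDimers()].
#'
#' @param traj a [Trajectory-class].
#' @param dyes character vector of dye group names (each with a
#'   \code{"<dye>_core"} group).
#' @param np optional [NanoparticleModel-class] for surface distances.
#' @return list with \code{times} (ns), \code{coreCom} (frames x dyes x 3),
#'   \code{normals} (frames x dyes x 3), \code{dyes}, and optionally
#'   \code{np} and \code{surfDist} (frames x dyes).
#' @export
dimerFrameData <- function(traj, dyes, np = NULL) {
  top <- topologyOf(traj)
  times <- frameTimes(traj)
  nf <- length(times)
  nd <- length(dyes)
  coreCom <- array(NA_real_, c(nf, nd, 3))
  normals <- array(NA_real_, c(nf, nd, 3))
  surfDist <- if (!is.null(np)) matrix(NA_real_, nf, nd) else NULL
  for (f in seq_len(nf)) {
    fr <- frameCoords(traj, f)
    for (i in seq_len(nd)) {
      core <- paste0(dyes[i], "_core")
      coreCom[f, i, ] <- centerOfMass(top, fr, core)
      normals[f, i, ] <- corePlaneNormal(top, fr, core)
      if (!is.null(np))
        surfDist[f, i] <- vecNorm(coreCom[f, i, ] - np@centers[f, ]) - np@radius
    }
  }
  list(times = times, coreCom = coreCom, normals = normals, dyes = dyes,
       np = np, surfDist = surfDist)
}

# Vectorized per-frame stacking contacts for all dye pairs: core distance
# within cutoff AND folded inter-normal angle within tolerance.
# Returns pairs (2 x npairs), contact (nf x npairs), dist (nf x npairs).
stackingContactSeries <- function(frameData, config) {
  nd <- length(frameData$dyes)
  nf <- length(frameData$times)
  pairs <- utils::combn(nd, 2)
  npair <- ncol(pairs)
  dist <- matrix(NA_real_, nf, npair)
  contact <- matrix(FALSE, nf, npair)
  for (p in seq_len(npair)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    dv <- frameData$coreCom[, i, , drop = FALSE] -
      frameData$coreCom[, j, , drop = FALSE]
    dim(dv) <- c(nf, 3)
    d <- sqrt(rowSums(dv^2))
    dot <- rowSums(matrix(frameData$normals[, i, ], nf, 3) *
                     matrix(frameData$normals[, j, ], nf, 3))
    ang <- foldAngle(acos(pmin(1, pmax(-1, dot))) * 180 / pi)
    dist[, p] <- d
    contact[, p] <- d <= config@coreDistanceCutoff &
      ang <= config@stackingTolerance
  }
  list(pairs = pairs, contact = contact, dist = dist)
}

#' Detect stacked dimer events
#'
#' A dimer episode is a maximal run of frames in which a dye pair is in
#' stacking contact (core distance within cutoff, core planes parallel or
#' antiparallel within tolerance) and mutually assigned. A dye can belong
#' to at most one dimer at a time: per frame, contacts are assigned
#' greedily by increasing core distance, so in a pairwise-stacked triple the
#' closest pair forms the dimer and the third dye stays free. Episodes
#' shorter than the minimum duration are discarded.
#'
#' @param frameData output of [dimerFrameData()].
#' @param config a [DimerConfig-class].
#' @return data.frame with columns \code{dye_a, dye_b, start_ns, end_ns,
#'   startFrame, endFrame}.
#' @export
detectDimers <- function(frameData, config = dimerConfig()) {
  nd <- length(frameData$dyes)
  nf <- length(frameData$times)
  emptyEvents <- data.frame(dye_a = character(0), dye_b = character(0),
                            start_ns = numeric(0), end_ns = numeric(0),
                            startFrame = integer(0), endFrame = integer(0))
  if (nd < 2) return(emptyEvents)
  cs <- stackingContactSeries(frameData, config)
  pairs <- cs$pairs
  matched <- matrix(FALSE, nf, ncol(pairs))
  multi <- which(rowSums(cs$contact) > 0)
  for (f in multi) {
    inContact <- which(cs$contact[f, ])
    if (length(inContact) == 1) {
      matched[f, inContact] <- TRUE
      next
    }
    taken <- rep(FALSE, nd)
    for (p in inContact[order(cs$dist[f, inContact])]) {
      i <- pairs[1, p]; j <- pairs[2, p]
      if (taken[i] || taken[j]) next
      matched[f, p] <- TRUE
      taken[i] <- taken[j] <- TRUE
    }
  }
  out <- list()
  for (p in seq_len(ncol(pairs))) {
    runs <- trueRuns(matched[, p])
    if (nrow(runs) == 0) next
    for (r in seq_len(nrow(runs))) {
      dur <- frameData$times[runs[r, "end"]] - frameData$times[runs[r, "start"]]
      if (dur < config@minDimerDuration) next
      out[[length(out) + 1L]] <- data.frame(
        dye_a = frameData$dyes[pairs[1, p]],
        dye_b = frameData$dyes[pairs[2, p]],
        start_ns = frameData$times[runs[r, "start"]],
        end_ns = frameData$times[runs[r, "end"]],
        startFrame = as.integer(runs[r, "start"]),
        endFrame = as.integer(runs[r, "end"]))
    }
  }
  if (length(out) == 0) return(emptyEvents)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$start_ns, res$dye_a), ]
}

#' Detect transient trimer intervals around dimer events
#'
#' A trimer is a third dye in stacking contact with either member of an
#' active dimer. Trimers are intermediate states that enable member
#' exchange; they are flagged transient and never promoted to a stable
#' species.
#'
#' @param events dimer events from [detectDimers()].
#' @param frameData output of [dimerFrameData()].
#' @param config a [DimerConfig-class].
#' @return data.frame with columns \code{dye_a, dye_b, dye_c, start_ns,
#'   end_ns, transient}.
#' @export
detectTrimers <- function(events, frameData, config = dimerConfig()) {
  empty <- data.frame(dye_a = character(0), dye_b = character(0),
                      dye_c = character(0), start_ns = numeric(0),
                      end_ns = numeric(0), transient = logical(0))
  if (nrow(events) == 0) return(empty)
  dyes <- frameData$dyes
  cs <- stackingContactSeries(frameData, config)
  pairIndex <- matrix(NA_integer_, length(dyes), length(dyes))
  for (p in seq_len(ncol(cs$pairs)))
    pairIndex[cs$pairs[1, p], cs$pairs[2, p]] <-
      pairIndex[cs$pairs[2, p], cs$pairs[1, p]] <- p
  out <- list()
  for (e in seq_len(nrow(events))) {
    ia <- match(events$dye_a[e], dyes)
    ib <- match(events$dye_b[e], dyes)
    frames <- events$startFrame[e]:events$endFrame[e]
    for (k in setdiff(seq_along(dyes), c(ia, ib))) {
      inContact <- cs$contact[frames, pairIndex[k, ia]] |
        cs$contact[frames, pairIndex[k, ib]]
      runs <- trueRuns(inContact)
      if (nrow(runs) == 0) next
      for (r in seq_len(nrow(runs))) {
        out[[length(out) + 1L]] <- data.frame(
          dye_a = dyes[ia], dye_b = dyes[ib], dye_c = dyes[k],
          start_ns = frameData$times[frames[runs[r, "start"]]],
          end_ns = frameData$times[frames[runs[r, "end"]]],
          transient = TRUE)
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify dimer events: location and end reason
#'
#' Location is \code{"matrix"} when the median dimer-COM surface distance
#' during the event is within the matrix threshold, else \code{"solute"}.
#' The end reason is \code{"censored"} when the event reaches the final
#' frame; \code{"desorption"} when the intact pair's surface distance rises
#' from within the matrix threshold to beyond twice it before the contact
#' breaks; otherwise \code{"dissociation"} (the pair contact breaks; when
#' state segments are supplied, a break near the surface followed by a
#' partner entering A/RA within 1 ns is the canonical
#' dissociation-then-adsorption signature, recorded in the
#' \code{adsorption_followed} column).
#'
#' @param events dimer events from [detectDimers()].
#' @param frameData output of [dimerFrameData()] built with an \code{np};
#'   without one, every event is located in the solute.
#' @param segments optional state segments from [classifyStates()] used for
#'   the partner-adsorption check.
#' @param config a [DimerConfig-class].
#' @return the events data.frame with \code{location}, \code{end_reason}
#'   and \code{adsorption_followed} columns added.
#' @export
classifyEvents <- function(events, frameData, segments = NULL,
                           config = dimerConfig()) {
  events$location <- character(nrow(events))
  events$end_reason <- character(nrow(events))
  events$adsorption_followed <- rep(NA, nrow(events))
  if (nrow(events) == 0) return(events)
  times <- frameData$times
  nf <- length(times)
  dyes <- frameData$dyes
  for (e in seq_len(nrow(events))) {
    ia <- match(events$dye_a[e], dyes)
    ib <- match(events$dye_b[e], dyes)
    frames <- events$startFrame[e]:events$endFrame[e]
    if (is.null(frameData$np)) {
      events$location[e] <- "solute"
      events$end_reason[e] <- if (events$endFrame[e] >= nf)
        "censored" else "dissociation"
      next
    }
    np <- frameData$np
    mid <- (matrix(frameData$coreCom[frames, ia, ], length(frames), 3) +
              matrix(frameData$coreCom[frames, ib, ], length(frames), 3)) / 2
    sdist <- sqrt(rowSums((mid - np@centers[frames, , drop = FALSE])^2)) -
      np@radius
    events$location[e] <- if (stats::median(sdist) <= config@matrixThreshold)
      "matrix" else "solute"
    if (events$endFrame[e] >= nf) {
      events$end_reason[e] <- "censored"
      next
    }
    firstNear <- which(sdist <= config@matrixThreshold)[1]
    desorbed <- !is.na(firstNear) &&
      any(sdist[firstNear:length(sdist)] > 2 * config@matrixThreshold)
    if (desorbed) {
      events$end_reason[e] <- "desorption"
      next
    }
    events$end_reason[e] <- "dissociation"
    if (!is.null(segments) && nrow(segments) > 0) {
      nearBreak <- sdist[length(sdist)] <= config@matrixThreshold + 5
      partners <- segments$dye %in% c(events$dye_a[e], events$dye_b[e]) &
        segments$label %in% c("A", "RA") &
        segments$start_ns >= events$end_ns[e] &
        segments$start_ns <= events$end_ns[e] + 1
      events$adsorption_followed[e] <- nearBreak && any(partners)
    }
  }
  events
}

#' Dimer statistics per system
#'
#' Summarizes events grouped by independent runs of the same system:
#' \code{mean_dimer_count} is the mean number of events per run,
#' \code{total_time_ns} the mean over runs of summed event durations, and
#' \code{mean_lifetime_ns} the mean of the pooled individual event
#' durations (so for a single run, lifetime x count equals total time
#' exactly).
#'
#' @param events data.frame of dimer events with a \code{run} column.
#' @param runs vector of run identifiers; runs without events count as zero.
#' @return one-row data.frame: \code{mean_dimer_count, total_time_ns,
#'   mean_lifetime_ns}.
#' @export
dimerStatistics <- function(events, runs = unique(events$run)) {
  if (length(runs) == 0) stop("at least one run required")
  counts <- vapply(runs, function(r) sum(events$run == r), numeric(1))
  totals <- vapply(runs, function(r)
    sum(events$end_ns[events$run == r] - events$start_ns[events$run == r]),
    numeric(1))
  lifetimes <- events$end_ns - events$start_ns
  data.frame(
    mean_dimer_count = mean(counts),
    total_time_ns = mean(totals),
    mean_lifetime_ns = if (length(lifetimes)) mean(lifetimes) else 0
  )
}
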