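#' Near-surface episodes of a distance time series
#'
#' Maximal runs of frames whose surface distance is at most the adsorption
#' threshold; interruptions shorter than the gap tolerance are merged, so a
#' brief excursion does not split one physical visit into two.
#'
#' @param distance numeric vector of per-frame surface distances (Angstrom).
#' @param times numeric vector of frame times (ns), aligned with
#'   \code{distance}.
#' @param config a [ClassifierConfig-class].
#' @return data.frame with columns \code{startFrame, endFrame, start_ns,
#'   end_ns} (possibly 0 rows).
#' @export
nearSurfaceEpisodes <- function(distance, times, config = classifierConfig()) {
  if (length(distance) == 0) stop("empty distance series")
  if (length(distance) != length(times))
    stop("distance series not aligned with frame times")
  near <- distance <= config@adsorptionThreshold
  runs <- trueRuns(near)
  if (nrow(runs) == 0)
    return(data.frame(startFrame = integer(0), endFrame = integer(0),
                      start_ns = numeric(0), end_ns = numeric(0)))
  # merge episodes separated by gaps shorter than gapTolerance
  if (nrow(runs) > 1) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- times[runs[i, "start"]] - times[merged[nrow(merged), "end"]]
      if (gap < config@gapTolerance) {
        merged[nrow(merged), "end"] <- runs[i, "end"]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
    runs <- merged
  }
  data.frame(startFrame = as.integer(runs[, "start"]),
             endFrame = as.integer(runs[, "end"]),
             start_ns = times[runs[, "start"]],
             end_ns = times[runs[, "end"]])
}

#' Label one near-surface episode
#'
#' Labels follow the classification used for dye-on-silica trajectories:
#' \strong{A} (stable adsorption) when the episode lasts at least
#' \code{minADuration} and the planar core faces the surface (parallelism
#' angle within tolerance) for at least \code{parallelFractionA} of its
#' frames; \strong{T} (electrostatic trapping) when the core is essentially
#' never parallel (fraction below \code{parallelFractionTMax}) -- such
#' episodes typically last under \code{maxTDuration}, and longer
#' never-parallel episodes are still T but flagged; everything in between is
#' \strong{RA} (reorientation near the surface, short adsorption periods
#' included).
#'
#' @param episode one row of [nearSurfaceEpisodes()] output.
#' @param parallelAngle per-frame parallelism angles (deg) for the whole
#'   series.
#' @param theta per-frame dipole angles (deg) for the whole series; reported
#'   per segment as a corroborating observable, never used as a criterion.
#' @param distance per-frame surface distances (Angstrom).
#' @param times frame times (ns).
#' @param config a [ClassifierConfig-class].
#' @return one-row data.frame: \code{label, start_ns, end_ns,
#'   mean_surface_distance_A, parallel_fraction, mean_theta_deg, flagged}.
#' @export
labelEpisode <- function(episode, parallelAngle, theta, distance, times,
                         config = classifierConfig()) {
  n <- length(times)
  if (length(parallelAngle) != n || length(distance) != n ||
      (!is.null(theta) && length(theta) != n))
    stop("series misaligned with frame times")
  idx <- episode$startFrame:episode$endFrame
  if (episode$startFrame < 1 || episode$endFrame > n)
    stop("episode outside the trajectory span")
  duration <- times[episode$endFrame] - times[episode$startFrame]
  frac <- mean(parallelAngle[idx] <= config@parallelTolerance)
  label <- if (duration >= config@minADuration &&
               frac >= config@parallelFractionA) {
    "A"
  } else if (frac < config@parallelFractionTMax) {
    "T"
  } else {
    "RA"
  }
  flagged <- label == "T" && duration > config@maxTDuration
  data.frame(label = label,
             start_ns = times[episode$startFrame],
             end_ns = times[episode$endFrame],
             mean_surface_distance_A = mean(distance[idx]),
             parallel_fraction = frac,
             mean_theta_deg = if (is.null(theta)) NA_real_ else mean(theta[idx]),
             flagged = flagged)
}

#' Segment per-frame metrics into labelled state segments
#'
#' Applies [nearSurfaceEpisodes()] and [labelEpisode()] to every
#' dye-nanoparticle pair of a [trajectoryMetrics()] table.
#'
#' @param metrics data.frame from [trajectoryMetrics()].
#' @param config a [ClassifierConfig-class].
#' @return data.frame of [StateSegment]-style rows: \code{dye, np, label,
#'   start_ns, end_ns, mean_surface_distance_A, parallel_fraction,
#'   mean_theta_deg, flagged}.
#' @export
classifyStates <- function(metrics, config = classifierConfig()) {
  out <- list()
  for (key in split(metrics, list(metrics$dye, metrics$np), drop = TRUE)) {
    key <- key[order(key$time_ns), ]
    eps <- nearSurfaceEpisodes(key$surface_dist_A, key$time_ns, config)
    if (nrow(eps) == 0) next
    segs <- do.call(rbind, lapply(seq_len(nrow(eps)), function(i)
      labelEpisode(eps[i, ], key$parallel_angle_deg, key$theta_deg,
                   key$surface_dist_A, key$time_ns, config)))
    segs <- cbind(dye = key$dye[1], np = key$np[1], segs)
    out[[length(out) + 1L]] <- segs
  }
  if (length(out) == 0)
    return(data.frame(dye = character(0), np = character(0),
                      label = character(0), start_ns = numeric(0),
                      end_ns = numeric(0),
                      mean_surface_distance_A = numeric(0),
                      parallel_fraction = numeric(0),
                      mean_theta_deg = numeric(0), flagged = logical(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$dye, res$np, res$start_ns), ]
}

# Union measure (total length) of a set of [start, end] intervals.
intervalUnionLength <- function(start, end) {
  if (length(start) == 0) return(0)
  o <- order(start)
  start <- start[o]; end <- end[o]
  total <- 0
  curS <- start[1]; curE <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= curE) {
      curE <- max(curE, end[i])
    } else {
      total <- total + (curE - curS)
      curS <- start[i]; curE <- end[i]
    }
  }
  total + (curE - curS)
}

#' Percentage of the trajectory with at least one dye adsorbed
#'
#' The union over dyes of the counted segments, as a percentage of the
#' trajectory length. By default both A and RA segments count as adsorbed
#' time: per-repetition adsorbed percentages of weakly adsorbing systems are
#' dominated by RA episodes, so A-only counting cannot reproduce them.
#'
#' @param segments data.frame from [classifyStates()] (one run).
#' @param trajectoryLength ns (> 0).
#' @param countStates labels counted as adsorbed (default \code{c("A",
#'   "RA")}).
#' @return percent in [0, 100].
#' @export
adsorbedPercentage <- function(segments, trajectoryLength,
                               countStates = c("A", "RA")) {
  if (trajectoryLength <= 0) stop("trajectory length must be positive")
  keep <- segments[segments$label %in% countStates, , drop = FALSE]
  100 * intervalUnionLength(keep$start_ns, keep$end_ns) / trajectoryLength
}

#' Average per-repetition percentages, rounding half up
#'
#' Arithmetic mean over repetitions, rounded half away from zero to an
#' integer percent -- the convention under which a printed adsorbed-time
#' table reports 23 for a mean of 22.5 and 33 for 32.5.
#'
#' @param percentages numeric vector (>= 1 value).
#' @param rounding round half-up to integer (default TRUE).
#' @return percent.
#' @export
averageOverRepetitions <- function(percentages, rounding = TRUE) {
  if (length(percentages) == 0) stop("no repetition values supplied")
  m <- mean(percentages)
  if (rounding) roundHalfUp(m) else m
}

#' Per-frame state labels implied by a segment table
#'
#' Utility for scoring classifier output against ground truth: every frame
#' is labelled with the segment covering it (FREE outside all segments).
#' Segment intervals are treated as closed.
#'
#' @param segments data.frame with \code{dye, label, start_ns, end_ns}.
#' @param times frame times (ns).
#' @param dye dye name to extract labels for.
#' @return character vector of per-frame labels.
#' @export
frameLabels <- function(segments, times, dye) {
  lab <- rep("FREE", length(times))
  segs <- segments[segments$dye == dye, , drop = FALSE]
  if (nrow(segs) > 0) {
    for (i in seq_len(nrow(segs))) {
      sel <- times >= segs$start_ns[i] & times <= segs$end_ns[i]
      lab[sel] <- segs$label[i]
    }
  }
  lab
}
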