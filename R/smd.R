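# centered moving average with shrinking window at the edges
movingAverage <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2 == 0) window <- window + 1L
  half <- (window - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect unbinding transitions in a pulling force trace
#'
#' In constant-velocity pulling, each unbinding step shows as a sawtooth: the
#' spring force ramps up, then drops abruptly while the pulled compound jumps
#' forward. Transitions are detected on a smoothed trace by hysteresis: a
#' running maximum followed by a drop exceeding \code{dropThreshold} times
#' the robust noise sd (median absolute deviation of the detrended trace)
#' opens a transition, closed at the subsequent local minimum. A candidate
#' is kept only if the displacement increases by at least \eqn{dF/k} across
#' the drop, which separates genuine escapes from force noise. Force
#' amplitudes at the peak and the end are refined on a lightly smoothed
#' trace so the heavy smoothing used for detection does not bias the drop
#' magnitude.
#'
#' @param trace a [ForceTrace-class].
#' @param smoothingWindow ps, width of the centred moving average used for
#'   detection (default 50).
#' @param dropThreshold multiple of the robust noise sd a drop must exceed
#'   (default 3).
#' @return data.frame with columns \code{t_peak_ps, t_end_ps, f_end_pN,
#'   dF_pN}, ordered in time and non-overlapping.
#' @seealso [transitionEnergy()], [bindingEnergy()]
#' @export
detectTransitions <- function(trace, smoothingWindow = 50, dropThreshold = 3) {
  n <- length(trace@timePs)
  if (n == 0) stop("empty force trace")
  dt <- if (n > 1) stats::median(diff(trace@timePs)) else 1
  wSamples <- max(1L, round(smoothingWindow / dt))
  if (n < wSamples) stop("trace shorter than the smoothing window")
  smooth <- movingAverage(trace@forcePn, wSamples)
  fine <- movingAverage(trace@forcePn, max(1L, min(5L, wSamples)))
  resid <- trace@forcePn - smooth
  noiseSd <- stats::mad(resid)
  thr <- max(dropThreshold * noiseSd, 1e-9)
  empty <- data.frame(t_peak_ps = numeric(0), t_end_ps = numeric(0),
                      f_end_pN = numeric(0), dF_pN = numeric(0))
  # hysteresis walk on the smoothed trace
  events <- list()
  iMax <- 1L; inDrop <- FALSE; iMin <- NA_integer_
  for (i in seq_len(n)) {
    if (!inDrop) {
      if (smooth[i] >= smooth[iMax]) iMax <- i
      if (smooth[iMax] - smooth[i] > thr) {
        inDrop <- TRUE
        iMin <- i
      }
    } else {
      if (smooth[i] < smooth[iMin]) iMin <- i
      if (smooth[i] - smooth[iMin] > thr || i == n) {
        events[[length(events) + 1L]] <- c(iMax, iMin)
        iMax <- i
        inDrop <- FALSE
      }
    }
  }
  if (inDrop) events[[length(events) + 1L]] <- c(iMax, iMin)
  if (length(events) == 0) return(empty)
  half <- max(1L, wSamples %/% 2L)
  out <- list()
  lastEnd <- -Inf
  for (ev in events) {
    pk <- ev[1]; tr <- ev[2]
    # refine extrema on the lightly smoothed trace near the detected ones
    pkWin <- max(1L, pk - half):min(n, pk + half)
    pkRef <- pkWin[which.max(fine[pkWin])]
    trWin <- max(1L, tr - half):min(n, tr + half)
    trWin <- trWin[trWin > pkRef]
    if (length(trWin) == 0) next
    trRef <- trWin[which.min(fine[trWin])]
    dF <- fine[pkRef] - fine[trRef]
    if (dF < thr) next
    # displacement must advance by ~dF/k across the drop; the 0.9 factor
    # absorbs noise-induced overestimation of dF
    dx <- trace@displacementA[trRef] - trace@displacementA[pkRef]
    if (dx < 0.9 * dF / trace@springConstant) next
    if (trace@timePs[pkRef] - lastEnd < smoothingWindow && lastEnd > -Inf)
      next
    lastEnd <- trace@timePs[trRef]
    out[[length(out) + 1L]] <- data.frame(
      t_peak_ps = trace@timePs[pkRef], t_end_ps = trace@timePs[trRef],
      f_end_pN = fine[trRef], dF_pN = dF)
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}

#' Spring potential-energy release of one transition
#'
#' The energy released when the stored spring energy relaxes across a force
#' drop: \deqn{dE = \frac{(F_0 + dF)^2 - F_0^2}{2k}} with \eqn{F_0} the
#' force at the end of the transition, \eqn{dF} the force change, and
#' \eqn{k} the spring constant -- equivalently \eqn{F_0 dF/k + dF^2/(2k)}.
#' With \code{f0 = "peak"} the supplied force is instead interpreted as the
#' force at the peak, i.e. \eqn{dE = (F_0^2 - (F_0 - dF)^2)/(2k)}; the
#' "end" convention is the default and the one used throughout.
#'
#' @param f0 force at the end of the transition (pN); with
#'   \code{f0Convention = "peak"}, the force at the peak.
#' @param dF drop magnitude (pN, >= 0).
#' @param k spring constant (pN/Angstrom, > 0).
#' @param f0Convention "end" (default) or "peak".
#' @return energy in eV.
#' @examples
#' transitionEnergy(100, 200, 278) # (300^2 - 100^2) / (2*278) pN.A in eV
#' @export
transitionEnergy <- function(f0, dF, k, f0Convention = c("end", "peak")) {
  f0Convention <- match.arg(f0Convention)
  if (any(k <= 0)) stop("spring constant must be positive")
  if (any(dF < 0)) stop("drop magnitude must be non-negative")
  pnA <- if (f0Convention == "end") {
    ((f0 + dF)^2 - f0^2) / (2 * k)
  } else {
    (f0^2 - (f0 - dF)^2) / (2 * k)
  }
  pnA * PNA_TO_EV
}

#' Total binding energy from detected transitions
#'
#' The estimated desorption or dissociation energy is the sum of the
#' per-transition spring energy releases.
#'
#' @param transitions data.frame from [detectTransitions()].
#' @param k spring constant (pN/Angstrom).
#' @param f0Convention passed to [transitionEnergy()].
#' @return total energy in eV.
#' @export
bindingEnergy <- function(transitions, k, f0Convention = "end") {
  if (nrow(transitions) == 0) return(0)
  sum(transitionEnergy(transitions$f_end_pN, transitions$dF_pN, k,
                       f0Convention = f0Convention))
}

#' Analyze a pulling trace end to end
#'
#' Convenience wrapper: detect transitions, attach per-transition energies,
#' and report the total in eV, kcal/mol and pN.Angstrom.
#'
#' @param trace a [ForceTrace-class].
#' @param smoothingWindow,dropThreshold passed to [detectTransitions()].
#' @param f0Convention passed to [transitionEnergy()].
#' @return list with \code{transitions} (data.frame incl. \code{dE_eV}) and
#'   \code{totalEnergy} (named numeric: eV, kcal_mol, pN_A).
#' @export
analyzeSMDTrace <- function(trace, smoothingWindow = 50, dropThreshold = 3,
                            f0Convention = "end") {
  tr <- detectTransitions(trace, smoothingWindow, dropThreshold)
  tr$dE_eV <- if (nrow(tr)) transitionEnergy(tr$f_end_pN, tr$dF_pN,
                                             trace@springConstant,
                                             f0Convention = f0Convention)
  else numeric(0)
  totalEv <- sum(tr$dE_eV)
  list(transitions = tr,
       totalEnergy = c(eV = totalEv,
                       kcal_mol = totalEv / PNA_TO_EV / KCALMOL_TO_PNA,
                       pN_A = totalEv / PNA_TO_EV))
}

#' Read a pulling force trace from TSV
#'
#' Columns \code{time_ps, force_pN, displacement_A}.
#'
#' @param path path to the TSV.
#' @param springConstant pN/Angstrom.
#' @param pullingVelocity Angstrom/ps (optional).
#' @return a [ForceTrace-class].
#' @export
readForceTrace <- function(path, springConstant, pullingVelocity = NA_real_) {
  if (!file.exists(path)) stop(sprintf("trace file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t")
  need <- c("time_ps", "force_pN", "displacement_A")
  if (!all(need %in% names(df)))
    stop("trace must have columns time_ps, force_pN, displacement_A")
  forceTrace(df$time_ps, df$force_pN, df$displacement_A, springConstant,
             pullingVelocity)
}

#' Write a pulling force trace to TSV
#'
#' @param trace a [ForceTrace-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeForceTrace <- function(trace, path) {
  df <- data.frame(time_ps = sprintf("%.4f", trace@timePs),
                   force_pN = sprintf("%.4f", trace@forcePn),
                   displacement_A = sprintf("%.4f", trace@displacementA))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
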