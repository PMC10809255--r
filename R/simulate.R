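# --- quaternion helpers (unit quaternions as c(w, x, y, z)) ---

quatToMat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

quatMultiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

rotvecToQuat <- function(v) {
  ang <- vecNorm(v)
  if (ang < 1e-12) return(c(1, 0, 0, 0))
  ax <- v / ang
  c(cos(ang / 2), sin(ang / 2) * ax)
}

randomQuat <- function() {
  q <- stats::rnorm(4)
  q / vecNorm(q)
}

# rotation matrix sending the body z-axis onto the unit vector n
alignZTo <- function(n) {
  n <- n / vecNorm(n)
  z <- c(0, 0, 1)
  v <- c(z[2] * n[3] - z[3] * n[2], z[3] * n[1] - z[1] * n[3],
         z[1] * n[2] - z[2] * n[1])
  s <- vecNorm(v)
  cth <- sum(z * n)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # flip around x
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

# --- rigid templates ---

# Rigid dye body: a planar near-rectangular core grid (the xanthene proxy)
# plus an out-of-plane tail, all sites equal mass, total charge +1e with an
# in-plane gradient so the dipole is non-zero. Coordinates are centred on
# the COM; the core plane normal is the body z-axis.
makeDyeTemplate <- function(siteCount = 64) {
  siteCount <- as.integer(siteCount)
  if (siteCount < 8) stop("dye template needs at least 8 sites")
  nCore <- if (siteCount >= 64) 30L else max(4L, siteCount %/% 2L)
  ncol_ <- ceiling(sqrt(nCore))
  nrow_ <- ceiling(nCore / ncol_)
  gx <- rep(seq_len(ncol_), times = nrow_)[seq_len(nCore)]
  gy <- rep(seq_len(nrow_), each = ncol_)[seq_len(nCore)]
  core <- cbind((gx - mean(gx)) * 1.4, (gy - mean(gy)) * 1.4, 0)
  nTail <- siteCount - nCore
  tdir <- c(1, 0, 0.6); tdir <- tdir / vecNorm(tdir)
  t0 <- c(max(core[, 1]) + 1.2, 0, 0)
  tail <- t(sapply(seq_len(nTail), function(i) t0 + tdir * 1.2 * (i - 1)))
  xyz <- rbind(core, tail)
  xyz <- sweep(xyz, 2, colMeans(xyz))
  q <- rep(1 / siteCount, siteCount)
  q <- q + 0.01 * (xyz[, 1] - mean(xyz[, 1]))
  q <- q - (sum(q) - 1) / siteCount  # renormalize to +1e exactly
  list(xyz = xyz, mass = rep(12, siteCount), charge = q,
       coreIdx = seq_len(nCore))
}

# Nanoparticle proxy: sites on a Fibonacci sphere of the given radius; total
# charge is the negative of the neutralizing sodium count implied by an
# ionized-silanol surface density of ~0.01 per A^2, with a polar gradient so
# the particle carries a non-zero dipole moment.
makeNPTemplate <- function(radius, nSites = 128) {
  i <- seq_len(nSites) - 0.5
  phi <- acos(1 - 2 * i / nSites)
  theta <- pi * (1 + sqrt(5)) * i
  xyz <- radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta),
                        cos(phi))
  totalCharge <- -roundHalfUp(0.01 * 4 * pi * radius^2)
  q <- rep(totalCharge / nSites, nSites) + 0.004 * xyz[, 3]
  q <- q - (sum(q) - totalCharge) / nSites
  list(xyz = xyz, mass = rep(20, nSites), charge = q)
}

#' Build the synthetic topology for a simulator configuration
#'
#' Nanoparticle sites come first (groups \code{"SNP1"}, ...), then each
#' dye's sites (groups \code{"R6G_i"} with core subset \code{"R6G_i_core"}).
#'
#' @param config a [SimConfig-class].
#' @return list with \code{topology}, the per-body templates and site index
#'   offsets (internal layout).
#' @export
makeSyntheticTopology <- function(config) {
  npT <- lapply(config@np, function(np) makeNPTemplate(np$radius))
  dyeT <- makeDyeTemplate(config@dyeSiteCount)
  nDye <- as.integer(config@nDye)
  masses <- c(unlist(lapply(npT, `[[`, "mass")),
              rep(dyeT$mass, nDye))
  chargesV <- c(unlist(lapply(npT, `[[`, "charge")),
                rep(dyeT$charge, nDye))
  groups <- list()
  offset <- 0L
  npOffsets <- integer(length(npT))
  for (k in seq_along(npT)) {
    nS <- nrow(npT[[k]]$xyz)
    groups[[paste0("SNP", k)]] <- offset + 0:(nS - 1L)
    npOffsets[k] <- offset
    offset <- offset + nS
  }
  dyeOffsets <- integer(nDye)
  for (i in seq_len(nDye)) {
    nS <- nrow(dyeT$xyz)
    dye <- paste0("R6G_", i)
    groups[[dye]] <- offset + 0:(nS - 1L)
    groups[[paste0(dye, "_core")]] <- offset + dyeT$coreIdx - 1L
    dyeOffsets[i] <- offset
    offset <- offset + nS
  }
  top <- topology(0:(offset - 1L), masses, chargesV, groups)
  list(topology = top, dyeTemplate = dyeT, npTemplates = npT,
       npOffsets = npOffsets, dyeOffsets = dyeOffsets)
}

# smooth orientation gate: 1 well inside the gate, cosine ramp to 0 at the
# gate edge (ramp width 10 degrees)
gateFactor <- function(angleDeg, gateDeg, ramp = 10) {
  x <- (angleDeg - (gateDeg - ramp)) / ramp
  ifelse(x <= 0, 1, ifelse(x >= 1, 0, 0.5 * (1 + cos(pi * x))))
}

# assemble the [particle, 3, frame] coordinate array from rigid-body states
assembleCoords <- function(layout, config, centers, quats, nf) {
  nDye <- as.integer(config@nDye)
  nTotal <- nParticles(layout$topology)
  coords <- array(NA_real_, c(nTotal, 3, nf))
  for (k in seq_along(layout$npTemplates)) {
    xyz <- sweep(layout$npTemplates[[k]]$xyz, 2,
                 -as.numeric(config@np[[k]]$center))
    idx <- layout$npOffsets[k] + seq_len(nrow(xyz))
    for (f in seq_len(nf)) coords[idx, , f] <- xyz
  }
  body <- layout$dyeTemplate$xyz
  for (f in seq_len(nf)) {
    for (i in seq_len(nDye)) {
      R <- quatToMat(quats[[i]][f, ])
      idx <- layout$dyeOffsets[i] + seq_len(nrow(body))
      coords[idx, , f] <- body %*% t(R) +
        matrix(centers[f, i, ], nrow(body), 3, byrow = TRUE)
    }
  }
  coords
}

# emergent overdamped Langevin propagation; returns centers [frame, dye, 3],
# quats (list of frame x 4 matrices) and per-frame engagement logs
propagateEmergent <- function(config) {
  nDye <- as.integer(config@nDye)
  dt <- config@timestep
  nf <- as.integer(round(config@duration / dt))
  Dt <- config@translationalDiffusion
  Dr <- config@rotationalDiffusion
  npList <- config@np
  centers <- array(NA_real_, c(nf, nDye, 3))
  quats <- lapply(seq_len(nDye), function(i) matrix(NA_real_, nf, 4))
  adsEngaged <- array(FALSE, c(nf, nDye, length(npList)))
  stackEngaged <- array(FALSE, c(nf, nDye, nDye))
  # initial placement: random directions, 8-20 A off the first NP surface
  # (or around the origin if no NP)
  pos <- matrix(NA_real_, nDye, 3)
  refC <- if (length(npList)) as.numeric(npList[[1]]$center) else c(0, 0, 0)
  refR <- if (length(npList)) npList[[1]]$radius else 0
  for (i in seq_len(nDye)) {
    u <- stats::rnorm(3); u <- u / vecNorm(u)
    pos[i, ] <- refC + u * (refR + stats::runif(1, 8, 20))
  }
  qs <- lapply(seq_len(nDye), function(i) randomQuat())
  noiseScale <- sqrt(2 * Dt * dt)
  rotScale <- sqrt(2 * Dr * dt)
  s0 <- 2.5; wW <- 2.0   # adsorption well centre and width (A)
  d0 <- 4.0; wS <- 2.0   # stacking well centre and width (A)
  # stability: each interaction's deterministic displacement per step must
  # stay below 0.5 A, otherwise the timestep cannot resolve the force
  checkStable <- function(stepLen) {
    m <- max(stepLen)
    if (m > 0.5)
      stop(sprintf(
        "unstable timestep: deterministic displacement %.2f A > 0.5 A per step",
        m))
  }
  for (f in seq_len(nf)) {
    normals <- t(vapply(qs, function(q) quatToMat(q) %*% c(0, 0, 1),
                        numeric(3)))
    drift <- matrix(0, nDye, 3)
    for (k in seq_along(npList)) {
      np <- npList[[k]]
      rel <- sweep(pos, 2, as.numeric(np$center))
      r <- sqrt(rowSums(rel^2))
      u <- rel / r
      s <- r - np$radius
      # screened electrostatic attraction
      dUds <- config@electrostaticStrength / config@screeningLength *
        exp(-pmax(s, 0) / config@screeningLength)
      # orientation-gated adsorption well
      ang <- foldAngle(acos(pmin(1, pmax(-1, rowSums(normals * u)))) *
                         180 / pi)
      g <- gateFactor(ang, config@orientationGateWidth)
      adsOn <- np$wellDepth > 0 & g >= 0.5 & s <= 5
      adsEngaged[f, , k] <- adsOn
      dUds <- dUds + np$wellDepth * g * (s - s0) / wW^2 *
        exp(-(s - s0)^2 / (2 * wW^2))
      checkStable(abs(Dt * dUds * dt))
      drift <- drift - Dt * dUds * u * dt
    }
    if (nDye > 1 && config@stackingWellDepth > 0) {
      for (i in seq_len(nDye - 1)) for (j in (i + 1):nDye) {
        dv <- pos[i, ] - pos[j, ]
        d <- vecNorm(dv)
        if (d > d0 + 4 * wS) next
        angN <- foldAngle(angleDeg(normals[i, ], normals[j, ]))
        g <- gateFactor(angN, config@stackingGateWidth)
        if (g <= 0) next
        on <- g >= 0.5 & d <= 6
        stackEngaged[f, i, j] <- stackEngaged[f, j, i] <- on
        dUdd <- config@stackingWellDepth * g * (d - d0) / wS^2 *
          exp(-(d - d0)^2 / (2 * wS^2))
        fvec <- Dt * dUdd * dv / d * dt
        checkStable(vecNorm(fvec))
        drift[i, ] <- drift[i, ] - fvec
        drift[j, ] <- drift[j, ] + fvec
      }
    }
    pos <- pos + drift +
      matrix(stats::rnorm(3 * nDye, 0, noiseScale), nDye, 3)
    # reflective exclusion at each NP surface and at the box walls
    for (k in seq_along(npList)) {
      np <- npList[[k]]
      rel <- sweep(pos, 2, as.numeric(np$center))
      r <- sqrt(rowSums(rel^2))
      inside <- r < np$radius + 1
      if (any(inside)) {
        u <- rel[inside, , drop = FALSE] / r[inside]
        pos[inside, ] <- matrix(as.numeric(np$center), sum(inside), 3,
                                byrow = TRUE) + u * (np$radius + 1)
      }
    }
    if (is.finite(config@box)) {
      half <- config@box / 2
      over <- pos > half
      pos[over] <- 2 * half - pos[over]
      under <- pos < -half
      pos[under] <- -2 * half - pos[under]
    }
    for (i in seq_len(nDye)) {
      qs[[i]] <- quatMultiply(rotvecToQuat(stats::rnorm(3, 0, rotScale)),
                              qs[[i]])
      qs[[i]] <- qs[[i]] / vecNorm(qs[[i]])
      quats[[i]][f, ] <- qs[[i]]
    }
    centers[f, , ] <- pos
  }
  list(centers = centers, quats = quats, adsEngaged = adsEngaged,
       stackEngaged = stackEngaged, nf = nf)
}

# label engagement episodes of the emergent simulator into ground-truth
# state intervals using the episode duration / orientation rules
emergentGroundTruth <- function(config, state, times) {
  nDye <- as.integer(config@nDye)
  rows <- list()
  for (i in seq_len(nDye)) {
    covered <- rep(FALSE, length(times))
    for (k in seq_along(config@np)) {
      runs <- trueRuns(state$adsEngaged[, i, k])
      if (nrow(runs) == 0) next
      for (r in seq_len(nrow(runs))) {
        dur <- times[runs[r, "end"]] - times[runs[r, "start"]]
        lab <- if (dur >= 5) "A" else if (dur <= 2) "T" else "RA"
        rows[[length(rows) + 1L]] <- data.frame(
          dye = paste0("R6G_", i), np = paste0("SNP", k), label = lab,
          start_ns = times[runs[r, "start"]], end_ns = times[runs[r, "end"]])
        covered[runs[r, "start"]:runs[r, "end"]] <- TRUE
      }
    }
    freeRuns <- trueRuns(!covered)
    if (nrow(freeRuns))
      for (r in seq_len(nrow(freeRuns)))
        rows[[length(rows) + 1L]] <- data.frame(
          dye = paste0("R6G_", i), np = NA_character_, label = "FREE",
          start_ns = times[freeRuns[r, "start"]],
          end_ns = times[freeRuns[r, "end"]])
  }
  states <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dye = character(0), np = character(0), label = character(0),
               start_ns = numeric(0), end_ns = numeric(0))
  dimers <- list()
  for (i in seq_len(max(nDye - 1, 0))) for (j in (i + 1):nDye) {
    runs <- trueRuns(state$stackEngaged[, i, j])
    if (nrow(runs) == 0) next
    for (r in seq_len(nrow(runs)))
      dimers[[length(dimers) + 1L]] <- data.frame(
        dye_a = paste0("R6G_", i), dye_b = paste0("R6G_", j),
        start_ns = times[runs[r, "start"]], end_ns = times[runs[r, "end"]],
        location = NA_character_)
  }
  dimers <- if (length(dimers)) do.call(rbind, dimers) else
    data.frame(dye_a = character(0), dye_b = character(0),
               start_ns = numeric(0), end_ns = numeric(0),
               location = character(0))
  new("GroundTruth", stateIntervals = states, dimerEvents = dimers)
}

# deterministic scripted kinematics: replay user-specified state intervals
# and dimer events exactly (noise-free paths; measurement noise is added
# separately if requested)
propagateScripted <- function(config, layout, times) {
  nDye <- as.integer(config@nDye)
  nf <- length(times)
  script <- config@scripted
  stateDf <- script$stateIntervals
  dimerDf <- script$dimerEvents
  if (is.null(stateDf))
    stateDf <- data.frame(dye = character(0), np = character(0),
                          label = character(0), start_ns = numeric(0),
                          end_ns = numeric(0))
  if (is.null(dimerDf))
    dimerDf <- data.frame(dye_a = character(0), dye_b = character(0),
                          start_ns = numeric(0), end_ns = numeric(0),
                          location = character(0))
  refC <- if (length(config@np)) as.numeric(config@np[[1]]$center) else
    c(0, 0, 0)
  npCenter <- function(npName) {
    k <- as.integer(sub("SNP", "", npName))
    as.numeric(config@np[[k]]$center)
  }
  npRadius <- function(npName) {
    k <- as.integer(sub("SNP", "", npName))
    config@np[[k]]$radius
  }
  refR <- if (length(config@np)) config@np[[1]]$radius else 0
  # fixed home directions spread around the (first) particle
  az <- 2 * pi * (seq_len(nDye) - 1) / max(nDye, 1)
  elev <- rep(c(0.35, -0.35), length.out = nDye)
  home <- cbind(cos(az) * cos(elev), sin(az) * cos(elev), sin(elev))
  centers <- array(NA_real_, c(nf, nDye, 3))
  quats <- lapply(seq_len(nDye), function(i) matrix(NA_real_, nf, 4))
  matToQuat <- function(R) {
    w <- sqrt(max(0, 1 + R[1, 1] + R[2, 2] + R[3, 3])) / 2
    if (w > 1e-6) {
      q <- c(w, (R[3, 2] - R[2, 3]) / (4 * w), (R[1, 3] - R[3, 1]) / (4 * w),
             (R[2, 1] - R[1, 2]) / (4 * w))
    } else {
      q <- c(1, 0, 0, 0)
    }
    q / vecNorm(q)
  }
  # tangent direction helper (unit vector orthogonal to u)
  tangentOf <- function(u) {
    t <- c(-u[2], u[1], 0)
    if (vecNorm(t) < 1e-6) t <- c(1, 0, 0)
    t / vecNorm(t)
  }
  for (i in seq_len(nDye)) {
    u <- home[i, ]
    th <- tangentOf(u)
    dyeName <- paste0("R6G_", i)
    segs <- stateDf[stateDf$dye == dyeName, , drop = FALSE]
    for (f in seq_len(nf)) {
      t <- times[f]
      row <- segs[segs$start_ns <= t & t < segs$end_ns, , drop = FALSE]
      lab <- if (nrow(row)) row$label[1] else "FREE"
      cN <- if (nrow(row) && !is.na(row$np[1])) npCenter(row$np[1]) else refC
      rN <- if (nrow(row) && !is.na(row$np[1])) npRadius(row$np[1]) else refR
      if (lab == "A") {
        centers[f, i, ] <- cN + u * (rN + 2.5)
        R <- alignZTo(u)
      } else if (lab == "RA") {
        centers[f, i, ] <- cN + u * (rN + 2.5 + 1.5 * sin(2 * pi * t / 0.8))
        tilt <- if (sin(2 * pi * t / 0.5) >= 0) 0 else 60
        R <- alignZTo(u) %*% alignZTo(c(sin(tilt * pi / 180), 0,
                                        cos(tilt * pi / 180)))
      } else if (lab == "T") {
        centers[f, i, ] <- cN + u * (rN + 3.0)
        R <- alignZTo(u) %*% alignZTo(c(sin(75 * pi / 180), 0,
                                        cos(75 * pi / 180)))
      } else {
        centers[f, i, ] <- cN +
          u * (rN + 12 + 6 * sin(2 * pi * t / 23 + i)) +
          th * 3 * sin(2 * pi * t / 17 + 2 * i)
        R <- alignZTo(th)
      }
      quats[[i]][f, ] <- matToQuat(R)
    }
  }
  # dimer events override both members; core COMs are placed symmetric about
  # the pair point with antiparallel normals (folded stacking angle 0)
  coreOffset <- colMeans(layout$dyeTemplate$xyz[layout$dyeTemplate$coreIdx, ,
                                                drop = FALSE])
  if (nrow(dimerDf)) {
    pairAz <- pi / max(nDye, 1)  # directions between dye homes
    for (e in seq_len(nrow(dimerDf))) {
      ia <- as.integer(sub("R6G_", "", dimerDf$dye_a[e]))
      ib <- as.integer(sub("R6G_", "", dimerDf$dye_b[e]))
      w <- c(cos(pairAz * e + 0.7), sin(pairAz * e + 0.7), 0.2)
      w <- w / vecNorm(w)
      a <- tangentOf(w)
      sDist <- if (identical(dimerDf$location[e], "matrix")) 3 else 15
      desorb <- isTRUE(dimerDf$script_desorb[e])
      sel <- which(times >= dimerDf$start_ns[e] & times < dimerDf$end_ns[e])
      for (f in sel) {
        sHere <- sDist
        if (desorb) {
          frac <- (times[f] - dimerDf$start_ns[e]) /
            (dimerDf$end_ns[e] - dimerDf$start_ns[e])
          if (frac > 0.8) sHere <- sDist + (frac - 0.8) / 0.2 * 12
        }
        p <- refC + w * (refR + sHere)
        Ra <- alignZTo(a)
        Rb <- alignZTo(-a)
        centers[f, ia, ] <- p - a * 1.75 - as.numeric(Ra %*% coreOffset)
        centers[f, ib, ] <- p + a * 1.75 - as.numeric(Rb %*% coreOffset)
        quats[[ia]][f, ] <- matToQuat(Ra)
        quats[[ib]][f, ] <- matToQuat(Rb)
      }
    }
  }
  # ground truth: the script itself, FREE-filled to partition the time span
  rows <- list()
  tEnd <- times[nf] + (times[2] - times[1])
  for (i in seq_len(nDye)) {
    dyeName <- paste0("R6G_", i)
    segs <- stateDf[stateDf$dye == dyeName, , drop = FALSE]
    segs <- segs[order(segs$start_ns), , drop = FALSE]
    cur <- 0
    for (s in seq_len(nrow(segs))) {
      if (segs$start_ns[s] > cur)
        rows[[length(rows) + 1L]] <- data.frame(
          dye = dyeName, np = NA_character_, label = "FREE",
          start_ns = cur, end_ns = segs$start_ns[s])
      rows[[length(rows) + 1L]] <- segs[s, c("dye", "np", "label",
                                             "start_ns", "end_ns")]
      cur <- segs$end_ns[s]
    }
    if (cur < tEnd)
      rows[[length(rows) + 1L]] <- data.frame(
        dye = dyeName, np = NA_character_, label = "FREE",
        start_ns = cur, end_ns = tEnd)
  }
  gt <- new("GroundTruth",
            stateIntervals = do.call(rbind, rows),
            dimerEvents = dimerDf[, intersect(
              c("dye_a", "dye_b", "start_ns", "end_ns", "location"),
              names(dimerDf)), drop = FALSE])
  list(centers = centers, quats = quats, groundTruth = gt)
}

#' Simulate a synthetic dye-nanoparticle trajectory
#'
#' Two modes share one rigid-body kinematic model (dyes as rigid site
#' clusters, nanoparticles as fixed charged spheres):
#' \describe{
#' \item{emergent}{overdamped Langevin dynamics: screened radial attraction
#'   to each particle, an adsorption well that engages only when the core
#'   normal is within the orientation gate of the radial direction, a
#'   pairwise face-to-face stacking well, rotational diffusion, thermal
#'   noise. Ground truth logs the episodes during which a well was actually
#'   engaged, labelled by the episode duration rules.}
#' \item{scripted}{\code{config@scripted} supplies state intervals
#'   (\code{dye, np, label, start_ns, end_ns}; half-open \code{[start,
#'   end)}) and/or dimer events (\code{dye_a, dye_b, start_ns, end_ns,
#'   location}, optional logical \code{script_desorb}); the generator
#'   replays them exactly with deterministic noise-free paths, and the
#'   ground truth is the script itself.}
#' }
#' Measurement noise (\code{noiseSd}) is added to the emitted coordinates
#' only; ground truth always refers to the latent noise-free kinematics.
#'
#' @param config a [SimConfig-class].
#' @return list with \code{trajectory} ([Trajectory-class]),
#'   \code{topology} ([Topology-class]) and \code{groundTruth}
#'   ([GroundTruth-class]).
#' @export
simulateTrajectory <- function(config) {
  validObject(config)
  set.seed(as.integer(config@seed))
  layout <- makeSyntheticTopology(config)
  dt <- config@timestep
  nf <- as.integer(round(config@duration / dt))
  times <- (seq_len(nf) - 1) * dt
  if (length(config@scripted)) {
    st <- propagateScripted(config, layout, times)
    centers <- st$centers
    quats <- st$quats
    gt <- st$groundTruth
  } else {
    st <- propagateEmergent(config)
    centers <- st$centers
    quats <- st$quats
    gt <- emergentGroundTruth(config, st, times)
  }
  coords <- assembleCoords(layout, config, centers, quats, nf)
  if (config@noiseSd > 0)
    coords <- coords + stats::rnorm(length(coords), 0, config@noiseSd)
  traj <- trajectory(times, coords, layout$topology)
  list(trajectory = traj, topology = layout$topology, groundTruth = gt)
}

#' Simulate a constant-velocity pulling force trace with known well depths
#'
#' Quasi-static construction: the pulled compound sits in a sequence of
#' wells along the pulling coordinate; between escapes the spring force
#' ramps linearly at slope \eqn{k v}, and at each escape the compound jumps
#' to the next well, dropping the force by \eqn{k d} (jump distance d). The
#' escape force of well \eqn{i} with depth \eqn{E_i} and jump \eqn{d_i}
#' satisfies \eqn{F_{peak} d_i - k d_i^2/2 = E_i}, so the spring-energy
#' release across each drop equals the well depth exactly and the
#' ground-truth total is \eqn{\sum E_i}. With \code{positions = NULL} the
#' jumps are auto-sized to \eqn{d_i = \sqrt{2 E_i / k}}, giving a clean
#' sawtooth that relaxes to zero force after each escape.
#'
#' @param depthsEv well depths in eV (possibly empty for a flat trace).
#' @param positions optional well positions along the pulling coordinate
#'   (Angstrom, strictly increasing); jump distances are their differences,
#'   the final jump is auto-sized.
#' @param k spring constant (pN/Angstrom), default 278.
#' @param velocity pulling velocity (Angstrom/ps), default 0.01.
#' @param noiseSd Gaussian force noise (pN).
#' @param seed RNG seed.
#' @param dtPs sampling interval (ps).
#' @return list with \code{trace} ([ForceTrace-class]) and
#'   \code{groundTruth} ([GroundTruth-class] with the total depth in eV).
#' @export
simulateSMDTrace <- function(depthsEv, positions = NULL, k = 278,
                             velocity = 0.01, noiseSd = 0, seed = 1,
                             dtPs = 1) {
  set.seed(as.integer(seed))
  nW <- length(depthsEv)
  if (nW == 0) {
    tGrid <- seq(0, 500, by = dtPs)
    f <- pmin(tGrid / 50, 1) * 5  # small drag plateau
    f <- f + stats::rnorm(length(f), 0, noiseSd)
    tr <- forceTrace(tGrid, f, rep(0, length(tGrid)), k, velocity)
    return(list(trace = tr,
                groundTruth = new("GroundTruth", smdWellDepthEv = 0)))
  }
  if (any(depthsEv <= 0)) stop("well depths must be positive")
  depthsPnA <- depthsEv / PNA_TO_EV
  jumps <- numeric(nW)
  if (!is.null(positions)) {
    if (length(positions) != nW || any(diff(positions) <= 0))
      stop("positions must be strictly increasing, one per well")
    if (nW > 1) jumps[seq_len(nW - 1)] <- diff(positions)
  }
  jumps[jumps == 0] <- sqrt(2 * depthsPnA[jumps == 0] / k)
  jumps[nW] <- sqrt(2 * depthsPnA[nW] / k)
  fPeak <- depthsPnA / jumps + k * jumps / 2
  fEnd <- fPeak - k * jumps
  fStart <- c(0, fEnd[-nW])
  if (any(fPeak <= fStart))
    stop("overlapping wells: escape force not reachable from the previous well")
  tList <- list(); fList <- list(); xList <- list()
  tNow <- 0
  xNow <- 0
  for (i in seq_len(nW)) {
    rampT <- (fPeak[i] - fStart[i]) / (k * velocity)
    seg <- seq(0, rampT, by = dtPs)
    tList[[length(tList) + 1L]] <- tNow + seg
    fList[[length(fList) + 1L]] <- fStart[i] + k * velocity * seg
    xList[[length(xList) + 1L]] <- rep(xNow, length(seg))
    tNow <- tNow + rampT + dtPs
    xNow <- xNow + jumps[i]
  }
  # post-escape tail so the last drop is followed by a quiet stretch
  tailSeg <- seq(0, 200, by = dtPs)
  tList[[length(tList) + 1L]] <- tNow + tailSeg
  fList[[length(fList) + 1L]] <- rep(fEnd[nW], length(tailSeg))
  xList[[length(xList) + 1L]] <- rep(xNow, length(tailSeg))
  tAll <- unlist(tList); fAll <- unlist(fList); xAll <- unlist(xList)
  o <- order(tAll)
  tAll <- tAll[o]; fAll <- fAll[o]; xAll <- xAll[o]
  keep <- c(TRUE, diff(tAll) > 1e-9)
  tAll <- tAll[keep]; fAll <- fAll[keep]; xAll <- xAll[keep]
  fAll <- fAll + stats::rnorm(length(fAll), 0, noiseSd)
  tr <- forceTrace(tAll, fAll, xAll, k, velocity)
  list(trace = tr,
       groundTruth = new("GroundTruth", smdWellDepthEv = sum(depthsEv)))
}
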