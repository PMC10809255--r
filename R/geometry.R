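#' Centre of mass of a selection in one frame
#'
#' @param topology a [Topology-class].
#' @param frame nParticles x 3 coordinate matrix (Angstrom).
#' @param group group name.
#' @return numeric(3), the mass-weighted mean position (Angstrom).
#' @export
centerOfMass <- function(topology, frame, group) {
  ids <- groupMembers(topology, group)
  if (length(ids) == 0) stop(sprintf("group '%s' is empty", group))
  idx <- ids + 1L
  m <- topology@mass[idx]
  as.numeric(colSums(frame[idx, , drop = FALSE] * m) / sum(m))
}

#' Spherical nanoparticle model from a trajectory
#'
#' Computes the per-frame COM of the nanoparticle group and fixes a sphere
#' radius, either nominal (half the construction diameter) or empirical (the
#' 95th percentile of member radial distances from the COM in the first
#' frame, since the measured heavy-atom diameter of a small crystal can
#' deviate slightly from the nominal one). Nominal is the default for
#' reproducibility.
#'
#' @param traj a [Trajectory-class].
#' @param group nanoparticle group name.
#' @param diameter nominal diameter (Angstrom), required for
#'   \code{method = "nominal"}.
#' @param method "nominal" or "empirical".
#' @return a [NanoparticleModel-class].
#' @export
nanoparticleModel <- function(traj, group, diameter = NULL,
                              method = c("nominal", "empirical")) {
  method <- match.arg(method)
  top <- topologyOf(traj)
  centers <- t(vapply(seq_len(nFrames(traj)), function(i)
    centerOfMass(top, frameCoords(traj, i), group), numeric(3)))
  radius <- if (method == "nominal") {
    if (is.null(diameter)) stop("nominal method requires a diameter")
    diameter / 2
  } else {
    idx <- groupMembers(top, group) + 1L
    f1 <- frameCoords(traj, 1)
    d <- sqrt(rowSums((f1[idx, , drop = FALSE] -
                         matrix(centers[1, ], length(idx), 3, byrow = TRUE))^2))
    as.numeric(stats::quantile(d, 0.95))
  }
  new("NanoparticleModel", group = group, centers = centers, radius = radius)
}

#' Distance from a dye COM to the nanoparticle surface
#'
#' \code{|com - center| - radius}; negative when the COM lies inside the
#' nominal sphere.
#'
#' @param dyeCom numeric(3), Angstrom.
#' @param np a [NanoparticleModel-class].
#' @param frame frame index selecting the nanoparticle centre.
#' @return numeric scalar, Angstrom.
#' @export
surfaceDistance <- function(dyeCom, np, frame = 1) {
  vecNorm(dyeCom - np@centers[frame, ]) - np@radius
}

#' Best-fit plane normal of a planar core selection
#'
#' The unit normal is the eigenvector of the smallest principal second
#' moment of the centred core coordinates (no mass weighting). When a
#' radial direction is supplied the sign is fixed so the normal has a
#' non-negative dot product with it; otherwise the sign is arbitrary.
#'
#' @param topology a [Topology-class].
#' @param frame nParticles x 3 coordinate matrix.
#' @param coreGroup name of the core selection (>= 3 non-collinear sites).
#' @param radial optional numeric(3) reference direction for the sign
#'   convention.
#' @return unit numeric(3).
#' @export
corePlaneNormal <- function(topology, frame, coreGroup, radial = NULL) {
  ids <- groupMembers(topology, coreGroup)
  if (length(ids) < 3)
    stop(sprintf("core group '%s' needs at least 3 particles", coreGroup))
  pts <- frame[ids + 1L, , drop = FALSE]
  centered <- sweep(pts, 2, colMeans(pts))
  mom <- crossprod(centered) / nrow(centered)
  eig <- eigen(mom, symmetric = TRUE)
  # collinear points: two vanishing principal moments
  if (eig$values[2] < 1e-9 * max(eig$values[1], 1e-12))
    stop(sprintf("core group '%s' is collinear or degenerate", coreGroup))
  normal <- eig$vectors[, 3]
  if (!is.null(radial) && sum(normal * radial) < 0) normal <- -normal
  as.numeric(normal / vecNorm(normal))
}

#' Angle between a core-plane normal and the local radial direction
#'
#' Folded into [0, 90] degrees: 0 means the core plane is exactly parallel
#' to the local (spherical) surface, 90 means it stands on edge.
#'
#' @param normal unit numeric(3).
#' @param radial unit numeric(3), direction from the nanoparticle centre to
#'   the dye.
#' @return degrees in [0, 90].
#' @export
parallelismAngle <- function(normal, radial) {
  foldAngle(angleDeg(normal, radial))
}

#' Dipole moment of a selection
#'
#' \eqn{\sum_i q_i (r_i - r_{ref})} with the selection COM as the default
#' reference. For net-charged selections the result depends on the
#' reference; pinning it to the selection COM keeps per-molecule dipoles
#' comparable while excluding the diffusing counterion layer.
#'
#' @param topology a [Topology-class].
#' @param frame nParticles x 3 coordinate matrix.
#' @param group group name.
#' @param reference "com" or an explicit numeric(3) point (Angstrom).
#' @return a [DipoleVector-class].
#' @export
dipoleMoment <- function(topology, frame, group, reference = "com") {
  ids <- groupMembers(topology, group)
  if (length(ids) == 0) stop(sprintf("group '%s' is empty", group))
  idx <- ids + 1L
  q <- topology@charge[idx]
  if (any(is.na(q))) stop(sprintf("charges missing for group '%s'", group))
  ref <- if (identical(reference, "com"))
    centerOfMass(topology, frame, group) else as.numeric(reference)
  stopifnot(length(ref) == 3)
  disp <- sweep(frame[idx, , drop = FALSE], 2, ref)
  comp <- as.numeric(colSums(disp * q))
  new("DipoleVector", components = comp,
      magnitudeDebye = EA_TO_DEBYE * vecNorm(comp),
      referencePoint = ref, netCharge = sum(q))
}

#' Angle theta between two dipole vectors
#'
#' For a dye stably adsorbed on an oppositely charged particle the two
#' dipoles approach an antiparallel arrangement (theta near 180 degrees),
#' though in a fluctuating multi-source electric field the stable-adsorption
#' mean sits well below that ideal.
#'
#' @param d1,d2 [DipoleVector-class] objects with non-zero magnitude.
#' @return degrees in [0, 180].
#' @export
dipoleAngleTheta <- function(d1, d2) {
  if (d1@magnitudeDebye == 0 || d2@magnitudeDebye == 0)
    stop("zero dipole has no direction")
  angleDeg(d1@components, d2@components)
}

#' Per-frame geometric metrics for every dye-nanoparticle pair
#'
#' For each frame, dye and nanoparticle: the COM-to-surface distance, the
#' folded angle between the dye core-plane normal and the radial direction,
#' and the angle theta between the dye and nanoparticle dipole moments.
#' This is the input of the state classifier and the dimer detector.
#'
#' @param traj a [Trajectory-class].
#' @param dyes character vector of dye group names; each must have a
#'   matching \code{"<dye>_core"} group.
#' @param nps named list of [NanoparticleModel-class] objects (names are the
#'   nanoparticle labels).
#' @return data.frame with columns \code{time_ns, dye, np, surface_dist_A,
#'   parallel_angle_deg, theta_deg}.
#' @export
trajectoryMetrics <- function(traj, dyes, nps) {
  top <- topologyOf(traj)
  times <- frameTimes(traj)
  nf <- length(times)
  npNames <- names(nps)
  nd <- length(dyes)
  nn <- length(npNames)
  dist <- array(NA_real_, c(nf, nd, nn))
  par <- array(NA_real_, c(nf, nd, nn))
  theta <- array(NA_real_, c(nf, nd, nn))
  for (f in seq_len(nf)) {
    fr <- frameCoords(traj, f)
    npDips <- lapply(nps, function(np) dipoleMoment(top, fr, np@group))
    for (i in seq_len(nd)) {
      d <- dyes[i]
      com <- centerOfMass(top, fr, d)
      dyeDip <- dipoleMoment(top, fr, d)
      for (j in seq_len(nn)) {
        np <- nps[[j]]
        radial <- com - np@centers[f, ]
        dist[f, i, j] <- vecNorm(radial) - np@radius
        normal <- corePlaneNormal(top, fr, paste0(d, "_core"), radial = radial)
        par[f, i, j] <- parallelismAngle(normal, radial)
        theta[f, i, j] <- dipoleAngleTheta(dyeDip, npDips[[j]])
      }
    }
  }
  out <- vector("list", nd * nn)
  k <- 0L
  for (i in seq_len(nd)) for (j in seq_len(nn)) {
    k <- k + 1L
    out[[k]] <- data.frame(time_ns = times, dye = dyes[i], np = npNames[j],
                           surface_dist_A = dist[, i, j],
                           parallel_angle_deg = par[, i, j],
                           theta_deg = theta[, i, j])
  }
  do.call(rbind, out)
}
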