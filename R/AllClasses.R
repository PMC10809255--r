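#' @import methods
NULL

#' Particle topology with named selections
#'
#' A \code{Topology} holds the static description of the simulated system:
#' per-particle masses (amu) and partial charges (elementary charges e), and
#' named selections ("groups") such as the nanoparticle, each dye, and each
#' dye's planar xanthene-core subset. Particle ids are 0-based and contiguous,
#' mirroring the usual MD convention.
#'
#' @slot particleId integer vector, 0-based contiguous ids.
#' @slot mass numeric vector, particle masses in amu (> 0).
#' @slot charge numeric vector, partial charges in e.
#' @slot groups named list of integer vectors of particle ids; every group
#'   named \code{"<dye>_core"} must be a subset of its parent group
#'   \code{"<dye>"}.
#'
#' @seealso [readTopology()], [groupMembers()]
#' @export
setClass("Topology",
  representation(
    particleId = "integer",
    mass = "numeric",
    charge = "numeric",
    groups = "list"
  )
)

setValidity("Topology", function(object) {
  n <- length(object@particleId)
  msgs <- character()
  if (length(object@mass) != n || length(object@charge) != n)
    msgs <- c(msgs, "mass, charge and particleId must have equal length")
  if (n > 0 && !identical(object@particleId, 0:(n - 1L)))
    msgs <- c(msgs, "particle ids must be unique and contiguous from 0")
  if (any(!is.finite(object@mass)) || any(object@mass <= 0))
    msgs <- c(msgs, "masses must be finite and > 0")
  if (any(!is.finite(object@charge)))
    msgs <- c(msgs, "charges must be finite")
  gn <- names(object@groups)
  if (length(object@groups) > 0 && (is.null(gn) || any(gn == "") || anyDuplicated(gn)))
    msgs <- c(msgs, "groups must have unique non-empty names")
  for (g in gn) {
    ids <- object@groups[[g]]
    if (!is.numeric(ids) && !is.integer(ids)) {
      msgs <- c(msgs, sprintf("group '%s' is not an id vector", g))
      next
    }
    if (n > 0 && (any(ids < 0) || any(ids > n - 1)))
      msgs <- c(msgs, sprintf("group '%s' references unknown particle ids", g))
    if (grepl("_core$", g)) {
      parent <- sub("_core$", "", g)
      if (!parent %in% gn)
        msgs <- c(msgs, sprintf("core group '%s' has no parent group '%s'", g, parent))
      else if (!all(ids %in% object@groups[[parent]]))
        msgs <- c(msgs, sprintf("core group '%s' is not a subset of '%s'", g, parent))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Multi-frame coordinate trajectory
#'
#' Coordinates are stored as a 3-D array \code{[particle, xyz, frame]} in
#' Angstrom; frame times are in ns and strictly increasing.
#'
#' @slot times numeric vector of frame times (ns), strictly increasing.
#' @slot coords numeric array \code{c(nParticles, 3, nFrames)}, Angstrom.
#' @slot topology the associated [Topology-class].
#'
#' @seealso [readTrajectory()], [simulateTrajectory()]
#' @export
setClass("Trajectory",
  representation(
    times = "numeric",
    coords = "array",
    topology = "Topology"
  )
)

setValidity("Trajectory", function(object) {
  msgs <- character()
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3)
    msgs <- c(msgs, "coords must be an [nParticles, 3, nFrames] array")
  else {
    if (d[3] != length(object@times))
      msgs <- c(msgs, "number of frames must match length(times)")
    if (d[1] != length(object@topology@particleId))
      msgs <- c(msgs, "particle count must match the topology")
  }
  if (length(object@times) < 1)
    msgs <- c(msgs, "trajectory must contain at least one frame")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msgs <- c(msgs, "frame times must be strictly increasing")
  if (any(!is.finite(object@coords)))
    msgs <- c(msgs, "coordinates must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Spherical nanoparticle model
#'
#' Wraps a nanoparticle selection as a sphere: per-frame center of mass and a
#' fixed radius. Surface distances are measured radially from the sphere
#' surface; the default radius is half the nominal construction diameter,
#' since the heavy-atom diameter of a small crystalline particle can deviate
#' slightly from the nominal value.
#'
#' @slot group character, the topology group name.
#' @slot centers numeric matrix \code{nFrames x 3}, per-frame COM (Angstrom).
#' @slot radius numeric, sphere radius in Angstrom (> 0).
#'
#' @seealso [nanoparticleModel()], [surfaceDistance()]
#' @export
setClass("NanoparticleModel",
  representation(group = "character", centers = "matrix", radius = "numeric")
)

setValidity("NanoparticleModel", function(object) {
  msgs <- character()
  if (length(object@radius) != 1 || !is.finite(object@radius) || object@radius <= 0)
    msgs <- c(msgs, "radius must be a single positive number")
  if (ncol(object@centers) != 3)
    msgs <- c(msgs, "centers must be an nFrames x 3 matrix")
  if (length(msgs)) msgs else TRUE
})

#' Dipole moment of a selection
#'
#' The dipole is \eqn{\sum_i q_i (r_i - r_{ref})} in e.Angstrom. For a
#' net-neutral selection the vector is independent of the reference point;
#' for a charged selection shifting the reference by \code{t} changes the
#' vector by exactly \code{-netCharge * t}, which is why the reference is
#' pinned to the selection's own centre of mass by default (the labile
#' counterion layer is deliberately excluded from nanoparticle dipoles).
#'
#' @slot components numeric(3), e.Angstrom.
#' @slot magnitudeDebye numeric, |components| in Debye (1 e.Angstrom =
#'   4.8032 D).
#' @slot referencePoint numeric(3), the origin used, Angstrom.
#' @slot netCharge numeric, total charge of the selection in e.
#'
#' @seealso [dipoleMoment()], [dipoleAngleTheta()]
#' @export
setClass("DipoleVector",
  representation(
    components = "numeric",
    magnitudeDebye = "numeric",
    referencePoint = "numeric",
    netCharge = "numeric"
  )
)

setValidity("DipoleVector", function(object) {
  msgs <- character()
  if (length(object@components) != 3) msgs <- c(msgs, "components must be length 3")
  if (length(object@referencePoint) != 3) msgs <- c(msgs, "referencePoint must be length 3")
  expected <- EA_TO_DEBYE * sqrt(sum(object@components^2))
  if (abs(object@magnitudeDebye - expected) > 1e-6 * max(1, expected))
    msgs <- c(msgs, "magnitudeDebye inconsistent with components")
  if (length(msgs)) msgs else TRUE
})

#' Adsorption-state classifier settings
#'
#' Thresholds used to segment each dye--nanoparticle distance/orientation
#' time series into episodes and to label them A (stable adsorption),
#' RA (reorientation near the surface) or T (transient electrostatic
#' trapping). The 5 Angstrom surface-distance threshold and the ~2 ns upper
#' bound on trapped episodes follow the reporting conventions of
#' dye-on-silica MD studies; the parallelism tolerance and minimum stable
#' duration are configurable because "parallel" and "stable" are otherwise
#' qualitative.
#'
#' @slot adsorptionThreshold Angstrom; a frame is near-surface when the
#'   COM-to-surface distance is at most this (default 5).
#' @slot parallelTolerance degrees; the xanthene core counts as parallel to
#'   the local surface when the plane-normal/radial angle is at most this
#'   (default 30).
#' @slot gapTolerance ns; sub-threshold interruptions shorter than this are
#'   merged into one episode (default 0.2).
#' @slot minADuration ns; minimum duration for label A (default 5).
#' @slot maxTDuration ns; typical upper duration of T episodes (default 2);
#'   longer never-parallel episodes are still labelled T and flagged.
#' @slot parallelFractionA minimum fraction of parallel frames for A
#'   (default 0.8).
#' @slot parallelFractionTMax below this parallel fraction an episode is T
#'   (default 0.2).
#'
#' @seealso [classifierConfig()], [classifyStates()]
#' @export
setClass("ClassifierConfig",
  representation(
    adsorptionThreshold = "numeric",
    parallelTolerance = "numeric",
    gapTolerance = "numeric",
    minADuration = "numeric",
    maxTDuration = "numeric",
    parallelFractionA = "numeric",
    parallelFractionTMax = "numeric"
  ),
  prototype(
    adsorptionThreshold = 5, parallelTolerance = 30, gapTolerance = 0.2,
    minADuration = 5, maxTDuration = 2, parallelFractionA = 0.8,
    parallelFractionTMax = 0.2
  )
)

setValidity("ClassifierConfig", function(object) {
  msgs <- character()
  if (object@adsorptionThreshold <= 0) msgs <- c(msgs, "adsorptionThreshold must be > 0")
  if (object@parallelFractionA <= 0 || object@parallelFractionA > 1)
    msgs <- c(msgs, "parallelFractionA must be in (0, 1]")
  if (object@parallelFractionTMax <= 0 || object@parallelFractionTMax > 1)
    msgs <- c(msgs, "parallelFractionTMax must be in (0, 1]")
  if (object@minADuration <= object@maxTDuration)
    msgs <- c(msgs, "minADuration must exceed maxTDuration")
  if (object@gapTolerance < 0) msgs <- c(msgs, "gapTolerance must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Dimer detector settings
#'
#' A stacked dimer is a pair of dyes whose xanthene-core centres are within
#' \code{coreDistanceCutoff} and whose core-plane normals are parallel or
#' antiparallel within \code{stackingTolerance} (pi-stacking places the flat
#' faces against each other, tails protruding). Episodes shorter than
#' \code{minDimerDuration} are discarded; \code{matrixThreshold} decides
#' whether a dimer lives in the solute or on the nanoparticle matrix.
#'
#' @slot coreDistanceCutoff Angstrom (default 6).
#' @slot stackingTolerance degrees, applied to the folded inter-normal angle
#'   (default 30).
#' @slot minDimerDuration ns (default 1).
#' @slot matrixThreshold Angstrom, dimer-COM surface distance (default 5).
#'
#' @seealso [dimerConfig()], [detectDimers()]
#' @export
setClass("DimerConfig",
  representation(
    coreDistanceCutoff = "numeric",
    stackingTolerance = "numeric",
    minDimerDuration = "numeric",
    matrixThreshold = "numeric"
  ),
  prototype(
    coreDistanceCutoff = 6, stackingTolerance = 30,
    minDimerDuration = 1, matrixThreshold = 5
  )
)

setValidity("DimerConfig", function(object) {
  vals <- c(object@coreDistanceCutoff, object@stackingTolerance,
            object@minDimerDuration, object@matrixThreshold)
  if (any(!is.finite(vals)) || any(vals <= 0))
    "all dimer-detector settings must be positive" else TRUE
})

#' Constant-velocity pulling force trace
#'
#' A steered-MD force--time record: spring force (pN) and pulled-compound
#' displacement (Angstrom) on a time grid (ps), together with the spring
#' constant (pN/Angstrom) and pulling velocity (Angstrom/ps) used.
#'
#' @slot timePs numeric, strictly increasing times (ps).
#' @slot forcePn numeric, spring force (pN).
#' @slot displacementA numeric, displacement of the pulled compound
#'   (Angstrom).
#' @slot springConstant numeric, k in pN/Angstrom (> 0).
#' @slot pullingVelocity numeric, Angstrom/ps.
#'
#' @seealso [forceTrace()], [detectTransitions()], [simulateSMDTrace()]
#' @export
setClass("ForceTrace",
  representation(
    timePs = "numeric",
    forcePn = "numeric",
    displacementA = "numeric",
    springConstant = "numeric",
    pullingVelocity = "numeric"
  )
)

setValidity("ForceTrace", function(object) {
  msgs <- character()
  n <- length(object@timePs)
  if (length(object@forcePn) != n || length(object@displacementA) != n)
    msgs <- c(msgs, "timePs, forcePn, displacementA must have equal length")
  if (n > 1 && any(diff(object@timePs) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (length(object@springConstant) != 1 || object@springConstant <= 0)
    msgs <- c(msgs, "springConstant must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' System composition record
#'
#' One row of the simulated-system bookkeeping table: nanoparticle crystal
#' structure and nominal diameter, pH, component counts (dyes, nanoparticle
#' atoms, counterions, water) and the silanol ionization state that sets the
#' nanoparticle charge.
#'
#' @slot name system label, e.g. "40qSNP7" (diameter in Angstrom, q/c for
#'   alpha-Quartz/alpha-Cristobalite, trailing pH).
#' @slot crystal "quartz" or "cristobalite".
#' @slot nominalDiameter Angstrom.
#' @slot pH unitless.
#' @slot nSNP number of nanoparticles.
#' @slot atomsPerSNP atoms in one nanoparticle.
#' @slot nDye number of dye molecules.
#' @slot atomsPerDye atoms in one dye.
#' @slot dyeCharge charge per dye in e.
#' @slot nSilanol surface silanol groups per nanoparticle.
#' @slot ionizationFraction fraction of silanols deprotonated at this pH.
#' @slot nCl chloride counterions.
#' @slot nNaPerSNP sodium counterions per nanoparticle (equals |SNP charge|).
#' @slot nWaterAtoms water atoms (nominally 3 per molecule; stored as
#'   printed in the composition table, where two systems' atom and molecule
#'   counts disagree by one atom, so divisibility by 3 is not enforced).
#'
#' @seealso [systemSpec()], [makeSystemFixture()], [totalAtomCount()]
#' @export
setClass("SystemSpec",
  representation(
    name = "character", crystal = "character",
    nominalDiameter = "numeric", pH = "numeric",
    nSNP = "numeric", atomsPerSNP = "numeric",
    nDye = "numeric", atomsPerDye = "numeric", dyeCharge = "numeric",
    nSilanol = "numeric", ionizationFraction = "numeric",
    nCl = "numeric", nNaPerSNP = "numeric", nWaterAtoms = "numeric"
  )
)

setValidity("SystemSpec", function(object) {
  msgs <- character()
  counts <- c(object@nSNP, object@atomsPerSNP, object@nDye, object@atomsPerDye,
              object@nSilanol, object@nCl, object@nNaPerSNP, object@nWaterAtoms)
  if (any(!is.finite(counts)) || any(counts < 0))
    msgs <- c(msgs, "all counts must be non-negative")
  if (object@ionizationFraction < 0 || object@ionizationFraction > 1)
    msgs <- c(msgs, "ionizationFraction must be in [0, 1]")
  if (!object@crystal %in% c("quartz", "cristobalite"))
    msgs <- c(msgs, "crystal must be 'quartz' or 'cristobalite'")
  if (length(msgs)) msgs else TRUE
})

#' Ground truth attached to synthetic data
#'
#' Produced by the generators alongside the data so recovery can be scored:
#' per-dye state intervals (FREE/T/RA/A), true dimer events, and for pulling
#' traces the total well depth in eV.
#'
#' @slot stateIntervals data.frame with columns dye, np, state, start_ns,
#'   end_ns; intervals partition the simulated time per dye.
#' @slot dimerEvents data.frame with columns dye_a, dye_b, start_ns, end_ns,
#'   location.
#' @slot smdWellDepthEv numeric, total well depth for a pulling trace (eV),
#'   or NA for trajectories.
#'
#' @export
setClass("GroundTruth",
  representation(
    stateIntervals = "data.frame",
    dimerEvents = "data.frame",
    smdWellDepthEv = "numeric"
  ),
  prototype(
    stateIntervals = data.frame(),
    dimerEvents = data.frame(),
    smdWellDepthEv = NA_real_
  )
)

#' Brownian toy-simulator settings
#'
#' Conditions for the rigid-body overdamped Langevin generator that emulates
#' several cationic dyes diffusing around one or more charged spheres, with
#' an orientation-gated adsorption well (stable adsorption requires the
#' planar core to face the surface), a pairwise face-to-face stacking well
#' (dimerization), screened electrostatic attraction, and thermal noise.
#' Defaults emulate the study conditions: six dyes with 64 internal sites,
#' one 40 Angstrom-diameter particle, 100 ns sampled every 0.01 ns.
#'
#' @slot nDye number of dyes.
#' @slot dyeSiteCount internal rigid sites per dye (default 64; roughly half
#'   form the planar core).
#' @slot np list of nanoparticles, each \code{list(center, radius, wellDepth)}
#'   with center (Angstrom), radius (Angstrom) and adsorption well depth (kT).
#' @slot translationalDiffusion Angstrom^2/ns.
#' @slot rotationalDiffusion rad^2/ns.
#' @slot timestep ns.
#' @slot duration ns.
#' @slot orientationGateWidth degrees; adsorption well engages only when the
#'   core normal is within this angle of the radial direction.
#' @slot stackingWellDepth kT.
#' @slot stackingGateWidth degrees, gate on the folded inter-normal angle.
#' @slot screeningLength Angstrom, Debye length of the always-on screened
#'   radial attraction.
#' @slot electrostaticStrength kT, amplitude of the screened attraction.
#' @slot noiseSd Angstrom, measurement noise added to emitted coordinates
#'   (does not affect dynamics or ground truth).
#' @slot box Angstrom, side of the reflective cubic box centred at the
#'   origin; NA disables confinement.
#' @slot seed integer RNG seed.
#' @slot scripted list(stateIntervals=, dimerEvents=) replayed exactly, or
#'   empty list for emergent dynamics.
#'
#' @seealso [simConfig()], [simulateTrajectory()]
#' @export
setClass("SimConfig",
  representation(
    nDye = "numeric", dyeSiteCount = "numeric", np = "list",
    translationalDiffusion = "numeric", rotationalDiffusion = "numeric",
    timestep = "numeric", duration = "numeric",
    orientationGateWidth = "numeric",
    stackingWellDepth = "numeric", stackingGateWidth = "numeric",
    screeningLength = "numeric", electrostaticStrength = "numeric",
    noiseSd = "numeric", box = "numeric", seed = "numeric",
    scripted = "list"
  ),
  prototype(
    nDye = 6, dyeSiteCount = 64,
    np = list(list(center = c(0, 0, 0), radius = 20, wellDepth = 6)),
    translationalDiffusion = 20, rotationalDiffusion = 0.8,
    timestep = 0.01, duration = 100,
    orientationGateWidth = 30, stackingWellDepth = 4, stackingGateWidth = 30,
    screeningLength = 10, electrostaticStrength = 2,
    noiseSd = 0, box = 100, seed = 1, scripted = list()
  )
)

setValidity("SimConfig", function(object) {
  msgs <- character()
  pos <- c(object@nDye, object@dyeSiteCount, object@translationalDiffusion,
           object@rotationalDiffusion, object@timestep, object@duration,
           object@orientationGateWidth, object@stackingGateWidth,
           object@screeningLength)
  if (any(!is.finite(pos)) || any(pos <= 0))
    msgs <- c(msgs, "rates, lengths, durations and gate widths must be positive")
  if (object@stackingWellDepth < 0 || object@electrostaticStrength < 0 ||
      object@noiseSd < 0)
    msgs <- c(msgs, "well depths and noise sd must be non-negative")
  if (object@timestep >= object@duration)
    msgs <- c(msgs, "timestep must be smaller than duration")
  for (np in object@np) {
    if (!all(c("center", "radius", "wellDepth") %in% names(np)))
      msgs <- c(msgs, "each np needs center, radius and wellDepth")
    else if (np$radius <= 0 || np$wellDepth < 0)
      msgs <- c(msgs, "np radius must be positive, wellDepth non-negative")
  }
  if (length(msgs)) msgs else TRUE
})
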