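#' @rdname Topology-class
#' @param particleId,mass,charge,groups see slot documentation.
#' @export
topology <- function(particleId, mass, charge, groups = list()) {
  new("Topology", particleId = as.integer(particleId), mass = as.numeric(mass),
      charge = as.numeric(charge),
      groups = lapply(groups, function(g) as.integer(sort(g))))
}

#' @rdname Trajectory-class
#' @param times,coords,topology see slot documentation.
#' @export
trajectory <- function(times, coords, topology) {
  new("Trajectory", times = as.numeric(times), coords = coords,
      topology = topology)
}

#' Accessors for trajectory and topology objects
#'
#' @param x a [Topology-class] or [Trajectory-class].
#' @param group a group name.
#' @param i frame index.
#' @return `nParticles`/`nFrames`: integer counts; `groupNames`: character;
#'   `groupMembers`: integer ids (0-based); `masses`/`charges`: numeric
#'   vectors; `frameTimes`: numeric ns; `frameCoords`: nParticles x 3 matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))
#' @rdname accessors
#' @export
setGeneric("groupNames", function(x) standardGeneric("groupNames"))
#' @rdname accessors
#' @export
setGeneric("groupMembers", function(x, group) standardGeneric("groupMembers"))
#' @rdname accessors
#' @export
setGeneric("masses", function(x) standardGeneric("masses"))
#' @rdname accessors
#' @export
setGeneric("charges", function(x) standardGeneric("charges"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))
#' @rdname accessors
#' @export
setGeneric("topologyOf", function(x) standardGeneric("topologyOf"))

#' @rdname accessors
setMethod("nParticles", "Topology", function(x) length(x@particleId))
#' @rdname accessors
setMethod("nParticles", "Trajectory", function(x) dim(x@coords)[1])
#' @rdname accessors
setMethod("groupNames", "Topology", function(x) names(x@groups))
#' @rdname accessors
setMethod("groupNames", "Trajectory", function(x) names(x@topology@groups))
#' @rdname accessors
setMethod("groupMembers", "Topology", function(x, group) {
  if (!group %in% names(x@groups)) stop(sprintf("unknown group '%s'", group))
  x@groups[[group]]
})
#' @rdname accessors
setMethod("groupMembers", "Trajectory", function(x, group)
  groupMembers(x@topology, group))
#' @rdname accessors
setMethod("masses", "Topology", function(x) x@mass)
#' @rdname accessors
setMethod("charges", "Topology", function(x) x@charge)
#' @rdname accessors
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])
#' @rdname accessors
setMethod("frameTimes", "Trajectory", function(x) x@times)
#' @rdname accessors
setMethod("frameCoords", "Trajectory", function(x, i) {
  m <- x@coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
})
#' @rdname accessors
setMethod("topologyOf", "Trajectory", function(x) x@topology)

setMethod("show", "Topology", function(object) {
  cat(sprintf("Topology: %d particles, %d groups\n",
              nParticles(object), length(object@groups)))
  if (length(object@groups))
    cat("  groups:", paste(names(object@groups), collapse = ", "), "\n")
})

setMethod("show", "Trajectory", function(object) {
  t <- frameTimes(object)
  cat(sprintf("Trajectory: %d particles x %d frames, %.3f-%.3f ns\n",
              nParticles(object), nFrames(object), t[1], t[length(t)]))
})

setMethod("show", "ForceTrace", function(object) {
  cat(sprintf(
    "ForceTrace: %d samples, %.1f-%.1f ps, k = %.1f pN/A, v = %g A/ps\n",
    length(object@timePs), object@timePs[1], max(object@timePs),
    object@springConstant, object@pullingVelocity))
})

setMethod("show", "SystemSpec", function(object) {
  cat(sprintf("SystemSpec %s: %d x %d A %s SNP at pH %g, %d dyes, %d atoms\n",
              object@name, object@nSNP, object@nominalDiameter,
              object@crystal, object@pH, object@nDye,
              totalAtomCount(object)))
})

#' @rdname ClassifierConfig-class
#' @param ... slot values overriding the defaults.
#' @export
classifierConfig <- function(...) new("ClassifierConfig", ...)

#' @rdname DimerConfig-class
#' @param ... slot values overriding the defaults.
#' @export
dimerConfig <- function(...) new("DimerConfig", ...)

#' @rdname SimConfig-class
#' @param ... slot values overriding the defaults.
#' @export
simConfig <- function(...) new("SimConfig", ...)

#' @rdname ForceTrace-class
#' @param timePs,forcePn,displacementA,springConstant,pullingVelocity see
#'   slot documentation.
#' @export
forceTrace <- function(timePs, forcePn, displacementA, springConstant,
                       pullingVelocity = NA_real_) {
  new("ForceTrace", timePs = as.numeric(timePs), forcePn = as.numeric(forcePn),
      displacementA = as.numeric(displacementA),
      springConstant = as.numeric(springConstant),
      pullingVelocity = as.numeric(pullingVelocity))
}

#' @rdname SystemSpec-class
#' @param name,crystal,nominalDiameter,pH,nSNP,atomsPerSNP,nDye,atomsPerDye
#'   see slot documentation.
#' @param dyeCharge,nSilanol,ionizationFraction,nCl,nNaPerSNP,nWaterAtoms see
#'   slot documentation.
#' @export
systemSpec <- function(name, crystal, nominalDiameter, pH, nSNP, atomsPerSNP,
                       nDye, atomsPerDye, dyeCharge, nSilanol,
                       ionizationFraction, nCl, nNaPerSNP, nWaterAtoms) {
  new("SystemSpec", name = name, crystal = crystal,
      nominalDiameter = nominalDiameter, pH = pH, nSNP = nSNP,
      atomsPerSNP = atomsPerSNP, nDye = nDye, atomsPerDye = atomsPerDye,
      dyeCharge = dyeCharge, nSilanol = nSilanol,
      ionizationFraction = ionizationFraction, nCl = nCl,
      nNaPerSNP = nNaPerSNP, nWaterAtoms = nWaterAtoms)
}
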