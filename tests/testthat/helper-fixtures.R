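# Shared fixture builders; everything is generated in code at test time.

# minimal hand-built topology: nanoparticle of 4 sites + one 5-site dye with
# a 4-site planar core
toyTopology <- function() {
  topology(
    particleId = 0:8,
    mass = c(rep(20, 4), rep(12, 5)),
    charge = c(rep(-0.5, 4), rep(0.2, 5)),
    groups = list(
      SNP1 = 0:3,
      R6G_1 = 4:8,
      R6G_1_core = 4:7
    )
  )
}

# one-frame coordinates for toyTopology: NP sites around the origin, dye
# core coplanar in z = z0 above the NP, tail site out of plane
toyFrame <- function(z0 = 6) {
  rbind(
    c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
    c(0.5, 0.5, z0), c(-0.5, 0.5, z0), c(-0.5, -0.5, z0), c(0.5, -0.5, z0),
    c(0, 0, z0 + 1.5)
  )
}

# static spherical nanoparticle model at the origin
staticNp <- function(nFrames, radius = 20, center = c(0, 0, 0),
                     group = "SNP1") {
  new("NanoparticleModel", group = group,
      centers = matrix(center, nFrames, 3, byrow = TRUE), radius = radius)
}

# scripted simulation shorthand
scriptedSim <- function(stateIntervals = NULL, dimerEvents = NULL, nDye = 3,
                        duration = 20, timestep = 0.02, dyeSiteCount = 16,
                        noiseSd = 0, seed = 7) {
  simulateTrajectory(simConfig(
    nDye = nDye, dyeSiteCount = dyeSiteCount, duration = duration,
    timestep = timestep, noiseSd = noiseSd, seed = seed,
    scripted = list(stateIntervals = stateIntervals,
                    dimerEvents = dimerEvents)))
}

# random rotation matrix (uniform via QR of a Gaussian matrix)
randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# per-frame labels implied by a ground-truth interval table (half-open
# [start, end) intervals, FREE elsewhere)
truthFrameLabels <- function(intervals, times, dye) {
  lab <- rep("FREE", length(times))
  rows <- intervals[intervals$dye == dye & intervals$label != "FREE", ,
                    drop = FALSE]
  if (nrow(rows))
    for (i in seq_len(nrow(rows))) {
      sel <- times >= rows$start_ns[i] & times < rows$end_ns[i]
      lab[sel] <- rows$label[i]
    }
  lab
}

# printed per-repetition adsorbed-time percentages (one column per system)
printedAdsorbedRepetitions <- function() {
  data.frame(
    repetition = 1:4,
    `40qSNP7` = c(31, 20, 21, 18),
    `40qSNP12` = c(3, 21, 12, 0),
    `40cSNP7` = c(30, 24, 28, 48),
    `40cSNP12` = c(6, 0, 9, 0),
    `20qSNP7` = c(53, 29, 51, 24),
    `20qSNP12` = c(3, 21, 12, 0),
    `20cSNP7` = c(38, 32, 37, 23),
    `20cSNP12` = c(10, 7, 5, 0),
    check.names = FALSE
  )
}
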