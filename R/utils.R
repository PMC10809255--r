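# Unit constants. 1 e.Angstrom in Debye; 1 kcal/mol in pN.Angstrom
# (4184 / 6.02214076e23 J = 69.4786e-22 J); 1 pN.Angstrom in eV
# (1e-22 J / 1.602177e-19 J/eV).
EA_TO_DEBYE <- 4.8032
KCALMOL_TO_PNA <- 69.4786
PNA_TO_EV <- 6.2415e-4

#' Convert a spring constant from kcal/(mol Angstrom) to pN/Angstrom
#'
#' The 4 kcal/(mol Angstrom) harmonic constraint commonly used in
#' constant-velocity pulling corresponds to about 278 pN/Angstrom.
#'
#' @param value spring constant in kcal mol^-1 Angstrom^-1 (>= 0).
#' @return spring constant in pN/Angstrom.
#' @examples
#' convertSpringConstant(4) # ~278
#' @export
convertSpringConstant <- function(value) {
  stopifnot(is.numeric(value))
  if (any(value < 0)) stop("spring constant must be non-negative")
  value * KCALMOL_TO_PNA
}

# Round half away from zero (printed tables round 22.5 -> 23, 32.5 -> 33,
# unlike banker's rounding in base round()).
roundHalfUp <- function(x) floor(x + 0.5)

vecNorm <- function(v) sqrt(sum(v^2))

# Angle between two vectors in degrees, numerically clamped.
angleDeg <- function(a, b) {
  na <- vecNorm(a); nb <- vecNorm(b)
  if (na == 0 || nb == 0) stop("zero vector has no direction")
  cosang <- sum(a * b) / (na * nb)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

# Fold an angle into [0, 90]: orientation of an unsigned axis.
foldAngle <- function(deg) pmin(deg, 180 - deg)

# Maximal runs of TRUE in a logical vector -> matrix of start/end indices.
trueRuns <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Derive a reproducible 31-bit sub-seed from a base seed and a stream index.
subSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103515245 + stream * 12345) %% 2147483647)
}
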