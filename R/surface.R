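# Composition of the eight simulated systems (one row per system): six
# +1e dyes of 64 atoms; one 40 A or three 20 A silica particles, quartz or
# cristobalite crystal, at pH 7 or 12; chloride neutralizes the dyes and
# sodium the ionized surface silanols. Water counts are atoms (3 per
# molecule). Silanol counts per particle are inferred from the sodium count
# and the pH ionization fraction (synthetic bookkeeping, not printed in the
# source table).
.systemTable <- data.frame(
  name = c("40qSNP7", "40qSNP12", "40cSNP7", "40cSNP12",
           "20qSNP7", "20qSNP12", "20cSNP7", "20cSNP12"),
  crystal = c("quartz", "quartz", "cristobalite", "cristobalite",
              "quartz", "quartz", "cristobalite", "cristobalite"),
  nominalDiameter = c(40, 40, 40, 40, 20, 20, 20, 20),
  pH = c(7, 12, 7, 12, 7, 12, 7, 12),
  nDye = rep(6, 8),
  atomsPerDye = rep(64, 8),
  nSNP = c(1, 1, 1, 1, 3, 3, 3, 3),
  atomsPerSNP = c(3141, 3077, 2725, 2638, 436, 421, 376, 354),
  nCl = rep(6, 8),
  nNaPerSNP = c(51, 116, 58, 155, 11, 27, 17, 39),
  nWaterAtoms = c(80118, 80612, 81832, 80292, 82731, 84153, 83325, 81861),
  total = c(83700, 84195, 85005, 83475, 84462, 85887, 84894, 83430),
  stringsAsFactors = FALSE
)

#' Silanol ionization fraction at a tabulated pH
#'
#' The pH enters the model through the fraction of surface silanol groups
#' that are deprotonated: 13.3% at pH 7 and 30% at pH 12. Only these two
#' values are tabulated; other pH values are rejected rather than
#' interpolated.
#'
#' @param ph 7 or 12.
#' @return unitless fraction.
#' @export
ionizationFractionForPH <- function(ph) {
  if (length(ph) != 1 || !ph %in% c(7, 12))
    stop(sprintf("no tabulated ionization fraction for pH %s", format(ph)))
  if (ph == 7) 0.133 else 0.30
}

#' Surface group density per unit area
#'
#' Groups per square Angstrom on a sphere of the given nominal diameter
#' (area pi d^2). Nominal diameters are used so particles of different
#' crystal structures are compared on an equal footing.
#'
#' @param count number of surface groups.
#' @param diameter sphere diameter (Angstrom, > 0).
#' @return groups per Angstrom^2.
#' @export
surfaceDensity <- function(count, diameter) {
  if (any(diameter <= 0)) stop("diameter must be positive")
  count / (pi * diameter^2)
}

#' Counterion counts required for neutrality
#'
#' Chloride neutralizes the cationic dyes (one per +1e dye charge); sodium
#' neutralizes each particle's negative charge, which equals the rounded
#' product of its silanol count and the pH ionization fraction. With
#' \code{validate = TRUE}, disagreement with the counts stored in the spec
#' is an error, never silently accepted.
#'
#' @param spec a [SystemSpec-class].
#' @param validate check the computed counts against the stored ones.
#' @return list with \code{nCl} and \code{nNaPerSNP}.
#' @export
neutralizingIonCounts <- function(spec, validate = TRUE) {
  nCl <- spec@nDye * spec@dyeCharge
  snpCharge <- -roundHalfUp(spec@nSilanol * spec@ionizationFraction)
  nNa <- abs(snpCharge)
  if (validate) {
    if (!is.na(spec@nCl) && spec@nCl != nCl)
      stop(sprintf("%s: stored Cl count %d disagrees with computed %d",
                   spec@name, spec@nCl, nCl))
    if (!is.na(spec@nNaPerSNP) && spec@nNaPerSNP != nNa)
      stop(sprintf("%s: stored Na count %d disagrees with computed %d",
                   spec@name, spec@nNaPerSNP, nNa))
  }
  list(nCl = nCl, nNaPerSNP = nNa)
}

#' Total atom count of a system
#'
#' Dye atoms + nanoparticle atoms + chloride + sodium + water atoms.
#'
#' @param spec a [SystemSpec-class].
#' @return integer count.
#' @export
totalAtomCount <- function(spec) {
  vals <- c(spec@nDye, spec@atomsPerDye, spec@nSNP, spec@atomsPerSNP,
            spec@nCl, spec@nNaPerSNP, spec@nWaterAtoms)
  if (any(is.na(vals))) stop("missing component count")
  spec@nDye * spec@atomsPerDye + spec@nSNP * spec@atomsPerSNP +
    spec@nCl + spec@nSNP * spec@nNaPerSNP + spec@nWaterAtoms
}

#' Percent difference between two dipole magnitudes
#'
#' \code{100 * (b - a) / a}: e.g. 125 vs 250 D is a 100% difference, 500 vs
#' 900 D is 80%.
#'
#' @param a reference magnitude (Debye, > 0).
#' @param b compared magnitude (Debye).
#' @return percent.
#' @export
percentDifference <- function(a, b) {
  if (any(a == 0)) stop("reference magnitude must be non-zero")
  100 * (b - a) / a
}

#' Dye contribution to the measured complex size
#'
#' A flat-adsorbed dye adds its core thickness to the measured particle
#' diameter: \code{100 * layerThickness / npDiameter} percent. An ~8
#' Angstrom xanthene core on a 40 Angstrom particle contributes ~20%; on
#' more curved 20 Angstrom particles the geometric estimate reaches 40%,
#' larger than the ~30% observed for such constructs because small
#' particles are not perfectly spherical and the measured diameter depends
#' on direction.
#'
#' @param layerThickness Angstrom (> 0).
#' @param npDiameter Angstrom (> 0).
#' @return percent.
#' @export
sizeContribution <- function(layerThickness, npDiameter) {
  if (any(layerThickness <= 0) || any(npDiameter <= 0))
    stop("thickness and diameter must be positive")
  100 * layerThickness / npDiameter
}

#' Build the composition record of a named system
#'
#' Returns the [SystemSpec-class] for one of the eight simulated systems
#' ("40qSNP7", "40qSNP12", "40cSNP7", "40cSNP12", "20qSNP7", "20qSNP12",
#' "20cSNP7", "20cSNP12"). The silanol count per particle is inferred from
#' the sodium count and the pH ionization fraction (synthetic bookkeeping).
#'
#' @param name system name.
#' @return a [SystemSpec-class].
#' @export
makeSystemFixture <- function(name) {
  row <- .systemTable[.systemTable$name == name, ]
  if (nrow(row) != 1)
    stop(sprintf("unknown system name '%s'", name))
  frac <- ionizationFractionForPH(row$pH)
  systemSpec(
    name = row$name, crystal = row$crystal,
    nominalDiameter = row$nominalDiameter, pH = row$pH,
    nSNP = row$nSNP, atomsPerSNP = row$atomsPerSNP,
    nDye = row$nDye, atomsPerDye = row$atomsPerDye, dyeCharge = 1,
    nSilanol = roundHalfUp(row$nNaPerSNP / frac),
    ionizationFraction = frac,
    nCl = row$nCl, nNaPerSNP = row$nNaPerSNP,
    nWaterAtoms = row$nWaterAtoms
  )
}

#' Names of the eight tabulated systems
#'
#' @return character vector.
#' @export
systemNames <- function() .systemTable$name

#' Characterize all tabulated systems
#'
#' Emits a composition table with derived quantities: total atom count,
#' nanoparticle charge, and silanol/ionized-silanol/sodium surface densities
#' per Angstrom^2.
#'
#' @param names systems to include (default all eight).
#' @return data.frame, one row per system.
#' @export
characterizeSystems <- function(names = systemNames()) {
  rows <- lapply(names, function(nm) {
    spec <- makeSystemFixture(nm)
    ions <- neutralizingIonCounts(spec)
    data.frame(
      system = spec@name, crystal = spec@crystal,
      diameter_A = spec@nominalDiameter, pH = spec@pH,
      n_snp = spec@nSNP, atoms_per_snp = spec@atomsPerSNP,
      n_dye = spec@nDye, n_cl = ions$nCl, n_na_per_snp = ions$nNaPerSNP,
      snp_charge_e = -ions$nNaPerSNP,
      total_atoms = totalAtomCount(spec),
      silanol_per_A2 = surfaceDensity(spec@nSilanol, spec@nominalDiameter),
      ionized_per_A2 = surfaceDensity(ions$nNaPerSNP, spec@nominalDiameter),
      na_per_A2 = surfaceDensity(ions$nNaPerSNP, spec@nominalDiameter)
    )
  })
  do.call(rbind, rows)
}
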