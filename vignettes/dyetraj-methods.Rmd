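---
title: "Methods: adsorption states, dimer kinetics and pulling energetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adsorption states, dimer kinetics and pulling energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyetraj)
```

# The system and the observables

Rhodamine 6G is a cationic (+1e) xanthene dye used to label silica
nanoparticles for time-resolved fluorescence anisotropy sizing. Whether the
dye contributes to the measured size of the dye–particle complex depends on
how it sits on the surface, which cannot be observed experimentally and is
therefore studied with all-atom MD. This package implements the
*post-processing* of such trajectories; it does not run MD. The observables
it works with are:

* the **COM-to-surface distance** of each dye: the distance from the dye's
  mass-weighted centre to the centre of a spherical nanoparticle model,
  minus the sphere radius. The radius defaults to half the nominal
  construction diameter; an empirical mode (95th percentile of member
  radial distances) exists because the heavy-atom diameter of a small
  crystal can differ slightly from nominal. Nominal is the default so
  results do not depend on a fitted quantity.
* the **parallelism angle**: the angle between the best-fit plane normal of
  the dye's planar xanthene core and the local radial direction, folded to
  [0°, 90°]. 0° means the core lies flat on the (locally spherical)
  surface. The plane fit is the eigenvector of the smallest principal
  second moment of the centred core coordinates, without mass weighting —
  the standard planarity estimator; "parallel to the surface" is never
  operationalized in visual analyses, so this package defines it
  explicitly.
* the **dipole angle θ** between the dye's and the particle's dipole
  moments. Dipoles of net-charged selections depend on the reference
  point; the reference is pinned to each selection's own COM so that
  per-molecule dipoles are comparable and the diffusing counterion layer is
  excluded. The identity "shifting the reference by *t* changes the dipole
  by −q·t" is tested exactly. θ is reported per segment as corroborating
  evidence but is *not* a classification criterion: in a crowded
  fluctuating electric field the stable-adsorption θ sits well below the
  ideal 180°.

# State classification

Each dye–particle distance series is segmented into **near-surface
episodes**: maximal runs with distance ≤ `adsorptionThreshold` (5 Å),
merging interruptions shorter than `gapTolerance` (0.2 ns) so a one-frame
excursion does not split a physical visit. Episodes are labelled:

* **A** — duration ≥ `minADuration` (5 ns) *and* the core is parallel
  (angle ≤ `parallelTolerance`, 30°) in at least `parallelFractionA` (80 %)
  of frames;
* **T** — the core is essentially never parallel (parallel fraction <
  `parallelFractionTMax`, 20 %). Trapped episodes typically last under
  `maxTDuration` (2 ns); longer never-parallel episodes remain T and are
  flagged rather than reclassified;
* **R/A** — everything in between: the dye is near the surface but
  repositioning, with intermittent parallel orientation.

Defaults and why: the 5 Å surface threshold and the ~2 ns trapped-lifetime
scale follow the conventions used when such trajectories are read off COM
plots. The 30° parallel tolerance separates flat from tilted poses while
tolerating thermal wobble of the plane normal; the 5 ns minimum stable
duration is a conservative divider between stable adsorption (tens of ns)
and the "multiple short interactions" phenotype of R/A. Both are
configurable; none of the downstream bookkeeping depends on them being
exactly these values.

**Adsorbed-time tables.** The per-repetition summary is the percentage of
the trajectory during which *at least one* dye is adsorbed: the union over
dyes of counted segments divided by the trajectory length. Both A and R/A
count by default — per-repetition values of weakly adsorbing systems are
dominated by R/A episodes, so A-only counting cannot reproduce them.
Averages over repetitions are rounded half away from zero (a mean of 22.5
prints as 23, 32.5 as 33), which is the convention consistent with six of
the eight printed column averages of the published adsorbed-time table; the
remaining two printed averages are not the arithmetic means of their
printed repetitions and are deliberately *not* reproduced — the computed
means are reported as-is.

# Dimers and trimers

A stacked dimer is a pair of dyes whose core COMs are within
`coreDistanceCutoff` (6 Å) and whose core-plane normals are parallel or
antiparallel within `stackingTolerance` (30°). The plane-normal test, not
the dipole angle, encodes π-stacking geometry: stacked cores are
face-to-face with tails protruding, and the folded normal angle is the
measurable proxy for that. A dye can be in at most one dimer at a time;
per frame, contacting pairs are assigned greedily by increasing core
distance (verified against exhaustive assignment), so a pairwise-stacked
triple resolves to the closest dimer plus a free dye. Episodes shorter
than `minDimerDuration` (1 ns) are discarded.

Events are classified by where they live and how they end:

* **location** — matrix if the median dimer-COM surface distance during
  the event is ≤ `matrixThreshold` (5 Å), else solute;
* **censored** — the event reaches the final frame;
* **desorption** — the intact pair's surface distance rises from within
  the matrix threshold to beyond twice it before the contact breaks;
* **dissociation** — the pair contact breaks. When state segments are
  available, a break near the surface (≤ threshold + 5 Å) followed by a
  partner entering A/R-A within 1 ns is recorded in
  `adsorption_followed`, the canonical dissociation-then-adsorption
  signature. The 1 ns window and the 2× threshold are package-defined
  operationalizations of behaviour that is otherwise narrated visually.

Trimers are third dyes in stacking contact with either member of an active
dimer. They are flagged transient and never promoted: stable aggregates
beyond the dimer are geometrically excluded (each core has two faces, both
of which are already engaged in a stacked dimer-plus-one arrangement).

Per-system statistics follow the published table layout: mean event count
per run, mean total dimer time per run, and the mean of pooled individual
lifetimes. The printed per-system lifetime statistics in the source table
are mutually inconsistent (total/count ≠ per-dimer time), so they serve as
a format reference only; the pooled-lifetime definition used here
satisfies lifetime × count = total time exactly for a single run.

# Pulling energetics

In constant-velocity steered MD, unbinding shows as a sawtooth in the
force–time trace: force ramps at slope k·v, then drops as the compound
jumps forward. Detection operates on a smoothed trace (centred moving
average, default window 50 ps) with a hysteresis walk: a running maximum
followed by a drop exceeding `dropThreshold` (3) × the robust noise sd
(MAD of the detrended trace) opens a transition, closed at the subsequent
minimum. Two guards reject noise: the displacement must advance by at
least dF/k across the drop (with a 0.9 factor absorbing noise-driven
overestimation of dF), and transitions must be separated by at least the
smoothing window. Force amplitudes are refined on a lightly smoothed
(5-sample) trace so the heavy detection smoothing does not bias the drop
height.

Each transition releases the spring potential energy

$$dE = \frac{(F_0 + dF)^2 - F_0^2}{2k},$$

with \(F_0\) the force at the end of the transition, and the binding
energy is the sum of the releases, converted via 1 pN·Å =
6.2415×10⁻⁴ eV. The algebraic form follows the stated roles of F₀, dF and
k (force at the *end* of the transition); because the source formula is
only rendered graphically, the alternative peak-anchored convention
\(dE = (F_0^2 - (F_0-dF)^2)/(2k)\) is exposed through the documented
`f0Convention = "peak"` switch. Spring constants given in kcal mol⁻¹ Å⁻¹
convert at 69.4786 pN·Å per kcal/mol, so the standard 4 kcal mol⁻¹ Å⁻¹
constraint is 278 pN/Å.

The absolute desorption/dissociation energies reported for the real
systems (≈1.08, 0.36, 0.27 eV) require the original force traces and are
not reproducible here; the estimator is instead validated against
generator traces of known total well depth (below).

# The synthetic generator

The generator exists to exercise every analysis stage with known ground
truth; it is a *toy*, not a silica model.

**Rigid bodies.** Each dye is a rigid cluster of 64 sites (30 coplanar
core sites in a 1.4 Å grid, the rest an out-of-plane tail), total charge
+1e with an in-plane gradient so the dipole is non-zero; orientation is a
unit quaternion. Nanoparticles are fixed Fibonacci-sphere shells whose
total charge matches an ionized-silanol density of ~0.01 /Å², with a polar
charge gradient providing a dipole. Site counts are configurable so
geometry operators run on realistic group sizes cheaply.

**Emergent mode** integrates overdamped Langevin dynamics: translational
noise \( \sqrt{2 D_t \Delta t}\), rotational noise as small random
rotations \( \sqrt{2 D_r \Delta t}\), a screened radial attraction
\(-A e^{-s/\lambda}\), a Gaussian adsorption well at 2.5 Å from the
surface engaged only when the core normal is inside the orientation gate
(cosine-ramped, width 30°), and a pairwise stacking well at 4 Å core
separation gated on the folded inter-normal angle. Gates are smooth so
forces are continuous. Defaults: D_t = 20 Å²/ns and D_r = 0.8 rad²/ns
(the experimental scale for a small dye in water), 6 dyes, one 20 Å-radius
particle, 100 ns at 0.01 ns steps, adsorption well 6 kT, stacking well
4 kT. Ground truth logs the episodes during which a well was actually
engaged (well on, within range, gate ≥ 0.5) — with all wells off, pure
diffusion produces no ground-truth episodes by construction.

*Stability.* The integrator refuses to run when any single interaction's
deterministic displacement exceeds 0.5 Å in one step: such a step cannot
resolve the force gradient. The check is per interaction term and excludes
the thermal noise, which has unbounded Gaussian tails at any timestep.

**Scripted mode** replays user-specified state intervals and dimer events
exactly, with deterministic noise-free kinematics (smooth sinusoidal free
wander between scripted episodes, exact placements during them:
adsorbed = 2.5 Å off the surface with the core flat, trapped = 3 Å with a
75° tilt, reorienting = oscillating distance with a 50 % parallel duty
cycle, dimer = cores 3.5 Å apart with antiparallel normals). Ground truth
is the script itself. Optional Gaussian measurement noise is added to the
*emitted* coordinates only, never to the latent kinematics, so recovery
against ground truth is well defined. Intervals are half-open
[start, end); all episodes are reported at frame resolution, so recovered
boundaries agree with scripted ones to within one frame spacing.

**SMD traces** are built quasi-statically: the compound sits in a sequence
of wells; escapes occur when the releasable spring energy over the jump
distance d equals the well depth, \(F_{peak} d - k d^2/2 = E\), which
makes the spring-energy release across each drop equal the depth *exactly*
and the ground-truth total equal Σ depths. Auto-sized jumps
\(d = \sqrt{2E/k}\) give a clean sawtooth relaxing to zero force.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: explicit water and ions, internal dye
flexibility, torques from the wells (orientations only diffuse), aspheric
particles, force-field accuracy, and the absolute adsorption percentages
of the real systems, which depend on the real electrostatics. The tests
demonstrate that the *estimators* are correct on data whose truth is
known, not that the toy reproduces silica photophysics.

# Surface bookkeeping

pH enters through the tabulated ionization fraction of surface silanols
(13.3 % at pH 7, 30 % at pH 12; other pH values are rejected rather than
interpolated). A particle's charge is −round(n_silanol × fraction), its
neutralizing sodium count is the absolute charge, and chloride matches the
dye charges one-to-one; stored counts that disagree with the computed ones
raise a validation error rather than being silently accepted. Surface
densities are counts over the nominal sphere area πd², so different
crystal structures are compared on equal footing. Total atom counts are
rebuilt from components (dye + particle + ions + water) and reproduce all
eight published system totals exactly. Two published water *atom* counts
are not divisible by 3 although water has 3 atoms per molecule (they
disagree with the printed molecule counts by one atom); the atom counts
are taken as printed, since the totals require them, and the divisibility
rule is therefore not enforced. Silanol counts per particle are not
printed and are inferred from the sodium counts and the ionization
fraction — synthetic bookkeeping, self-consistent under round-half-up for
all eight systems.

# Numerical choices and degenerate inputs

* Units: Å, ns, degrees, e; 1 e·Å = 4.8032 D; 1 kcal/mol = 69.4786 pN·Å;
  1 pN·Å = 6.2415×10⁻⁴ eV.
* Plane fits reject collinear cores (second principal moment ≈ 0); the
  normal's sign follows the supplied radial direction when one is given
  and is arbitrary otherwise (all consumers fold angles).
* Angle computations clamp cosines to [−1, 1]; zero vectors and zero
  dipoles are errors, not NaNs.
* Episode boundaries are reported at frame times; durations are
  end − start of member frames. Half-open ground-truth intervals avoid
  double-claimed boundary frames.
* Dimer exclusivity ties break by smaller core distance; equality is
  resolved by pair enumeration order (stable across runs).
* Readers reject malformed input (non-monotone times, particle-count
  mismatches, duplicate ids, unknown groups, core ⊄ dye) instead of
  repairing it. Trajectory tables store coordinates at fixed 4-decimal
  precision; a table written from coordinates already at that precision
  round-trips bit-identically.
* All stochastic stages take explicit integer seeds; sub-streams are
  derived with a fixed 31-bit linear map.

# Problem sizes used in the shipped checks

The shipped tests and the acceptance script choose sizes that keep the
whole suite in a few minutes while leaving the statistics decisive:
scripted recovery on 3 dyes × 1500 frames; dimer recovery on 4 dyes ×
2000 frames; SMD recovery over 20 seeds of a 5-well, 1.0 eV trace with
10 pN noise; free-dye diffusion with 50 dyes × 100 ns (MSD at 2 ns lag
against 6·D·τ); the stacking-depth rank test over 10 seeds × 4 depths;
and one full-scale end-to-end run (6 dyes × 64 sites, one particle,
100 ns at 10⁴ frames) scored against its scripted ground truth.

# Known limitations

* The spherical surface-distance model ignores asphericity; for strongly
  aspheric small particles the empirical-radius mode only rescales the
  sphere, it does not reshape it.
* θ is reported, not classified on; systems where orientation data are
  missing simply classify on distance + parallelism.
* The dimer end-reason taxonomy is threshold-based and inherits the
  arbitrariness of its windows (documented above); censored events are
  excluded from lifetime interpretation by their label, not dropped.
* Emergent-mode ground truth is defined by well engagement; it is the
  generator's truth, not an independent physical definition of adsorption.
* `bio3d` PDB I/O carries the usual PDB column-width limits; masses and
  charges always come from the sidecar table, never guessed from element
  symbols.
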