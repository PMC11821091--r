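---
title: "Micelle analysis methods: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micelle analysis methods: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micellr)
```

This vignette is the package's own account of the science it implements:
the descriptors, their assumptions, the tunable parameters, what the
synthetic generators do and do not emulate, and the choices made where
conventions genuinely differ between groups.

## Coordinate model and periodic boundaries

All lengths are nanometres internally (GRO is nm-native); Angstrom
appears only in report tables, where micelle radii are conventionally
printed.  Boxes are orthorhombic; triclinic GRO box lines are rejected
outright rather than silently truncated, because every supported analysis
assumes independent per-axis wrapping.

The minimum-image displacement wraps each component into the half-open
interval (−L/2, L/2].  Putting the boundary point at +L/2 is arbitrary
but fixed, so constructed fixtures that land exactly on the boundary are
deterministic.

Selections are made *whole* before any shape computation by
minimum-imaging every atom to a reference point.  We use the per-axis
circular mean of the selection (each coordinate mapped to an angle on a
circle of circumference L and averaged) rather than the more common
"first atom of the selection" reference: a reference atom on the micelle
surface fails as soon as the aggregate's diameter exceeds L/2, which a
60-chain micelle in a snug box reaches easily, while the circular-mean
centre is exact for any compact object with radius below L/2.  Micelle
centres of mass are then the mass-weighted average of the whole
selection, wrapped back into the box.

Masses are inferred from the first alphabetic character of each atom name
(H, C, N, O, S, ...; all-caps CL/NA/BR ion names are special-cased), and
a species map can override any atom's mass.  Coordinate files do not
carry masses, and mass-weighted inertia and R~g~ follow the convention of
the common MD engines' built-in tools.

## Shape descriptors

For a whole selection with masses $m_i$ and positions $\mathbf r_i$
relative to the centre of mass, the inertia tensor is
$\mathbf I = \sum_i m_i (r_i^2 \mathbb 1 - \mathbf r_i \mathbf r_i^T)$
with ascending principal moments $I_1 \le I_2 \le I_3$.  The
eccentricity is

$$e = 1 - \frac{I_{\min}}{I_{\mathrm{mean}}},$$

which is 0 for a perfect sphere and grows with elongation.  (Some papers
typeset this quantity as the bare ratio $I_{\min}/I_{\mathrm{mean}}$
while describing a sphere as $e \approx 0$; the sphere limit fixes the
sign convention, and we implement the standard micelle-literature form
above.)  The radius of gyration is the mass-weighted RMS distance from
the COM, and the effective micellar radius is
$R_s = \sqrt{5/3}\,\bar R_g$ — the radius of the uniform solid sphere
with the same $R_g$.  The `shape_series()` summary keeps
$R_s/\bar R_g = \sqrt{5/3}$ exactly by construction.

Run averages use every production frame by default (`burn_in = 0`),
matching the usual practice of analysing the full production run after a
separate equilibration phase; a burn-in is available when the user wants
to discard early frames.  As an equilibration check the linear trend of
$R_g$ over the last half of the series is fitted, and the run is flagged
when the slope exceeds twice its standard error — a deliberately simple
drift indicator, not a substitute for inspecting the series.

Whether shape descriptors should use all micelle atoms or only heavy
atoms is not standardised; the default selection is all atoms of the
micelle species, and any subset can be passed explicitly.

## Conformation metrics

Head-to-tail distance and the bend angle at a central reference atom are
computed per surfactant from minimum-image vectors (molecules may be
imaged across the boundary), then averaged molecules → frame → run.  The
headline spread is the standard deviation over frame means, the
convention behind "mean (SD)" run tables; the spread over individual
molecule-frame values is also reported (`sd_*_mol`), since the two answer
different questions and published tables rarely say which they use.

## Radial distribution functions

Site–site $g(r)$ histograms minimum-image A–B distances, excluding
self-pairs, and normalises each frame by $N_A\,\rho_B\,V_{\text{shell}}$
with $V_{\text{shell}} = \tfrac{4\pi}{3}[(r+\Delta)^3 - r^3]$ and
$\rho_B$ the bulk number density of the B selection.  When the two
selections share a species, intra-molecular pairs are excluded by
default: self-interaction curves of a surfactant species are meant to
show inter-molecular structure, not covalent geometry.  The flag is
explicit (`exclude_same_molecule`) for cases where the default is wrong.

COM-centred distributions treat the per-frame micelle COM as a single
reference point ($N_A = 1$) with the same shell normalisation, using the
number density of the *selected target* species as the bulk density —
the curves are true $g(r)$, approaching 1 where the target is uniform,
not raw density profiles.

The default bin width is 0.002 nm with `r_max` at half the smallest box
edge: fine enough to separate contact peaks 0.02 nm apart, which is the
resolution at which such peaks are typically discussed.  `r_max` beyond
the half box is an error (the minimum-image distance distribution is
only geometrically clean below L/2).

## Hydrogen bonds

Detection is the geometric Luzar–Chandler criterion: donor–acceptor
distance ≤ 0.35 nm *and* hydrogen–donor–acceptor angle at the donor
≤ 30°, both inclusive.  The angle is measured at the donor between the
donor→hydrogen and donor→acceptor vectors — the convention of the
original criterion and of the common engine tools; phrases like
"H···donor–acceptor angle" in the literature are ambiguous, and this
reading is the one that reproduces the 30° cutoff semantics.  Inclusive
boundaries make constructed fixtures deterministic.  Each (donor,
hydrogen, acceptor) triplet counts once; multiple hydrogens of one donor
reaching the same acceptor are separate triplets and are not
deduplicated.  A hydrogen more than 0.15 nm from its heavy donor raises
a topology warning, since that usually means the donor pairing is wrong.

Species-pair tables bin bonds by the unordered pair of donor-heavy and
acceptor species in the order Surf–Surf, Surf–Ch, Surf–HBD, Surf–Cl,
Ch–Ch, Ch–HBD, Ch–Cl, Cl–HBD, HBD–HBD, other.  Halide anions are
acceptors only; sodium is neither donor nor acceptor (there are no
Na-involving categories in the standard table layout).  Grouped shares
split the total into surfactant-involving vs DES-only percentages, and
`percent_change()` expresses the growth of a category sum between two
systems.

The production detector is a compiled double loop over donors and
acceptors; the test-suite checks it for exact equality against a plain-R
triple-loop oracle on 50 random frames, so any future optimisation (cell
lists, neighbour tables) must preserve bit-identical results.

## Transport

MSD uses every frame as a time origin by default (`origin_stride`
configurable purely for speed), averaging over origins and entities.
Three entity conventions are supported: each atom (`per_particle`), the
COM of each molecule (`molecule_com` — the natural definition of a
surfactant-monomer $D$), and the COM of the whole selection (`com` — the
micelle $D$).  Published work rarely states which convention produced a
reported $D$; ours are documented here.  Unwrapped coordinates are used
when the trajectory provides them; otherwise frames are unwrapped by
accumulating minimum-image steps, which is valid while no entity moves
more than half a box edge between frames (violations cannot be detected
after the fact — this is stated rather than silently assumed).

The diffusive regime is validated via
$\beta(\tau) = \mathrm d\ln \mathrm{MSD}/\mathrm d\ln\tau$, computed by
centred finite differences on the log–log series.  The diffusive window
is the longest contiguous run with $|\beta - 1| \le 0.1$, and the series
is flagged non-diffusive when that window spans less than 20 % of the
available lags.  The 0.1 tolerance and 20 % span are choices —
$\beta$-validation is cited in the viscous-liquid MD literature without a
universal threshold — and both are parameters of `beta_exponent()`.
$D$ is the least-squares MSD slope over the window divided by 6; an
additive MSD constant is absorbed by the intercept.  The conversion
nm²/ps → 10⁻¹¹ m²/s is a factor 10⁵.

## Free energy perturbation

Each window's increment is the Zwanzig exponential average
$\Delta G = -k_BT \ln \langle e^{-\Delta U/k_BT} \rangle$, evaluated with
the log-sum-exp trick (subtract the largest exponent) so that large
$|\Delta U|$ cannot overflow.  The ladder sums windows gas → solvated;
negative totals mean favourable solvation.  Uncertainty is the standard
deviation of the total over 200 seeded bootstrap resamples within each
window.  Forward Zwanzig over adjacent pairs is the estimator because
that is what a plain λ-ladder FEP protocol specifies; BAR/MBAR are
deliberately out of scope.  $k_B = 0.0083144621$ kJ mol⁻¹ K⁻¹; all
energies kJ/mol.  The estimator is biased high at finite $n$ (Jensen);
the test suite checks the bound and that the bias shrinks with sample
size.

## Synthetic generators: what they do and do not emulate

All generators are pure functions of their arguments and a seed, and
attach their ground truth to the returned object, so no test ever reads
truth from the code under test.

* `build_micelle()` places chains on a Fibonacci lattice mapped to an
  ellipsoid, heads outward, straight (or bent at a marked site) radial
  chains, optional Gaussian jitter.  Defaults are the study conditions
  for a small spherical micelle: 60 chains (120 for the large case),
  2 nm semi-axes, and a 13-site dodecyl-sulfate-like chain (S1 head,
  twelve carbons at 0.12 nm radial steps, head-to-tail span ≈ 1.45 nm,
  consistent with reported SDS head-to-tail distances of ~1.4 nm).  It
  emulates geometry only: no excluded volume, no force field, no solvent,
  no thermal conformational ensemble.  Passing shape/conformation tests
  therefore shows the *estimators* are correct on known geometry, not
  that real micelles look like this.
* `ellipsoid_cloud()` gives exactly uniform solid-ellipsoid samples
  (Gaussian direction × radial $u^{1/3}$), for which the population
  inertia is analytic — e.g. eccentricity exactly 0.5 for 2:1:1 — and
  shell samples for the $R_g \to R$ sphere limit.
* `brownian_trajectory()` takes independent Gaussian steps of per-axis
  variance $2D\,\mathrm dt$: exactly the diffusive limit, with none of
  the caging/subdiffusive behaviour of a real viscous DES.  It stores
  wrapped frames *and* the unwrapped ground truth, because wrapping
  destroys MSD.
* `make_hbond_fixture()` constructs donor–hydrogen–acceptor triplets
  with exact requested distance and angle (hydrogen at 0.1 nm, a typical
  covalent O–H length), labelled with their expected bond status.
* `harmonic_fep_samples()` interpolates a harmonic force constant
  $k(\lambda)$ over the ladder and samples each window's Boltzmann
  distribution exactly; the full transformation has the closed form
  $\Delta G = \tfrac{k_BT}{2}\ln(k_1/k_0)$.  Real solvation ladders have
  far harder overlap problems than this fixture.

Stochastic recovery tests state their tolerances as multiples of an
estimated standard error (Poisson errors for RDF bins, replica scatter
for $D$, bootstrap SDs and the lognormal delta-method error for FEP),
not as ad-hoc constants.

## Problem sizes and numerical choices

The validation suite runs at sizes chosen to make the statistical
tolerances meaningful while staying desk-scale: 2 × 10⁵ points for the
analytic ellipsoid (sampling error in $e$ well below the 0.01 check),
5 × 10³ atoms for the ideal-gas RDF, 10³ particles × 2 × 10³ steps for
the Brownian recovery (slope error comfortably inside 5 %), and 21-stage
ladders with 2–5 × 10³ samples per window.  Degenerate inputs fail loudly
rather than returning numbers: all-zero inertia, empty selections,
non-positive MSD on the log scale, zero-sample windows, `r_max` past the
half box.

## Known limitations

* Orthorhombic boxes only; no XTC/TRR binary trajectories (the
  `trajectory` contract is the extension point).
* One predefined micelle per system: no aggregation-number detection or
  clustering of free monomers.
* No hydrogen-bond lifetime/kinetics analysis; no finite-size
  (Yeh–Hummer) corrections to $D$; no BAR/MBAR estimators.
* The unwrap-by-steps fallback cannot detect entities that jump more
  than half a box edge between frames.
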