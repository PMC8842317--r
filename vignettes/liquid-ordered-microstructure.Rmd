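---
title: "Quantifying liquid-ordered membrane microstructure and its thermotropic crossover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying liquid-ordered membrane microstructure and its thermotropic crossover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidorder)
```

## The scientific problem

Cholesterol-rich bilayers of high-melting phosphatidylcholines form the
liquid-ordered (L~o~) phase: acyl chains almost as ordered as in the gel
phase, but rotational and translational dynamics only modestly slower
than in the liquid-disordered (L~d~) phase. Within the L~o~ region the
membrane is not structurally uniform across temperature. At low
temperature, saturated chains can assemble into small hexagonally
packed, cholesterol-depleted clusters embedded in a fluid matrix; on
heating these clusters melt, and many membrane properties — area per
phospholipid, chain tilt, deuterium order parameters, glycerol
dynamics, lateral diffusion — change their temperature dependence at a
*crossover temperature* T~co~ while remaining continuous. `lipidorder`
implements the quantitative machinery for detecting and characterizing
this behavior from three kinds of input: molecular-dynamics
trajectories, temperature series of scalar observables, and
experimental melting curves (DSC thermograms, generalized polarization
and fluorescence anisotropy).

Because microsecond atomistic trajectories and calorimetric raw data
are rarely shippable, the package carries a first-class synthetic-data
module that generates every input class with *planted ground truth*.
The test suite and the acceptance script validate each analysis stage
as a recovery problem: plant a structure, analyze it, compare with the
planted parameters.

## Packing analysis

### Neighbor graphs

The hexatic order parameter is defined on a neighbor graph over the 2D
projected positions of acyl-chain reference sites. The default site of
a chain is the in-plane centroid of its carbons 4–14: mid-chain atoms
carry the hexagonal packing signal without headgroup noise, and the
range is configurable (`project_chain_sites(carbons = ...)`).
Cholesterol is excluded from the site set by default (its ring packs
against chains rather than participating in the chain lattice) but can
be included.

Two graph constructions are available:

* `voronoi_capped` (default): periodic Voronoi (Delaunay) adjacency
  with edges longer than `cutoff` removed. Voronoi adjacency is
  parameter-light; the cap (default 0.9 nm, about 1.5 chain spacings)
  removes the spurious long edges that Voronoi produces at cluster
  borders and low-density regions. Adjacency is decided by the exact
  empty-circumcircle criterion evaluated on the perpendicular bisector
  of each candidate pair (all pairs within the cutoff under the minimum
  image), with third sites contributing half-line exclusion
  constraints. This formulation is exact, handles the periodic box
  natively, and rejects four-point degeneracies — the diagonals of a
  square lattice share only a Voronoi vertex, not a facet, and are
  correctly excluded.
* `k_nearest`: each site is linked to its six nearest minimum-image
  neighbors and the edge set is symmetrized. Used as the automatic
  fallback for degenerate (collinear) configurations.

### Hexatic order

For site *j* with neighbors *N(j)* and bond angles θ~jk~ measured from
the +x axis,

$$S_\mathrm{hex}(j) = \left| \frac{1}{n_j} \sum_{k \in N(j)} e^{\,i\,6\,\theta_{jk}} \right| \in [0, 1].$$

Interior sites of a perfect triangular lattice give exactly 1 (six
bond angles 60° apart, all phase factors equal); interior sites of a
square lattice give exactly 0 (angles 0°, 90°, 180°, 270° produce
alternating ±1 phase factors). Both identities are asserted exactly in
the test suite. Sites with fewer than two neighbors have no meaningful
bond-angle statistics; they are flagged undefined and excluded from
aggregates.

### Core/edge/free classification

A site is **packed** when S~hex~ ≥ `hex_threshold` (default 0.8) *and*
it has at least `min_packed_neighbors` bonds (default 3). The second
condition is a reliability guard: the magnitude of a mean of *n* unit
phasors is strongly biased upward for small *n* (a site with two
random bonds reads S~hex~ ≥ 0.8 about 40% of the time), and a
genuinely hexagonally packed chain necessarily has a substantial
neighbor shell.

Labels are then:

* **core** — packed with a complete six-neighbor shell, all packed
  (a core chain is *surrounded* by hexagonally packed chains);
* **edge** — any other packed site; with `edge_side = "both"`,
  unpacked sites touching a packed site are also counted as edges;
* **free** — everything else, including undefined-S~hex~ sites.

Two design choices here were genuinely open. First, which side of the
packed boundary carries the edge label: defining edges on the unpacked
side propagates single-site S~hex~ noise into wide edge halos around
every spuriously packed site, which measurably degrades planted-truth
recovery, so the default is the packed side (`edge_side` exposes the
alternative). Second, the full-shell requirement for core: without it,
the boundary ring of an all-packed patch is indistinguishable from its
interior, contradicting both the topological ground-truth definition
used by the generator and the physical meaning of "surrounded".

The default threshold 0.8 cleanly separates the lattice mode
(S~hex~ near 1 at small jitter) from the fluid mode of the planted
generator; it is exposed in the configuration, as the appropriate value
for a particular force field or site definition may differ.

Over a frame sequence, a label change must persist for at least
`persistence` consecutive frames (default 2) or the previous stable
label is kept — transient single-frame flips at the packing threshold
are measurement noise, not cluster exchange. Exchange rates then count
transitions between the in-cluster state (core ∪ edge — edges belong
to their cluster) and free, per chain per nanosecond.

### Distances to cholesterol

Per-class chain–cholesterol distances use the in-plane minimum-image
distance from each chain site to the nearest cholesterol ring-system
centroid (the ring is what packs against chains; the hydroxyl oxygen is
available as an alternative reference).

## Per-lipid observables

* **Deuterium order parameters.** S~CD~ per carbon is
  ⟨(3 cos²θ~CH~ − 1)/2⟩ with θ~CH~ the angle between the C–H vector
  and the bilayer normal. Frames are assumed pre-oriented with the
  normal along z (planar patches only; no instantaneous-normal
  estimation). When hydrogens are absent, they are reconstructed from
  heavy-atom geometry with ideal tetrahedral angles — standard practice
  for united-atom trajectories — and the result is flagged. All-trans
  collinear neighborhoods are handled explicitly (the two H directions
  then span the plane perpendicular to the chain, preserving the
  S~CD~ = −0.5 identity). The aggregate "mean order parameter" uses
  carbons 8–16 by default, i.e. the chain middle onward.
* **Chain tilt** is the angle between the first-to-last chain-carbon
  vector and the normal, folded into [0°, 90°].
* **Cholesterol depth** is the z-offset of the hydroxyl oxygen from the
  phosphorus plane of its leaflet, positive toward the headgroups.
* **Glycerol rotational dynamics.** The backbone orientation is the
  C1→C3 glycerol vector by default (configurable); its autocorrelation
  C(t) = ⟨u(s)·u(s+t)⟩ is averaged over molecules and time origins and
  fitted with the stretched exponential exp(−(t/τ)^β). The reported
  correlation time is the analytic integral τ~c~ = (τ/β)Γ(1/β), which
  reduces to τ for β = 1 — the appropriate summary when relaxation
  times vary over orders of magnitude across a temperature range. β is
  bounded in (0.3, 1] and τ is initialized at the 1/e crossing of the
  ACF, which keeps the fit in the physical basin.
* **Lateral diffusion.** Tracks are unwrapped by minimum-imaging
  consecutive displacements and accumulating them — exact whenever the
  frame spacing is much shorter than the box-crossing time. D is
  slope/4 of the time-and-ensemble averaged MSD, fitted by least
  squares over a lag window of 10–50% of the maximum lag by default
  (early lags are dominated by sub-diffusive cage motion in real data,
  late lags by estimator variance). No finite-size (periodic-boundary)
  hydrodynamic correction is applied.

## Crossover detection

`segmented_fit()` fits the continuous two-slope model

$$y(T) = y_0 + s_1\,(T - T_\mathrm{co}) + (s_2 - s_1)\,\max(T - T_\mathrm{co}, 0),$$

with the breakpoint profiled out: a scan over interior data
temperatures (keeping at least two points strictly on each side)
followed by golden-section refinement of the profiled residual sum of
squares, solving the remaining three parameters linearly at each
candidate. Continuity at the breakpoint is enforced by construction:
the phenomenon is a crossover in slope, not a discontinuous
transition. Confidence intervals come from a seeded nonparametric
bootstrap over residuals (default 1000 resamples).

A single straight line is always fitted alongside. The two-segment
model is preferred only when the variance-ratio statistic
F = [(RSS₁ − RSS₂)/2] / [RSS₂/(n − 4)] is significant; because the
breakpoint is chosen to maximize that statistic over the candidate
grid, the naive F p-value is anti-conservative, so it is
Bonferroni-adjusted over the number of grid candidates. This bound is
deliberately conservative: it guarantees the false-crossover rate stays
below the threshold (default p < 0.05, configurable) while costing
essentially nothing against real slope breaks, whose adjusted p-values
are many orders of magnitude below any reasonable threshold at the
noise levels of interest. Series whose best breakpoint lands on the
grid boundary are likewise flagged as having no interior crossover.

Thermal expansion coefficients are α = slope / A(T~mid~) per segment,
evaluated at each segment's temperature midpoint. The consensus
crossover across observables is the inverse-variance weighted mean of
the non-flagged breakpoints (weights from bootstrap standard errors;
equal weights when no CIs are available), with a weighted standard
deviation as the spread. Heating and cooling series can be fitted
separately to check for hysteresis.

## Experimental-arm fits

Generalized polarization and steady-state anisotropy are direct
arithmetic with domain checks: GP ∈ [−1, 1] wherever defined and
antisymmetric under channel swap; anisotropy outside the physical
range [−0.2, 0.4] is flagged rather than silently accepted.

**Sigmoid fits.** Melting curves are fitted with a Boltzmann sigmoid
between two *sloped* baselines,

$$f(T) = (a_2 + b_2 T) + \frac{(a_1 + b_1 T) - (a_2 + b_2 T)}{1 + e^{(T - T_i)/w}},$$

because both GP and anisotropy drift approximately linearly away from
the transition; the plain flat-baseline form is available via
`baseline = "flat"`, and the two coincide when the fitted baseline
slopes vanish. Initialization is multi-start — T~i~ seeded at the
maximum-|slope| temperature and at the median, w at 1/10 and 1/20 of
the range, baselines from straight-line fits to the outer thirds — and
the best converged solution is kept, which avoids the flat-baseline
local minimum. Monotone featureless series are flagged
`no_inflection` by comparison against a single sloped line, as are
fits whose inflection leaves the data range. Points above a
configurable cutoff (default 333 K) can be masked before fitting,
because hot-tail anisotropy data can become wavelength-dependent and
unreliable. Parameter CIs come from a seeded residual bootstrap.

**DSC decomposition.** Thermograms are fitted as a linear baseline
plus 1–3 Gaussian components by bounded nonlinear least squares
(amplitudes ≥ 0, means inside the scan range), again with multi-start
initialization: component means seeded at the largest local maxima of
the lightly smoothed detrended curve, at evenly spread quantiles, and
at splits of the dominant peak — narrow components riding on broad
ones are otherwise easy to miss. Auto mode selects the component count
by BIC among baseline-only and 1–3 components; a baseline-only winner,
or amplitudes indistinguishable from the point-to-point noise, flags
the thermogram as featureless. Components with negligible fitted
amplitude are dropped and the model refitted. Components are reported
sorted by mean; peak maxima equal component means. Scans are fitted
independently per direction when a `scan` column is present.
Sigmoidal DSC baselines are out of scope; the baseline is linear.

## The synthetic-data module

The generators plant structure; they do not simulate thermodynamics.
What each emulates, and what it does not:

* `make_planted_configuration()` builds hexagonal-lattice patches
  (grown ring by ring around seed cells of one randomly oriented global
  lattice, so overlapping patches merge; recentred so the patch does
  not straddle the periodic wall) inside a hard-disk random matrix with
  a 0.45 nm minimum distance, about chain–chain contact. The lattice
  constant defaults to 0.6 nm, consistent with the 0.9 nm graph cutoff
  being 1.5 chain spacings. Truth labels follow lattice topology: full
  six-neighbor shell in the patch = core, other patch cells = edge,
  matrix = free. The standard recovery fixture uses 1000 sites in a
  32 × 32 nm box. The matrix is therefore *dilute* (roughly 0.6
  sites/nm²) so that the generator's disordered mode is unambiguous; a
  real L~d~ matrix is considerably denser and locally correlated, so
  passing recovery on this fixture validates the classifier's logic,
  not its segmentation of dense fluids.
* `make_toy_trajectory()` plants lateral diffusion (independent 2D
  Brownian centers), chain tilt (stiff rods), mean |S~CD~| (a mixture
  of perpendicular and magic-angle C–H draws relative to the normal,
  giving the target exactly in expectation, including the
  |S~CD~| = 0.5 identity for perfectly ordered untilted rods), glycerol
  rotational diffusion with a prescribed correlation time, and a
  cholesterol population at a prescribed depth. It does not model
  chain conformational statistics, inter-lipid forces, or realistic
  membrane undulations.
* `make_observable_series()` plants piecewise-linear thermotropic
  series (defaults resemble an APPL curve: 0.55 nm² at the break,
  slopes 1.2·10⁻³ and 2.8·10⁻³ nm²/K), sloped-baseline sigmoids
  (GP-like baselines 0.40 and −0.05 with gentle negative slopes),
  Gaussian-mixture thermograms, stretched-exponential decays and 2D
  Brownian walks, all with iid Gaussian noise.

Every generator draws from a single explicitly seeded stream without
touching the caller's RNG state, so any fixture regenerates
bit-for-bit from its seed.

## Numerical choices and degenerate inputs

* Voronoi degeneracies: cocircular four-point configurations are
  rejected by requiring a strictly positive feasible interval on the
  bisector (tolerance 10⁻⁷ nm); fully collinear inputs fall back to
  k-nearest with a warning.
* Leaflet assignment splits phosphorus z at the midpoint of the
  largest gap in the sorted values — identical to a median split for
  balanced bilayers, robust for odd or asymmetric lipid counts — and
  flags a monolayer (all lipids one side) when the largest gap is
  below 1 nm. Cholesterol is re-assigned every frame from its hydroxyl
  z against that midplane, so flip-flop is handled. The assignment is
  invariant under rigid z-translation.
* Molecules are kept whole on reading: each lipid is shifted by its
  reference atom's periodic image rather than wrapping atoms
  individually, so chain vectors never tear across the box.
* Chains shorter than a requested carbon range fall back to their
  available carbons with a warning; zero-length chain vectors yield NA
  tilt; zero total fluorescence intensity yields NA GP.
* Breakpoint and sigmoid fits run against exact interpolating inputs:
  when the straight line already interpolates the data, the simpler
  model is preferred outright instead of dividing by a zero residual
  variance.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
data at desk scale: classification recovery uses 10 seeds of 1000
sites; breakpoint and inflection recovery use 20 seeds of 21- and
15-point series; DSC recovery uses 10 seeds of 81-point thermograms;
diffusion uses 100 walkers over 1000 steps; the rotational-dynamics
check uses 100 lipids over 200 frames. These sizes give planted-truth
recovery well inside the stated tolerances while keeping the whole
suite in the minutes range on one core.

## Known limitations

* Orthorhombic, pre-oriented planar patches only: the bilayer normal
  is the z axis, in-plane periodicity is always on, z is non-periodic.
* Trajectory I/O supports (multi-model) PDB through bio3d's reader;
  compressed MD formats (XTC/TRR/DCD) are not read in this
  implementation — convert to multi-model PDB upstream.
* The classifier's absolute class fractions at a given temperature
  depend on force field, site definition and thresholds; the package
  validates recovery of planted structure, not absolute fractions of
  any particular simulation.
* The segmented model assumes exactly one interior slope change;
  multi-break series will report the dominant one.
* No spectral processing: emission spectra must be reduced to band
  intensities upstream of the GP/anisotropy helpers.
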