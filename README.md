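# lipidorder

Analysis toolkit for the microstructure of liquid-ordered (L<sub>o</sub>)
lipid membranes across temperature.

Cholesterol-rich bilayers of saturated phosphatidylcholines (e.g.
DPPC/CHOL and DPPC/DOPC/CHOL mixtures) form the liquid-ordered phase:
gel-like chain order combined with fluid-like dynamics. Within the
L<sub>o</sub> region, such membranes can harbor transient hexagonally
packed, cholesterol-depleted clusters of saturated chains that melt on
heating, producing a subtle *crossover* — a change of slope, not a
first-order transition — in observables such as the area per
phospholipid (APPL), chain tilt, deuterium order parameters and lipid
dynamics. `lipidorder` provides the quantitative machinery to detect and
characterize this behavior, for membrane biophysicists working with
molecular-dynamics trajectories, calorimetry and fluorescence melting
curves.

## What it computes

**Packing microstructure** (from trajectories or 2D site configurations)

- Per-site hexatic order parameter on a periodic capped-Voronoi (or
  k-nearest) neighbor graph:
  S<sub>hex</sub>(j) = | (1/n<sub>j</sub>) Σ<sub>k∈N(j)</sub>
  exp(i·6·θ<sub>jk</sub>) | ∈ [0, 1], exactly 1 on a triangular lattice
  and 0 on a square lattice.
- Core/edge/free chain classification with a temporal persistence
  filter, class fractions vs temperature, cluster exchange rates, and
  per-class chain-to-cholesterol distances.

**Per-lipid observables**

- Deuterium order parameters S<sub>CD</sub> = ⟨(3 cos²θ<sub>CH</sub> −
  1)/2⟩ (explicit or reconstructed hydrogens), chain tilt, cholesterol
  depth relative to the phosphate plane.
- Glycerol orientation autocorrelation with stretched-exponential (KWW)
  fits and the analytic correlation time τ<sub>c</sub> = (τ/β)·Γ(1/β);
  lateral diffusion from time-and-ensemble averaged MSD (D = slope/4).

**Thermotropic crossover detection**

- Continuous segmented two-slope regression with profiled breakpoint
  search, bootstrap confidence intervals, a conservative variance-ratio
  flag for series with no interior crossover, thermal expansion
  coefficients α = (1/A)(dA/dT) per segment, and an inverse-variance
  consensus crossover temperature across observables.

**Experimental curve analytics**

- Generalized polarization GP = (I₄₂₀ − I₄₉₅)/(I₄₂₀ + I₄₉₅) and
  steady-state anisotropy r = (I_VV − G·I_VH)/(I_VV + 2G·I_VH).
- Sloped-baseline Boltzmann sigmoid fits with inflection temperatures,
  and DSC thermogram decomposition into 1–3 Gaussian components over a
  linear baseline with BIC model selection.

**Synthetic data with planted truth** — every input class the pipeline
consumes can be generated with known ground truth (lattice clusters in a
disordered matrix, toy bilayer trajectories with prescribed D, tilt,
|S<sub>CD</sub>| and rotational correlation time, piecewise-linear /
sigmoid / Gaussian-mixture temperature series), so every stage is
testable without running molecular dynamics.

## Worked example

Classify chains in a synthetic leaflet with half of the sites on a
jittered hexagonal lattice, then detect a planted crossover in an
APPL-like temperature series:

```r
library(lipidorder)

cfg    <- make_planted_configuration(1000, cluster_fraction = 0.5,
                                     jitter_sd = 0.02, seed = 1)
field  <- hexatic_order(build_neighbor_graph(cfg))
labels <- classify_chains(field)
class_fractions(labels)
#> # A tibble: 1 x 4
#>   frame f_core f_edge f_free
#> 1     1  0.407   0.09  0.503

s   <- make_observable_series("piecewise_linear",
                              truth = list(breakpoint = 308),
                              grid = seq(293, 333, 2),
                              noise_sd = 0.0015, seed = 1)
fit <- segmented_fit(s, seed = 1)
fit
#> <segmented_fit> breakpoint 308.61 K [307.00, 310.14],
#>   slopes 0.001288 / 0.002836, p = 6.8e-09
expansion_coefficients(fit)
#> # A tibble: 2 x 5
#>   segment t_mid area_mid   slope   alpha
#> 1 below    301.    0.542 0.00129 0.00238
#> 2 above    321.    0.586 0.00284 0.00484
```

Half the sites were planted on the lattice; the classifier reports 40.7%
core + 9% edge against the planted 50% (patch boundaries are edges), and
the other half free. The segmented fit recovers the planted 308 K break
within the bootstrap CI and reports the thermal expansion coefficient of
each regime.

`autoplot()` works on every fit object (`segmented_fit`,
`boltzmann_fit`, `dsc_fit`, `hexatic_field`, `diffusion_fit`,
`correlation_result`), and `tidy()`/`glance()` return broom-style
parameter tables.

A thin command-line wrapper over the pipeline functions
(`simulate_bundle()`, `run_packing()`, `run_thermal()`, `run_expfit()`)
is installed at `inst/scripts/lipidorder-cli.R`:

```sh
Rscript inst/scripts/lipidorder-cli.R simulate --out fixtures --seed 1
Rscript inst/scripts/lipidorder-cli.R run-thermal --out fits fixtures/appl_series.tsv
```

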