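---
title: "Modelling laser heating of cryo-TEM support grids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling laser heating of cryo-TEM support grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridheat)
```

## The problem

In correlated cryogenic light and electron microscopy (cryo-CLEM) a
vitrified sample sits on a thin support film carried by a metal mesh grid.
During fluorescence imaging the film absorbs excitation light and heats.
Vitreous ice devitrifies above roughly 136 K; once any part of a grid
square crosses that temperature the ice crystallises, destroying nearby
structure and scattering electrons in the subsequent TEM step. The
practical question is how much illumination a given grid design can take,
and which designs take the most.

`gridheat` implements a steady-state heat-transport model of one grid
square, a calibration of its single free material parameter from measured
damage thresholds, and the comparison and ranking analyses that turn the
model into grid-selection guidance.

## The model

One grid square is a film of size $L$ bounded by metal bars. The bars are
bolted, thermally speaking, to the liquid-nitrogen-cooled stage and are
treated as ideal isothermal heat sinks at $T_0 = 77$ K. The film absorbs
the incident power density $P$ (W/cm²) in proportion to an absorptivity
$A$, and conducts heat with conductance $c$. Convective cooling by the
cold nitrogen gas is negligible against conduction and is not modelled.
The thermal mass of film plus ice is tiny, so the system reaches steady
state within tens of milliseconds of any power change — damage is governed
by the instantaneous power density (dose rate), not by accumulated dose.
The transient solver (`transient_2d()`) exists to demonstrate exactly
this: fields relax to the steady solution on the time scale
$\tau (L/\pi)^2$ and stay there.

Along a line through the centre of the square the steady-state balance is

$$\frac{d^2 T}{dx^2} = -\alpha P, \qquad T(0) = T(L) = T_0,$$

where $\alpha = A/c$ (units K µm⁻² (W/cm²)⁻¹) lumps every material
property — absorptivity, conductivity, film thickness — into one
parameter. Integrating twice gives the parabolic profile

$$T(x) = T_0 + \frac{\alpha P}{2}\,x\,(L - x),
\qquad T_{\mathrm{peak}} = T_0 + \frac{\alpha P L^2}{8}.$$

Care is needed with this closed form: the profile is sometimes quoted as
$T(x) = \alpha P\,x(x-L) + T_0$, which as written dips *below* $T_0$ and
drops the factor $\tfrac12$. `steady_1d()` implements the form above,
which is what the stated ODE and boundary conditions actually integrate
to; the finite-difference oracle in the test suite confirms it to
$10^{-9}$ of the peak rise.

The model explains the observed phenomenology directly:

* damage starts at the square centre (farthest from the sinks) and spreads
  outward as $P$ rises — the half-width of the region above a threshold
  power $P_{\mathrm{thr}}$ is $(L/2)\sqrt{1 - P_{\mathrm{thr}}/P}$
  (`damage_half_width()`);
* the peak rise is linear in $P$ and quadratic in $L$, so the maximum safe
  power scales as $1/L^2$: higher meshes (smaller squares) sustain more
  light;
* for a holey film only the fraction $\eta_c$ covered by material absorbs,
  so $P_{\max} = 8(T_{\max}-T_0)/(\alpha\,\eta_c\,L^2)$ and the product
  $\eta_c P_{\max}$ is conserved across hole geometries at fixed material
  and mesh.

### One dimension versus two

The 1D model has sinks on two sides. A real grid square is sunk on all
four edges, and the 2D solver (`steady_2d()`) accounts for that: for a
uniform source on a square the peak rise is $0.0736713\,\alpha P L^2$
(the classical Poisson-problem constant) rather than $\alpha P L^2/8$ — a
factor 1.70 less heating, because the extra two edges help. This does not
matter for any calibrated prediction: $\alpha$ is fitted *through* the 1D
formula, so the geometric constant is absorbed into it, and every
comparison between grids (ratios of thresholds, the $\eta_c P_{\max}$
law) is unaffected. It does mean the fitted $\alpha$ is an effective 1D
parameter, not a material constant; the test suite checks the 2D solver
against the series solution on the square and against the 1D closed form
in the two-side-sunk strip limit ($L_y = 8 L_x$, agreement within 1%).

### Absorption of holey films

Two treatments are provided and agree within 5% for the catalogued
patterns: the closed form scales $\alpha$ by the area fraction $\eta_c$
(homogenisation), while the 2D solver can take the explicit hole mask
(`film_mask()`) times the beam intensity map as its source. The mask uses
a square hole lattice with pitch $d+s$, validated by the catalogue's
printed material fractions (2/1 → 65%, 1/4 → 97%, 1.2/1.3 → 82% after
integer rounding); a hexagonal lattice does not reproduce them and is not
offered.

One subtlety: the raster mean of the mask converges, as resolution grows,
to the coverage of the *window*, which equals $\eta_c$ exactly only when
$L$ is a multiple of the pitch (the lattice phase is centred on the
square). On the 58 µm (300-mesh) square with a 3 µm pitch the truncation
bias is about 0.012; tests assert exact convergence on the commensurate
57 µm window and the sub-0.01 agreement at 16 px/µm on the 58 µm square.

## Parameters, defaults, and why

| parameter | default | meaning |
|---|---|---|
| `T0` | 77 K | stage temperature (liquid nitrogen) |
| `Tmax` | 136 K | devitrification onset of amorphous ice |
| `alpha_eff` | calibrated | effective absorptivity/conductance, K µm⁻² (W/cm²)⁻¹ |
| `f_onset`, `f_severe` | 0.05, 0.50 | area fractions separating damage states 2/3 and 3/4 |
| `safety_factor` | 0.70 | operating power as a fraction of the threshold |
| `censor_limit` | 690 W/cm² | instrument ceiling for threshold measurements |
| `noise_cv` | 0.05 | multiplicative measurement noise in simulations |

Notes on the choices:

* **$\alpha$ is always calibrated, never taken from handbooks.** Threshold
  data identify only the ratio $A/c$ with the film thickness folded in;
  absorptivity and conductance are not separately identifiable, and the
  handbook route would also miss manufacturing differences — CFlat and
  Quantifoil are both "holey carbon" yet differ by roughly a factor two in
  threshold, so they are calibrated as separate materials.
* **Damage states.** The four-state scale is visual in origin; the package
  maps it to the fraction of the square above `Tmax`. State 2 is onset
  "barely discernible at the centre", hence a small default `f_onset` of
  5%; state 4 affects "a large fraction" of the square, hence `f_severe`
  of 50%. Both are configurable and nothing downstream depends on them.
  Because the parabola is flat at its peak, the area fraction grows
  steeply just above threshold ($\sqrt{1 - P_{\mathrm{thr}}/P}$), so
  states 2 and 3 occupy narrow power windows — consistent with damage
  appearing abruptly.
* **The 70% rule.** Operating at 70% of the threshold leaves margin for
  everything the model ignores (ice thickness, film integrity, sample
  composition, stage-to-stage variation). The reference high-power
  operating point of 186.5 W/cm² is actually ~73% of the 254 W/cm²
  gold-film threshold; the package implements the stated 70% rule and does
  not attempt to resolve the 3-point discrepancy.
* **Beam profile.** The instrument's illumination is an offset Gaussian
  known only through one constraint: a 27% intensity drop 45 µm from the
  centre. That under-determines the (σ, pedestal $b$) pair, so the default
  takes $b = 0$ and solves σ from the constraint
  (`sigma_from_drop(0.27, 45)` ≈ 56.7 µm); both are exposed. Power
  densities are W/cm² everywhere in the public interface, lengths µm.
* **Grid-square sizes.** For 200/300/400 mesh the measured square sizes
  (90/58/37 µm) are used directly. They imply slightly different bar
  widths (the 200-mesh entry is wider), so the lookup takes precedence;
  other meshes use pitch − bar width with a default 26.5 µm bar consistent
  with the 300/400 entries.

## Calibration with censored thresholds

Thresholds span more than a 40-fold range (16 to beyond 690 W/cm²), so
`fit_alpha()` works on the log scale — a multiplicative error model — and
the per-material estimate is the geometric mean of the single-measurement
inversions. Censored rows never enter the point fit: a grid that survived
the 690 W/cm² ceiling ("gt") only bounds $\alpha$ from above, and a
threshold known to lie below a value ("lt") bounds it from below. Bounds
propagate through `predict_threshold()` (an upper bound on $\alpha$ is a
lower bound on $P_{\max}$) and censored rows are checked for consistency
against the fitted $\alpha$ where one exists.

The scaling-law report uses the larger product as denominator and carries
two decimals. Under this convention the CFlat film-geometry pair differs
by 1.70% and the Quantifoil pair by 3.39%; the latter is conventionally
quoted as "~3%", and the exact value depends on whether one rounds the
area fractions to integer percentages first. The package computes at full
precision and reports the convention.

The mesh-series comparison is deliberately framed as a model-adequacy
check, not a validated prediction: measured threshold gains between
meshes (≈1.5× per step) fall ~39% short of the ideal-sink $1/L^2$ law.
The model is qualitative — real bars are not perfect sinks and the beam
is not uniform — and the report quantifies exactly how far.

## The synthetic-data generator

`simulate_threshold_dataset()` emulates the measurement campaign: a set of
designs (default: three commercial hole patterns × 300/400 mesh, six
designs per material), each yielding one observed threshold
$P_{\mathrm{obs}} = P_{\mathrm{model}}\,e^\varepsilon$ with
$\varepsilon \sim N(0, \sigma^2)$, $\sigma^2 = \log(1 + \mathrm{CV}^2)$,
censored from above at the instrument ceiling. There is no published
replicate data from which to estimate the measurement CV, so `noise_cv`
is a pure simulation knob; 5% is used as a realistic optical-power
measurement error. Draws come from counter-based substreams of the study
seed keyed to (replicate, row), so row order never changes any draw and
identical seeds give bit-identical datasets.

What the generator does *not* emulate: reflected-light or fluorescence
micrographs, per-grid systematic effects (ice-thickness variation, film
tears), operator censoring decisions, or any correlation between grids
measured in one session. Passing recovery tests therefore show that the
estimator inverts the model correctly under the stated noise, not that
real measurement error is 5% log-normal.

`recovery_experiment()` closes the loop: with 5% CV, six grids per
material and 200 replicates the median relative error of $\hat\alpha$ is
about 1.3% per material (well under the 5% design requirement), and zero
noise recovers $\alpha$ to numerical precision.

## Numerical choices

* **2D discretisation.** Cell-centred 5-point Laplacian on the pixel grid
  of `film_mask()`/`intensity_map()`; the Dirichlet boundary lies half a
  pixel beyond the outermost centres and ghost values are eliminated by
  linear reflection, keeping the scheme second order (peak error on the
  unit-square benchmark: 1.6 × 10⁻⁵ at 65 px, O(h²) under refinement).
  The SPD system is solved by sparse Cholesky (`Matrix`); the relative
  residual is checked against 10⁻¹⁰ and a violation is an error, not a
  warning.
* **Transient scheme.** Backward Euler with a factorisation reused across
  steps (unconditionally stable, monotone for a cold start under constant
  source); explicit Euler is available for cross-checks and enforces
  $dt \le \tau h^2/4$, naming the bound in its error.
* **Threshold bisection.** `max_power_density_2d()` brackets and bisects
  the peak temperature to 10⁻⁶ relative; the heat equation is linear in
  the source, so the spatial solve is done once and rescaled — the
  bisection then converges to the exact linear solution.
* **Ranking determinism.** `rank_grids()` breaks threshold ties by lower
  $\eta_c$, then smaller $L$, then `grid_id`, so output order is
  reproducible across platforms.
* **Degenerate inputs.** Zero power gives a constant field at $T_0$;
  negative power, overlapping holes, non-increasing schedule times,
  unsatisfiable beam-drop constraints and sub-32-pixel rasters are
  rejected with named errors.

Problem sizes in the shipped tests and analyses are chosen to keep
everything comfortably interactive: 2D rasters of 32–129 pixels per side,
1D profiles of a few hundred points, and 200-replicate recovery studies —
the full suite runs in well under a minute of solver time.

## Known limitations

* The model is one free parameter per material wrapped around a
  qualitative PDE: it predicts ratios and trends (mesh, geometry,
  material) far better than absolute thresholds, and the mesh-series
  deviation (~39%) is the honest measure of that.
* Bar metal is assumed irrelevant (ideal sinks). The measured copper/gold
  pair supports this, but very poorly conducting bar materials would break
  it.
* Sample-side heat transport (ice thickness, adjacent thick cellular
  material) is known to raise real thresholds and is not modelled; the
  calibrated thresholds are for thin aqueous layers and are conservative
  for thicker samples.
* No radiative transfer, temperature-dependent conductivity, latent heat
  of crystallisation, or through-thickness gradients.
* Formvar and silicon monoxide remain bound-only: their true $\alpha$ is
  below 8.4 × 10⁻⁵ K µm⁻² (W/cm²)⁻¹, and any prediction for them is a
  lower bound on the threshold.
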