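---
title: "Scaling leaf photosynthesis to tree crowns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaling leaf photosynthesis to tree crowns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crownscale)
```

## The problem

Leaf-scale net photosynthesis of C3 trees has a parabolic temperature
response with an optimum (`Topt`) typically in the 20–30 °C range. Direct
measurements of *whole-crown* CO~2~ exchange — for example in climate-controlled
whole-tree chambers — often show a much cooler optimum, or a monotonic
decline with temperature over the whole observed range. `crownscale`
implements the modelling chain needed to reproduce and dissect that
divergence: a coupled leaf gas-exchange model, three leaf-to-canopy scaling
schemes of increasing structural realism, parameterization scenarios that
add within-crown capacity gradients and seasonal thermal acclimation, the
fitting machinery used to extract temperature optima from flux series, and
a synthetic whole-tree-chamber data generator so the full analysis runs
with no external data.

The central mechanism is light limitation: below light saturation,
photosynthesis is governed by the quantum yield, which declines
monotonically with temperature (photorespiration rises), so the deeper a
crown's leaf area sits in shade, the cooler its aggregate optimum.

## Leaf gas exchange

`solve_coupled_leaf()` finds the joint fixed point of three relations:

1. **Biochemical demand** (Farquhar–von Caemmerer–Berry):
   `Anet = min(Ac, Aj) − Rl` with
   `Ac = Vcmax (Ci − Γ*)/(Ci + Kc(1 + Oi/Ko))` and
   `Aj = (J/4)(Ci − Γ*)/(Ci + 2Γ*)`. The electron transport rate `J` is the
   lower root of the non-rectangular hyperbola
   `θJ² − (αI + Jmax)J + αI·Jmax = 0` in absorbed PAR `I`. The transition
   between `Ac` and `Aj` is a hard minimum (no co-limitation smoothing).
   Below the compensation point the gross term is clamped at zero so
   `Anet = −Rl` continuously.
2. **Diffusive supply** with Medlyn optimal stomatal conductance:
   `A = (gs/1.6)(Ca − Ci)`, `gs = g0 + 1.6(1 + g1/√D)·A/Ca`. With the
   default `g0 = 0` this fixes `Ci/Ca = (g1/√D)/(1 + g1/√D)` in closed
   form whenever `A > 0`; if demand at that `Ci` is non-positive the
   stomata close and the net flux is pinned at 0 (hot limit) or `−Rl`
   (dark), keeping the response continuous. For `g0 > 0` the supply–demand
   root is bracketed numerically.
3. **Energy balance** (isothermal-net-radiation form):
   `Tleaf = Tair + (Rabs − λE)/(cp·(2gb + 2gr))`, with `Rabs` the absorbed
   shortwave load (absorbed PAR at 0.2175 J µmol⁻¹, plus 20% for the
   NIR band given the leaf's weak NIR absorptance), `gr` the radiative
   conductance linearized at `Tair` (the enclosure radiates at air
   temperature, so isothermal net longwave is zero), and `E` the
   transpiration through stomatal and boundary-layer conductances in
   series. The leaf-to-air vapour pressure deficit driving the stomata is
   recomputed at `Tleaf` each iteration (floored at 0.05 kPa against the
   `√D` singularity) and `Tleaf` updates are damped by 0.5. Convergence:
   |ΔTleaf| < 0.01 °C and |ΔCi| < 0.01 µmol mol⁻¹, at most 100 iterations.

Temperature dependence: `Vcmax` and `Jmax` follow the peaked Arrhenius
function (`peaked_arrhenius()`) with the deactivation energy fixed at
200 kJ mol⁻¹; its optimum has the closed form
`Topt = Hd/(ΔS − R ln(Ea/(Hd − Ea)))`. The kinetic constants `Γ*`, `Kc`,
`Ko` use the in-vivo Bernacchi (2001) set with simple Arrhenius scaling —
the de-facto standard behind the FvCB model; they are held in
`kinetic_constants()` so an alternative set is a one-line swap. Day
respiration follows `Rl25·Q10^((T−25)/10)`. Temperatures are °C at every
interface; Kelvin conversion is internal to the Arrhenius forms.

### Aerodynamics: cuvette vs chamber

Two boundary-layer regimes matter and they are deliberately distinct:

* **Leaf-scale protocols** (light-saturated temperature-response
  measurements) are made in stirred gas-exchange cuvettes that hold leaf
  temperature at air temperature. `temperature_sweep("leaf")` therefore
  defaults to the well-coupled limit (`gb_leaf = Inf`, so `Tleaf = Tair`),
  which is also the convention under which the leaf parameters were fitted.
* **Canopy simulations** use chamber aerodynamics: `gb = 0.135·√(u/d)` with
  default wind `u = 2.5` m s⁻¹ and leaf width `d = 0.02` m. At saturating
  light this puts sunlit leaves ≈ 1.9 °C above air temperature, inside the
  1–2 °C range observed for leaves in these chambers. Canopy energy
  balances use the *physically absorbed* PAR per unit leaf area as the
  radiation load, whatever light basis drives the biochemistry.

## Canopy schemes

**Big leaf** (`bigleaf_flux()`). Capacity is assumed proportional to light,
so canopy-integrated capacity per ground area is `Vcmax25·Λ` with
`Λ = (1 − e^{−k·LAI})/k`, and one coupled-leaf solve represents the crown.
Two conventions exist for the light level driving that equivalent leaf, and
they differ by a factor `k`: the package default (`light_basis =
"sunleaf"`) notes that capacity∝light makes the *capacity-specific*
irradiance uniform and equal to its value on a fully illuminated
top-of-canopy leaf, so the big leaf runs at `APAR = α·PAR·Λ`. This
reproduces the classic big-leaf behaviour — a canopy temperature response
that mirrors the light-saturated leaf response — which is exactly the
scheme's documented failure mode at canopy scale. The alternative
(`"absorbed"`) drives it with the Beer-absorbed total `α·PAR·(1−e^{−k·LAI})`,
i.e. a `k`-fold dimmer equivalent leaf; it is conservative and matches the
sun/shade partition as beam extinction vanishes, but its optimum sits well
below the leaf optimum, which is not how the big-leaf approximation is
meant to behave.

**Two-leaf** (`twoleaf_flux()`, `partition_sun_shade()`). Incident PAR is
split into diffuse and beam by an irradiance-keyed fraction (1.0 below
100 µmol m⁻² s⁻¹, 0.3 above 800, linear between — chamber PAR is measured
as a single stream, so no clearness index is available). The beam
extinction coefficient is `kb' = kb/cos z` for solar zenith `z` (spherical
leaf angle distribution; clipped at 85°, beam zero beyond 88°). Sunlit
leaf area is `(1 − e^{−kb'·LAI})/kb'`; absorbed beam, diffuse, and a
single-scattering term (proportional to leaf reflectance + transmittance,
routed to the shaded fraction) are integrated analytically per fraction;
capacity integrals use uniform weight (T1) or `e^{−kn·ξ}` weight (T2/T3,
`kn = 0.3`). One coupled-leaf solve per fraction on the integrated
quantities.

**Multilayer** (`build_crown_grid()`, `gridpoint_apar()`,
`multilayer_flux()`). Each cylindrical crown is divided into 6 equal
layers × 12 gridpoints (4 on an inner ring at r/3, 8 at 2r/3) = 72
sub-volumes of equal leaf area (uniform leaf area density). For every
gridpoint, the beam transmittance is `exp(−G·pathLAI)` with `G = 0.5`
along the exact ray through the own crown and any intersected neighbour
cylinders (`ray_cylinder_path()`); the sunlit leaf fraction equals that
transmittance. Sunlit leaves receive the projected beam irradiance
`G/cos z · Pb` per unit leaf area plus the local diffuse; shaded leaves
receive diffuse plus a single-scattering term `0.5·(ρ+τ)·Pb·(1−τb)`.
Diffuse attenuation uses a 3-zenith × 4-azimuth quadrature of a uniform
overcast sky with the same `G/cos` leaf projection, normalized so the
unattenuated per-leaf diffuse irradiance equals the horizontal diffuse
flux (the spherical-distribution identity). The coupled leaf model is
solved for both light classes of all 72 sub-volumes in one vectorized
pass. Coordinates: x east, y north, z up, metres; solar azimuth clockwise
from north.

Scheme consistency, not strict ordering, is the meaningful invariant:
big-leaf exceeds two-leaf at saturating light, and in the horizontally
homogeneous (slab) limit the multilayer scheme agrees with the two-leaf
integral to within a few percent. An isolated chamber crown, by contrast,
is side-lit: it legitimately intercepts *more* light per unit leaf area
than a closed canopy of the same LAI, so its multilayer flux can exceed
the slab-based schemes. With the default 9 m chamber spacing, neighbour
shading is a minor correction.

## Scenarios and acclimation

Eight scenarios (`scenario_table()`) cross the three schemes with two
parameterization switches. The within-crown gradient assigns per-layer
capacities by exponential interpolation between the sun-leaf value (layer
1) and a shade-leaf value reduced by 21% (Vcmax25) / 26% (Jmax25) at layer
6; the two-leaf analogue is the `kn` capacity weighting. Seasonal
acclimation shifts `Vcmax25` by −1.9 and `Jmax25` by −3.7 µmol m⁻² s⁻¹ per
°C that the growth temperature (preceding 30-day mean air temperature,
current day excluded) exceeds the reference `T_ref = 19.4` °C — the
experiment-mean daytime temperature, used because the temperature at which
the baseline capacities were estimated is not itself part of the parameter
table. Capacities are floored at 10% of baseline, applied equally to all
layers (acclimation capacity is taken as independent of canopy position),
with the temperature-response parameters `Ea`/`ΔS` held constant.
`run_scenario()` re-assigns capacities per calendar month (month-mean
growth temperature) by default, or daily.

## Fitting and evaluation

* `fit_quadratic_topt()`: nonlinear least squares of
  `A = Aopt − b(T − Topt)²` directly in the `(Aopt, Topt, b)`
  parameterization (Levenberg–Marquardt), so the optimum's standard error
  comes from the Jacobian; non-positive curvature or an optimum outside
  the data range raises a boundary flag.
* `fit_peaked_arrhenius()`: estimates `k25`, `Ea`, `ΔS` with `Hd` fixed at
  200 kJ mol⁻¹; an entropy estimate at its bound flags a response with no
  peak inside the data.
* `fit_aci()`: two-branch FvCB least squares at the measurement
  temperature with the package's kinetic constants; minimum-rule branch
  assignment with an optional transition-Ci override; curves with no
  RuBP-limited region fall back to a Rubisco-only fit and return Jmax as
  not estimable.
* `fit_g1()`: the Medlyn model with `g0 = 0` is linear in `g1` given the
  data, so the least-squares estimate is closed-form; single-D datasets
  are flagged low-information.
* `fit_smooth_response()`: penalized cubic regression spline (mgcv, basis
  dimension 8, smoothness by GCV), optimum from the fitted smooth on a
  0.1 °C grid with a pointwise 95% band; two responses are deemed
  different where their bands are disjoint. Replicate-chamber random
  effects are replaced by fixed-effects fits on pooled data — exact for
  the single synthetic chamber, and the population-level estimate is the
  quantity used downstream.
* `hourly_average()` (arithmetic means per clock hour, partial hours
  flagged, hours with fewer than 2 sub-intervals dropped),
  `highlight_subset()` (strictly PAR > 1200 µmol m⁻² s⁻¹), and
  `regress_model_obs()` (OLS of modelled on observed; RMSE is the paired
  root-mean-square difference modelled − observed, chosen because the
  evaluation tables pair each modelled hour with its observation).

## Synthetic chamber data

`synth_met()` builds 15-min (default) forcing: a seasonal daily-mean cycle
peaking mid-January with AR(1) day-to-day anomalies, an afternoon-peaking
diurnal sinusoid, clear-sky PAR from the site's solar geometry scaled by a
per-day sky-quality multiplier, VPD from temperature and a slowly varying
humidity state, and constant CO~2~ at 400 µmol mol⁻¹. A final constant
offset (temperature) and scale factor (VPD) calibrate the daytime means
exactly to the configured targets (21.9 °C, 1.3 kPa); the quoted VPD range
is treated as a daytime range, so only its upper bound clips the series.
`synth_trees()` grows height piecewise-linearly between noisy fortnightly
"measurements", takes crown radius from a power-law allometry (0.6 m at
3 m height, exponent 0.8, capped at the 1.625 m chamber radius) and scales
a logistic leaf-area trajectory to a period mean of 3.3 m².
`synth_observations()` adds AR(1) Gaussian noise (σ = 1.5 µmol m⁻² s⁻¹,
lag-1 correlation 0.4 — chosen to make evaluation statistics of realistic
magnitude achievable; a stand-in for the uncharacterized chamber
measurement error, not an estimate of it).

What the generator does **not** emulate: covariance structure of real
weather fronts, rainfall and soil state, the warming and drought
treatments, chamber optics and leak corrections, and the real trees'
late-season growth to leaf areas far above 3.3 m². Passing tests therefore
demonstrate that the analysis machinery recovers known structure under the
stated statistical assumptions — not that the model chain reproduces every
feature of the original chamber data set.

## Numerical choices and degenerate inputs

Solver tolerances 0.01 °C / 0.01 µmol mol⁻¹ with damping 0.5 and 100
iterations (non-convergence raises an error carrying the last state); the
vectorized multilayer solver requires `g0 = 0` and matches the scalar
solver to those tolerances. `D` floored at 0.05 kPa; beam extinction
clipped at zenith 85° and zeroed beyond 88°; LAI 0 returns zero flux;
degenerate crowns (radius or depth ≤ 0) are rejected; a 1 × 1 crown grid
is valid and reproduces the two-leaf flux in the slab limit when the
two-leaf diffuse extinction is set to the sky-quadrature effective value.
Idealized temperature sweeps default to zenith 33°, the mean solar zenith
of saturating-light hours over the simulated measurement period. Problem
sizes in the test-suite: sweeps of 71 temperature steps; scenario runs of
3–4 weeks at hourly cadence; 100–500 Monte-Carlo seeds per recovery study
— sizes at which the checked statistics are stable while the full suite
runs in well under a minute per file.

## Known limitations

* No mesophyll conductance, triose-phosphate limitation, or dynamic
  (non-steady-state) photosynthesis; no leaf clumping; cylinders only.
* NIR and thermal radiation are not transferred as separate canopy
  streams; the energy balance uses the simplified isothermal form with a
  fixed NIR load fraction.
* The kinetic-constant set and boundary-layer formulation behind the
  original study's runs are not documented there; absolute flux magnitudes
  can differ by a few percent from the original for that reason alone.
* The multilayer scheme treats each gridpoint's light classes with a
  single mean irradiance; penumbra and within-class irradiance
  distributions are not represented.
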