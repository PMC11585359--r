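# crownscale

Why do leaves and whole tree crowns disagree about the best temperature
for photosynthesis? Light-saturated leaf measurements on a eucalypt crown
put the optimum near 25 °C, yet the net CO₂ flux of the same crown,
measured in a whole-tree chamber at saturating incident light, can decline
monotonically with temperature — an optimum 6 °C or more below the leaf
scale. `crownscale` implements the modelling chain needed to reproduce and
dissect that divergence, for plant ecophysiologists and land-surface
modellers who want the mechanisms explicit and testable.

## What is inside

**Leaf scale.** The Farquhar–von Caemmerer–Berry model,
`A_net = min(A_c, A_j) − R_l`, with peaked Arrhenius temperature responses
for `Vcmax` and `Jmax`

    k(T) = k25 · exp[Ea(T−298.15)/(298.15·R·T)] ·
           (1 + exp((298.15·ΔS − Hd)/(298.15·R))) / (1 + exp((T·ΔS − Hd)/(T·R)))

coupled to the Medlyn optimal stomatal conductance model
`gs = g0 + 1.6(1 + g1/√D)·A/Ca` and an iterative leaf energy balance
(`solve_coupled_leaf()`). Baseline parameters are for field-grown
*Eucalyptus tereticornis* sun leaves (`Vcmax25 = 103.6`,
`Jmax25 = 178.2` µmol m⁻² s⁻¹, `g1 = 2.4` kPa^0.5).

**Canopy scale.** Three scaling schemes: a single big leaf (capacity
proportional to light, `Λ = (1−e^{−k·LAI})/k`), a sunlit/shaded two-leaf
partition with zenith-adjusted beam extinction, and a multilayer crown
grid (6 layers × 12 gridpoints) with exact ray-traced self- and
neighbour-shading through cylindrical crowns. Eight parameterization
scenarios (B1–M3) cross the schemes with within-crown capacity gradients
and seasonal thermal acclimation of `Vcmax25`/`Jmax25` to 30-day growth
temperature.

**Analysis.** Quadratic (`Asat = Aopt − b(T−Topt)²`) and peaked-Arrhenius
temperature-response fitting, A/Ci and `g1` estimation, penalized-spline
(GAM) optimum extraction with confidence bands, hourly averaging, the
saturating-light subset (PAR > 1200 µmol m⁻² s⁻¹), and modelled-vs-observed
regression summaries.

**Synthetic data.** A whole-tree-chamber emulator (15-min meteorology with
calibrated daytime means, allometric tree growth, AR(1) flux noise) so the
complete pipeline runs with no downloads.

## Worked example

```r
library(crownscale)

# one sunlit chamber leaf at 25 degC air, VPD 1.2 kPa, PAR 1500
solve_coupled_leaf(env_conditions(Tair = 25, VPD = 1.2, PAR = 1500))
#> Leaf state: Tleaf 26.82 degC  Anet 20.33  gs 0.238  Ci 263.1  (RuBP-limited)
```

The leaf sits 1.8 °C above air temperature, assimilates 20.3 µmol m⁻² s⁻¹
and is RuBP-regeneration (light-reaction) limited. Sweeping air
temperature at saturating light for the three model levels:

```r
Ts <- seq(10, 45, by = 0.5)
leaf <- temperature_sweep("leaf", Tair = Ts)        # cuvette protocol
b1   <- temperature_sweep("bigleaf", Tair = Ts)     # scenario B1
m1   <- temperature_sweep("multilayer", Tair = Ts)  # scenario M1
#> leaf Topt: 24.0 C   big-leaf Topt: 23.5 C   multilayer argmax: 17.0 C
```

The big-leaf canopy inherits the leaf optimum (its documented failure
mode), while the multilayer crown — where about half the leaf area is
shaded and light-limited — peaks 7 °C cooler. The full pipeline on
synthetic data (truth = scenario M3 plus AR(1) noise, σ = 1.5):

```r
res <- reproduce_analysis(seed = 1, start = "2013-12-15", end = "2014-01-10",
                          scenarios = c("B1", "T1", "M1", "M3"))
res$summary
#>   scenario intercept slope    r2 rmse topt_canopy_c topt_boundary
#> 1       B1     11.54 0.340 0.153 2.35          16.8          TRUE
#> 2       T1      8.28 0.406 0.251 1.92          16.8          TRUE
#> 3       M1     11.81 0.352 0.301 2.39          16.8          TRUE
#> 4       M3     11.00 0.301 0.306 1.56          16.8          TRUE
```

Each row regresses a scenario's modelled high-light flux on the noisy
pseudo-observations: the generating scenario M3 attains the lowest RMSE
(1.56 ≈ the noise σ), every scenario's high-light temperature response has
its maximum at the cool boundary of the simulated summer range
(`topt_boundary`), and the leaf-scale optimum for the same parameters is
`res$topt_leaf_c = 24` °C — the leaf-vs-canopy gap the package exists to
dissect.

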