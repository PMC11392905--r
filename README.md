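# aquanit

Water–nitrogen optimization for drip-fertigated factorial field trials.

`aquanit` is an R package for analysing two-factor irrigation × nitrogen
fertigation experiments of the kind used to derive water and fertilizer
recommendations in arid-region agronomy: a 3 × 3 factorial of soil-water
bands (fractions of field capacity F_C) and nitrogen rates, with replicated
plots followed over one or more seasons. It implements the full analysis
chain from plot records to a recommended (ET, N) management window, and
ships a synthetic trial generator with exported ground truth so every
estimation stage can be validated against known parameters.

## The analysis

**Crop growth.** Leaf area index is estimated from sampled leaf dimensions,
LAI = 0.6564 · NP · Σ(LL·LB)/A (sunflower conversion factor; NP plants per
plot, A plot area). Aboveground dry-matter accumulation y(t) over days
after emergence t is fitted with the logistic model

    y(t) = k / (1 + a·e^(−b·t))

whose closed forms give the rapid-growth characteristics: peak rate
V_max = k·b/4 at t_max = ln(a)/b, and the rapid-growth window
[t₁, t₂] = [ln(a/(2+√3))/b, ln(a/(2−√3))/b] with duration
Δt = ln(7+4√3)/b.

**Water and nitrogen productivity.** Seasonal water consumption comes from
the field water balance ET = P + U + I + ΔW − D − R (mm); productivity
indices are WUE = GY/(10·ET) and IWUE = GY/(10·I) in kg/m³, and nitrogen
partial factor productivity NPFP = GY/N_T in kg/kg. Treatment effects are
screened with a balanced two-way ANOVA (replication block) and Duncan's
multiple range test.

**Optimization.** Each production objective (yield, WUE, NPFP) is fitted
as a quadratic response surface in x₁ = ET and x₂ = N,

    y = y₀ + a·x₁ + b·x₂ + c·x₁x₂ + d·x₁² + e·x₂²,

maximized analytically over the design box (interior stationary point or
edge/corner logic). The multi-objective step thresholds each surface at a
fraction of its box-constrained maximum (defaults 95% for yield and WUE,
75% for NPFP), intersects the acceptability masks on a shared (ET, N)
grid, and projects the intersection onto each axis to give the recommended
ET and N intervals; seasons are combined by interval intersection.

## Worked example

```r
library(aquanit)

# closed-form growth characteristics from fitted logistic parameters
characteristic_params(k = 17398.01, a = 204.06, b = 0.078)
#> vmax 339.26 kg/ha/day at tmax 68.18 d; rapid growth 51.30-85.07 d (33.77 d)

# end-to-end run on a simulated trial (two seasons, 27 plots each)
out <- run_pipeline(run_config("demo", seed = 1, grid_n = 500))
print(out$regions[["2021"]])
#> Multi-objective acceptability region (2021)
#>   thresholds: yield >= 95% of max, wue >= 95% of max, npfp >= 75% of max
#>   ET interval: 321.1 - 349.0 mm
#>   N interval:  150.5 - 177.0 kg/ha
round(out$combined$et_interval, 1)   # 321.4 349.0  (mm, both seasons)
round(out$combined$n_interval, 1)    # 157.5 177.0  (kg/ha)
```

The run writes `indices.csv`, `summaries.csv`, `growth_fits.csv`,
`anova.csv`, `letters.csv`, `surfaces.csv`, `optima.csv`, `intervals.csv`,
region masks and a plain-text report into the output directory. The
interpretation: any (ET, N) combination inside the combined window keeps
yield and WUE within 5% of their attainable maxima while holding NPFP at
75% of its maximum — the window above brackets a mild-deficit, medium-N
management strategy.

### CSV schemas

* `plots.csv`: `plot_id, year, water_level, n_level, replicate,
  grain_yield_kg_ha, irrigation_mm, rainfall_mm, delta_storage_mm,
  [groundwater_mm, drainage_mm, runoff_mm], n_total_kg_ha`
* `dma.csv` (long): `plot_id, year, water_level, n_level, replicate,
  t_days, dma_kg_ha`
* `leaves.csv`: `plot_id, stage, plant_idx, leaf_idx, leaf_length_cm,
  leaf_width_cm`

Water/N levels use the controlled vocabulary `W1–W3` / `N1–N3`; the
optional water-balance columns default to zero, a missing
`delta_storage_mm` is an error.

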