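---
title: "Methods: water-nitrogen optimization for drip-fertigated trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: water-nitrogen optimization for drip-fertigated trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquanit)
```

## Scope and data model

`aquanit` analyses balanced two-factor fertigation trials: three
irrigation levels held as soil-water bands (55–65%, 65–75%, 75–85% of
field capacity), three nitrogen rates (120/180/240 kg/ha split 40/30/30%
across sowing, budding and flowering), three replicates, one or more
seasons. `treatment_catalog()` encodes this design and validates its
invariants (split fractions sum to one, bands ordered and below field
capacity, N rates strictly increasing). Plot records, dry-matter series
and leaf samples travel as three plain CSV schemas with a controlled
treatment vocabulary; free-text labels are rejected to prevent silent
mis-joins. Missing groundwater/drainage/runoff columns default to zero —
the trials this targets have deep groundwater and no runoff — but a
missing soil-water storage change is an error, because it shifts ET by
tens of millimetres and therefore every downstream surface.

## Growth characterization

Leaf area index follows LAI = f · NP · S̄ / A with f = 0.6564 (sunflower
leaf-shape conversion factor), NP the plot plant count, A the plot area,
and S̄ the *mean per-plant* sum of leaf length × width over the sampled
plants. The per-plant averaging is a documented interpretation: sampling
protocols measure ~5 plants per plot while NP counts all plants, so
scaling the *summed* area of all sampled plants by NP would double-count.
With this reading LAI is invariant to how leaves are partitioned among
sampled plants and scales linearly in NP and 1/A (both tested). When NP is
not recorded, `default_plant_count()` derives it from plot geometry
(3.4 m × 8 m, paired rows at 50/80 cm spacing, 45 cm in-row spacing →
5 rows × 18 plants = 90); it is a convention, overridable by a count.

Dry matter accumulation y(t) (kg/ha, t in days after emergence — supplied
by the data, never derived from calendar dates) is fitted with the
logistic model y = k/(1 + a·e^(−b·t)) by nonlinear least squares. The
rapid-growth characteristics come from closed forms: V_max = k·b/4,
t_max = ln(a)/b, t₁ = ln(a/(2+√3))/b, t₂ = ln(a/(2−√3))/b,
Δt = ln(7+4√3)/b. The t₂ denominator is 2−√3: the second derivative of
the logistic vanishes where the logistic state is at (3±√3)/6 of k, which
gives the 2±√3 pair; this also reproduces the reference trial's published
characteristic columns (Δt and V_max for all 18 treatment rows exactly at
2 decimals, and the time columns for all but a handful of entries whose
printed parameters are internally inconsistent with their own derived
values — evidently a typographic slip in the source table, which we do
not repair). t₁ < 0 is allowed (rapid growth before the first sample) and
flagged rather than errored.

### Fitting choices

Starting values: k₀ = 1.05·max(y), then (a₀, b₀) by ordinary least
squares on ln(k₀/y − 1) vs t — the exact linearization of the model at
fixed k. Optimization runs on (ln k, ln a, ln b), which enforces
positivity without constrained solvers, via Levenberg–Marquardt
(`minpack.lm::nlsLM`, `ftol = 1e-10`, 200 iterations), with up to five
seeded, jittered restarts on failure. Preconditions: ≥ 5 points, strictly
increasing times, at least one observation past the empirical inflection
(y > max(y)/2) — without it k is unidentifiable. Degenerate (constant)
series are rejected. Noise-free series are recovered to ~1e-15 relative;
the suite asserts 1e-8. Cell-level fits (`fit_growth_curves`) average
replicates at each sampling time first, matching how trial growth tables
are built; a per-plot mode exists.

## Indices and treatment screening

ET = P + U + I + ΔW − D − R. The ΔW sign convention is storage at
planting minus storage at harvest, so a drying profile *adds* to ET; this
is what makes deficit treatments' ET sit 30–130 mm above their irrigation
plus rain. WUE = GY/(10·ET), IWUE = GY/(10·I) (the factor 10 converts
mm·ha to m³), NPFP = GY/N_T. The identities WUE·10·ET = NPFP·N_T = GY are
asserted property-style on generated data.

Aggregation reports mean and sample SD per cell, per water level and per
N level; with a balanced design the marginal means equal unweighted
averages of cell means (tested). Percent contrasts are computed under an
explicit baseline convention (`relative_to_reference` or
`relative_to_other`) because published contrast sentences mix both; the
reference trial's 2021 water-level ET reductions (20.04%, 30.89%) are
only consistent under different baselines, which we surface rather than
harmonize. Recomputing its NPFP contrasts from the printed 2-dp cell
means reproduces the printed percentages to within 0.02 percentage
points — the propagation bound of the source's own rounding — and that is
the tolerance the acceptance suite uses.

The ANOVA is the balanced fixed-effects decomposition
`y ~ replicate + W + N + W:N` with all F tests against the error mean
square. The source protocol calls replication "random"; with balanced
data the W, N and W×N tests coincide under either treatment, so we keep
the fixed block and avoid mixed-model machinery. On 1000 null trials the
per-factor type-I error is checked against the central 99% binomial band
around 0.05. Duncan's multiple range test computes the critical range for
a span of p means from the studentized-range quantile at the protection
level 1 − 0.95^(p−1) (`stats::qtukey`, not printed tables). Letters mark
maximal homogeneous intervals of the descending means; because both the
extreme gap and the critical range grow with span, homogeneity is not
monotone and each start's widest homogeneous extension is found by full
scan. The letter display is verified against an exhaustive enumeration of
the step-down rule (a pair is non-significant iff some covering interval
has extreme gap below its span's critical range).

## Response surfaces and the multi-objective window

Each objective is regressed on [1, x₁, x₂, x₁x₂, x₁², x₂²] by OLS.
Default observations are the 9 treatment-cell means, matching the
structure of published summary tables and reproducing their R² regime
(noisy plot-level fits are available). The default domain box is the
observed per-year ET range × the design N range [120, 240] kg/ha: N
enters at exactly the design rates, and boundary maxima (NPFP peaks at
N = 120) are meaningless without a box. Stationary points solve the 2×2
gradient system in closed form and are classified by the Hessian
[[2d, c], [c, 2e]]; an interior maximum requires d < 0 and 4de − c² > 0,
asserted on every analysis. Box maximization is exact vertex-or-endpoint
logic on the four edge restrictions plus corners, cross-checked against
dense grids in the suite (20 random surfaces within one grid step of a
800² search).

Acceptability masks threshold each surface at a fraction of its
*box-constrained* maximum — not the unconstrained stationary value (wrong
for boundary maxima) and not a printed maximum (coarsely rounded
published coefficients can make such thresholds unreachable). Defaults
are 95%/95%/75% for yield/WUE/NPFP; the lower NPFP fraction is analysis
policy, chosen because NPFP falls monotonically in N so its 95% band
cannot overlap the yield/WUE optima — all three are configurable. The
intersection is a logical AND on a shared grid (default 1000 × 1000,
~0.1 mm × 0.12 kg/ha; endpoints reported at 1 decimal). Projections are
the min/max coordinates of surviving cells; non-contiguous projections
return the bounding interval with a gap flag. Which response blocks each
endpoint is reported, since (for instance) a 75% NPFP band and a 95% WUE
band can each own one end of the N interval. Threshold sets of concave
quadratics are ellipses, so projections and areas are verified against
closed forms (within one grid step; halving the step moves endpoints by
at most one old step). Seasons combine by per-axis interval intersection,
with an explicit empty result for disjoint years.

Re-deriving the reference trial's regions from its *printed* coefficients
reproduces the 2022 intervals to a few mm/kg·ha but widens 2021
substantially: the printed 2021 WUE coefficients (2–3 significant
figures at 1e-5 scale) imply a surface maximum of 1.84 against the
printed 1.63, flattening the 95% band. The unrounded coefficients are
unpublished, so the acceptance check for region re-derivation is overlap
per axis, while the exact checks live on the published interval
combination and the synthetic ellipse oracles.

## The synthetic generator

`generate_trial()` emulates the study conditions: 9 cells × 3 replicates
× 2 seasons (rainfall 164.4/136.3 mm), per-cell logistic curves and
per-cell ET means at the published values, per-year yield surfaces at the
published yield coefficients, noise at dma CV 0.05 (mean-corrected
lognormal), yield SD 150 kg/ha, ET SD 5 mm (Gaussian). ET is drawn
directly and the balance back-filled (I = ET − P − ΔW, ΔW ~ N(20, 5) mm)
so the water balance holds exactly — soil-moisture dynamics are out of
scope. Sowing density (34,188 plants/ha from the 65 × 45 cm geometry) and
emergence rate (0.95, a typical establishment fraction for the region's
hole-sown mulched plots) are generator inputs, not constants of the
analysis. Leaf tables are built so plot LAI equals a target trajectory
exactly (peak at flowering, treatment-scaled 1.9–3.4, consistent with the
reported ~46% W1N1-vs-W3N3 reduction); WUE and NPFP per cell follow
implicitly from yield and ET rather than being drawn, so the generator
cannot contradict the index identities. One root seed streams
per-purpose sub-seeds, making stages individually reproducible;
`generate_null_trial()` removes all treatment structure for ANOVA
calibration. What the generator does *not* emulate: weather beyond
seasonal totals, spatial field trends, measurement-correlated errors
between indices, or season × treatment interactions beyond the two
parameter sets — passing recovery tests therefore demonstrate estimator
correctness under the assumed error model, not robustness to field
artefacts.

## Problem sizes and runtime

The test suite fits ~200 logistic curves (10 seeds × 18 cells plus unit
cases), uses 800²–1000² grids for surface and region oracles, and runs
the ANOVA calibration on 1000 null trials of 27 plots (about a minute);
the full suite completes in a few minutes on one core. These sizes were
chosen to keep Monte-Carlo error well inside the asserted bands (binomial
99% band ±1.8 points at n = 1000; median-of-10 k-error well under the 5%
bound measured at ~1.6%).

## Known limitations

* The pipeline is balanced-design only; unbalanced layouts are rejected
  rather than approximated.
* Only the logistic sigmoid is offered (no Gompertz/Richards), and only
  quadratic response surfaces; both match the intended analysis, not the
  space of plausible models.
* Published-coefficient verification inherits the source's rounding;
  where that rounding is demonstrably inconsistent (one growth-table row,
  the 2021 WUE surface) the discrepancy is reported, not corrected.
* Economic and seed-quality objectives are outside the optimization
  (yield, WUE, NPFP only).
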