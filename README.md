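# mismatchr

Body sizes of some migratory shorebirds have been shrinking for decades.
One proposed mechanism is not direct thermal selection but a
**demand–resource mismatch** during early development: Arctic snowmelt
advances, the emergence peak of the chicks' key prey (adult crane flies,
*Tipulidae*) advances with it, but hatch dates do not — so chicks
increasingly grow up after the food peak, grow more slowly, and reach
smaller final sizes. `mismatchr` implements the full inference chain
needed to test that mechanism from field and satellite data, plus a
synthetic-data generator that emulates the whole study design so every
stage carries parameter-recovery tests. It is aimed at quantitative
ecologists working on phenological mismatch, developmental plasticity, and
stable-isotope diet reconstruction.

## What it computes

* **Snowmelt phenology** — per-pixel NDSI series are binarized at 0.4 and
  the daily snow-covered pixel count is modelled as Binomial with mean
  `1 − g(t)`, `g` an asymmetric Gaussian (separate spring/autumn widths)
  for the snow-free fraction, fitted by maximum likelihood. The snowmelt
  date is the 0.5 down-crossing of snow cover on the spring limb
  (closed form `μ − σ_L √(2 ln 2)` for a full-amplitude curve). Local
  surveys are interpolated to the first date below 50% cover; the
  across-year trend is OLS.
* **Chick growth and condition** — logistic `A/(1+e^{−k(t−T)})` and von
  Bertalanffy `A(1−e^{−k(t−T)})` population curves with per-chick
  growth-rate deviations `k_i = k + δ_i`, `δ_i ~ N(0, sd_k²)` (penalized
  nonlinear least squares, Laplace-profiled `sd_k`); fixed asymptotes for
  structural traits from winter juveniles; a condition index
  `(obs − pred)/pred`; age calibration from 10th-primary length; AICc
  model selection with the ΔAICc < 2 / uninformative-parameter rule and
  model averaging for condition ~ relative hatch date + temperature.
* **Prey availability and electivity** — interval pitfall totals to daily
  biomass by anchored linear interpolation, length–mass allometry
  `m = aL^b`, Ivlev electivity `(O−E)/(O+E)`, the >1% key-prey rule, and
  crane-fly peak timing relative to station-specific snow-free dates with
  a Welch t-test between years.
* **Feather-isotope diet mixing** — per-bird Bayesian mixing of δ¹⁵N with
  feather discrimination factors (3.53 ± 0.30 ‰ juvenile coverts,
  3.33 ± 0.28 ‰ chick body feathers), flat Dirichlet prior on the source
  proportions, MCMC on a logistic-normal reparameterization
  (4 × 10,000 draws, 1,000 burn-in, split-chain convergence checks), and
  AICc-compared trend models of the crane-fly fraction.
* **Path analysis** — the three-equation recursive model
  Time → Snowmelt → PropCranefly → BodySize (+ Sex) on standardized
  variables, Gibbs-sampled under near-flat priors, with per-coefficient
  direction probabilities `max(P(b>0), P(b<0))` and a simulate–refit
  reliability check.

## Worked example

Simulate a small five-year study and run the stages on it:

```r
library(mismatchr)

cfg  <- scenario_config(years = 2015:2019, n_pixels = 120, n_broods_per_year = 12,
                        n_juveniles_per_year = 20, n_stations = 20, seed = 42)
scen <- simulate_scenario(cfg)

bin <- binarize_ndsi(subset(scen$tables$ndsi, year == 2018))
fit_snow_curve(bin, year = 2018)
#> Asymmetric-Gaussian snow curve fit (2018)
#>   snowmelt day (50% crossing): 171.08
#>   mu = 183.2, sigma_l = 10.3, sigma_r = 141.4, baseline = 0.000, height = 1.000
#>   logLik = -3159.3, converged: TRUE
```

The generator's true melt day for 2018 is 170.18, so the extracted
crossing lands within a day (a stable offset of this size is expected when
the underlying melt ramp is not itself the fitted Gaussian family; see the
methods vignette). Prey phenology and diet follow the same pattern:

```r
peak <- cranefly_peak_timing(scen$tables$pitfall_daily)
#> crane-fly peak: 29.9 +/- 4.5 days after station snowmelt (40 stations)

mix <- fit_mixing_model(data.frame(bird = "juv0001", d15n = scen$tables$juveniles$d15n[1]),
                        scen$tables$sources, seed = 1)
subset(mix$summary, family == "Tipulidae")
#>      bird    family      mean        sd
#> 1 juv0001 Tipulidae 0.3187003 0.1297967
```

The per-station crane-fly peak sits about 29 days after snowmelt (the
generating lag is 29, with a 4.9-day between-station SD), and the mixing
model returns a posterior mean *and SD* for the crane-fly share of each
bird's chick-period diet — the SD matters, because one isotope cannot
sharply identify seven sources. Two closed-form quantities used throughout:

```r
ivlev_index(0.548, 0.47)            # 0.077  -> mild preference for crane flies
round(biomass_equivalents(6.56, 0.10))  # 66 midges match one crane fly's dry mass
```

`run_pipeline(scen$tables, seed = 1)` chains all stages (validation,
phenology, growth, diet, mixing, path model) and returns per-stage results
plus a manifest with checksums; `inst/scripts/mismatchr.R` wraps
simulate/validate/run for shell use.

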