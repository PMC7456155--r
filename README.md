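# woodonset

Environmental drivers of the springtime onset of wood formation
(xylogenesis) in Northern Hemisphere conifers.

Cambial activity resumes each spring, and the day of year (DOY) on which
the first enlarging xylem cell appears varies from early January in the
subtropics to midsummer near the treeline. `woodonset` implements the full
analysis chain used to quantify what triggers that onset across a
continental network of monitoring sites:

1. **Drivers** — from daily site climate it computes, for each tree-year
   record: photoperiod on the onset day (solar declination + sunrise
   hour-angle with the refraction-adjusted 90.833° zenith), mean annual
   temperature (MAT) of the onset year, accumulated *forcing units*

   `DFU(T) = 28.4 / (1 + exp(-0.185 (T - 18.4)))` for `T > 5 °C`,

   summed from Jan 1 to the day before onset, *chilling days* (days with
   daily mean in [-5, 5] °C from Nov 1 of the previous year, with [0,5],
   [-5,0], [-10,0] as alternative windows), the monthly scPDSI drought
   index of the month before onset, and precipitation sums.
2. **Mixed models** — onset DOY is modelled with crossed random
   intercepts for species *i* and site *j*:

   `D_ijk = α + β₁·X_ijk + β₂·F_ijk + β₃·C_ijk + β₄·PDSI_ijk + a_i + b_j + ε_ijk`

   with `X` either photoperiod (model 1) or MAT (model 2). Fits are
   REML via `lme4`, with marginal/conditional R² (variance-components
   formula), VIF screening of interaction terms, AIC/BIC model comparison
   (ML refits across fixed structures) and subgroup fits by biome or
   successional type.
3. **Variance partition** — per-predictor explained-variance shares, both
   *unique* (loss on deletion) and *orderings-averaged* (LMG; these sum
   exactly to the marginal R²), plus random-effect and residual shares,
   photoperiod↔MAT collinearity, and a chilling-window comparison.
4. **Synthetic data** — a generator that emulates the study design
   (79 sites over 23–67.5° N, 21 species, 826 trees, 2,030 tree-year
   records, 1998–2016) and draws onset dates from the *driver-dependent*
   model itself, solving `D = round(α + β·X(D) + a + b + ε)` per record on
   the daily grid. Latent effects are stored so every downstream stage is
   testable by parameter recovery without any external data.
5. **Pipeline/CLI** — `run_pipeline()` (or the `woodonset.R` launcher in
   `inst/cli/`) chains simulate → drivers → fits → partition → thresholds
   → report with a manifest and deterministic, replayable seeds.

## Worked example

```r
library(woodonset)

sim <- simulate_dataset(generator_config(seed = 1))
drivers <- build_driver_table(sim$onsets, sim$climates, sim$scpdsi,
                              sim$sites, species_table = sim$species)
fit <- fit_lmm(drivers, onset_model(2))
print(fit)
```

```
Crossed random-intercept LMM (REML), n = 1969
Fixed effects:
  (Intercept)      123.004 (1.267)***
  mat               -6.032 (0.059)***
  forcing            0.125 (0.000)***
  chilling           0.240 (0.007)***
  scpdsi             0.975 (0.066)***
Random-effect SDs:
  species            2.287
  site_id            6.437
  residual           5.497
R2 marginal 0.985, conditional 0.994; AIC 12645.3, BIC 12690.0
```

The generating truth here was `α = 124.6`, `β = (-5.92, 0.12, 0.23,
1.09)` with SDs `(2.42, 7.53, 5.85)` — the fit recovers the MAT slope
within 2%, chilling within 0.01 DOY/day, and the variance components
within ~10% (the small systematic offsets of the forcing and drought
coefficients are a documented property of generating data from an
implicit, driver-dependent model; see the methods vignette).

Variance partition and chilling-window comparison:

```r
partition_variance(drivers, onset_model(2))
compare_chilling_thresholds(drivers, sim$climates, onset_model(2))
regress_collinearity(drivers)   # R² of MAT on photoperiod
```

## CLI

```sh
Rscript inst/cli/woodonset.R simulate --out-dir data/ --seed 1
Rscript inst/cli/woodonset.R drivers  --data-dir data/ --out drivers.csv
Rscript inst/cli/woodonset.R fit      --drivers drivers.csv --model 2 --out fit.json
Rscript inst/cli/woodonset.R run      --out-dir results/ --seed 1
```

Exit codes: 0 success, 2 argument/data error, 3 fit error.
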