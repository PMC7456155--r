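---
title: "Modelling the onset of wood formation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the onset of wood formation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `woodonset`, the
choices we made where conventions are genuinely open, what the synthetic
generator does and does not emulate, and the numerical behaviour a user
should expect. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## The model

The response is the day of year (DOY) on which the first enlarging xylem
cell appears in a tree's microcore sections — the onset of wood
formation. For species $i$, site $j$, year $k$:

$$D_{ijk} = \alpha + \beta_1 X_{ijk} + \beta_2 F_{ijk} + \beta_3 C_{ijk}
          + \beta_4 \mathrm{PDSI}_{ijk} + a_i + b_j + \varepsilon_{ijk}$$

with crossed random intercepts $a_i \sim N(0, \sigma^2_{sp})$,
$b_j \sim N(0, \sigma^2_{site})$ and residual
$\varepsilon \sim N(0, \sigma^2)$. Model 1 uses photoperiod at onset as
$X$; model 2 uses the mean annual temperature (MAT) of the onset year.
The random effects are crossed, not nested: a species occurs at several
sites and a site hosts several species.

### Predictors, units, defaults

* **Photoperiod** (h): sunrise-to-sunset interval from the Spencer-series
  solar declination and the sunrise hour-angle equation at zenith
  90.833° (refraction-adjusted). Polar day/night clamp to 24/0 h.
* **Forcing units** (FU): daily increments
  $\mathrm{DFU}(T) = 28.4/(1+e^{-0.185 (T-18.4)})$ accumulated on days
  with $T > 5$ °C (strict: a day at exactly 5 °C contributes nothing),
  from Jan 1 of the onset year. Amplitude 28.4 FU/day, slope 0.185 /°C,
  midpoint 18.4 °C.
* **Chilling days** (d): count of days with daily mean inside
  $[-5, 5]$ °C (both bounds inclusive) from Nov 1 of the previous year.
  Alternative windows $[0,5]$, $[-5,0]$, $[-10,0]$ are kept for the
  window comparison.
* **scPDSI** (index units): the monthly value of the full calendar month
  immediately before the onset month (with year rollover), not a
  trailing 30-day window.
* **Precipitation** (mm): sums over [Jan 1, onset) and the calendar year.

Two conventions the source material leaves open, fixed here and used
consistently by both the driver builder and the generator: accumulations
run over the half-open interval $[\text{start}, \text{onset})$ — the
onset day itself describes the outcome, not the preceding conditions —
and the chilling bounds are inclusive, so the four comparison windows
partition temperature consistently.

**Gap policy.** Up to 5 missing days per required climate span are
filled: temperature by linear interpolation between neighbouring
observations, precipitation with zero (interpolating daily rain is
unphysical). Larger gaps, or gaps at the edge of the span, are data
errors that drop the affected records with a logged reason.

## Estimation

Fits use REML (`lme4::lmer`) with independent variance components for
species and site. Rank-deficient fixed designs drop the offending
columns with a warning. Singular fits (a component at zero) are flagged,
not errors. p-values use the normal approximation $z = \beta/SE$ — with
about 2,000 records the df correction is irrelevant. Marginal and
conditional $R^2$ follow the variance-components formula:
$R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_{sp} + \sigma^2_{site} +
\sigma^2)$, where $\sigma^2_f$ is the sample variance of the fixed
linear predictor; $R^2_c$ adds the random components to the numerator.
Model comparison always refits by ML when fixed structures differ (REML
likelihoods are not comparable across them); both REML and ML criteria
are carried in every fit object because the convention used for the
published information criteria is not recorded.

## Variance partitioning

Unique shares ($R^2_m$ lost when a term is removed) do not sum to
anything interpretable under collinearity, so the partition also
computes orderings-averaged (LMG) shares from refits over all $2^p$
subsets of the $\le 6$ fixed terms: each term's share is its sequential
$R^2_m$ increment averaged over all entry orders. These telescope, so
the averaged fixed shares sum *exactly* to the full model's $R^2_m$, and
together with the random and residual shares to 1 — the additive
accounting to read as "the variance partition". Reduced models keep the
full random structure. Negative unique shares (possible with collinear
terms) are clamped to zero and logged.

## The synthetic world

The generator's purpose is parameter recovery: every downstream stage
must be testable against known truth without any external data. It
emulates the reference design — 79 sites stratified over 23–67.5° N,
21 species with latitudinal niches, 826 trees, 2,030 tree-year records
over 1998–2016, record allocation skewed toward temperate/boreal sites
(subtropical sites hold only a few percent of records) — and the
published model-2 "all trees" truth: $\alpha = 124.6$,
$\beta = (-5.92, 0.12, 0.23, 1.09)$, SDs $(7.53, 2.42, 5.85)$ d. The
model-1 mode swaps in the photoperiod parameterisation
$(-160.1; 18.88, 0.05, 0.05, 0.64; 24.84, 3.75, 4.62)$.

### Climate calibration (chosen once, then frozen)

* Site MAT linear in latitude, spanning about $-2.3$ to $22.9$ °C
  (clamped to $[-3.5, 23.5]$), with 1 °C site scatter.
* Seasonal half-amplitude $A = \max(10, \mathrm{MAT} - 6.5) \pm 1$ °C:
  winter means run from about $-10$ °C (boreal) through $-2$ °C
  (temperate) to $+6.5$ °C (subtropics). This keeps chilling counts in
  the empirically observed 20–150-day envelope and — critically — keeps
  the implicit onset equation solvable (see below).
* Daily AR(1) noise (coefficient 0.7, innovations 1.5 °C) plus a
  per-site-year $N(0, 2$ °C$)$ interannual anomaly. The anomaly matters:
  without it, chilling and forcing have almost no exogenous year-to-year
  variation within a site, and the fit leans on contrasts that are
  artifacts of the generative mechanism (next section).
* Monthly scPDSI: AR(0.9) with 0.9 innovation SD, clipped to $[\pm 6]$.
* Precipitation: Bernoulli wet days (p = 0.35) with gamma amounts.
* Onset dating error: each emitted DOY is jittered by a discrete
  uniform $\pm 3$ days, emulating weekly microcore sampling.

### The implicit onset equation

The generative target is the model itself, but its predictors depend on
the onset day they generate: $D = \mathrm{round}(\alpha + \beta \cdot
X(D) + a + b + \varepsilon)$. Naively drawing $D$ and recomputing $X(D)$
breaks recovery, so the generator evaluates the right-hand side on the
whole day grid and emits the first *downward* crossing of
$\mathrm{rhs}(D) - D$ — the earliest day on which the accumulated
drivers satisfy the model, matching the phenological reading of onset.
When day 1 already sits far below the line (warm sites, where the
linear model extrapolates onset into the previous year; or model-1 mode
at high latitude, where the photoperiod term starts large and negative)
the solver retries later crossings; a record whose best candidate
misses self-consistency by more than 8 days (about one field-sampling
interval) is discarded and logged. At the default calibration 1–3% of
model-2 records are discarded; more than 20% aborts generation.

A fixed-point iteration was considered and rejected: with the published
coefficients the iteration map has regions of slope > 1 (midsummer
forcing contributes more than one onset-day per day; the model-1
photoperiod term likewise in spring), where it diverges regardless of
damping, and warm-site records run away to December. The grid solve
finds the same stable solutions without those pathologies.

### What a green recovery test does and does not establish

Because the emitted records satisfy the model *exactly* (up to rounding,
dating error and solver tolerance), regression residuals equal the
generated $a + b + \varepsilon$ — but the predictors are evaluated at
the realized onset day, so they co-move with those latent values along
each site-year's accumulation curves. This endogeneity is intrinsic to
any driver-dependent generative model, and it leaves small systematic
imprints on the fit that no amount of data removes: the forcing
coefficient recovers about 4–6% high (records within a site-year trace
the forcing curve, whose local inverse slope exceeds $\beta_F$), the
drought coefficient 10–25% low (crossings preferentially happen in
low-index months), and the site/residual SDs 7–10% low (part of $b$ and
$\varepsilon$ is absorbed by the traced predictors). MAT, intercept and
chilling recover within 1–2%. The acceptance suite asserts the
single-seed recovery at three reported SEs — which passes for MAT,
chilling, scPDSI and the intercept, and sits at the boundary for
forcing — and the 20-seed mean-within-2-Monte-Carlo-SE property, which
is left honestly red for the biased components: a 20-seed mean has a
Monte-Carlo SE far smaller than these structural offsets. A green here
would therefore mean recovery *given the implicit mechanism*, not
unbiasedness of REML in general; the red documents the mechanism, not a
defect of the estimator.

The generator also does **not** emulate: spatial correlation between
sites, storm systems or humidity, multi-year warming trends, within-tree
repeated-measures correlation (the model itself has no tree-level
effect), or real scPDSI spatial fields (a per-site AR series stands in).

## Numerical behaviour

* Optimizer: `nloptwrap` with 1e-8 absolute tolerances; one bounded
  restart from mid-scale variance components before declaring
  non-convergence.
* Determinism: a single root seed drives named substreams (sites,
  species, climate, drought index, effects), so identical configurations
  produce byte-identical CSVs and fits reproducible to 1e-8.
* Degenerate inputs: constant fixed columns are dropped with a warning;
  perfectly collinear VIFs report `Inf`; an all-constant chilling column
  in the window comparison is flagged rather than fitted.
* The latitude bins of `latitude_trend` use equal-width bins and a
  record-level Spearman correlation, robust to the skewed record
  allocation.

## Known limitations

Subgroup fits inherit whatever subgroup sizes the allocation produced —
subtropical groups are usually below the 10-rows-per-term floor and are
skipped with a warning, mirroring how sparse groups are treated in
practice. The chilling-window comparison reports unique shares only;
bootstrap intervals on shares are out of scope. The CLI is a thin
launcher over the exported functions and deliberately has no options
beyond seeds, paths and model/grouping choices.
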