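---
title: "Methods: small-area analysis of soil metals, deprivation and respiratory health"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-area analysis of soil metals, deprivation and respiratory health}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(soilhealth)
```

## The scientific question

Environmental-justice studies ask whether disadvantaged communities carry a
disproportionate share of environmental burdens. For a post-industrial city,
one such burden is the chemical quality of urban soil: decades of heavy
industry leave metals — arsenic, chromium, copper, nickel, lead, selenium,
zinc — concentrated in topsoil. This package implements the full analytical
chain for asking, at the scale of small statistical reporting zones
(intermediate geography zones, IGZs, of roughly 4,000 households), three
questions:

1. Is soil metal contamination spatially associated with socioeconomic
   deprivation?
2. Is it associated with respiratory hospital admissions once age and sex
   structure are removed?
3. Do those associations survive adjustment for deprivation and air
   pollution?

Because the underlying survey, health and deprivation datasets are not
publicly deposited, the package pairs the analysis with a synthetic
study-region generator whose statistical structure matches what such data
look like, with known generating parameters. Every stage of the pipeline is
validated by parameter recovery and calibration tests against that known
truth — which is the strongest validation available in the absence of the
original data.

## The pipeline, stage by stage

### Zone aggregation of point geochemistry

Soil samples are points with per-metal concentrations; analysis happens at
zone level. Samples are assigned to zones by containment (half-open
`[min, max)` rectangles for the synthetic grid, even-odd ray casting for
polygon zones read from GeoJSON; the half-open convention guarantees a
boundary point belongs to exactly one zone). Metal concentrations are
strongly right-skewed, so the zone-level average is the *geometric mean*
`exp(mean(log x))` of the raw concentrations, which never exceeds the
arithmetic mean and is robust to the multiplicative character of
contamination. Zones with few samples are retained and flagged via
`n_samples` rather than suppressed, so downstream users can weight or
exclude them deliberately.

Below-detection-limit values are substituted at half the detection limit by
default (`below_detection = "halve"`), with exclusion as an option; metals
for which the majority of measurements sit below detection (as cadmium
typically does in such surveys, and mercury where unmeasured) are simply not
part of the measured suite.

### The composite soil metal index

General land quality is summarised by a three-step composite over the five
metals of concern under UK contaminated-land (CLEA) guidance — As, Cr, Ni,
Pb, Se:

1. For each metal, study-wide concentrations are classed into deciles of
   their empirical cumulative distribution and scored 1 (lowest tenth) to
   10 (highest tenth).
2. The five scores are summed per sample, giving a total in 5–50.
3. Zone land quality is the arithmetic mean of sample totals.

**Numerical choice — the scoring rule.** Scoring is purely rank-based: a
value's score is `ceiling(10 * rank / n)` with tied values taking the
smallest rank of their tie group (so ties share the *lower* class — the
conservative direction). We deliberately do not classify by comparison with
interpolated percentile cut points: interpolated quantiles sit strictly
between order statistics, and for some sample sizes (e.g. n = 13) the two
rules classify the same observation differently. The rank rule is exactly
reproducible, agrees with the natural "sort, rank, bin" definition, and is
invariant under any strictly monotone study-wide transform — which is also
why the log transform applied to concentrations before fitting changes no
score; it is retained because the distribution work (and the exported audit
cut points, type-7 quantiles on the log scale) are conventionally done on
logs. Deciles are fitted on all samples pooled, urban and rural, since the
index is defined against one study-wide distribution per metal.

The index is a *relative* land-quality ranking for this study area. It is
not a guideline exceedance measure and carries no health-risk threshold
interpretation.

### Standardised incidence ratios

Respiratory admissions vary strongly with age and sex, so zone counts are
expressed as standardised incidence ratios via indirect standardisation:
with standard stratum rates `r_s` (per 100,000) and zone stratum
populations `n_zs`,

    E_z = sum_s n_zs * r_s / 1e5,    SIR_z = O_z / E_z.

SIR = 1 means parity between observed and expected. By default the standard
population is the study itself (`derive_standard_rates()`), which enforces
the identity `sum_z E_z = sum_z O_z` exactly — a property the test suite
asserts to 1e-9 relative. External reference rates are accepted through
`standard_rates()`. Zones with expected counts below `e_floor = 0.5` are
flagged unstable rather than dropped. Smoking is not modelled; as in
comparable small-area studies, deprivation serves as its proxy.

**Identifiability note.** With internal standardisation the offset absorbs
the study-mean relative risk, so the *intercept* of a generating model is
not recoverable — only differences along covariates are. The
parameter-recovery tests therefore standardise against the known baseline
rates of the generator (the external-rates path), under which every
generating coefficient, intercept included, is identifiable.

### Deprivation without the health domain

Multiple-deprivation indices (the SIMD family) combine domain rankings —
income, employment, health, education, housing, access to services, crime.
Relating such an index to a *health* outcome would be circular, because
health sits inside the index; the package therefore rebuilds the composite
from the six non-health domains. Defaults follow the published SIMD-2009
weighting renormalised after removing health (income and employment 28/86
each, education 14/86, access 9/86, crime 5/86, housing 2/86) and the
SIMD-style exponential rank transform
`X(r) = -23 * log(1 - R (1 - e^{-100/23}))` with `R = (n - r + 1)/n`, which
maps the most-deprived unit to 100 and concentrates weight in the deprived
tail so deprivation on one domain is not averaged away. Both the weights
and the transform are configuration, not constants of nature: a linear
transform is available, and under it (only) "reversing every domain
reverses the composite" holds exactly — the exponential transform is
nonlinear, so there it holds only as a strong inverse association, which is
how the tests state it.

Composite ranks go to deciles by `ceiling(10 * rank / n)` (class sizes
differ by at most one for any n), with **decile 1 = most deprived**
throughout — which is why deprivation correlations in the output tables are
negative when worse conditions accompany more deprivation. Data-zone
deciles convert to the coarser reporting zones by the median, with
half-integer medians floored — rounded toward the more deprived class, the
conservative convention for an inequality analysis.

### Association models

*Correlations.* All pairwise Pearson coefficients among zone-level
variables, on complete cases, flagged against the critical value at the 5%
level. Two conventions for the critical value are implemented:
`method = "table"` (default) is the large-sample form
`z_{alpha/2}/sqrt(n - 2)` used by the classic critical-r look-up tables and
gives 0.118 at n = 279; `method = "exact"` inverts the t test,
`t_{alpha/2,n-2}/sqrt(t^2 + n - 2)`, giving 0.1175 at the same n. The two
differ only in the third decimal at this sample size; the default matches
the tabulated convention such studies cite.

*GLMs.* Zone SIRs are modelled with a log link against one land-quality
covariate (the composite index, or one metal's geometric mean), deprivation
decile as a categorical factor with decile 1 (most deprived) as reference,
and one air pollutant. Two families are provided, because "log-link GLM of
SIRs" does not pin one down:

- `poisson_offset` (default): Poisson on observed counts with
  `log(expected)` as offset. This is the principled choice for
  count-derived SIRs — it weights zones by their information content and is
  exactly equivalent to a log-linear model of the SIR. With expected counts
  identically 1 it reduces to a plain Poisson log-linear model on counts
  (tested).
- `gaussian_log`: Gaussian with log link directly on the SIRs, the other
  common reading; fitted with a log-scale least-squares warm start for
  stability.

Soil metals are strongly inter-correlated (they rise together wherever
industry contaminated the ground), so entering several at once produces
classic multicollinearity. The model interface enforces the
one-metal-at-a-time policy: more than one soil covariate is refused with an
explanatory error. NO2 and PM10 are near-collinear across zones (r around
0.97 in the synthetic world) and are likewise never entered together; NO2
is the default air covariate with PM10 interchangeable.

Candidate models are nested — soil term only, plus deprivation, plus air —
and the minimum-AIC fit (`AIC = 2k - 2 logLik`) is selected, ties going to
the smaller model. p-values are Wald-based with no multiplicity
correction, matching the single 5% level convention of such analyses.

## The synthetic world: what it emulates, and what it does not

`generate_study()` draws, in order, with a deterministic sub-seed per
component (so adding one component never perturbs another):

- **Zones**: 279 contiguous rectangular zones of 3 one-km2 cells on a
  near-square grid; the 117 zones nearest the grid centre form the urban
  block. With urban sampling at a fixed 4 per km2 and rural cells sampled
  with probability 0.5 ("every second square kilometre"), expected sample
  totals are ~1,400 urban and ~243 rural, matching the scale of a real
  urban geochemistry survey. Every zone keeps at least one sample, since
  the analysis presumes soil data are available for all zones.
- **Metals**: multivariate log-normal on the log scale (common pairwise
  correlation 0.6, log-sd 0.7), urban locations three times rural;
  potassium independent of the rest and mildly higher in rural soil, so it
  behaves as a genuine control element downstream.
- **Air**: NO2 and PM10 share the urban shift plus correlated noise
  (noise correlation 0.95), reproducing near-collinearity at zone level.
- **Deprivation**: a latent zone deprivation factor correlated 0.45 with
  the standardised zone soil index (metal-rich zones more deprived), five
  data zones per zone scattered around it (sd 0.4 against a zone latent of
  sd 1 — enough within-zone agreement that zone medians span all ten
  deciles), seven domain scores sharing the latent at pairwise correlation
  0.6, each converted to ranks.
- **Admissions**: zone populations of about 8,800 (4,000 households at 2.2
  persons), split over four age bands and two sexes; stratum baseline
  rates of a few hundred to a few thousand per 100,000, typical of
  respiratory admissions; expected counts multiplied by
  `exp(b0 + b1*index + b_decile + b2*NO2)` and observed counts drawn
  Poisson. Defaults: `b1 = 0.01` per index point (the order of magnitude a
  zone-level land-quality effect plausibly takes on the log scale),
  `b2 = 0.01` per ug/m3, a linear decile trend of -0.06 per decile step,
  intercept -0.2. These are placeholders of this package's world, visible
  and changeable in `synth_config()`, never estimates from any survey.

Deliberately *not* emulated: spatially autocorrelated noise fields
(kriging/CAR structure), population-weighted pollution exposure modelling,
irregular zone polygons (accepted via GeoJSON but not generated), and
household microdata. A green test suite therefore establishes that the
pipeline's arithmetic, conventions and inference are correct and
calibrated under the stated world — not that any particular real-world
effect size is reproduced, which undeposited source data make impossible.

## Calibration evidence computed by the tests

The acceptance suite (not this vignette) computes: exact decile-oracle
agreement over 1,000 random concentration vectors; recovery of each
generating GLM coefficient within 95% Wald intervals in at least 90 of 100
replicates at 279 zones; type-I error of the soil-index Wald test within
3–7% over 500 null replicates; and the expected-equals-observed
standardisation identity to 1e-9. Re-run it with `devtools::test()`.

## Known limitations

- Ecological design: associations at zone level say nothing causal about
  individuals (the classic ecological fallacy), and no exposure pathway is
  modelled.
- The SIMD-style weights and exponential transform are configurable
  conventions; official index scores for real data zones are out of scope.
- SIR uncertainty intervals (Byar/exact) are not provided; unstable zones
  are only flagged.
- AIC comparison presumes genuine likelihoods; quasi-likelihood families
  are intentionally absent.
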