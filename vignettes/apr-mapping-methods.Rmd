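---
title: "Methods: desk-scale estimation of pesticide application-rate maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale estimation of pesticide application-rate maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aprmap)
```

## The estimation problem

Coarse global grids of pesticide application rates (kg of active
ingredient per hectare of cropland) exist, but they are too coarse to say
anything about exposure near a specific river, reserve or town. `aprmap`
implements a downscaling-and-calibration pipeline that turns such a coarse
first-guess rate product into 250 m maps for the EU, constrained by
country-level applied-mass statistics:

1. **Crop map fusion.** A fine (10 m) categorical crop map is corrected
   with a land-cover inventory where the crop map is known to be weak
   (rice, woody permanent crops, managed pastures), upscaled to 250 m by
   modal block aggregation, and re-labelled to the eight crop classes of
   the coarse rate product (Corn, Soybean, Wheat, Rice, VegFru, OrcGra,
   PasHay, Other — Cotton and Alfalfa cannot be separated from composite
   source classes and are excluded).
2. **Rate projection.** Each per-ingredient coarse rate grid is projected
   onto the 250 m grid by nearest-neighbour lookup of cell centres,
   country-specific authorizations and bans are applied (banned pixels get
   a zero rate, not nodata, so mass sums stay defined), and the implied
   *first-guess applied mass* per (major group, crop, country),
   $\tilde m_{mg}(crop, country)$ in kg, is accumulated as rate × cell
   area over the pixels of each ingredient's applicable crops. Crop keys
   are pooled to the three calibration classes: Corn, Wheat, and "Any
   Other Crop" (AOC).
3. **Reference data preparation.** National applied-mass records, keyed by
   chemical class, crop label and year, are averaged over a 2015–2020
   window (missing years skipped, never zero-filled), restricted to
   chemical classes present in the ingredient taxonomy, pooled to the
   calibration crop classes, aggregated to major groups (herbicides H,
   fungicides F, insecticides I), and filtered of keys below 100 kg. The
   result is the reference mass $m^{*}_{mg}(crop, country)$.
4. **Calibration.** A seven-parameter multiplicative scaling model links
   first guess and reference per major group:
   $$m_{mg} = k_C(crop)\, k_L(region)\, \tilde m_{mg}^{\alpha},$$
   with one factor per calibration crop ($k_{Corn}, k_{Wheat}, k_{AOC}$),
   one per European region ($k_{SEU}, k_{CEU}, k_{NEU}$) and a shared
   power $\alpha$. Parameters are estimated by minimizing the sum of
   squared log10 residuals over the keys present in both tables.
5. **Uncertainty propagation.** Parameter uncertainty is propagated by
   Monte Carlo: independent normal draws around the estimates, pushed
   through the scaling model, with the per-key first/second/third
   quartiles defining Low/Median/High mass scenarios.
6. **Map generation.** Because every cell of the equal-area 250 m grid
   covers exactly 6.25 ha, rescaling the first-guess rate raster by the
   correction factor $K_{mg,S} = m_{mg,S} / \tilde m_{mg}$ of the pixel's
   (group, crop, country) key reproduces each scenario mass exactly
   ("mass closure", tested to 1e-6 relative).
7. **Quality indexing.** The accuracy score
   $QI = 1 - |\hat m - m^{*}| / (\hat m + m^{*}) \in [0, 1]$ is computed
   per key from the fitted mass, spatialized on the same grid, and keys
   without reference data borrow the unweighted mean of same-region,
   same-crop direct scores. The validation ratio
   $R = m_{mg,S} / m^{*}_{mg}$ (ideally 1) summarizes scenario fidelity.

## Calibration details

**Optimizer.** The objective is minimized with bounded L-BFGS-B
(`stats::optim`) from the all-ones start — the first guess is the initial
solution — with an analytic gradient, bounds $k \in [10^{-3}, 10^{3}]$ and
$\alpha \in [0.1, 2]$, and a convergence factor targeting ~1e-10 on the
objective. Bounds and a deterministic start make runs reproducible; in
log-parameter space the model is linear, so an ordinary least-squares fit
serves as an independent cross-check in the test suite.

**Non-identifiability.** Multiplying all crop factors and dividing all
region factors by the same constant leaves the model unchanged; only the
products $k_C \cdot k_L$ and $\alpha$ are determined by data. The package
documents this gauge freedom rather than constraining it away, mirroring
the seven-parameter formulation: recovery tests compare products, and the
posterior covariance uses a pseudo-inverse (below).

**Posterior uncertainty.** With $G$ the Jacobian of the log10 predictions
at the optimum and $s^2 = J_{min}/(n - 7)$, the covariance is
$s^2 (G^{\top}G)^{-1}$. $G^{\top}G$ is rank-deficient by exactly one (the
gauge direction), so the Moore–Penrose pseudo-inverse is used, with a
warning. The reported NLL is the profiled Gaussian likelihood
$\tfrac{n}{2}(\ln(2\pi J_{min}/n) + 1)$; a perfect fit returns `-Inf` as a
documented sentinel.

**Key alignment.** Keys present in only one of the two mass tables are
skipped and counted (`n_skipped`), never imputed.

## Numerical choices

- **Modal upscaling ties** break to the smallest class code: deterministic
  and independent of pixel order. Partial edge blocks aggregate the pixels
  available rather than being dropped, so no area is lost.
- **Fusion rule order** (rice → orchards → pastures) is immaterial: the
  triggering source codes are disjoint, so no pixel can satisfy two rules;
  a test asserts idempotence of the whole correction pass.
- **Nearest-neighbour projection** requires both grids in the same
  projected CRS (no projection library is available to this package, and
  its scope excludes reprojection); fine cells may extend at most half a
  coarse cell beyond the coarse extent.
- **Quantiles** use the linear-interpolation estimator (R type 7)
  everywhere, so scenario values are reproducible across implementations.
- **Monte-Carlo draws** that are non-positive are rejected and re-drawn:
  the scaling model needs positive factors, and rejection preserves the
  shape of the sampling distribution better than clamping at zero.
- **Missing correction factors** (keys without reference data) fall back
  to the unweighted mean factor of same-region countries for the same crop
  and scenario, mirroring the quality-index fallback, with a warning.
- **Thresholds**: the reference filter keeps masses `>= 100` kg (strictly
  "smaller than" is dropped); coverage fractions above 1 — possible when
  group totals and class records are reported asynchronously — are
  disregarded, and coverage aggregates are weighted by the total mass of
  each key.
- **Rasters** are written as ESRI ASCII grids with an EPSG sidecar: a
  plain-text interchange format readable by standard GIS tooling, with
  nodata tagged in the header and preserved through round trips.

## The synthetic-data module

All stages are exercised against generated inputs with known ground truth
(`synthetic_scenario()`, `gen_crop_raster()`, `gen_coarse_apr()`,
`gen_reference_masses()`, `run_pipeline()`). Defaults mirror the
production configuration where one exists: a 10 m fine grid upscaled by a
factor of 25 to 250 m, the 2015–2020 reference window, the 100 kg filter,
1000 Monte-Carlo realizations, and the published H/F/I parameter
estimates as the generating truth. Where the production value is not a
single number, the defaults are chosen once as field-realistic: log-normal
coarse rates with mean 1 kg/ha and CV 0.5 (the order of typical
per-ingredient rates), log10 noise of 0.2 on reference masses (the
scatter a desk-scale calibration is expected to absorb), and a reference
sparsity of 0.3 (roughly the fraction of (group, crop, country) keys
missing from the continental reference dataset). The country panel is the
27-country region fixture: the region lists name 27 countries (Croatia is
not assigned; it is accepted only through an explicit override), grouped
8 SEU / 13 CEU / 6 NEU.

The generator emulates the *statistical structure* the pipeline assumes —
categorical class frequencies, planted land-cover disagreement patches
that exercise each fusion rule, a contiguous country partition, positive
log-normal rate fields on an offset coarser grid, chemical-class
disaggregation of reference masses with an out-of-taxonomy class mixed in,
and multiplicative log-normal noise. It deliberately does not emulate
satellite classification error, spatial autocorrelation of crops, crop
rotation, or realistic country shapes (countries are axis-aligned blocks:
only the induced partition matters). Passing tests therefore demonstrate
the correctness of the algorithms and their statistical behaviour under
the assumed model, not the fidelity of any continental-scale product.

Per-year reference records are replicated identically across the window
years with fixed per-class weights, so year-averaging is exact and the
zero-noise end-to-end recovery test (quality index 1 and median validation
ratio 1 on every key) has a clean oracle; year-to-year jitter would blur
that oracle without adding a tested behaviour.

## Problem sizes

Test fixtures are sized for quick iteration: 100×100 to 150×150 fine
grids upscaled by 5 (giving 250 m cells from a 50 m analogue), 4–8
countries, 150–1000 Monte-Carlo realizations, and table-level calibration
panels of 20–81 keys with 25 replicates in the recovery study. The full
suite runs in well under a minute. Miniature domains imply miniature
masses, so pipeline runs on these fixtures lower `threshold_kg`
accordingly; the 100 kg default is meant for country-scale masses.

## Known limitations

- No CRS transformation: all rasters of one run must share a projected,
  area-true CRS (EPSG:3035 in production use).
- The crop/region factor split is reported as the optimizer's solution;
  only products and $\alpha$ are physically meaningful.
- Correction factors are resolved per (group, crop, country); all
  ingredients of a major group share the same factor and quality index,
  so within-group heterogeneity beyond the first guess is not modelled.
- Parameter draws are independent normals; correlations in the posterior
  are deliberately ignored (a cautionary choice that widens, never
  narrows, the sampled space).
- The taxonomy fixture enumerates 36 chemical classes across the four
  major groups; accompanying prose sources sometimes count 37. The
  package follows the enumerated rows and documents, rather than
  resolves, the discrepancy.
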