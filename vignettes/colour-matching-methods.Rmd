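---
title: "Quantifying camouflage: the models and numerical choices behind crypsis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying camouflage: the models and numerical choices behind crypsis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crypsis)
```

## The scientific question

Background matching — fur coloured like the substrate an animal lives on —
is a classic camouflage prediction, but testing it across a clade is
confounded by shared ancestry (related species resemble each other
regardless of adaptation), by geography, and, for museum material, by
collection effects. **crypsis** implements a comparative pipeline that
quantifies specimen and habitat colouration on a common 8-bit RGB
reflectance scale, expresses phylogenetic relatedness as regression
covariates, and tests phenotype–habitat colour matching while those
nuisance factors compete in the same model.

The pipeline has five statistical layers:

1. **Colorimetry.** Photographs taken next to a reference chart are black-
   and white-balanced per channel (linear map sending the observed black
   reference to 0 and the white one to 255), a square patch is averaged,
   and total reflectance is the BT.601 luma
   $L = 0.299R + 0.587G + 0.114B$. The same $L$ is used for habitat
   rasters, so fur and habitat live on one scale.
2. **Habitat extraction.** Multi-date reflectance rasters are averaged per
   pixel (nodata skipped) and each sampling point receives the mean of all
   pixels whose centre falls within a buffer radius (1 km in the motivating
   design). Splitting the raster stack into two periods and re-extracting
   gives paired values for a repeatability estimate.
3. **Repeatability and species effects.** Repeatability is the one-way
   intraclass correlation from ANOVA mean squares,
   $\tau = (MS_B - MS_W)/(MS_B + (k-1)MS_W)$ with $k = 2$ throughout
   (re-measured patches; period-split habitat). Species differences are
   tested with sequential ANOVA, collection origin entered before species.
4. **Phylogenetic signal.** The patristic distance matrix $D$ is
   double-centred, $G = -\tfrac12 J D J$, and eigendecomposed; the
   eigenvectors are the PVR covariates. Moran's $I$ (inverse-distance,
   row-standardised weights) drives a greedy eigenvector selection, and
   signal-representation (PSR) curves plot sequential $R^2$ against
   cumulative relative eigenvalues; under Brownian motion the curve tracks
   the 1:1 line, and traits dominated by non-phylogenetic variation fall
   below it (negative mean deviation).
5. **Partial least squares regression.** Fur colours (the four responses,
   jointly or singly) are regressed on habitat colours, latitude/longitude,
   collection and field-origin indicators, and the selected eigenvector
   scores, by NIPALS PLS. Components are retained while cross-validated
   $Q^2 \ge 0.0975$; a predictor is *important* when its variance-weighted
   squared weight exceeds 5%; coefficient uncertainty comes from case
   bootstrapping. Species with more than 20 specimens additionally get
   separate within-species models.

## Why raw distances in the double-centring

For tips at depths $t_i$ with shared root-to-ancestor path length $C_{ij}$,
the patristic distance is $d_{ij} = t_i + t_j - 2C_{ij}$, and because the
centring matrix $J$ annihilates row/column constants,
$-\tfrac12 J D J = J C J$ — exactly the double-centred Brownian covariance.
The retained eigenvectors are therefore the principal axes of trait
divergence expected under Brownian motion, which is what gives the PSR
curve its 1:1 Brownian reference line. Centring *squared* distances
(classical PCoA) destroys this identity: in our Monte-Carlo checks the mean
PSR deviation of Brownian traits on 14-taxon pure-birth trees is about
−0.06 with squared distances versus −0.02 to −0.05 with raw ones.
`pvr_eigenvectors(..., squared = TRUE)` keeps the PCoA convention available
for comparison.

## A small-sample property of the PSR statistic

Even with the covariance-exact centring, the expected PSR mean deviation
under Brownian motion is slightly negative at small $n$. Writing the
sequential $R^2$ in the eigenbasis,
$R^2(k) = \sum_{i \le k} \lambda_i u_i / \sum_j \lambda_j u_j$ with
$u_i \sim \chi^2_1$, a second-order expansion gives
$E[R^2(k)] \approx p_k - \frac{2\sum\lambda^2}{(\sum\lambda)^2}(q_k - p_k)$
where $p_k$ and $q_k$ are the cumulative fractions of $\lambda$ and
$\lambda^2$; since the eigenvalues are sorted, $q_k \ge p_k$ and the bias
is negative, vanishing only for flat spectra (star phylogenies) and with
growing $n$. At $n = 14$ on pure-birth trees the 500-replicate mean of the
mean deviation is about −0.02 to −0.05 depending on the tree. Interpreting
observed PSR deviations should therefore use a simulated Brownian
reference on the *same* tree (as `simulate_bm()` makes cheap), not the
nominal zero line.

## The synthetic-data generator

`sim_config()` fixes the generative model the pipeline assumes, emulating a
museum + field study of a desert rodent radiation:

* 14 species on a pure-birth tree (birth rate 1), ~460 specimens with
  skewed per-species counts clipped to 5–120;
* habitat colour = sandy baseline (R 180, G 160, B 120) + a west–east
  longitudinal gradient (amplitude ≈ 50 units across the window) + local
  heterogeneity (sd 10), measured twice with between-period noise (sd 4,
  giving habitat repeatability ≈ 0.94);
* fur channel = baseline + 0.5 × habitat deviation − 1.0 × latitude
  deviation (brighter at low latitudes) + 8-unit field-collection
  brightness offset + a Brownian species pigmentation effect
  (rate 25 units² per unit branch length, one shared effect across
  channels) + specimen noise (sd 8), duplicated with measurement noise
  (sd 1, fur repeatability ≈ 0.996), truncated to [0, 255];
* ~20% field specimens, museum specimens spread over seven collections.

Two deliberate idealisations matter for interpreting test results. First,
the default habitat gradient runs along longitude only, so habitat is
independent of the latitude effect on fur; real substrate colour co-varies
with latitude, which inflates the sampling variability of habitat
importance under the no-effect null. Second, specimen locations are
uniform over the window for all species; real species have structured
ranges, which couples geography to phylogeny. Passing recovery tests on
this generator therefore demonstrates correctness of the machinery, not
robustness to every field confound.

```{r example}
ds <- simulate_dataset(sim_config(seed = 1))
report <- run_full(run_config(ds$tree, ds$specimens, bootstrap_B = 200,
                              seed = 2))
report
```

## Numerical and design choices

* **NIPALS.** Components are extracted by NIPALS with deflation of both
  blocks; coefficients are $\beta = W(P'W)^{-1}C'$. The inner loop is
  started at its own fixed point — the dominant left singular vector of
  $X'Y$, obtained from the $q \times q$ eigenproblem — so nearly collinear
  response blocks (fur $L$ is an exact linear combination of RGB before
  transformation) cannot stall the power iteration; the 500-iteration /
  $10^{-10}$ convergence guard remains as a hard error. With one response
  the component is closed-form. At full rank the coefficients reproduce
  multi-response OLS to $10^{-6}$, which the test suite asserts.
* **$Q^2$.** $Q^2(a) = 1 - PRESS(a)/RSS(a-1)$ from 10-fold cross-validation
  (folds stratified by species in the global models), retention threshold
  0.0975, scanning stops at the first failing component. Standardisation
  happens once, globally; folds are not re-standardised, so indicator
  columns constant within a training fold are tolerated, and a fold is
  degenerate only if its response loses all variance (one reshuffle, then
  an error).
* **Importance.** Share of predictor $j$ is
  $\sum_a w_{ja}^2 EV_a / \sum_a EV_a$ — plain squared weights when one
  component is retained, which is the typical case. The 5% cutoff is
  applied per predictor; the variance partition additionally sums shares
  within blocks (habitat, geography, origin, phylogeny) and multiplies by
  the total explained percentage, so blocks add up to the model's explained
  variance.
* **Bootstrap.** Case resampling with the component count held fixed,
  standard errors as replicate standard deviations, two-sided normal
  p-values, percentile intervals as a by-product; replicates whose
  predictor block drops below rank $A$ are redrawn (at most 10 times).
  Default 1000 replicates.
* **Eigenvector selection.** Greedy: add whichever unselected eigenvector
  most reduces residual Moran's $I$, stop once $I < 0.06$ (the threshold is
  a tuning parameter), ties broken by lower index, perfect fits stop the
  loop. The weight matrix is inverse patristic distance, row-standardised
  (`inverse-squared` and `binary-nn` are available). All-vector exhaustion
  returns the full set with a warning flag rather than an error.
* **Determinism.** Every stochastic stage (fold shuffles, bootstraps)
  derives its seed from the run seed; identical configuration and seed
  reproduce report tables byte for byte, and each table carries the
  configuration hash and seed.
* **Degenerate inputs.** Constant traits error in `psr_curve()` and
  `morans_i()` (a zero-variance trait has no autocorrelation); eigenvalues
  below $10^{-10}$ of the maximum (including all negative ones) are
  dropped with a count; eigenvector signs are fixed (first non-negligible
  entry positive) so outputs are platform-stable; balance correction clips
  to [0, 255] and reports the clip count.

## Problem sizes used in validation

The shipped tests exercise the study scale end to end: 460-specimen /
14-species syntheses for pipeline runs; 500-replicate Monte-Carlo checks
for the PSR Brownian reference and white-noise behaviour; 100 seeded
pipeline replicates (400 specimens, 200 bootstrap draws) for habitat-effect
recovery and its null; 10,000-replicate permutation and moment checks for
Moran's I and the Brownian simulator.

## Known limitations

* The geographic buffer uses a local cos-latitude metric for rasters in
  degrees; studies spanning large latitudinal ranges should supply
  projected rasters.
* Satellite-scene curation (cloud screening, reprojection, seasonal
  selection) is upstream of this package; nodata masks are honoured but
  not created.
* PSR deviations at 14 taxa carry the small-sample bias described above.
* The per-species models drop the phylogenetic block by construction and
  inherit whatever collection structure survives within a species; with
  very few specimens per collection their bootstrap intervals are wide.
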