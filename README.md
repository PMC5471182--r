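# crypsis

Comparative analysis of camouflage as **background colour matching**: do
species' fur colours track the colours of the substrates they live on, once
shared ancestry, geography and collection artefacts are accounted for?

The package is aimed at evolutionary ecologists working with museum +
field specimen series (photographed next to a reference chart) and
remote-sensed habitat reflectance. It provides the full analysis chain as
composable functions plus a one-call pipeline, and a synthetic-data
generator with the same statistical structure so every stage can be
validated without the original material.

## The statistical core

* **Colorimetry** — per-channel black/white balance correction, square
  patch means, and total reflectance `L = 0.299 R + 0.587 G + 0.114 B`
  (ITU-R BT.601), shared between fur and habitat so both live on one
  0–255 scale.
* **Habitat extraction** — per-pixel temporal means of raster stacks and
  point-buffer averages (pixel centre within radius r), with a two-period
  split feeding repeatability.
* **Repeatability & species effects** — one-way intraclass correlation
  τ = (MS_B − MS_W)/(MS_B + (k−1) MS_W); sequential ANOVA with origin
  covariates entered before species.
* **Phylogenetic signal (PVR/PSR)** — eigenvectors of the double-centred
  patristic distance matrix G = −½ J D J (equal to the centred Brownian
  covariance), greedy Moran's-I eigenvector selection (stop at I < 0.06),
  and phylogenetic signal-representation curves: sequential R² against
  cumulative relative eigenvalues, with the 1:1 line as the
  Brownian-motion reference.
* **PLSR** — NIPALS partial least squares (multi- and single-response),
  β = W(PᵀW)⁻¹Cᵀ, component retention by cross-validated Q² ≥ 0.0975,
  per-predictor importance by variance-weighted squared weights (> 5%
  rule), and case-bootstrap coefficient inference; separate models for
  species with more than 20 specimens.

## Worked example

```r
library(crypsis)

ds     <- simulate_dataset(sim_config(seed = 1))     # 460 specimens, 14 species
report <- run_full(run_config(ds$tree, ds$specimens,
                              bootstrap_B = 200, seed = 2))
report
```

```
Colour-matching analysis report
  specimens: 460  species: 14  seed: 2  config: 70846d1a 
  repeatability: fur tau >= 0.995, habitat tau >= 0.939
  PSR mean deviation: red -0.053, green -0.184, blue -0.144, L -0.112
  global PLSR: 2 component(s), 51.7% explained, r(T1,U1) = 0.73
  variance partition: geography 18.8%, habitat 28.3%, origin 4.6% 
  per-species models: 6 
```

Reading the output: duplicated fur measurements and period-split habitat
extractions are highly repeatable (τ ≥ 0.99 / ≥ 0.94); PSR mean deviations
are negative for all four colour traits, i.e. closely related species are
less similar than Brownian motion predicts — expected here, because the
generator makes fur track habitat; the global multi-response PLSR keeps
two cross-validated components explaining 51.7% of fur-colour variance,
and the variance partition attributes most of that to the habitat block
(28.3%), with geography and collection origin behind it — matching how the
data were generated (habitat effect 0.5, latitude gradient, field offset).
`report$weights`, `report$per_species_summary`, `report$correlations` and
`report$partition` hold the full tables; `write_report(report, dir)` writes
them as CSV plus JSON metadata carrying the seed and configuration hash.

A command-line wrapper with `run`, `simulate`, `psr` and `plsr` subcommands
lives in `inst/scripts/crypsis.R`:

```sh
Rscript inst/scripts/crypsis.R simulate --seed 5 --out data/
Rscript inst/scripts/crypsis.R run --config config.yaml --verbose
```

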