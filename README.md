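# plastisize

Allometric scaling of ingestible plastic size, hold-out validation, and
gridded ingestion-risk mapping for zooplankton.

## The problem

Gut-content surveys show that animals across the size spectrum ingest
plastic, but not every animal can ingest every particle. For risk
assessment the missing link is *ingestibility*: the largest plastic
fragment an animal of a given size can swallow. Meta-analyses of gut-content
records (one record per taxon: mean body length paired with the longest
plastic found in any surveyed specimen) support a power-law — allometric —
relationship,

```
log10(plastic_max, mm) = β1 · log10(body, mm) + β0 + ε,   ε ~ N(0, σ²)
```

whose canonical published coefficients are β1 = 0.9341, β0 = −1.1200
(n = 65 taxa, 9.00 mm to 10,340 mm, R² = 0.42): a body-to-plastic size
ratio of roughly 20:1. This package is for quantitative ecologists who want
to fit, validate and apply that relationship:

* **allometry** — closed-form log10–log10 OLS (`fit_loglog()`), the fixed
  published coefficients (`published_fit()`), point predictions with
  t-based confidence/prediction intervals (`predict_plastic()`), and the
  size ratio (`body_plastic_ratio()`);
* **validation** — repeated random 90/10 hold-out resampling
  (`monte_carlo_validate()`): pooled log10 RMSE, interval coverage, and an
  observed-vs-predicted regression;
* **risk mapping** — linearisation of exponential class rasters by
  `y = 10^((E/C)·x)` (`linearise_classes()`), conservative ingestible
  size-class selection (`select_ingestible_class()`), and the cellwise
  ingestible-plastic / zooplankton-density risk index (`risk_index()`);
* **synthetic data** — `generate_taxa()` draws taxon tables with noise
  calibrated to a target R² (`calibrate_noise_sd()`), so the entire
  pipeline is testable without field data;
* **CLI** — `run_command()` / `exec/plastisize` with subcommands
  `simulate`, `fit`, `predict`, `validate`, `riskmap`.

## Worked example

```r
library(plastisize)

# Largest zooplankter on record: 13.5 mm. What can it ingest?
predict_plastic(published_fit(), 13.5)
#>   body_length_mm  point_mm lower_mm upper_mm level interval_kind
#> 1           13.5 0.8626702       NA       NA    NA          none

select_ingestible_class(published_fit(), 13.5)
#> Ingestible size class 1: 0.33-1.00 mm (predicted 0.86 mm, buffer 0.14 mm)
```

A 13.5 mm animal can ingest plastics up to 0.86 mm, so the 0.33–1.00 mm
class of the global plastic distribution model is the ingestible fraction,
with 0.14 mm of deliberately conservative slack to the class bound. At the
geometric middle of the observed body range the size ratio is ~20:1:

```r
round(body_plastic_ratio(published_fit(), 305.1), 1)
#> [1] 19.2
```

Synthetic data through fit and validation:

```r
taxa <- generate_taxa(generator_config(seed = 1))   # 65 taxa, R² = 0.42 world
fit_loglog(taxa)
#> Allometric log10-log10 fit (max_plastic)
#>   plastic_mm = 10^(1.2453 * log10(body_mm) -1.8822)
#>   n = 65, R2 = 0.600, F(1,63) = 94.41, p = 3.8e-14

monte_carlo_validate(taxa, reps = 1000, interval = "prediction", seed = 1)
#> Monte-Carlo hold-out validation
#>   1000 reps x 6 held out = 6000 pairs; prediction intervals at 95%
#>   RMSE (log10 mm) = 0.856; coverage = 95.93%
#>   observed ~ predicted: R2 = 0.568, F(1,5998) = 7872.54, p = 0

monte_carlo_validate(taxa, reps = 1000, interval = "confidence", seed = 1)
#> Monte-Carlo hold-out validation
#>   1000 reps x 6 held out = 6000 pairs; confidence intervals at 95%
#>   RMSE (log10 mm) = 0.856; coverage = 29.15%
#>   observed ~ predicted: R2 = 0.568, F(1,5998) = 7872.54, p = 0
```

Prediction intervals cover held-out observations at the nominal 95%;
confidence intervals of the mean cover ~29% — they answer a different
question, and the contrast reproduces the "roughly a third within 95% CIs"
phenomenon reported for the real data. A single 65-record fit scatters
around the generating slope (here 1.25 vs 0.9341 at R² ≈ 0.42 noise); the
acceptance suite shows the estimator is centred by averaging 1,000 such
fits.

From the command line:

```sh
exec/plastisize simulate --seed 1 --out out/
exec/plastisize fit      --input out/taxa.csv --out out/
exec/plastisize predict  --paper-fit --body-mm 13.5 --out out/
exec/plastisize validate --input out/taxa.csv --reps 1000 \
                         --interval prediction --seed 1 --out out/
exec/plastisize riskmap  --fit out/fit.txt --body-mm 13.5 --seed 1 --out out/
```

Each command logs (stderr) the package version, seed and input digests, and
writes its tables plus a machine-readable `summary.json` under `--out`.

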