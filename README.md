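# specFusion

Multivariate calibration of pesticide residues from paired NIR and SERS
spectra, for analytical chemists and chemometricians who need to quantify
trace analytes (here: an equimolar chlorpyrifos + pymetrozine mixture,
10⁻⁶–10⁻³ mol/L) from two complementary spectral modalities.

The package implements the full workflow:

* **Preprocessing** — AirPLS baseline correction, multiplicative scatter
  correction (MSC), standard normal variate (SNV), Savitzky–Golay
  smoothing, min–max scaling, composed into leakage-free pipelines fitted
  on calibration data only.
* **Calibration** — NIPALS PLS1 on mean-centered data with k-fold RMSECV
  for choosing the number of latent variables L, and the evaluation
  metrics RMSE, R² = 1 − SSres/SStot, and RPD = sd(y)/RMSEP.
* **Wavelength selection (HSIC-VSIO)** — an iterative selector that blends
  a kernel-dependence importance with a sampling frequency. The empirical
  Hilbert–Schmidt Independence Criterion,

      HSIC(x, y) = (n − 1)⁻² tr(K H L H),    H = I − n⁻¹ 1 1ᵀ,

  measures dependence between the response and model residuals; channel
  importance is WIₘ = HSIC(y, ε₋ₘ)/HSIC(y, ε_full), the change in
  residual–response dependence when channel m is removed. Weighted binary
  matrix sampling (WBMS) draws M candidate channel subsets (column i of the
  M×p binary matrix carries round(M·wᵢ) ones), each scored by 5-fold
  RMSECV; Q records each channel's frequency among the top-σ models, and
  weights iterate as W = 0.5·T′ + 0.5·Q until the best RMSECV stops
  improving. The K largest-weight channels are selected.
* **Fusion** — direct (full-spectrum concatenation) and feature-level
  (concatenation of the per-modality selected channels), with a four-way
  comparison against the single-modality models.
* **Synthetic data** — a dual-modality generator with planted ground truth
  (sharp Langmuir-response SERS lines with substrate variability; broad
  overlapping NIR bands with scatter and matrix interference), so every
  stage is testable without proprietary instrument data.

Data live in a `SpectrumSet` (an S4 class extending `SummarizedExperiment`:
channels × samples, axis in `rowData`, concentrations in `colData`), and the
calibration response is log10 concentration by default.

## Worked example

Simulate the paired benchmark (6 concentration levels × 10 replicates,
36/24 calibration/prediction split per modality), run wavelength selection
and the four-way comparison:

```r
library(specFusion)

res <- runBenchmark(seed = 11,
                    cfg = vsioConfig(M = 200, sigma = 0.1, K = 20,
                                     nLV = 10, seed = 11))
res$comparison$table
#>                            Method LVs RMSE1   Rc2 RMSE2   Rp2  RPD
#> 1                             NIR   6 0.126 0.985 0.280 0.925 3.73
#> 2                            SERS   4 0.125 0.985 0.168 0.973 6.22
#> 3        NIR+SERS (direct fusion)   3 0.175 0.971 0.198 0.963 5.30
#> 4 NIR+SERS (feature-level fusion)   5 0.136 0.982 0.195 0.964 5.36
res$recovery
#> [1] 0.875
```

Reading the output: `RMSE1`/`Rc2` describe the calibration fit and
`RMSE2`/`Rp2`/`RPD` the prediction set, all in log10-concentration units —
e.g. the SERS model predicts held-out samples to 0.168 decades with
R² = 0.973 and an RPD of 6.2 (RPD > 3 is usually read as reliable
quantitation). `recovery = 0.875` says the selector placed 7 of the 8
planted informative SERS channels in its selected top-20.

Individual pieces are exported too:

```r
d <- defaultDesign("sers", nChannels = 200)
sim <- simulateSpectra(d, seed = 7)
split <- stratifiedSplit(sim$set, nCalPerLevel = 6, seed = 7)
cal <- calibrationSet(split)

sel <- runHsicVsio(intensities(cal), responseVector(cal),
                   vsioConfig(M = 200, sigma = 0.1, K = 20, seed = 7))
selectedChannels(sel)                 # sorted channel indices
detectPeaks(selectSamples(sim$set, 1), baselineCorrect = TRUE)
```

A thin command-line front end ships in `inst/scripts/specfusion`
(subcommands `simulate`, `preprocess`, `select`, `train`, `evaluate`,
`compare`, `sweep`, `peaks`); every subcommand takes `--seed` and
reproduces its outputs byte-identically.

The methods vignette (`vignettes/specFusion-methods.Rmd`) documents the
models, the selector's numerical choices, the synthetic designs and their
rationale, and known limitations — including the observation that on the
synthetic benchmark the two fusion modes perform within ~2% RPD of each
other, with direct fusion typically a hair ahead.

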