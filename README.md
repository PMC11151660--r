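# paox — wavelength-flexible data-driven photoacoustic oximetry

`paox` estimates blood oxygen saturation (sO₂) from per-pixel multispectral
photoacoustic amplitude spectra on a fixed 41-channel lattice (700–900 nm in
5 nm steps). It is aimed at researchers in quantitative photoacoustic
imaging who need (a) an sO₂ regressor that keeps working when the available
wavelengths change between systems or scans, and (b) a principled way to
choose *which* simulated training distribution to use for a given target
dataset.

Three ideas are implemented:

1. **A wavelength-masked LSTM regressor.** Each spectrum is a 41-step
   sequence of scalar amplitudes with a presence mask; masked steps leave
   the recurrent state untouched, so any wavelength subset can be used at
   training or inference. The per-step hidden vectors (hidden size 100) are
   flattened into a 4100-long encoding feeding a fully connected head
   (hidden width 1000, leaky ReLU, sigmoid output so estimates stay in
   [0, 1]). Training minimizes mean absolute error with Adam (lr 10⁻³,
   halved after a 5-epoch validation plateau). Baselines with the same
   interface: non-negative linear unmixing (LU) of the HbO₂/Hb bases, and a
   fixed-wavelength feedforward regressor (learned spectral decoloring,
   LSD).

2. **A layered-tissue spectrum simulator.** A fast analytic surrogate for
   Monte Carlo tissue simulation generates labeled, spectrally colored
   vessel spectra: fluence
   `Φ(λ,z) = G(z)·exp(−μ_a,water d_w − μ_eff,skin d_s − μ_eff,bg z)` with
   `μ_eff = √(3 μ_a (μ_a + μ_s'))`, times the vessel blood absorption and a
   radius-dependent self-shading factor, plus multiplicative noise. Sixteen
   built-in tissue variants (background oxygenation ranges, water-only
   background, melanin skin layer, halved vessels, voxel sizes, diverging
   illumination, water coupling layers) mirror a standard study design in
   which each variant changes exactly one assumption.

3. **A dataset distance that predicts accuracy.** For two datasets, the
   per-wavelength distributions of z-scored amplitudes are histogrammed
   (100 bins on ±3σ) and compared with the Jensen–Shannon distance
   (√ of the divergence, natural log, bounded by √ln 2 ≈ 0.8326); the mean
   over the shared wavelengths, `D̄_JS`, ranks candidate training sets for a
   target dataset, and correlates with the realized estimation error.

## Worked example

```r
library(paox)

v <- builtin_variants()

# training data: generate -> select -> z-score -> resample
train_ds <- generate_dataset(v$BASE, n_spectra = 8000, seed = 1)
train_ds <- select_spectra(train_ds)$dataset
train_ds <- zscore_dataset(train_ds)

model <- train(build_lstm(lstm_hyperparams(epochs = 10, seed = 1)), train_ds)

# held-out data from the same tissue family
raw_test <- select_spectra(
  generate_dataset(v$BASE, n_spectra = 3000, seed = 99))$dataset
test_ds <- zscore_dataset(raw_test)
est <- predict(model, test_ds)
median_abs_error(est, test_ds$so2)
#> [1] 5.28741
median_abs_error(predict(build_lu(), raw_test), raw_test$so2)
#> [1] 6.515238

# which training set fits a water-coupled target best?
target <- zscore_dataset(generate_dataset(v$WATER_4cm, n_spectra = 2000, seed = 7))
cands <- lapply(v[c("BASE", "SKIN", "WATER_4cm")], generate_dataset,
                n_spectra = 2000, seed = 11)
rank_training_sets(target, cands, n_subsample = 2000, repeats = 3, seed = 5)
#>   candidate    djs_bar rank
#> 1 WATER_4cm 0.08501967    1
#> 2      BASE 0.34416537    2
#> 3      SKIN 0.43283748    3
```

The ~5.3 pp median absolute error above is a quick 10-epoch run; the
reference configuration (`baseline_holdout_error()`, 50,000 spectra, 30
epochs) reaches the low single digits, and already beats the 6.5 pp of
linear unmixing on the same spectra at a fraction of the training budget.
The ranking table reads: the 4 cm-water-layer variant is, as it should be,
the closest training distribution to a water-coupled target (smallest
`D̄_JS`), with the baseline and skin variants clearly farther away.

A thin command-line front end wraps the same functions
(`generate`, `preprocess`, `train`, `predict`, `jsd`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli/paox", package = "paox"))')
Rscript "$CLI" generate --variant BASE --n 2000 --seed 1 --out base.csv
Rscript "$CLI" preprocess --in base.csv --out clean.csv --n-resample 2000 --seed 2
```

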