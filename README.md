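# aifcorr

Saturation correction of arterial input functions (AIFs) for quantitative
myocardial perfusion MRI, by simulation and a bidirectional LSTM.

## The problem

Myocardial blood flow is quantified by fitting a tracer-kinetic model to
gadolinium concentration curves, driven by the AIF measured in the
left-ventricular blood pool. At first-pass concentrations (several mM) the
saturation-recovery MRI signal compresses strongly, and converting measured
signal back to concentration with a Bloch-simulated dictionary is biased by
whatever the dictionary does not model: flip-angle deviation (B1),
concentration-driven T2\* decay, and residual magnetization after an
imperfect saturation pulse. The distorted AIF propagates directly into the
fitted transfer constant ktrans, which is proportional to blood flow.

`aifcorr` builds the whole loop in one package:

* **Curve populations** — a 12-parameter AIF model (sum of three unit-peak
  gamma variates and a sigmoidal washout,
  `sample_aif_params()`/`evaluate_aif()`), and the four-parameter extended
  compartment model
  `C_tiss(t) = C_AIF(t−Δt) ⊗ ktrans e^(−kep t) + vp C_AIF(t−Δt)`
  (`tissue_curve()`, `ladder_pk_set()`).
* **Signal model** — a Bloch recursion for the saturation-recovery
  stack-of-stars centre partition (`simulate_signal()`), tabulated
  dictionaries (`build_dictionary()`), controlled acquisition deviations
  (`sample_bias()`), and signal-domain noise (`add_noise()`).
* **Datasets** — seeded, reproducible corrupted train/val/test collections
  (`make_dataset()`), plus synthetic pixel-curve clustering for
  distribution-shift tests (`simulate_pixel_curves()`,
  `cluster_tissue_curves()`).
* **The corrector** — a 4-layer Bi-LSTM (32 hidden units per direction)
  mapping the saturated AIF, optionally stacked with tissue curves, to the
  true AIF (`aif_lstm()`, `predict()`, `correct_aif()`), with three loss
  functions: curve L1, curve + compartment-parameter L1, and curve +
  model-based tissue L1. The recurrent core (BPTT, Adam) is implemented in
  compiled single-precision code; training is bit-reproducible given a seed.
* **Quantification** — Levenberg–Marquardt compartment fits (`fit_pk()`),
  percent-error metrics and agreement statistics
  (`evaluate_dataset()`: peak and ktrans errors, Pearson/linear fit,
  Bland–Altman limits).

## Worked example

```r
library(aifcorr)

# corrupted dataset: 10 ladder tissue curves per record, symmetric ±10%
# deviations, 5%-of-tissue-peak signal noise, T1-dictionary inversion
ds <- make_dataset(dataset_spec(n_train = 2000, n_val = 500, n_test = 1000,
                                n_tissue = 10, seed = 1000001))

# how biased is the dictionary conversion before any correction?
evaluate_dataset(lapply(ds$test, `[[`, "saturated_aif"),
                 lapply(ds$test, `[[`, "true_aif"))
#> <aif_eval> 1000 records
#>   AIF peak error : -12.30 +/- 15.57 %
#>   estimate vs target: r = 0.763, y = 0.719 x + 0.873
#>   Bland-Altman  : bias -0.8217, LoA [-3.11, 1.467]

# train the corrector (4-layer Bi-LSTM, curve L1 loss; ~3 min on one CPU)
fit <- aif_lstm(ds, n_tissue = 10, epochs = 30, seed = 1)
print(fit)
#> <aif_lstm> 4-layer Bi-LSTM (32 hidden/dir), 11 input channels, 'aif' loss
#>   85825 parameters; best epoch 30/30 (val L1 0.05193)

evaluate_model(fit, ds$test, fit_ktrans = FALSE)
#> <aif_eval> 1000 records
#>   AIF peak error :   1.12 +/-  5.62 %
#>   estimate vs target: r = 0.984, y = 0.927 x + 0.467
#>   Bland-Altman  : bias 0.0273, LoA [-0.594, 0.6486]
```

The dictionary conversion underestimates the AIF peak by ~12% on average
with a wide spread; the trained corrector brings the mean peak error to
about one percent with a three-fold tighter spread (training longer
tightens both further), and the improvement carries through to ktrans
fitted from the corrected AIFs (`evaluate_model(..., fit_ktrans = TRUE)`).

`run_experiment()` wires the pieces into the three packaged studies
(`"tissue_count_sweep"`, `"loss_comparison"`, `"hybrid"`), and
`inst/cli/aifcorr.R` exposes simulate / build-dict / train / correct /
evaluate / experiment subcommands for shell use. The methods vignette
(`vignettes/aif-correction-methods.Rmd`) documents the models, conventions
and their rationale.

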