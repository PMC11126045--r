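---
title: "Correcting saturated arterial input functions with a Bi-LSTM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting saturated arterial input functions with a Bi-LSTM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aifcorr)
```

## The problem

Quantitative myocardial perfusion MRI estimates myocardial blood flow by
fitting a tracer-kinetic model to gadolinium concentration curves. The model
is driven by the arterial input function (AIF) — the concentration--time
curve in the left-ventricular blood pool. At the concentrations reached
during the first pass (several mM), the saturation-recovery signal is a
strongly compressive, nonlinear function of concentration, and converting
the measured signal back to concentration with a tabulated signal model (a
"dictionary") is sensitive to everything the dictionary does not know about
the acquisition: flip-angle deviation from B1 inhomogeneity, concentration-
driven T2* decay, and residual longitudinal magnetization after an imperfect
saturation pulse. The result is a systematically distorted — mostly
underestimated — AIF peak, which propagates directly into the fitted
transfer constant `ktrans` (proportional to blood flow).

`aifcorr` implements a simulation-to-correction pipeline: generate realistic
AIF and tissue curve populations, corrupt them through a Bloch-recursion
signal model with controlled deviations, train a bidirectional LSTM to
recover the true AIF from the corrupted AIF (optionally stacked with tissue
curves), and quantify recovery through AIF peak errors and compartment-model
`ktrans` errors.

## Curve populations

**AIF model.** `evaluate_aif()` is a sum of three gamma variates (first pass
and two recirculation terms) and one sigmoidal washout term, with 12 free
parameters drawn uniformly from fixed population intervals
(`aif_param_ranges()`). The gamma variate is parameterized with unit peak,
\[
G(t;\lambda,\tau,\Delta) =
\left(\tfrac{t-\Delta}{\lambda\tau}\right)^{\lambda}
e^{\lambda-(t-\Delta)/\tau},
\]
so the amplitude constants $A_k$ set peak concentrations directly in mM
($A_1\in[3,9]$ mM matches realistic first-pass blood-pool peaks). The
washout is a regularized lower-incomplete-gamma rise times
$e^{-(t-\Delta)/T}$ — the standard family in blind AIF estimation, since the
exact functional forms are a modelling choice rather than something the
curve population pins down. The third width parameter is tied to $\tau_2$,
leaving exactly 12 free parameters. All kinetic quantities are in minutes;
the canonical grid (`time_grid()`) is 120 points spaced 0.5 s.

**Tissue model.** `tissue_curve()` implements the four-parameter extended
compartment model
\[
C_{tiss}(t) = C_{AIF}(t-\Delta t)\otimes k^{trans}e^{-k_{ep}t}
 + v_p\,C_{AIF}(t-\Delta t),
\]
with a trapezoid-rule causal convolution on the native grid and the arrival
delay applied by linear interpolation (delays of a few seconds are not
multiples of the 0.5 s step). At this step size the quadrature error against
the analytic rectangle-input solution is far below 1%; the only subtlety is
that a sampled step function is read by the trapezoid rule as ending half a
sample past its last nonzero point, which the tests account for explicitly.

Two tissue parameter samplers exist because they serve different roles:
`sample_pk_params()` draws from broad uniform ranges (a mix of normal and
abnormal perfusion) and is used for the evaluation splits, while
`ladder_pk_set()` builds the graded battery of network-input curves —
`ktrans` from 0.3 in steps of 0.2 (up to 2.3), `kep = ktrans/ve` with
$v_e\in[0.2,0.3]$. The ladder gives the network inputs with diverse, known
uptake; `vp` and the delay are drawn from the population ranges since
nothing constrains them further.

## Signal model and dictionary

`simulate_signal()` models the saturation-recovery centre-partition readout
of a 3D radial stack-of-stars acquisition: after the saturation pulse the
longitudinal magnetization starts at `residual_mz * m0`, recovers with
$R_1 = 1/T_{1,0} + r_1\,[\mathrm{Gd}]$ for the saturation-recovery time
(100 ms), and is then read out by 24 excitations (flip angle 12°, TR 2 ms);
each ray contributes $M_z \sin\alpha\, e^{-TE\,R_2^*}$ and leaves
$M_z\cos\alpha$ to relax for TR. The reported sample is the arithmetic mean
of the 24 ray signals, since every radial ray traverses the k-space centre;
the saturation-recovery time is referenced to the first centre-partition
ray. Defaults are the 3T settings being emulated (T1 1.8 s, T2* 60 ms,
r1 = 3.8, r2* = 5.7 L/mmol/s, TE 1 ms).

Two dictionary physics are exposed in `build_dictionary()`:

* `"full"` tabulates the complete forward equation including the
  concentration-driven $R_2^* = 1/T_2^{*}{}_{,0} + r_2^*\,[\mathrm{Gd}]$
  decay. Inverting a nominally acquired curve through it is exact to the
  table resolution (0.005 mM), the degenerate no-deviation case.
* `"t1"` tabulates the saturation-recovery T1 response alone. This is the
  dictionary a practitioner can actually apply to measured data — dynamic
  per-pixel T2* is unknown in vivo — and it is the default inversion used
  when building corrupted datasets: concentration-driven transverse decay is
  then one of the acquisition deviations the inversion does not model,
  together with flip-angle error and residual magnetization.

This split is the package's resolution of a genuinely open modelling
question. With the `"full"` dictionary on both sides of the conversion, the
symmetric flip-angle/T2*/residual deviations map through the convex
dictionary inverse with a *positive* mean peak error — the conversion would
on average overestimate the peak, which contradicts the saturation-dominated
underestimation the method exists to correct. Treating transverse decay as
unmodeled in the inversion reproduces the expected signature: a strongly
negative mean peak error with a wide spread, driven by the flat top of the
dictionary at first-pass concentrations. The residual-magnetization
deviation is implemented as signed post-saturation $M_z$ (fraction of
$m_0$, up to ±10%); perturbing $m_0$ itself can be expressed through the
`m0` field of `sequence_params()`.

Under this convention the remaining mismatch with larger reported baselines
is the flatness of the dictionary: a full 3D readout train burns more
magnetization than the 24-ray centre-partition recursion modelled here, and
a flatter dictionary amplifies both the systematic deficit and its spread.
Pre-burned-magnetization variants were explored and narrow the spread
without moving the mean, so the simpler convention is kept.

One consequence worth stating plainly: an underestimated AIF peak
mechanically *overestimates* fitted `ktrans` (amplitude reciprocity of the
linear model — scaling the AIF by $c$ scales the fitted `ktrans` by
$1/c$). A corruption pipeline in which both the AIF peak error and the
dictionary-fitted `ktrans` error are strongly negative at the same time is
therefore not reachable within this family of signal models; the package
reports what its pipeline actually produces.

**Noise.** Gaussian noise is added in the signal domain only
(`add_noise()`), with SD equal to 5% of the mean tissue-curve peak signal of
the record — pixel-scale noise — and the identical level on the AIF signal.
Using the record-level mean (rather than per-curve peaks) keeps one noise
level per simulated scan.

## Datasets

`make_dataset()` generates train/validation/test collections of records
(`curve_set`): true AIF, corrupted-and-inverted "saturated" AIF, measured
tissue curves, and all generating parameters. One bias draw is shared by
every curve of a record (one scan). The three splits use disjoint seeded
substreams so any split regenerates independently; two runs with the same
specification are bit-identical. Default sizes are 8000/1000/1000; the
packaged experiments and tests run reduced sizes (below).

For the distribution-shift ("hybrid") setting, training uses one-sided
deviations up to 10% with a validation split up to 15%, noise-free curves
(the cleaner curves train better), and four ladder tissue curves; the
held-out test records come from `make_clustered_test_sets()`, which builds
tissue inputs by k-means clustering of synthetic pixel-wise myocardial
curves (`simulate_pixel_curves()`, 10 restarts, centres sorted by peak) —
a stand-in for segmented in vivo data, with one-sided deviations up to 15%.
The pixel generator's defaults (a few hundred pixels, ±10% parameter
jitter, 5% noise) are plausible placeholders, not fitted to any dataset.

`preprocess_curve()` brings arbitrarily sampled measured curves onto the
canonical grid: linear interpolation, then alignment so that bolus arrival —
the first sample exceeding 10% of the curve peak — lands at index 10. The
10%/index-10 convention is chosen to be deterministic and shift-invariant.

## The correction network

`aif_lstm()` trains a four-layer bidirectional LSTM, 32 hidden units per
direction. Input is the per-time-step channel vector of the stacked curves
(saturated AIF always channel 1, tissue curves in ascending `ktrans`;
sequence length 120); a per-time-step linear layer maps the 64 concatenated
features to the predicted AIF sample, which keeps the output aligned with
the input time axis. Curves are fed in mM without normalization — the peak
amplitude is precisely the information the correction must restore, and the
simulated ranges are bounded. Weights are He-normal, biases zero; Adam with
learning rate 3e-4, batch 16; the retained model is the epoch with the
lowest validation curve L1 loss ("best validation accuracy" made concrete).
Given a seed, initialization, shuffling and the single-threaded training
loop are bit-reproducible. One observable consequence of this selection
rule: for a mildly tissue-weighted loss the retained epoch tends to predate
the slide into the degenerate tissue-loss basin, so at reduced training
scale the 1:10 tissue-weighted model degrades far less than a fully
converged run would show, while 1:100 collapses regardless.

Three losses are available:

* `"aif"` — mean absolute deviation of the predicted from the true AIF;
* `"aif_param"` — adds $\beta/N \sum_n \lVert\theta_n-\hat\theta_n\rVert_1$
  over the four compartment parameters of each tissue curve, predicted by a
  linear head on the final concatenated hidden state (shared trunk — the
  cheapest reading of the architecture);
* `"aif_tissue"` — adds $\delta/N \sum_n$ L1 between the measured tissue
  curves and the compartment model driven by the *predicted* AIF and
  *predicted* parameters, using the exact generator convolution. The delay
  enters by fractional-sample interpolation with its gradient detached
  (the shift is a documented non-smooth point); predicted `kep` and delay
  are clamped to sane ranges inside the forward model for stability. The
  parameter head predicts raw values on their natural scales — the known
  scale mismatch with curve values is part of what the loss comparison
  demonstrates, and is deliberately not "fixed".

The recurrent core (forward pass, backprop through time, Adam) is
implemented in single-precision C++ (RcppArmadillo), single-threaded; input
projections are batched into one matrix product per layer and direction.
`compute_loss()` is an independent plain-R reference of all three losses
used by the tests, sharing only the generator's convolution.

## PK fitting and evaluation

`fit_pk()` estimates the four compartment parameters by Levenberg-Marquardt
(`minpack.lm::nls.lm`) with bounds bracketing the generator ranges
(`ktrans` ≤ 5, `kep` ≤ 20, `vp` ≤ 0.2, delay ≤ 0.1 min). The objective has
genuine local minima in (`kep`, delay) — a fixed start such as
(0.5, 2.0, 0.02, 0.02), even with jittered restarts, strands a few percent
of ladder-curve fits (high `ktrans` with `kep` near 10 and a nonzero
delay) at the delay bound with percent-level `ktrans` errors. The default
initializer therefore exploits the model's structure: given (`kep`,
delay) the model is *linear* in (`ktrans`, `vp`), so a coarse 6×6 grid
over `kep` and delay with a two-parameter least-squares solve at each node
locates the global basin cheaply (the convolution commutes with the delay
shift, so each `kep` costs one convolution), and LM polishes from the best
node. A numeric `init` with jittered multistart remains available.
Noise-free recovery is then accurate to well under 1% in `ktrans` for the
overwhelming majority of fits; scaling the AIF by $c$ divides fitted
`ktrans` and `vp` by $c$ to within 2% — the reciprocity that links AIF
bias to flow bias.

The `ktrans` percent errors of a split are computed by fitting the
*reference* (noise-free generated) tissue curves against the estimated
AIF, so the metric isolates what the AIF distortion does to the flow
estimate; reciprocity then makes the `ktrans` error spread mirror the
peak-error spread. Fitting the corrupted round-tripped tissue curves
instead (available via `tissue_reference = "measured"`) folds the record's
shared acquisition deviations into every fit and inflates the spread to
tens of percent regardless of how good the AIF is — a property of the
corruption, not of the correction being assessed.

`evaluate_dataset()` reports, per split: AIF peak percent error (the peak is
the maximum grid sample — no sub-sample interpolation), `ktrans` percent
errors averaged over all tissue curves of every record, Pearson correlation
and least-squares line of estimate against target, and Bland–Altman bias
with mean ± 1.96 SD limits of agreement (computed on `ktrans` when fits are
available, as estimate − target).

## Problem sizes and numerical choices

The package's desk-scale reproductions use: 1000-record evaluation splits;
2000/500 training/validation records and 45 epochs for the two headline
correctors (AIF-only input, and AIF + 10 ladder tissue curves);
600-record, 12-epoch models for the loss-comparison checks; and
1200-record, 20-epoch models for the distribution-shift check. These sizes were chosen once as the smallest at which the
qualitative ordering of the full-scale study is stable; `run_experiment()`
accepts the full-scale sizes unchanged. Dictionary grid: 0–12 mM in
0.005 mM steps (covering the maximal simulated peak with margin), strict
monotonicity verified at build time; inversion clamps signal above the
table to the grid top and maps signal below the zero-concentration entry
to 0 mM.

## What the synthetic data does and does not show

The generator emulates the curve shapes, concentration ranges, acquisition
physics, deviation ranges and pixel-scale noise of a dynamic
saturation-recovery cardiac study. It does not emulate: coil-sensitivity
profiles (correctable by proton-density normalization in practice, hence
excluded), respiratory/cardiac motion, reconstruction artefacts of
undersampled radial data, water-exchange effects, population covariance
between AIF parameters (drawn independently), or the exact spectral
character of in vivo noise. Passing tests therefore demonstrate that the
correction learns to invert the modelled corruption family — not that a
network trained on these simulations transfers to scanner data; the
distribution-shift experiment probes robustness only within the synthetic
family.

## Known limitations

* The Bloch recursion models the centre partition of the readout only; a
  full readout-train simulation would be flatter at high concentration and
  would likely widen the baseline error spread.
* The dictionary-inversion convention (`"t1"` vs `"full"`) changes the sign
  structure of the baseline errors; both are provided, and the corrupted
  datasets default to `"t1"` for the reasons given above.
* `ktrans` error summaries are means over fat-tailed distributions —
  severely clipped AIFs can drive individual fits to the parameter bounds;
  medians are available from the per-record errors in the report object.
* On the clustered-pixel stand-in the tissue-input model's advantage in
  peak-error spread over the AIF-only model is real but thin (a fraction of
  a percentage point at the packaged sizes): the stand-in's AIF corruption
  stays within the simulated deviation family, so the AIF-only model
  extrapolates far better there than it could on measured data, leaving
  the tissue channels little to add.
* Training is CPU-bound and single-precision; at the packaged sizes a model
  trains in minutes, but the full 8000-record, 100-epoch configuration is
  an overnight CPU job.
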