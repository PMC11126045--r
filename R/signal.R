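#' Sequence settings of the saturation-recovery stack-of-stars acquisition
#'
#' Container of the pulse-sequence and relaxometry constants of the signal
#' model. Defaults describe the 3T acquisition being emulated: flip angle
#' 12 deg, 24 radial rays for the k-space centre partition, saturation
#' recovery time 100 ms, TR 2 ms, TE 1 ms, native blood T1 1.8 s,
#' non-contrast blood T2* 0.06 s, relaxivities r1 = 3.8 and r2* = 5.7
#' L/mmol/s.
#'
#' @param flip_angle_deg Readout flip angle in degrees.
#' @param n_center_rays Rays of the centre partition averaged into one sample.
#' @param srt_ms Saturation-recovery time: delay from the saturation pulse to
#'   the first centre-partition excitation, milliseconds.
#' @param tr_ms,te_ms Repetition and echo time in milliseconds.
#' @param t1_0_s Native (pre-contrast) blood T1 in seconds.
#' @param t2s_0_s Non-contrast blood T2* in seconds.
#' @param r1,r2s Longitudinal / effective-transverse relaxivities, L/mmol/s.
#' @param m0 Equilibrium magnetization (arbitrary units).
#' @return Object of class `sequence_params`.
#' @export
sequence_params <- function(flip_angle_deg = 12, n_center_rays = 24L,
                            srt_ms = 100, tr_ms = 2, te_ms = 1,
                            t1_0_s = 1.8, t2s_0_s = 0.06,
                            r1 = 3.8, r2s = 5.7, m0 = 1) {
  p <- list(flip_angle_deg = flip_angle_deg, n_center_rays = as.integer(n_center_rays),
            srt_ms = srt_ms, tr_ms = tr_ms, te_ms = te_ms, t1_0_s = t1_0_s,
            t2s_0_s = t2s_0_s, r1 = r1, r2s = r2s, m0 = m0)
  if (any(unlist(p) <= 0)) stop("all sequence parameters must be positive")
  structure(p, class = "sequence_params")
}

#' Acquisition bias factors
#'
#' Multiplicative deviations of the acquisition from its nominal settings:
#' flip-angle scale (B1 inhomogeneity), scale of the non-contrast T2*, and
#' residual longitudinal magnetization left by an imperfect saturation pulse
#' (signed fraction of m0). `bias_factors()` with no arguments is the nominal
#' (bias-free) acquisition.
#'
#' @param fa_scale,t2s_scale Multiplicative perturbations, nominal 1.
#' @param residual_mz Post-saturation Mz as a fraction of m0, nominal 0.
#' @return Object of class `bias_factors`.
#' @export
bias_factors <- function(fa_scale = 1, t2s_scale = 1, residual_mz = 0) {
  structure(list(fa_scale = fa_scale, t2s_scale = t2s_scale,
                 residual_mz = residual_mz), class = "bias_factors")
}

#' Draw random acquisition bias factors
#'
#' In `"symmetric"` mode each scale is uniform on `1 +/- magnitude` and the
#' residual magnetization uniform on `+/- magnitude`. In `"one_sided"` mode
#' all three are drawn upward only (`U(1, 1+m)`, residual `U(0, m)`),
#' emulating an acquisition whose deviations push the signal one way.
#'
#' @param mode `"symmetric"` or `"one_sided"`.
#' @param magnitude Maximal fractional deviation, in (0, 0.5].
#' @return A [bias_factors()] object.
#' @export
sample_bias <- function(mode = c("symmetric", "one_sided"), magnitude = 0.1) {
  mode <- match.arg(mode)
  if (magnitude <= 0 || magnitude > 0.5) stop("magnitude must be in (0, 0.5]")
  u <- stats::runif(3)
  if (mode == "symmetric") {
    bias_factors(fa_scale = 1 + magnitude * (2 * u[1] - 1),
                 t2s_scale = 1 + magnitude * (2 * u[2] - 1),
                 residual_mz = magnitude * (2 * u[3] - 1))
  } else {
    bias_factors(fa_scale = 1 + magnitude * u[1],
                 t2s_scale = 1 + magnitude * u[2],
                 residual_mz = magnitude * u[3])
  }
}

#' Bloch-recursion signal of the saturation-recovery readout
#'
#' Signal intensity for gadolinium concentration(s) `gd` under the
#' saturation-recovery centre-partition readout: longitudinal magnetization
#' starts at `residual_mz * m0` after the saturation pulse, relaxes with
#' `R1 = 1/T1_0 + r1 * gd` for the saturation-recovery time, then is read out
#' by `n_center_rays` excitations with effective flip angle
#' `fa_scale * flip_angle_deg` spaced TR apart. Each ray contributes
#' `Mz sin(FA) exp(-TE * R2*)` and leaves `Mz cos(FA)` to relax for TR. The
#' returned sample is the arithmetic mean of the ray signals (every radial
#' ray traverses the k-space centre).
#'
#' Two signal models are available: `"full"` includes the concentration-
#' driven transverse decay `R2* = 1/(T2*_0 t2s_scale) + r2s * gd`; `"t1"` is
#' the saturation-recovery T1 response alone (no transverse-decay factor),
#' the model conventionally assumed when inverting measured signal to
#' concentration, where per-pixel dynamic T2* is unknown.
#'
#' @param gd Gadolinium concentration(s), mM (vectorized).
#' @param seq A [sequence_params()] object.
#' @param bias A [bias_factors()] object.
#' @param model `"full"` (default) or `"t1"`.
#' @return Signal intensity, same length as `gd`.
#' @export
simulate_signal <- function(gd, seq = sequence_params(), bias = bias_factors(),
                            model = c("full", "t1")) {
  model <- match.arg(model)
  if (any(gd < 0)) stop("gd must be >= 0")
  R1 <- 1 / seq$t1_0_s + seq$r1 * gd
  fa <- seq$flip_angle_deg * bias$fa_scale * pi / 180
  m0 <- seq$m0
  mz <- m0 + (bias$residual_mz * m0 - m0) * exp(-R1 * seq$srt_ms / 1000)
  etr <- exp(-R1 * seq$tr_ms / 1000)
  ete <- if (model == "full") {
    exp(-(seq$te_ms / 1000) * (1 / (seq$t2s_0_s * bias$t2s_scale) + seq$r2s * gd))
  } else 1
  acc <- 0
  sfa <- sin(fa); cfa <- cos(fa)
  for (r in seq_len(seq$n_center_rays)) {
    acc <- acc + mz * sfa * ete
    mz <- m0 + (mz * cfa - m0) * etr
  }
  acc / seq$n_center_rays
}

#' Tabulated concentration-to-signal dictionary
#'
#' Tabulates [simulate_signal()] at nominal bias on a regular concentration
#' grid and verifies strict monotonicity, so the table can be inverted
#' unambiguously. The `"full"` model is the complete forward signal equation;
#' the `"t1"` model is the saturation-recovery T1 dictionary used to convert
#' measured signal to concentration when transverse decay is unknown.
#'
#' @param seq A [sequence_params()] object.
#' @param gd_max Upper end of the concentration grid, mM.
#' @param gd_step Grid spacing, mM.
#' @param model Signal model, see [simulate_signal()].
#' @return Object of class `signal_dictionary`: list with `gd_grid`,
#'   `si_values`, `seq`, `model`.
#' @examples
#' d <- build_dictionary()
#' plot(d)
#' @export
build_dictionary <- function(seq = sequence_params(), gd_max = 12,
                             gd_step = 0.005, model = c("full", "t1")) {
  model <- match.arg(model)
  if (gd_max <= 0 || gd_step <= 0) stop("gd_max and gd_step must be > 0")
  if (gd_step > gd_max) stop("gd_step must not exceed gd_max")
  gd <- seq.int(0L, round(gd_max / gd_step)) * gd_step
  si <- simulate_signal(gd, seq, bias_factors(), model = model)
  d <- diff(si)
  if (any(d <= 0)) {
    k <- which(d <= 0)[1]
    stop(sprintf("dictionary signal is non-monotone at gd = %.3f mM", gd[k]))
  }
  structure(list(gd_grid = gd, si_values = si, seq = seq, model = model),
            class = "signal_dictionary")
}

#' @export
print.signal_dictionary <- function(x, ...) {
  cat(sprintf("<signal_dictionary> model '%s', %d entries over [0, %.3g] mM, SI range [%.4g, %.4g]\n",
              x$model, length(x$gd_grid), max(x$gd_grid),
              x$si_values[1], x$si_values[length(x$si_values)]))
  invisible(x)
}

#' @export
plot.signal_dictionary <- function(x, ...) {
  graphics::plot(x$gd_grid, x$si_values, type = "l",
                 xlab = "[Gd] (mM)", ylab = "signal intensity",
                 main = sprintf("SR signal dictionary (%s model)", x$model), ...)
  invisible(x)
}

#' Convert a concentration curve to signal intensity
#'
#' Pointwise forward conversion through [simulate_signal()] with the given
#' (possibly perturbed) bias factors — the simulated acquisition of a curve.
#'
#' @param curve Concentration curve, mM.
#' @inheritParams simulate_signal
#' @return Signal-intensity curve.
#' @export
concentration_to_signal <- function(curve, seq = sequence_params(),
                                    bias = bias_factors(), model = "full") {
  simulate_signal(curve, seq, bias, model = model)
}

#' Invert a signal-intensity curve through a dictionary
#'
#' Piecewise-linear inversion of the tabulated map. Signal below the zero-
#' concentration entry maps to 0 mM; signal above the table maximum clamps to
#' the top of the concentration grid.
#'
#' @param si Signal-intensity curve.
#' @param dict A [build_dictionary()] object.
#' @return Concentration curve in mM.
#' @export
signal_to_concentration <- function(si, dict) {
  if (length(si) == 0L) stop("empty signal curve")
  gd_max <- dict$gd_grid[length(dict$gd_grid)]
  stats::approx(dict$si_values, dict$gd_grid, xout = si,
                yleft = 0, yright = gd_max, ties = "ordered")$y
}

#' Add acquisition noise to the signal curves of one record
#'
#' Zero-mean Gaussian noise in the signal-intensity domain. The standard
#' deviation is 5% (by default) of the mean peak signal of the tissue curves
#' of the record, and the identical level is applied to the AIF signal curve,
#' emulating pixel-wise thermal noise of the dynamic series.
#'
#' @param aif_si AIF signal curve.
#' @param tissue_si List of tissue signal curves (>= 1) used to set the level.
#' @param frac Noise SD as a fraction of the mean tissue peak signal.
#' @return List with noisy `aif_si`, `tissue_si` and the `sigma` used.
#' @export
add_noise <- function(aif_si, tissue_si, frac = 0.05) {
  if (length(tissue_si) < 1L) stop("need at least one tissue signal curve")
  sigma <- frac * mean(vapply(tissue_si, max, numeric(1)))
  list(aif_si = aif_si + stats::rnorm(length(aif_si), 0, sigma),
       tissue_si = lapply(tissue_si, function(x)
         x + stats::rnorm(length(x), 0, sigma)),
       sigma = sigma)
}
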