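#' Four-parameter compartment model tissue curve
#'
#' Myocardial tissue concentration from an arterial input via the extended
#' compartment model
#' \deqn{C_{tiss}(t) = C_{AIF}(t-\Delta t) \otimes k^{trans} e^{-k_{ep} t}
#'   + v_p\, C_{AIF}(t-\Delta t)}
#' The convolution is a causal trapezoid-rule quadrature on the native grid;
#' the arrival delay is applied by linear interpolation of the AIF (zero
#' before t = 0), so sub-sample delays are represented exactly to first order.
#'
#' @param aif Numeric AIF concentration curve on `grid` (mM).
#' @param pk Named list/one-row data.frame with `ktrans`, `kep` (1/min),
#'   `vp` (fraction) and `delta_t` (minutes).
#' @param grid The [time_grid()] the curves live on.
#' @return Numeric tissue concentration curve (mM), same length as `aif`.
#' @examples
#' g <- time_grid()
#' set.seed(2)
#' aif <- evaluate_aif(sample_aif_params(), g)
#' ct <- tissue_curve(aif, list(ktrans = 0.8, kep = 3, vp = 0.03, delta_t = 0.02), g)
#' @export
tissue_curve <- function(aif, pk, grid = time_grid()) {
  pk <- as.list(pk)
  if (pk$ktrans < 0 || pk$kep < 0) stop("ktrans and kep must be >= 0")
  if (pk$vp < 0 || pk$vp > 1) stop("vp must be in [0, 1]")
  if (pk$delta_t < 0) stop("delta_t must be >= 0")
  t <- grid$t
  if (length(aif) != grid$n) stop("aif length does not match grid")
  sa <- shift_curve(aif, t, pk$delta_t)
  conv_exp_trapz(sa, pk$ktrans, pk$kep, grid$dt) + pk$vp * sa
}

# delay a curve by dt_min via linear interpolation, zero-filled before onset
shift_curve <- function(values, t, dt_min) {
  if (dt_min == 0) return(values)
  stats::approx(t, values, xout = t - dt_min, yleft = 0,
                rule = 1, yright = values[length(values)])$y
}

# trapezoid-rule causal convolution of `x` with ktrans * exp(-kep * t)
conv_exp_trapz <- function(x, ktrans, kep, dt) {
  .Call(`_aifcorr_cpp_conv_exp`, as.numeric(x), ktrans, kep, dt)
}

# PK random sampling intervals (uniform)
.pk_ranges <- list(ktrans = c(0.3, 1.1), kep = c(1, 5),
                   vp = c(0, 0.05), delta_t = c(0, 0.05))

#' Draw compartment-model parameters from the population distribution
#'
#' Independent uniform draws of `ktrans` in \[0.3, 1.1\] 1/min, `kep` in
#' \[1, 5\] 1/min, `vp` in \[0, 0.05\] and arrival delay `delta_t` in
#' \[0, 0.05\] min, reflecting a mix of normal and abnormal perfusion.
#'
#' @param n Number of draws.
#' @return data.frame with columns `ktrans`, `kep`, `vp`, `delta_t`.
#' @export
sample_pk_params <- function(n = 1L) {
  out <- lapply(.pk_ranges, function(r) stats::runif(n, r[1], r[2]))
  as.data.frame(out)
}

#' PK parameter sampling ranges
#' @return Named list of uniform sampling intervals.
#' @export
pk_param_ranges <- function() .pk_ranges

#' Fixed-ktrans ladder of tissue-curve parameters
#'
#' Parameter sets for the graded battery of tissue curves fed to the
#' correction network: curve i gets `ktrans = 0.3 + 0.2 * (i - 1)` (1/min, up
#' to 2.3), `kep = ktrans / ve` with the extravascular-extracellular volume
#' fraction `ve` drawn uniformly from `ve_range`, and `vp`, `delta_t` drawn
#' from the population ranges of [sample_pk_params()].
#'
#' @param n_curves Number of curves (1 to 11; the ladder ends at ktrans 2.3).
#' @param ve_range Length-2 bounds of `ve`, default `c(0.2, 0.3)`.
#' @return data.frame with `n_curves` rows: `ktrans`, `kep`, `vp`, `delta_t`, `ve`.
#' @examples
#' set.seed(3)
#' ladder_pk_set(10)$ktrans  # 0.3 0.5 ... 2.1
#' @export
ladder_pk_set <- function(n_curves, ve_range = c(0.2, 0.3)) {
  if (n_curves < 1L || n_curves > 11L)
    stop("ladder exhausted: n_curves must be between 1 and 11")
  if (ve_range[1] <= 0 || ve_range[2] >= 1 || ve_range[1] > ve_range[2])
    stop("ve_range must satisfy 0 < lo <= hi < 1")
  ktrans <- 0.3 + 0.2 * (seq_len(n_curves) - 1L)
  ve <- stats::runif(n_curves, ve_range[1], ve_range[2])
  data.frame(ktrans = ktrans, kep = ktrans / ve,
             vp = stats::runif(n_curves, .pk_ranges$vp[1], .pk_ranges$vp[2]),
             delta_t = stats::runif(n_curves, .pk_ranges$delta_t[1],
                                    .pk_ranges$delta_t[2]),
             ve = ve)
}
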