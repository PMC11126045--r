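#' Unit-peak gamma-variate bolus shape
#'
#' Gamma variate used as the building block of the population arterial input
#' function (AIF) model. Parameterized so that its peak value is exactly 1 at
#' `t = delta + lam * tau`; the amplitude constants of the AIF model therefore
#' set peak concentrations directly in mM.
#'
#' @param t Sample times in minutes (vector) or a `time_grid`.
#' @param lam Shape parameter (dimensionless, > 0).
#' @param tau Width parameter in minutes (> 0).
#' @param delta Onset delay in minutes (>= 0).
#' @return Numeric vector: 0 for `t <= delta`, else
#'   `((t-delta)/(lam*tau))^lam * exp(lam - (t-delta)/tau)`.
#' @export
gamma_variate <- function(t, lam, tau, delta = 0) {
  if (is_time_grid(t)) t <- t$t
  if (lam <= 0 || tau <= 0) stop("gamma_variate: lam and tau must be > 0")
  if (delta < 0) stop("gamma_variate: delta must be >= 0")
  out <- numeric(length(t))
  i <- t > delta
  x <- t[i] - delta
  out[i] <- exp(lam * (log(x) - log(lam * tau) + 1) - x / tau)
  out
}

#' Sigmoidal washout term of the population AIF model
#'
#' Regularized lower incomplete gamma rise multiplied by an exponential
#' elimination: models the slow sigmoidal enhancement of the blood pool after
#' recirculation, decaying with the contrast elimination time constant `T`.
#'
#' @inheritParams gamma_variate
#' @param T Elimination time constant in minutes (> 0).
#' @return Numeric vector: 0 for `t <= delta`, else
#'   `P(lam, (t-delta)/tau) * exp(-(t-delta)/T)` with `P` the regularized
#'   lower incomplete gamma function.
#' @export
sigmoid_washout <- function(t, lam, tau, delta = 0, T) {
  if (is_time_grid(t)) t <- t$t
  if (lam <= 0 || tau <= 0 || T <= 0)
    stop("sigmoid_washout: lam, tau and T must be > 0")
  out <- numeric(length(t))
  i <- t > delta
  x <- t[i] - delta
  out[i] <- stats::pgamma(x / tau, shape = lam) * exp(-x / T)
  out
}

# Uniform sampling intervals of the 12 free AIF parameters.
# Amplitudes dimensionless (peak mM), taus/deltas/T in minutes.
.aif_ranges <- list(
  A1     = c(3, 9),       lambda1 = c(5, 13),
  tau1   = c(0.015, 0.025), delta1 = c(0.1, 0.15),
  A2     = c(0.75, 1.25), lambda2 = c(5, 7),
  tau2   = c(0.15, 0.25), delta2  = c(0.04, 0.05),
  A3     = c(0.35, 0.55), delta3  = c(0.56, 0.76),
  A4     = c(2.5, 3.5),   T       = c(0.35, 0.55))

#' Draw AIF model parameters from the population distribution
#'
#' Each of the 12 free parameters is drawn independently and uniformly from
#' its population interval. Uses the current R random number generator state;
#' call [set.seed()] beforehand for reproducibility.
#'
#' @param n Number of parameter sets to draw.
#' @return A data.frame with `n` rows and the 12 parameter columns
#'   `A1, lambda1, tau1, delta1, A2, lambda2, tau2, delta2, A3, delta3, A4, T`.
#' @seealso [evaluate_aif()] for turning a draw into a concentration curve.
#' @export
sample_aif_params <- function(n = 1L) {
  out <- lapply(.aif_ranges, function(r) stats::runif(n, r[1], r[2]))
  as.data.frame(out)
}

#' AIF parameter sampling ranges
#'
#' @return Named list of the `c(lo, hi)` uniform sampling interval of each of
#'   the 12 free AIF parameters.
#' @export
aif_param_ranges <- function() .aif_ranges

#' Evaluate the population AIF model
#'
#' Sum of three unit-peak gamma variates (first pass and two recirculation
#' peaks) and one sigmoidal washout term. The third width parameter of the
#' washout is tied to `tau2`, leaving 12 free parameters:
#' \deqn{C_{AIF}(t) = A_1 G(\lambda_1,\tau_1,\Delta_1)
#'   + A_2 G(\lambda_2,\tau_2,\Delta_1{+}\Delta_2)
#'   + A_3 G(\lambda_2,\tau_2,\Delta_1{+}\Delta_3)
#'   + A_4 S(\lambda_2,\tau_2,\Delta_1{+}\Delta_3,T)}
#'
#' @param params One row of [sample_aif_params()] (data.frame or named list).
#' @param grid A [time_grid()] (or numeric vector of times in minutes).
#' @return Numeric vector of gadolinium concentration in mM per grid point.
#' @examples
#' set.seed(1)
#' aif <- evaluate_aif(sample_aif_params(), time_grid())
#' max(aif)  # first-pass peak, approximately A1 mM
#' @export
evaluate_aif <- function(params, grid = time_grid()) {
  p <- as.list(params)
  t <- if (is_time_grid(grid)) grid$t else grid
  p$A1 * gamma_variate(t, p$lambda1, p$tau1, p$delta1) +
    p$A2 * gamma_variate(t, p$lambda2, p$tau2, p$delta1 + p$delta2) +
    p$A3 * gamma_variate(t, p$lambda2, p$tau2, p$delta1 + p$delta3) +
    p$A4 * sigmoid_washout(t, p$lambda2, p$tau2, p$delta1 + p$delta3, p$T)
}
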