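#' Percentage error
#'
#' `100 * (P - T) / T`, the error metric used for AIF peak values and fitted
#' ktrans.
#'
#' @param P Estimate(s).
#' @param T Target value(s); must be non-zero.
#' @return Percent error(s).
#' @export
percent_error <- function(P, T) {
  if (any(T == 0)) stop("percent error undefined for zero target")
  100 * (P - T) / T
}

#' Evaluate estimated AIFs against the truth on a test split
#'
#' For each record, computes the percent error of the AIF peak (the maximum
#' sample of each curve) and, when tissue curves are supplied, the percent
#' errors of ktrans fitted with the estimated AIF ([ktrans_errors()]).
#' Aggregates mean and SD, the Pearson correlation and least-squares line of
#' estimated vs target peaks, and Bland-Altman agreement (mean difference and
#' mean +/- 1.96 SD limits) of fitted vs true ktrans (of peaks when no
#' tissue curves are given).
#'
#' @param estimates List or `time x n` matrix of estimated AIF curves.
#' @param truths List or matrix of true AIF curves (same layout).
#' @param tissue_curves Optional list (per record) of lists of tissue curves.
#' @param true_ktrans Optional list/matrix of generating ktrans per record.
#' @param grid The [time_grid()].
#' @param n_starts Restarts for the ktrans fits.
#' @return Object of class `aif_eval` with fields `peak_error_mean`,
#'   `peak_error_sd`, `ktrans_error_mean`, `ktrans_error_sd`, `pearson_r`,
#'   `fit_slope`, `fit_intercept`, `bland_altman_bias`,
#'   `bland_altman_loa_low`, `bland_altman_loa_high`, `n_sets`, plus the
#'   per-record errors in `peak_errors` and `ktrans_errors`.
#' @export
evaluate_dataset <- function(estimates, truths, tissue_curves = NULL,
                             true_ktrans = NULL, grid = time_grid(),
                             n_starts = 1L) {
  as_curve_list <- function(x)
    if (is.matrix(x)) lapply(seq_len(ncol(x)), function(i) x[, i]) else x
  estimates <- as_curve_list(estimates)
  truths <- as_curve_list(truths)
  n <- length(estimates)
  if (length(truths) != n) stop("estimates and truths lengths differ")
  peak_est <- vapply(estimates, max, numeric(1))
  peak_true <- vapply(truths, max, numeric(1))
  perr <- percent_error(peak_est, peak_true)

  kerr <- numeric(0)
  kt_est <- kt_true <- numeric(0)
  if (!is.null(tissue_curves)) {
    for (i in seq_len(n)) {
      tk <- if (is.matrix(true_ktrans)) true_ktrans[, i] else true_ktrans[[i]]
      e <- ktrans_errors(estimates[[i]], tissue_curves[[i]], tk, grid,
                         n_starts = n_starts)
      kerr <- c(kerr, e)
      kt_true <- c(kt_true, tk)
      kt_est <- c(kt_est, tk * (1 + e / 100))
    }
  }
  # agreement statistics: on ktrans when fitted, else on the peaks
  a <- if (length(kt_est)) kt_est else peak_est
  b <- if (length(kt_est)) kt_true else peak_true
  d <- a - b
  fit <- stats::lm.fit(cbind(1, b), a)$coefficients
  structure(list(
    peak_error_mean = mean(perr), peak_error_sd = stats::sd(perr),
    ktrans_error_mean = if (length(kerr)) mean(kerr) else NA_real_,
    ktrans_error_sd = if (length(kerr)) stats::sd(kerr) else NA_real_,
    pearson_r = if (stats::sd(a) > 0 && stats::sd(b) > 0) stats::cor(b, a)
                else NA_real_,
    fit_slope = unname(fit[2]), fit_intercept = unname(fit[1]),
    bland_altman_bias = mean(d),
    bland_altman_loa_low = mean(d) - 1.96 * stats::sd(d),
    bland_altman_loa_high = mean(d) + 1.96 * stats::sd(d),
    n_sets = n, peak_errors = perr, ktrans_errors = kerr),
    class = "aif_eval")
}

#' @export
print.aif_eval <- function(x, ...) {
  cat(sprintf("<aif_eval> %d records\n", x$n_sets))
  cat(sprintf("  AIF peak error : %6.2f +/- %5.2f %%\n",
              x$peak_error_mean, x$peak_error_sd))
  if (!is.na(x$ktrans_error_mean))
    cat(sprintf("  ktrans error   : %6.2f +/- %5.2f %%  (%d fits)\n",
                x$ktrans_error_mean, x$ktrans_error_sd,
                length(x$ktrans_errors)))
  cat(sprintf("  estimate vs target: r = %.3f, y = %.3f x + %.3f\n",
              x$pearson_r, x$fit_slope, x$fit_intercept))
  cat(sprintf("  Bland-Altman  : bias %.4g, LoA [%.4g, %.4g]\n",
              x$bland_altman_bias, x$bland_altman_loa_low,
              x$bland_altman_loa_high))
  invisible(x)
}

#' @export
plot.aif_eval <- function(x, which = c("error", "bland_altman"), ...) {
  which <- match.arg(which)
  if (which == "error") {
    graphics::boxplot(list(`AIF peak` = x$peak_errors,
                           ktrans = x$ktrans_errors),
                      ylab = "percent error", ...)
    graphics::abline(h = 0, lty = 3)
  } else {
    d <- if (length(x$ktrans_errors)) x$ktrans_errors else x$peak_errors
    graphics::plot(seq_along(d), d, xlab = "measurement",
                   ylab = "difference", ...)
    graphics::abline(h = c(x$bland_altman_bias, x$bland_altman_loa_low,
                           x$bland_altman_loa_high), lty = c(1, 2, 2))
  }
  invisible(x)
}
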