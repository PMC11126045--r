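#' Canonical acquisition time grid
#'
#' Uniform time grid on which all simulated curves live. The default matches
#' a dynamic contrast-enhanced cardiac acquisition sampled every 0.5 s for
#' one minute: 120 points, step 1/120 min.
#'
#' @param n_points Number of samples.
#' @param dt Sample spacing in minutes.
#' @return An object of class `time_grid`: list with `n`, `dt` (minutes) and
#'   `t` (sample times in minutes, starting at 0).
#' @examples
#' g <- time_grid()
#' range(g$t)
#' @export
time_grid <- function(n_points = 120L, dt = 1 / 120) {
  if (n_points < 2L || dt <= 0) stop("need n_points >= 2 and dt > 0")
  structure(list(n = as.integer(n_points), dt = dt,
                 t = seq(0, by = dt, length.out = n_points)),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %d points, dt = %.4g min (%.3g s), span %.3g min\n",
              x$n, x$dt, x$dt * 60, x$t[x$n]))
  invisible(x)
}

is_time_grid <- function(x) inherits(x, "time_grid")

stopifnot_uniform <- function(times) {
  d <- diff(times)
  if (any(abs(d - d[1]) > 1e-9 * max(abs(d[1]), 1e-12)))
    stop("curve is not on a uniform time grid")
  invisible(d[1])
}
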