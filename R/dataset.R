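#' Specification of a simulated curve dataset
#'
#' Describes how training/validation/test records are generated: counts,
#' number of tissue curves per record, the tissue parameter sampler, the
#' acquisition bias mode and magnitudes, noise, and the root seed.
#'
#' @param n_train,n_val,n_test Records per split.
#' @param n_tissue Tissue curves per record (0 to 11).
#' @param pk_sampler `"ladder"`: graded ktrans ladder ([ladder_pk_set()]),
#'   the default for network-input tissue curves; `"random"`: population
#'   draws ([sample_pk_params()]).
#' @param bias_mode `"symmetric"` or `"one_sided"` (see [sample_bias()]).
#' @param bias_magnitude Maximal fractional bias for train/test.
#' @param val_bias_magnitude Maximal fractional bias for the validation
#'   split; defaults to `bias_magnitude`. A larger value emulates the
#'   broader deviation range expected of data from another source.
#' @param noisy Add signal-domain noise ([add_noise()])?
#' @param noise_frac Noise SD as fraction of mean tissue peak signal.
#' @param inversion Dictionary physics used to convert measured signal back
#'   to concentration: `"t1"` (default, saturation-recovery T1 dictionary;
#'   transverse decay is an unmodeled deviation, as when converting measured
#'   data) or `"full"` (inverts the complete forward model, exact round trip
#'   at nominal bias).
#' @param seed Root seed; all randomness of [make_dataset()] derives from it.
#' @return Object of class `dataset_spec`.
#' @export
dataset_spec <- function(n_train = 8000L, n_val = 1000L, n_test = 1000L,
                         n_tissue = 10L, pk_sampler = c("ladder", "random"),
                         bias_mode = c("symmetric", "one_sided"),
                         bias_magnitude = 0.1,
                         val_bias_magnitude = bias_magnitude,
                         noisy = TRUE, noise_frac = 0.05,
                         inversion = c("t1", "full"), seed = 1L) {
  pk_sampler <- match.arg(pk_sampler)
  bias_mode <- match.arg(bias_mode)
  inversion <- match.arg(inversion)
  if (min(n_train, n_val, n_test) < 1L) stop("split counts must be positive")
  if (n_tissue < 0L || n_tissue > 11L) stop("n_tissue must be in 0..11")
  structure(list(n_train = as.integer(n_train), n_val = as.integer(n_val),
                 n_test = as.integer(n_test), n_tissue = as.integer(n_tissue),
                 pk_sampler = pk_sampler, bias_mode = bias_mode,
                 bias_magnitude = bias_magnitude,
                 val_bias_magnitude = val_bias_magnitude, noisy = noisy,
                 noise_frac = noise_frac, inversion = inversion,
                 seed = as.integer(seed)),
            class = "dataset_spec")
}

#' Generate one simulated record
#'
#' Draws an AIF and tissue parameter sets, simulates the acquisition of all
#' curves with one shared draw of bias factors (one scan), optionally adds
#' signal-domain noise, and inverts all signal curves with the nominal
#' dictionary. Consumes the current RNG stream.
#'
#' @param spec A [dataset_spec()].
#' @param grid A [time_grid()].
#' @param dict_inv Inversion dictionary; built from `spec$inversion` when NULL.
#' @param seq Sequence settings of the simulated acquisition.
#' @param bias Bias override (a [bias_factors()]); drawn from
#'   `spec$bias_mode`/`spec$bias_magnitude` when NULL.
#' @param bias_magnitude Magnitude override used when drawing the bias.
#' @return Object of class `curve_set`: list with `true_aif`,
#'   `saturated_aif`, `tissue_curves` (measured, list), `true_tissue`
#'   (noise-free generated curves, list), `pk_params`, `aif_params`, `bias`,
#'   `sigma`.
#' @export
make_curve_set <- function(spec = dataset_spec(), grid = time_grid(),
                           dict_inv = NULL, seq = sequence_params(),
                           bias = NULL, bias_magnitude = spec$bias_magnitude) {
  if (is.null(dict_inv)) dict_inv <- build_dictionary(seq, model = spec$inversion)
  aifp <- sample_aif_params(1L)
  true_aif <- evaluate_aif(aifp, grid)
  if (spec$n_tissue > 0L) {
    pk <- if (spec$pk_sampler == "ladder") ladder_pk_set(spec$n_tissue)
          else sample_pk_params(spec$n_tissue)
    true_tissue <- lapply(seq_len(nrow(pk)),
                          function(i) tissue_curve(true_aif, pk[i, ], grid))
  } else {
    pk <- sample_pk_params(0L)
    true_tissue <- list()
  }
  if (is.null(bias)) bias <- sample_bias(spec$bias_mode, bias_magnitude)
  aif_si <- concentration_to_signal(true_aif, seq, bias)
  tiss_si <- lapply(true_tissue, concentration_to_signal, seq = seq, bias = bias)
  sigma <- 0
  if (spec$noisy && length(tiss_si) > 0L) {
    nz <- add_noise(aif_si, tiss_si, spec$noise_frac)
    aif_si <- nz$aif_si; tiss_si <- nz$tissue_si; sigma <- nz$sigma
  }
  structure(list(true_aif = true_aif,
                 saturated_aif = signal_to_concentration(aif_si, dict_inv),
                 tissue_curves = lapply(tiss_si, signal_to_concentration,
                                        dict = dict_inv),
                 true_tissue = true_tissue, pk_params = pk,
                 aif_params = aifp, bias = bias, sigma = sigma),
            class = "curve_set")
}

#' Generate seeded train/validation/test collections
#'
#' The three splits use disjoint seeded substreams derived from `spec$seed`,
#' so any split can be regenerated independently and two runs with the same
#' spec are identical. The validation split may use a wider bias magnitude
#' than training (`val_bias_magnitude`).
#'
#' @param spec A [dataset_spec()].
#' @param grid A [time_grid()].
#' @param seq Sequence settings.
#' @return Object of class `curve_dataset`: list with `train`, `val`, `test`
#'   (lists of `curve_set`), plus `spec`, `grid`, `seq`.
#' @examples
#' ds <- make_dataset(dataset_spec(n_train = 4, n_val = 2, n_test = 2,
#'                                 n_tissue = 2, seed = 7))
#' length(ds$train)
#' @export
make_dataset <- function(spec = dataset_spec(), grid = time_grid(),
                         seq = sequence_params()) {
  dict_inv <- build_dictionary(seq, model = spec$inversion)
  gen_split <- function(n, sub, magnitude) {
    set.seed(spec$seed * 8L + sub)
    lapply(seq_len(n), function(i)
      make_curve_set(spec, grid, dict_inv, seq, bias_magnitude = magnitude))
  }
  structure(list(train = gen_split(spec$n_train, 1L, spec$bias_magnitude),
                 val = gen_split(spec$n_val, 2L, spec$val_bias_magnitude),
                 test = gen_split(spec$n_test, 3L, spec$bias_magnitude),
                 spec = spec, grid = grid, seq = seq),
            class = "curve_dataset")
}

#' @export
print.curve_dataset <- function(x, ...) {
  cat(sprintf(paste0("<curve_dataset> %d/%d/%d train/val/test records, ",
                     "%d tissue curves (%s), bias %s %.0f%%%s, %s\n"),
              length(x$train), length(x$val), length(x$test),
              x$spec$n_tissue, x$spec$pk_sampler, x$spec$bias_mode,
              100 * x$spec$bias_magnitude,
              if (x$spec$noisy) ", noisy" else ", noise-free",
              sprintf("'%s' inversion", x$spec$inversion)))
  invisible(x)
}

#' Stack a split into network arrays
#'
#' @param sets List of `curve_set` records (a split of [make_dataset()]).
#' @param n_tissue Tissue input channels to use (defaults to all present).
#' @return List of arrays: `x` (time x channels x record; channel 1 is the
#'   saturated AIF, then tissue curves in ascending ktrans), `y` (time x
#'   record, true AIF), `par` (4*n_tissue x record: ktrans, kep, vp, delta_t
#'   per curve), `tissue` (time x n_tissue x record, measured curves).
#' @export
as_arrays <- function(sets, n_tissue = NULL) {
  n <- length(sets)
  T <- length(sets[[1]]$true_aif)
  if (is.null(n_tissue)) n_tissue <- length(sets[[1]]$tissue_curves)
  nc <- 1L + n_tissue
  x <- array(0, c(T, nc, n)); y <- matrix(0, T, n)
  par <- matrix(0, 4L * n_tissue, n)
  tissue <- array(0, c(T, max(n_tissue, 1L), n))
  for (i in seq_len(n)) {
    s <- sets[[i]]
    x[, 1L, i] <- s$saturated_aif
    y[, i] <- s$true_aif
    if (n_tissue > 0L) {
      ord <- order(s$pk_params$ktrans)[seq_len(n_tissue)]
      for (j in seq_len(n_tissue)) {
        x[, 1L + j, i] <- s$tissue_curves[[ord[j]]]
        tissue[, j, i] <- s$tissue_curves[[ord[j]]]
        par[(4L * (j - 1L) + 1L):(4L * j), i] <-
          unlist(s$pk_params[ord[j], c("ktrans", "kep", "vp", "delta_t")])
      }
    }
  }
  list(x = x, y = y, par = par, tissue = tissue, n_tissue = n_tissue)
}

#' Synthetic pixel-wise myocardial curves
#'
#' Stand-in for pixel-wise tissue curves segmented from a dynamic series:
#' draws `n_clusters` compartment-model parameter sets, assigns pixels to
#' clusters, jitters each pixel's parameters by a relative amount, generates
#' the curves and adds Gaussian noise scaled to the curve peaks.
#'
#' @param aif Driving AIF concentration curve.
#' @param n_pixels Number of pixel curves.
#' @param n_clusters Number of underlying tissue classes.
#' @param jitter Relative parameter jitter per pixel (0.1 = +/-10%).
#' @param noise_frac Noise SD as fraction of each curve's peak.
#' @param grid A [time_grid()].
#' @param pk Optional matrix/data.frame of cluster parameters (rows =
#'   clusters, columns ktrans, kep, vp, delta_t); drawn when NULL.
#' @param ve_range When drawing cluster parameters, tie `kep = ktrans / ve`
#'   with `ve` uniform in this range — the physiological restriction of the
#'   myocardial extravascular-extracellular fraction. `NULL` draws `kep`
#'   independently ([sample_pk_params()]).
#' @return List with `curves` (time x n_pixels matrix), `cluster` (pixel
#'   assignments), `pk` (cluster parameters).
#' @export
simulate_pixel_curves <- function(aif, n_pixels = 500L, n_clusters = 4L,
                                  jitter = 0.1, noise_frac = 0.05,
                                  grid = time_grid(), pk = NULL,
                                  ve_range = c(0.2, 0.3)) {
  if (n_clusters > n_pixels) stop("n_clusters must not exceed n_pixels")
  if (is.null(pk)) {
    pk <- sample_pk_params(n_clusters)
    if (!is.null(ve_range))
      pk$kep <- pk$ktrans / stats::runif(n_clusters, ve_range[1], ve_range[2])
  }
  pk <- as.data.frame(pk)
  cl <- rep_len(seq_len(n_clusters), n_pixels)
  curves <- matrix(0, grid$n, n_pixels)
  for (i in seq_len(n_pixels)) {
    p <- pk[cl[i], ]
    jit <- 1 + jitter * (2 * stats::runif(4) - 1)
    p <- list(ktrans = p$ktrans * jit[1], kep = p$kep * jit[2],
              vp = min(1, p$vp * jit[3]), delta_t = p$delta_t * jit[4])
    cv <- tissue_curve(aif, p, grid)
    curves[, i] <- cv + stats::rnorm(grid$n, 0, noise_frac * max(cv))
  }
  list(curves = curves, cluster = cl, pk = pk)
}

#' Cluster pixel curves into representative tissue curves
#'
#' K-means (Euclidean distance on the full time vector, 10 restarts) over
#' pixel-wise curves; returns the cluster-mean curves sorted by descending
#' peak value, the input format expected by the correction network when only
#' a few representative tissue curves are wanted.
#'
#' @param pixel_curves Matrix, time points x pixels.
#' @param k Number of clusters (1 <= k <= number of pixels).
#' @return Matrix, time points x k cluster-mean curves (descending peak).
#' @export
cluster_tissue_curves <- function(pixel_curves, k) {
  n <- ncol(pixel_curves)
  if (k < 1L || k > n) stop("k must be between 1 and the number of curves")
  if (k == 1L) return(matrix(rowMeans(pixel_curves), ncol = 1L))
  km <- stats::kmeans(t(pixel_curves), centers = k, nstart = 10L,
                      iter.max = 100L)
  centers <- t(km$centers)
  centers[, order(apply(centers, 2L, max), decreasing = TRUE), drop = FALSE]
}

#' Resample and align a measured curve onto the canonical grid
#'
#' Linear interpolation of an arbitrarily sampled curve onto the canonical
#' 0.5 s / 120-point grid, followed by alignment: the curve is shifted so
#' that bolus arrival (first sample exceeding 10% of the curve peak) lands at
#' a fixed canonical index. Values outside the measured span are zero-filled.
#'
#' @param times_s Strictly increasing sample times in seconds (>= 2).
#' @param values Curve values at `times_s`.
#' @param grid Target [time_grid()].
#' @param arrival_index Canonical bolus-arrival index (1-based).
#' @param arrival_frac Arrival threshold as a fraction of the curve peak.
#' @param align Shift the curve to the canonical arrival index? (`FALSE`
#'   resamples only.)
#' @return Numeric curve on `grid`.
#' @export
preprocess_curve <- function(times_s, values, grid = time_grid(),
                             arrival_index = 10L, arrival_frac = 0.1,
                             align = TRUE) {
  if (length(times_s) < 2L || any(diff(times_s) <= 0))
    stop("times must be strictly increasing with >= 2 samples")
  t_min <- times_s / 60
  res <- stats::approx(t_min, values, xout = grid$t, yleft = 0, yright = 0)$y
  if (!align) return(res)
  arr <- which(res > arrival_frac * max(res))[1]
  if (is.na(arr)) return(res)
  k <- arr - as.integer(arrival_index)
  if (k > 0) c(res[-seq_len(k)], numeric(k))
  else if (k < 0) c(numeric(-k), res[seq_len(grid$n + k)])
  else res
}
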