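#' Closed-form parameter count of the bidirectional LSTM stack
#'
#' @param layers Number of stacked bidirectional layers.
#' @param hidden Hidden units per direction.
#' @param channels Input channels (1 + number of tissue curves).
#' @param n_param_out Size of the auxiliary parameter head (0 = none).
#' @return Total number of learnable parameters, including the per-time-step
#'   linear read-out and any parameter head.
#' @export
lstm_param_count <- function(layers, hidden, channels, n_param_out = 0L) {
  per_dir <- function(cin) 4 * hidden * (cin + hidden + 1)
  rec <- 2 * per_dir(channels) +
    (layers - 1) * 2 * per_dir(2 * hidden)
  rec + (2 * hidden + 1) + ifelse(n_param_out > 0,
                                  n_param_out * (2 * hidden + 1), 0)
}

# He-normal weight initialization (sd = sqrt(2 / fan_in)), zero biases;
# draws from the current R RNG stream so the whole fit is seed-reproducible
init_weights <- function(layers, hidden, channels, n_param_out) {
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nc)), nr, nc)
  w <- list()
  for (l in seq_len(layers)) {
    cin <- if (l == 1L) channels else 2L * hidden
    for (d in c("f", "b")) {
      w[[sprintf("W_%d_%s", l, d)]] <- he(4L * hidden, cin)
      w[[sprintf("U_%d_%s", l, d)]] <- he(4L * hidden, hidden)
      w[[sprintf("b_%d_%s", l, d)]] <- numeric(4L * hidden)
    }
  }
  w$w_out <- as.numeric(he(2L * hidden, 1L))
  w$b_out <- 0
  if (n_param_out > 0L) {
    w$Wp <- he(n_param_out, 2L * hidden)
    w$bp <- numeric(n_param_out)
  }
  w
}

.loss_kind <- c(aif = 1L, aif_param = 2L, aif_tissue = 3L)

#' Fit the bidirectional LSTM AIF correction network
#'
#' Trains a sequence-regression network that maps the saturated
#' (dictionary-converted) AIF, optionally stacked with tissue concentration
#' curves as additional channels, to the true AIF. The architecture is four
#' stacked bidirectional LSTM layers with 32 hidden units per direction, a
#' per-time-step linear read-out producing the corrected curve, and — for the
#' parameter and tissue losses — a linear head on the final concatenated
#' hidden state predicting the four compartment-model parameters per tissue
#' curve. Optimized with Adam (learning rate 3e-4, batch 16 by default); the
#' retained model is the epoch with the lowest validation curve L1 loss.
#'
#' Three loss functions are supported: `"aif"` is the mean absolute deviation
#' between predicted and true AIF; `"aif_param"` adds `beta/N` times the L1
#' loss of the predicted compartment parameters; `"aif_tissue"` adds
#' `delta/N` times the L1 loss between the measured tissue curves and the
#' compartment-model forward simulation driven by the predicted AIF and
#' predicted parameters (the convolution of [tissue_curve()], differentiable
#' w.r.t. curve and parameters, with the delay detached).
#'
#' @param data A [make_dataset()] object (train/val splits are used), or a
#'   list with arrays `x`, `y` (and `par`, `tissue` for the extra losses) as
#'   produced by [as_arrays()], plus `val_x`, `val_y`.
#' @param n_tissue Tissue input channels; defaults to what `data` carries.
#' @param loss `"aif"`, `"aif_param"` or `"aif_tissue"`.
#' @param alpha,beta,delta Loss-term weights.
#' @param epochs,batch_size,lr Optimization settings.
#' @param layers,hidden Architecture settings.
#' @param seed Seed for weight initialization and batch shuffling.
#' @param verbose Print per-epoch losses?
#' @return Object of class `aif_lstm`: list with `weights` (best epoch),
#'   `history` (data.frame epoch/train_loss/val_loss), `best_epoch`, `config`.
#' @examples
#' \donttest{
#' ds <- make_dataset(dataset_spec(n_train = 64, n_val = 16, n_test = 8,
#'                                 n_tissue = 2, seed = 5))
#' fit <- aif_lstm(ds, epochs = 2)
#' print(fit)
#' }
#' @export
aif_lstm <- function(data, n_tissue = NULL,
                     loss = c("aif", "aif_param", "aif_tissue"),
                     alpha = 1, beta = 1, delta = 1,
                     epochs = 100L, batch_size = 16L, lr = 3e-4,
                     layers = 4L, hidden = 32L, seed = 1L, verbose = FALSE) {
  loss <- match.arg(loss)
  if (inherits(data, "curve_dataset")) {
    tr <- as_arrays(data$train, n_tissue)
    va <- as_arrays(data$val, n_tissue)
    data <- list(x = tr$x, y = tr$y, par = tr$par, tissue = tr$tissue,
                 val_x = va$x, val_y = va$y)
    if (is.null(n_tissue)) n_tissue <- tr$n_tissue
  } else if (is.null(n_tissue)) {
    n_tissue <- dim(data$x)[2] - 1L
  }
  channels <- 1L + n_tissue
  if (dim(data$x)[2] != channels)
    stop(sprintf("input has %d channels, expected %d (1 + n_tissue)",
                 dim(data$x)[2], channels))
  kind <- .loss_kind[[loss]]
  if (kind > 1L && n_tissue == 0L)
    stop("parameter/tissue losses need at least one tissue curve")
  n_param_out <- if (kind > 1L) 4L * n_tissue else 0L
  T <- dim(data$x)[1]
  dt <- 1 / 120  # canonical grid step, minutes

  set.seed(seed)
  w0 <- init_weights(layers, hidden, channels, n_param_out)
  ptr <- cpp_net_create(w0, layers, hidden, channels, n_param_out, T)
  n <- dim(data$x)[3]
  par_m <- if (n_param_out > 0L) data$par else matrix(0, 0L, n)
  tis <- if (kind == 3L) data$tissue else array(0, c(T, 1L, n))

  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  best <- list(val = Inf, epoch = 0L, weights = w0)
  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    tl <- cpp_net_train_epoch(ptr, data$x, data$y, par_m, tis, ord,
                              as.integer(batch_size), lr, alpha, beta, delta,
                              kind, dt)
    if (!is.finite(tl))
      stop(sprintf("training diverged at epoch %d (loss = %g)", e, tl))
    vl <- cpp_net_l1(ptr, data$val_x, data$val_y, 64L)
    hist <- rbind(hist, data.frame(epoch = e, train_loss = tl, val_loss = vl))
    if (vl < best$val) {
      best$val <- vl; best$epoch <- e; best$weights <- cpp_net_weights(ptr)
    }
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f%s", e, tl, vl,
                      if (best$epoch == e) " *" else ""))
  }
  structure(list(weights = best$weights, history = hist,
                 best_epoch = best$epoch,
                 config = list(layers = layers, hidden = hidden,
                               channels = channels, n_tissue = n_tissue,
                               loss = loss, alpha = alpha, beta = beta,
                               delta = delta, epochs = epochs,
                               batch_size = batch_size, lr = lr, seed = seed,
                               t_len = T, n_param_out = n_param_out)),
            class = "aif_lstm")
}

# rebuild the C++ network from stored weights (pointers do not persist)
net_pointer <- function(object) {
  cfg <- object$config
  cpp_net_create(object$weights, cfg$layers, cfg$hidden, cfg$channels,
                 cfg$n_param_out, cfg$t_len)
}

#' Correct saturated AIFs with a trained network
#'
#' @param object An [aif_lstm()] fit.
#' @param newdata A `curve_dataset` split (list of `curve_set`), a single
#'   `curve_set`, or an array `time x channels x n`.
#' @param ... Unused.
#' @return Matrix `time x n` of corrected AIF curves (clipped at 0 from
#'   below); a vector for a single record.
#' @export
predict.aif_lstm <- function(object, newdata, ...) {
  single <- inherits(newdata, "curve_set")
  if (single) newdata <- list(newdata)
  if (is.list(newdata) && !is.array(newdata))
    newdata <- as_arrays(newdata, object$config$n_tissue)$x
  if (dim(newdata)[2] != object$config$channels)
    stop(sprintf("input has %d channels but the model expects %d",
                 dim(newdata)[2], object$config$channels))
  out <- cpp_net_predict(net_pointer(object), newdata, 64L)$pred
  out[out < 0] <- 0
  if (single) out[, 1] else out
}

#' Correct one saturated AIF
#'
#' Convenience wrapper around [predict.aif_lstm()] for a single record given
#' as raw curves.
#'
#' @param object An [aif_lstm()] fit.
#' @param saturated_aif Saturated AIF concentration curve.
#' @param tissue_curves List of tissue curves (must match the model's
#'   `n_tissue`; ordered by ascending ktrans).
#' @return Corrected AIF concentration curve.
#' @export
correct_aif <- function(object, saturated_aif, tissue_curves = list()) {
  nt <- object$config$n_tissue
  if (length(tissue_curves) != nt)
    stop(sprintf("model expects %d tissue curves, got %d", nt,
                 length(tissue_curves)))
  x <- array(0, c(length(saturated_aif), 1L + nt, 1L))
  x[, 1L, 1L] <- saturated_aif
  for (j in seq_len(nt)) x[, 1L + j, 1L] <- tissue_curves[[j]]
  predict(object, x)[, 1L]
}

#' Training-loss reference implementation
#'
#' Computes the three network losses for a single record in plain R, using
#' the same quadrature and delay handling as the generator and the C++
#' training path; used to validate the training implementation.
#'
#' @param loss `"aif"`, `"aif_param"` or `"aif_tissue"`.
#' @param pred_aif,true_aif Predicted and true AIF curves.
#' @param pred_params,true_params Matrices `4 x N` (rows ktrans, kep, vp,
#'   delta_t) for the parameter/tissue losses.
#' @param tissue_curves List of measured tissue curves (length N).
#' @param alpha,beta,delta Loss weights.
#' @param grid The [time_grid()].
#' @return Scalar loss value.
#' @export
compute_loss <- function(loss = c("aif", "aif_param", "aif_tissue"),
                         pred_aif, true_aif, pred_params = NULL,
                         true_params = NULL, tissue_curves = NULL,
                         alpha = 1, beta = 1, delta = 1,
                         grid = time_grid()) {
  loss <- match.arg(loss)
  out <- alpha * mean(abs(pred_aif - true_aif))
  if (loss == "aif") return(out)
  if (is.null(pred_params))
    stop("parameter/tissue losses need predicted parameters")
  N <- ncol(pred_params)
  if (loss == "aif_param") {
    out <- out + beta * sum(abs(pred_params - true_params)) / N
  } else {
    for (n in seq_len(N)) {
      p <- pred_params[, n]
      model <- tissue_curve(pred_aif,
                            list(ktrans = p[1], kep = max(0, p[2]),
                                 vp = p[3],
                                 delta_t = min(max(p[4], 0), 0.1)),
                            grid)
      out <- out + delta * mean(abs(tissue_curves[[n]] - model)) / N
    }
  }
  out
}

#' @export
print.aif_lstm <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<aif_lstm> %d-layer Bi-LSTM (%d hidden/dir), %d input",
                     " channel%s, '%s' loss\n"),
              cfg$layers, cfg$hidden, cfg$channels,
              if (cfg$channels > 1) "s" else "", cfg$loss))
  cat(sprintf("  %d parameters; best epoch %d/%d (val L1 %.5f)\n",
              lstm_param_count(cfg$layers, cfg$hidden, cfg$channels,
                               cfg$n_param_out),
              x$best_epoch, nrow(x$history), min(x$history$val_loss)))
  invisible(x)
}

#' @export
summary.aif_lstm <- function(object, ...) {
  print(object)
  h <- object$history
  cat(sprintf("  train loss %.5f -> %.5f over %d epochs\n",
              h$train_loss[1], h$train_loss[nrow(h)], nrow(h)))
  invisible(object)
}

#' @export
plot.aif_lstm <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "L1 loss", main = "training history", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
coef.aif_lstm <- function(object, ...) object$weights
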