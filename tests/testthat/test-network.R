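test_that("parameter count of the stack matches the closed form", {
  set.seed(51)
  w <- aifcorr:::init_weights(layers = 4, hidden = 32, channels = 11,
                              n_param_out = 40)
  expect_equal(sum(lengths(w)), lstm_param_count(4, 32, 11, 40))
  w1 <- aifcorr:::init_weights(4, 32, 1, 0)
  expect_equal(sum(lengths(w1)), lstm_param_count(4, 32, 1, 0))
  # He init: weight SD near sqrt(2/fan_in), biases zero
  expect_equal(stats::sd(w$W_2_f), sqrt(2 / 64), tolerance = 0.1)
  expect_true(all(w$b_1_f == 0))
  set.seed(51)
  expect_identical(w, aifcorr:::init_weights(4, 32, 11, 40))
})

test_that("loss reference: exact prediction gives zero, offsets give their L1", {
  g <- time_grid()
  set.seed(52)
  aif <- evaluate_aif(sample_aif_params(), g)
  expect_equal(compute_loss("aif", aif, aif), 0)
  expect_equal(compute_loss("aif", aif + 0.3, aif), 0.3)
  p <- matrix(c(0.5, 2, 0.02, 0.01), 4, 2)
  expect_equal(compute_loss("aif_param", aif, aif, p, p), 0)
  expect_equal(compute_loss("aif_param", aif, aif, p + 1, p, beta = 2),
               2 * 4 * 2 / 2)  # beta * sum|1| over 4 params x 2 curves / N
})

test_that("tissue loss is self-consistent with the curve generator", {
  g <- time_grid()
  set.seed(53)
  aif <- evaluate_aif(sample_aif_params(), g)
  pk <- ladder_pk_set(3)
  tiss <- lapply(seq_len(3), function(i) tissue_curve(aif, pk[i, ], g))
  pmat <- t(as.matrix(pk[, c("ktrans", "kep", "vp", "delta_t")]))
  val <- compute_loss("aif_tissue", aif, aif, pmat, pmat, tiss, delta = 1)
  expect_lt(val, 1e-6)
  # and invariant under reordering of the tissue curves
  ord <- c(3, 1, 2)
  val2 <- compute_loss("aif_tissue", aif, aif, pmat[, ord], pmat[, ord],
                       tiss[ord], delta = 1)
  expect_equal(val, val2, tolerance = 1e-12)
})

test_that("training decreases validation loss and is bitwise seed-reproducible", {
  ds <- cached("ds_net", quick_dataset(n_train = 96, n_val = 24, n_test = 16,
                                       n_tissue = 2, seed = 55))
  f1 <- cached("fit_small", aif_lstm(ds, epochs = 4, seed = 2))
  expect_lt(min(f1$history$val_loss), f1$history$val_loss[1])
  f2 <- aif_lstm(ds, epochs = 4, seed = 2)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
  expect_equal(f1$best_epoch, which.min(f1$history$val_loss))
})

test_that("prediction is batch-invariant, clipped at zero, channel-checked", {
  ds <- cached("ds_net", quick_dataset(n_train = 96, n_val = 24, n_test = 16,
                                       n_tissue = 2, seed = 55))
  fit <- cached("fit_small", aif_lstm(ds, epochs = 4, seed = 2))
  batch <- predict(fit, ds$test)
  single <- predict(fit, ds$test[[5]])
  expect_equal(single, batch[, 5], tolerance = 1e-5)
  expect_true(all(batch >= 0))
  expect_error(predict(fit, array(0, c(120, 7, 1))), "channels")
  expect_error(correct_aif(fit, ds$test[[1]]$saturated_aif, list()), "tissue")
  one <- correct_aif(fit, ds$test[[1]]$saturated_aif,
                     ds$test[[1]]$tissue_curves)
  expect_equal(one, batch[, 1], tolerance = 1e-5)
})

test_that("AIF-only input trains with a single channel", {
  ds <- cached("ds_net", quick_dataset(n_train = 96, n_val = 24, n_test = 16,
                                       n_tissue = 2, seed = 55))
  f0 <- aif_lstm(ds, n_tissue = 0, epochs = 2, seed = 3)
  expect_equal(f0$config$channels, 1)
  expect_equal(dim(predict(f0, ds$test)), c(120, 16))
})

test_that("auxiliary losses train and need tissue channels", {
  ds <- cached("ds_net", quick_dataset(n_train = 96, n_val = 24, n_test = 16,
                                       n_tissue = 2, seed = 55))
  fb <- aif_lstm(ds, loss = "aif_param", beta = 1, epochs = 2, seed = 4)
  expect_true(all(is.finite(fb$history$train_loss)))
  fd <- aif_lstm(ds, loss = "aif_tissue", delta = 1, epochs = 2, seed = 4)
  expect_true(all(is.finite(fd$history$train_loss)))
  expect_error(aif_lstm(ds, n_tissue = 0, loss = "aif_param", epochs = 1),
               "tissue")
})

test_that("model save/load round trip preserves predictions", {
  ds <- cached("ds_net", quick_dataset(n_train = 96, n_val = 24, n_test = 16,
                                       n_tissue = 2, seed = 55))
  fit <- cached("fit_small", aif_lstm(ds, epochs = 4, seed = 2))
  f <- tempfile(fileext = ".json")
  save_model(fit, f)
  fit2 <- load_model(f)
  expect_equal(predict(fit2, ds$test), predict(fit, ds$test))
})
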