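test_that("dataset generation is seed-reproducible with disjoint splits", {
  ds1 <- quick_dataset(n_train = 6, n_val = 3, n_test = 3, seed = 7)
  ds2 <- quick_dataset(n_train = 6, n_val = 3, n_test = 3, seed = 7)
  expect_identical(ds1$train, ds2$train)
  expect_identical(ds1$test, ds2$test)
  expect_equal(length(ds1$train), 6)
  expect_equal(length(ds1$val), 3)
  # splits come from different substreams: records differ
  expect_false(identical(ds1$train[[1]]$aif_params, ds1$test[[1]]$aif_params))
})

test_that("records carry the ladder and consistent curve layouts", {
  ds <- quick_dataset(n_train = 2, n_val = 1, n_test = 1, n_tissue = 10, seed = 8)
  s <- ds$train[[1]]
  expect_length(s$tissue_curves, 10)
  expect_equal(s$pk_params$ktrans, seq(0.3, 2.1, by = 0.2))
  expect_length(s$saturated_aif, 120)
  arr <- as_arrays(ds$train)
  expect_equal(dim(arr$x), c(120, 11, 2))
  expect_equal(arr$x[, 1, 1], s$saturated_aif)
  expect_equal(dim(arr$par), c(40, 2))
  expect_equal(arr$par[1, 1], 0.3)
})

test_that("nominal-bias noise-free acquisition round-trips through the full dictionary", {
  spec <- dataset_spec(n_tissue = 2, noisy = FALSE, inversion = "full", seed = 9)
  dict <- cached("dict_full", build_dictionary())
  set.seed(9)
  s <- make_curve_set(spec, dict_inv = dict, bias = bias_factors())
  perr <- 100 * (max(s$saturated_aif) - max(s$true_aif)) / max(s$true_aif)
  expect_lt(abs(perr), 0.5)
})

test_that("symmetric biases mostly underestimate the converted AIF peak", {
  sets <- cached("sets_bias_small", {
    spec <- dataset_spec(n_tissue = 3, pk_sampler = "random", seed = 10)
    dict <- cached("dict_t1", build_dictionary(model = "t1"))
    set.seed(10)
    lapply(1:150, function(i) make_curve_set(spec, dict_inv = dict))
  })
  frac_under <- mean(vapply(sets, function(s)
    max(s$saturated_aif) <= max(s$true_aif), logical(1)))
  expect_gt(frac_under, 0.75)
  perr <- vapply(sets, function(s)
    100 * (max(s$saturated_aif) - max(s$true_aif)) / max(s$true_aif), numeric(1))
  expect_lt(mean(perr), 0)
})

test_that("pixel-curve generator and k-means clustering recover the partition", {
  g <- time_grid()
  set.seed(41)
  aif <- evaluate_aif(sample_aif_params(), g)
  # degenerate: one cluster, no jitter, no noise -> identical curves
  px0 <- simulate_pixel_curves(aif, n_pixels = 8, n_clusters = 1,
                               jitter = 0, noise_frac = 0)
  expect_equal(max(apply(px0$curves, 1, function(r) diff(range(r)))), 0)
  # well-separated clusters are recovered against a direct group-mean oracle
  pk <- data.frame(ktrans = c(0.3, 2.1), kep = c(1.5, 8), vp = c(0.01, 0.04),
                   delta_t = c(0.01, 0.02))
  set.seed(42)
  px <- simulate_pixel_curves(aif, n_pixels = 60, n_clusters = 2,
                              jitter = 0.02, noise_frac = 0.01, pk = pk)
  centers <- cluster_tissue_curves(px$curves, 2)
  oracle <- vapply(split(seq_len(60), px$cluster),
                   function(i) rowMeans(px$curves[, i, drop = FALSE]),
                   numeric(g$n))
  oracle <- oracle[, order(apply(oracle, 2, max), decreasing = TRUE)]
  expect_lt(max(abs(centers - oracle)), 0.02)
  # k = 1 returns the pointwise mean
  expect_equal(cluster_tissue_curves(px$curves, 1)[, 1], rowMeans(px$curves))
  expect_error(cluster_tissue_curves(px$curves, 100), "between 1")
  # seeded determinism of the generator
  set.seed(43); a <- simulate_pixel_curves(aif, 10, 2)
  set.seed(43); b <- simulate_pixel_curves(aif, 10, 2)
  expect_identical(a, b)
})

test_that("preprocessing aligns measured curves shift-invariantly", {
  g <- time_grid()
  set.seed(44)
  curve <- evaluate_aif(sample_aif_params(1), g)
  # alignment is idempotent: an already-aligned curve passes through unchanged
  once <- preprocess_curve(g$t * 60, curve)
  twice <- preprocess_curve(g$t * 60, once)
  expect_equal(twice, once, tolerance = 1e-9)
  expect_equal(which(once > 0.1 * max(once))[1], 10)
  # identical curve with timestamps shifted by 3 s aligns to the same output
  shifted <- preprocess_curve(g$t * 60 + 3, curve)
  expect_lt(max(abs(shifted[1:100] - once[1:100])), 1e-9)
  # linear ramp sampled at 1 s is interpolated exactly (no alignment)
  ramp <- preprocess_curve(0:59, 0:59, align = FALSE)
  expect_equal(ramp[seq(1, 119, 2)], 0:59, tolerance = 1e-9)
  expect_error(preprocess_curve(c(1, 1), c(0, 1)), "increasing")
})

test_that("records and models survive a serialization round trip", {
  ds <- quick_dataset(n_train = 2, n_val = 1, n_test = 1, seed = 11)
  f <- tempfile(fileext = ".json")
  save_json(ds$train[[1]], f)
  expect_equal(load_json(f), ds$train[[1]])
  # manifest round trip regenerates the identical dataset
  f2 <- tempfile(fileext = ".json")
  save_json(ds, f2)
  ds2 <- load_json(f2)
  expect_identical(ds$train, ds2$train)
  # curve CSV round trip
  f3 <- tempfile(fileext = ".csv")
  write_curve_csv(f3, ds$train[[1]]$true_aif)
  expect_equal(read_curve_csv(f3)$value, ds$train[[1]]$true_aif)
})
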