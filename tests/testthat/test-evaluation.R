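test_that("percent error matches its definition", {
  expect_equal(percent_error(1, 1), 0)
  expect_equal(percent_error(1.5, 1.0), 50)
  expect_equal(percent_error(0.764, 1), -23.6, tolerance = 1e-9)
  expect_error(percent_error(1, 0), "zero")
})

test_that("perfect estimates collapse every report statistic", {
  g <- time_grid()
  set.seed(71)
  truths <- lapply(1:6, function(i) evaluate_aif(sample_aif_params(), g))
  rep <- evaluate_dataset(truths, truths)
  expect_equal(rep$peak_error_mean, 0)
  expect_equal(rep$peak_error_sd, 0)
  expect_equal(rep$pearson_r, 1)
  expect_equal(rep$fit_slope, 1, tolerance = 1e-9)
  expect_equal(rep$fit_intercept, 0, tolerance = 1e-9)
  expect_equal(rep$bland_altman_loa_low, 0)
  expect_equal(rep$bland_altman_loa_high, 0)
})

test_that("uniform scaling appears as a constant peak error", {
  g <- time_grid()
  set.seed(72)
  truths <- lapply(1:5, function(i) evaluate_aif(sample_aif_params(), g))
  rep <- evaluate_dataset(lapply(truths, `*`, 0.8), truths)
  expect_equal(rep$peak_error_mean, -20)
  expect_equal(rep$peak_error_sd, 0)
})

test_that("report statistics match a direct spreadsheet-style recomputation", {
  g <- time_grid()
  set.seed(73)
  truths <- lapply(1:10, function(i) evaluate_aif(sample_aif_params(), g))
  scale <- runif(10, 0.7, 1.2)
  ests <- Map(`*`, truths, scale)
  rep <- evaluate_dataset(ests, truths)
  pt <- vapply(truths, max, 0); pe <- pt * scale
  d <- pe - pt
  expect_equal(rep$peak_error_mean, mean(100 * (pe - pt) / pt), tolerance = 1e-6)
  expect_equal(rep$peak_error_sd, sd(100 * (pe - pt) / pt), tolerance = 1e-6)
  expect_equal(rep$pearson_r, cor(pt, pe), tolerance = 1e-6)
  lmfit <- stats::lm(pe ~ pt)
  expect_equal(rep$fit_slope, unname(coef(lmfit)[2]), tolerance = 1e-6)
  expect_equal(rep$fit_intercept, unname(coef(lmfit)[1]), tolerance = 1e-6)
  expect_equal(rep$bland_altman_bias, mean(d), tolerance = 1e-6)
  expect_equal(rep$bland_altman_loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-6)
})

test_that("Bland-Altman limits contain about 95% of Gaussian differences", {
  g <- time_grid()
  set.seed(74)
  base <- evaluate_aif(sample_aif_params(), g)
  truths <- replicate(400, base, simplify = FALSE)
  ests <- lapply(truths, function(x) x * (1 + rnorm(1, 0, 0.05)))
  rep <- evaluate_dataset(ests, truths)
  pe <- vapply(ests, max, 0); pt <- vapply(truths, max, 0)
  d <- pe - pt
  inside <- mean(d >= rep$bland_altman_loa_low & d <= rep$bland_altman_loa_high)
  expect_gte(inside, 0.93)
})

test_that("the report integrates ktrans fits when tissue curves are supplied", {
  g <- time_grid()
  set.seed(75)
  truths <- lapply(1:3, function(i) evaluate_aif(sample_aif_params(), g))
  pk <- sample_pk_params(2)
  tiss <- lapply(truths, function(a)
    lapply(1:2, function(j) tissue_curve(a, pk[j, ], g)))
  rep <- evaluate_dataset(truths, truths, tiss,
                          replicate(3, pk$ktrans, simplify = FALSE), g)
  expect_length(rep$ktrans_errors, 6)
  expect_lt(max(abs(rep$ktrans_errors)), 1)
  expect_equal(rep$pearson_r, 1, tolerance = 1e-4)
})
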