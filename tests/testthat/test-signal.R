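test_that("vectorized signal model agrees with the scalar recursion oracle", {
  set.seed(31)
  for (i in 1:20) {
    gd <- runif(1, 0, 10)
    b <- list(fa = runif(1, 0.9, 1.1), t2 = runif(1, 0.9, 1.1),
              rz = runif(1, -0.1, 0.1))
    expect_equal(
      simulate_signal(gd, bias = bias_factors(b$fa, b$t2, b$rz)),
      oracle_signal(gd, b$fa, b$t2, b$rz),
      tolerance = 1e-12)
  }
  # T1-only model too
  expect_equal(simulate_signal(5, model = "t1"),
               oracle_signal(5, model = "t1"), tolerance = 1e-12)
  expect_error(simulate_signal(-1), ">= 0")
})

test_that("single-excitation limit reduces to the closed form", {
  sq <- sequence_params(n_center_rays = 1)
  # fully recovered magnetization: SI = m0 sin(FA) exp(-TE R2*)
  b <- bias_factors(residual_mz = 1)  # start at m0; relaxation is then a no-op
  r2s <- 1 / sq$t2s_0_s + sq$r2s * 4
  expect_equal(simulate_signal(4, sq, b),
               sin(12 * pi / 180) * exp(-0.001 * r2s), tolerance = 1e-12)
})

test_that("signal increases with flip angle below 90 degrees", {
  lo <- simulate_signal(5, bias = bias_factors(fa_scale = 0.9))
  mid <- simulate_signal(5)
  hi <- simulate_signal(5, bias = bias_factors(fa_scale = 1.1))
  expect_true(lo < mid && mid < hi)
})

test_that("dictionary is strictly monotone, consistent, and validates input", {
  d <- cached("dict_full", build_dictionary())
  expect_true(all(diff(d$si_values) > 0))
  expect_equal(d$si_values[1], simulate_signal(0))
  expect_error(build_dictionary(gd_max = 1, gd_step = 2), "exceed")
  dt1 <- cached("dict_t1", build_dictionary(model = "t1"))
  expect_true(all(diff(dt1$si_values) > 0))
})

test_that("dictionary inversion round-trips and clamps out-of-range signal", {
  d <- cached("dict_full", build_dictionary())
  g <- time_grid()
  set.seed(32)
  aif <- evaluate_aif(sample_aif_params(), g)
  si <- concentration_to_signal(aif, bias = bias_factors())
  back <- signal_to_concentration(si, d)
  expect_lt(max(abs(back - aif)), 0.005)  # within one grid step
  expect_equal(signal_to_concentration(max(d$si_values) * 1.1, d), 12)
  expect_equal(signal_to_concentration(0, d), 0)
  expect_error(signal_to_concentration(numeric(0), d), "empty")
})

test_that("underscaled flip angle lowers the converted signal pointwise", {
  g <- time_grid()
  set.seed(33)
  aif <- evaluate_aif(sample_aif_params(), g)
  nom <- concentration_to_signal(aif)
  low <- concentration_to_signal(aif, bias = bias_factors(fa_scale = 0.9))
  expect_true(all(low <= nom))
})

test_that("bias sampler respects mode bounds and is seed-reproducible", {
  set.seed(34)
  for (i in 1:300) {
    b <- sample_bias("symmetric", 0.1)
    expect_true(b$fa_scale >= 0.9 && b$fa_scale <= 1.1)
    expect_true(abs(b$residual_mz) <= 0.1)
    o <- sample_bias("one_sided", 0.1)
    expect_true(o$fa_scale >= 1 && o$t2s_scale >= 1 && o$residual_mz >= 0)
  }
  set.seed(35); b1 <- sample_bias("symmetric")
  set.seed(35); b2 <- sample_bias("symmetric")
  expect_identical(b1, b2)
  expect_error(sample_bias(magnitude = 0.6), "magnitude")
})

test_that("noise level follows the tissue peaks and has the right spread", {
  g <- time_grid()
  tis <- list(rep(1, g$n), rep(3, g$n))      # peaks 1 and 3 -> sigma = 0.1
  set.seed(36)
  nz <- add_noise(numeric(g$n), tis)
  expect_equal(nz$sigma, 0.05 * 2)
  # doubling all tissue signal doubles sigma
  nz2 <- add_noise(numeric(g$n), lapply(tis, `*`, 2))
  expect_equal(nz2$sigma, 2 * nz$sigma)
  # empirical SD over many draws within 3% of sigma
  set.seed(37)
  draws <- replicate(100, add_noise(numeric(g$n), tis)$aif_si)
  expect_lt(abs(stats::sd(draws) / nz$sigma - 1), 0.03)
  # zero noise fraction is the identity
  nz0 <- add_noise(1:5, list(rep(1, 5)), frac = 0)
  expect_equal(nz0$aif_si, 1:5)
})
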