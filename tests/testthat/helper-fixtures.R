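# shared small fixtures and a per-session cache so expensive objects
# (datasets, trained models) are built once and reused across test files
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

quick_dataset <- function(n_train = 64, n_val = 16, n_test = 16, n_tissue = 2,
                          seed = 42, ...) {
  make_dataset(dataset_spec(n_train = n_train, n_val = n_val, n_test = n_test,
                            n_tissue = n_tissue, seed = seed, ...))
}

# independent scalar Bloch recursion (plain loop, doubles) used as the oracle
# for the vectorized signal model
oracle_signal <- function(gd, fa_scale = 1, t2s_scale = 1, resid = 0,
                          model = "full", seq = sequence_params()) {
  R1 <- 1 / seq$t1_0_s + seq$r1 * gd
  fa <- seq$flip_angle_deg * fa_scale * pi / 180
  mz <- seq$m0 + (resid * seq$m0 - seq$m0) * exp(-R1 * seq$srt_ms / 1000)
  s <- 0
  for (r in seq_len(seq$n_center_rays)) {
    si <- mz * sin(fa)
    if (model == "full")
      si <- si * exp(-(seq$te_ms / 1000) *
                       (1 / (seq$t2s_0_s * t2s_scale) + seq$r2s * gd))
    s <- s + si
    mz <- seq$m0 + (mz * cos(fa) - seq$m0) * exp(-R1 * seq$tr_ms / 1000)
  }
  s / seq$n_center_rays
}
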