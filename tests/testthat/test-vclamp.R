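vc_cell <- function(...) {
  cell_params(noise_sd_pA = 0, noise_sd_mV = 0, latency_jitter = 0, ...)
}

leak_only <- function() {
  vc_cell(vg_inward = c(peak = 0, half = -30, slope = 6, decay = 4),
          vg_outward = c(peak = 0, half = -10, slope = 12, rise = 8),
          persistent_pA_per_mV = 0)
}

test_that("the -10 mV sweep subtracted against itself is exactly zero", {
  sim <- simulate_voltage_clamp(leak_only(), quick_vc(), seed = 1)
  sub <- leak_subtract(sim$sweeps)
  lev <- vapply(sub, function(s) s$command_level, numeric(1))
  leak <- sub[[which(lev == -10)]]
  expect_true(all(leak$samples == 0))
})

test_that("leak subtraction removes ohmic current to numerical tolerance", {
  sim <- simulate_voltage_clamp(leak_only(), quick_vc(), seed = 1)
  sub <- lapply(leak_subtract(sim$sweeps), zero_baseline)
  for (s in sub) expect_lt(max(abs(s$samples)), 1e-9)
})

test_that("leak subtraction leaves the active component (vs ground truth)", {
  p <- vc_cell()
  sim <- simulate_voltage_clamp(p, quick_vc(), seed = 1)
  sub <- lapply(leak_subtract(sim$sweeps), zero_baseline)
  feats <- vclamp_features(sub)
  expect_equal(feats$early_inward_pA, sim$truth$early_inward_pA,
               tolerance = 1e-9)
  expect_equal(feats$early_outward_pA, sim$truth$early_outward_pA,
               tolerance = 1e-9)
  expect_equal(feats$late_mean_pA, sim$truth$late_mean_pA, tolerance = 1e-9)
})

test_that("leak subtraction requires the -10 mV sweep and is linear", {
  sim <- simulate_voltage_clamp(leak_only(), quick_vc(), seed = 1)
  keep <- vapply(sim$sweeps, function(s) s$command_level != -10, logical(1))
  expect_error(leak_subtract(sim$sweeps[keep]), "impossible")
  # linearity: scaling a pure-leak trace scales the residual exactly
  sw <- sim$sweeps
  target <- which(vapply(sw, function(s) s$command_level == 50, logical(1)))
  sw2 <- sw
  sw2[[target]]$samples <- sw[[target]]$samples * 3
  r1 <- leak_subtract(sw)[[target]]$samples
  r2 <- leak_subtract(sw2)[[target]]$samples
  base <- sw[[target]]$samples
  leak_scaled <- base - r1
  expect_equal(r2, 3 * base - leak_scaled, tolerance = 1e-12)
})

test_that("zeroing removes a uniform offset and is idempotent", {
  sim <- simulate_voltage_clamp(leak_only(), quick_vc(), seed = 1)
  s <- sim$sweeps[[3]]
  s$samples <- s$samples + 37
  z <- zero_baseline(s)
  t <- sweep_times(z)
  expect_equal(mean(z$samples[t < z$step_onset]), 0, tolerance = 1e-12)
  z2 <- zero_baseline(z)
  expect_equal(z2$samples, z$samples, tolerance = 1e-12)
  short <- new_sweep(rep(0, 100), 10000, -10, 0.005, 0.009,
                     mode = "voltage_clamp")
  expect_error(zero_baseline(short), "10 ms")
})

test_that("zeroed noisy baselines scatter as noise_sd/sqrt(n_pre)", {
  set.seed(5)
  rate <- 10000
  n_pre <- 200
  sd0 <- 8
  means <- replicate(500, {
    v <- rnorm(600, 50, sd0)
    s <- new_sweep(v, rate, 20, n_pre / rate, 400 / rate,
                   mode = "voltage_clamp")
    z <- zero_baseline(s)
    mean(z$samples[seq_len(n_pre)])
  })
  expect_equal(mean(means), 0, tolerance = 1e-10)
  # the post-zeroing baseline mean of fresh draws has sd ~ sd0/sqrt(n_pre)
  fresh <- replicate(500, {
    v <- rnorm(600, 50, sd0)
    s <- new_sweep(v, rate, 20, n_pre / rate, 400 / rate,
                   mode = "voltage_clamp")
    z <- zero_baseline(s)
    mean(z$samples[201:400])
  })
  expect_equal(sd(fresh), sd0 * sqrt(2 / n_pre), tolerance = 0.15)
})

test_that("feature extraction demands prior leak subtraction and zeroing", {
  sim <- simulate_voltage_clamp(vc_cell(), quick_vc(), seed = 1)
  expect_error(vclamp_features(sim$sweeps), "leak-subtracted")
  short_proto <- voltage_clamp_protocol(pre_s = 0.02, step_s = 0.005,
                                        post_s = 0.02)
  sim2 <- simulate_voltage_clamp(vc_cell(), short_proto, seed = 1)
  sub2 <- lapply(leak_subtract(sim2$sweeps), zero_baseline)
  expect_error(vclamp_features(sub2), "shorter than the early window")
})

test_that("features respect the sign contract and ignore sweep order", {
  p <- vc_cell()
  sim <- simulate_voltage_clamp(p, quick_vc(), seed = 2)
  sub <- lapply(leak_subtract(sim$sweeps), zero_baseline)
  f1 <- vclamp_features(sub)
  expect_true(all(f1$early_inward_pA <= 0))
  expect_true(all(f1$early_outward_pA >= 0))
  f2 <- vclamp_features(rev(sub))
  expect_equal(f1, f2)
})

test_that("persistent component sets the late mean (closed form)", {
  p <- vc_cell(vg_inward = c(peak = 0, half = -30, slope = 6, decay = 4),
               vg_outward = c(peak = 0, half = -10, slope = 12, rise = 8),
               persistent_pA_per_mV = 2)
  sim <- simulate_voltage_clamp(p, quick_vc(), seed = 1)
  sub <- lapply(leak_subtract(sim$sweeps), zero_baseline)
  f <- vclamp_features(sub)
  expect_equal(f$late_mean_pA[f$injection_mV == 100], 200, tolerance = 1e-9)
  expect_equal(f$late_mean_pA[f$injection_mV == 50], 100, tolerance = 1e-9)
})

test_that("cell-level maxima: monotone outward peaks at 100 mV; zeros stay 0", {
  p <- vc_cell(vg_inward = c(peak = 0, half = -30, slope = 6, decay = 4),
               persistent_pA_per_mV = 0)
  sim <- simulate_voltage_clamp(p, quick_vc(), seed = 1)
  sub <- lapply(leak_subtract(sim$sweeps), zero_baseline)
  f <- vclamp_features(sub)
  expect_equal(f$injection_mV[which.max(f$early_outward_pA)], 100)
  s <- cell_vclamp_summary(f)
  expect_equal(s$max_outward_pA, max(f$early_outward_pA))
  zeros <- f
  zeros$early_inward_pA <- 0
  zeros$early_outward_pA <- 0
  s0 <- cell_vclamp_summary(zeros)
  expect_equal(s0$max_inward_pA, 0)
  expect_equal(s0$max_outward_pA, 0)
})
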