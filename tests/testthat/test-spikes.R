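flat_sweep <- function(v, rate = 10000, amp = 200, onset = 0.05,
                       offset = 0.25) {
  new_sweep(v, rate, amp, onset, offset, mode = "current_clamp")
}

test_that("flat and sub-criterion traces yield no spikes", {
  s <- flat_sweep(rep(-60, 3000))
  expect_equal(nrow(detect_spikes(s)), 0)
  # ramp with maximum slope 20 mV/ms, then decay: below the up criterion
  v <- c(rep(-60, 500), -60 + cumsum(rep(2, 50)), seq(40, -60, -1),
         rep(-60, 3000))[1:3000]
  expect_equal(nrow(detect_spikes(flat_sweep(v))), 0)
})

test_that("a template spike peaking below 0 mV is rejected", {
  v <- rep(-60, 3000)
  bump <- c(seq(0, 55, length.out = 12), seq(55, 0, length.out = 12)[-1])
  v[1000:(1000 + length(bump) - 1)] <- v[1000:(1000 + length(bump) - 1)] + bump
  s <- flat_sweep(v)
  expect_equal(nrow(detect_spikes(s)), 0)     # peak -5 mV
  v2 <- v + 10                                 # same shape, peak +5 mV
  expect_equal(nrow(detect_spikes(flat_sweep(v2))), 1)
})

test_that("detection errors on sweeps shorter than the pairing window", {
  expect_error(detect_spikes(flat_sweep(rep(-60, 50), onset = 0.001,
                                        offset = 0.004)),
               "shorter than the pairing window")
})

test_that("detection matches the exhaustive brute-force oracle", {
  set.seed(1234)
  n_agree <- 0
  for (i in 1:200) {
    v <- random_spiky_trace()
    s <- flat_sweep(v)
    got <- detect_spikes(s)
    want <- oracle_detect(v, 10000)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$upcross_time, want$upcross_time)
      expect_equal(got$peak_time, want$peak_time)
      expect_equal(got$peak_voltage, want$peak_voltage)
    }
    n_agree <- n_agree + identical(
      round(got$upcross_time, 10), round(want$upcross_time, 10))
  }
  expect_equal(n_agree, 200)
})

test_that("spikes are classified by the half-open depolarizing window", {
  bump <- c(seq(0, 80, length.out = 10), seq(80, -5, length.out = 12)[-1])
  place <- function(at, amp) {
    v <- rep(-60, 4000)
    v[at:(at + length(bump) - 1)] <- v[at:(at + length(bump) - 1)] + bump
    new_sweep(v, 10000, amp, 0.1, 0.3, mode = "current_clamp")
  }
  cls <- function(s) classify_spikes(detect_spikes(s), s)$classification
  expect_equal(cls(place(500, 200)), "spontaneous")   # before onset
  expect_equal(cls(place(2000, 200)), "evoked")       # inside window
  expect_equal(cls(place(2000, -100)), "rebound")     # non-depolarizing step
  expect_equal(cls(place(3500, 200)), "rebound")      # after offset
  # up-cross exactly at the offset sample: half-open window -> rebound
  s <- place(3001, 200)
  ev <- classify_spikes(detect_spikes(s), s)
  expect_equal(ev$classification, "rebound")
})

test_that("half-amplitude width of a symmetric triangle equals half its base", {
  # triangular spike above threshold -60: base 2 ms, amplitude 80 mV
  v <- rep(-60, 3000)
  up <- seq(-60, 20, length.out = 11)     # 1 ms rise at 10 kHz
  dn <- seq(20, -72, length.out = 12)[-1] # continues below threshold
  v[1500:(1500 + 21)] <- c(up, dn)
  s <- flat_sweep(v)
  ev <- spike_features(detect_spikes(s), s)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$threshold_voltage, -60, tolerance = 1e-6)
  expect_equal(ev$amplitude, 80, tolerance = 1e-6)
  expect_equal(ev$width, 1, tolerance = 0.06)   # within one sample equivalent
  expect_true(ev$width_defined)
})

test_that("a spike that never re-crosses threshold has no width", {
  v <- c(rep(-60, 1500), seq(-60, 30, length.out = 12),
         seq(30, -40, length.out = 31)[-1],
         rep(-40, 3000))[1:3000]            # stays above -60 to sweep end
  s <- flat_sweep(v)
  ev <- spike_features(detect_spikes(s), s)
  expect_equal(nrow(ev), 1)
  expect_false(ev$width_defined)
  expect_true(is.na(ev$width))
  expect_true(is.na(ev$end_time))
})

test_that("F-I curve averages evoked counts and proportions over repetitions", {
  co <- make_cohort(cohort_design(c("WT" = 1)), seed = 21,
                    cc_protocol = quick_cc(reps = 2),
                    vc_protocol = quick_vc(), tp_protocol = quick_tp(),
                    conditions = "from_rest", noiseless = TRUE)
  cell <- co$cells[[1]]
  fi <- fi_curve(cell$recordings$from_rest)
  expect_equal(nrow(fi), 30)
  tr <- cell$truth$spikes
  rec <- cell$recordings$from_rest
  on <- 0.05; off <- 0.25
  for (a in fi$amplitude_pA) {
    tr_a <- tr[tr$amplitude_pA == a &
                 tr$threshold_time_s >= on & tr$threshold_time_s < off &
                 a > 0, , drop = FALSE]
    expect_equal(fi$mean_spike_count[fi$amplitude_pA == a],
                 nrow(tr_a) / 2)
  }
  sub <- fi[fi$mean_spike_count == 0, ]
  expect_true(all(sub$prop_one_or_more == 0))
  expect_true(all(sub$prop_exactly_one == 0))
})

test_that("rheobase is the minimum amplitude firing in any repetition", {
  co <- make_cohort(cohort_design(c("WT" = 1)), seed = 31,
                    cc_protocol = quick_cc(reps = 2),
                    vc_protocol = quick_vc(), tp_protocol = quick_tp(),
                    conditions = "from_rest", noiseless = TRUE)
  cell <- co$cells[[1]]
  rf <- rheobase_features(cell$recordings$from_rest)
  tr <- cell$truth$spikes
  evoked <- tr[tr$amplitude_pA > 0 &
                 tr$threshold_time_s >= 0.05 & tr$threshold_time_s < 0.25, ]
  expect_equal(rf$rheobase_pA, min(evoked$amplitude_pA))
  first_truth <- evoked[evoked$amplitude_pA == rf$rheobase_pA, ]
  first_truth <- first_truth[order(first_truth$repetition,
                                   first_truth$threshold_time_s), ][1, ]
  expect_equal(rf$first_spike$threshold_voltage, first_truth$threshold_mV,
               tolerance = 0.5)
  expect_equal(rf$first_spike$amplitude, first_truth$amplitude_mV,
               tolerance = 0.5)
  expect_gt(rf$first_spike$latency, 0)
  expect_lte(rf$first_spike$latency, 200)   # step duration in ms
})

test_that("no evoked spikes means rheobase is absent", {
  p_design <- cohort_design(c("WT" = 1))
  p_design$WT$params$spike_threshold <- 60   # far above any reachable V
  co <- make_cohort(p_design, seed = 41, cc_protocol = quick_cc(reps = 1),
                    vc_protocol = quick_vc(), tp_protocol = quick_tp(),
                    conditions = "from_rest", noiseless = TRUE)
  expect_null(rheobase_features(co$cells[[1]]$recordings$from_rest))
})

test_that("raising the generator threshold never lowers estimated rheobase", {
  thresholds <- seq(-48, -29, by = 1)
  rheo <- numeric(length(thresholds))
  proto <- quick_cc(reps = 1)
  for (i in seq_along(thresholds)) {
    p <- cell_params(spike_threshold = thresholds[i], noise_sd_mV = 0,
                     latency_jitter = 0)
    sim <- simulate_current_clamp(p, proto, seed = 51)
    rec <- new_cell_recording("m", "WT", "vehicle", "from_rest", -65,
                              sweeps = list(current_clamp = sim$sweeps))
    rf <- rheobase_features(rec)
    rheo[i] <- if (is.null(rf)) Inf else rf$rheobase_pA
  }
  expect_true(all(diff(rheo) >= 0))
})
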