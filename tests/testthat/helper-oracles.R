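# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles are written sample-by-sample, sharing no code with the
# package implementations they check.

# Exhaustive crossing-pair spike detector: scalar loops over every sample,
# enumerating all up-/down-crossings of the slope criteria, pairing them
# greedily left to right, and applying the peak rule.
oracle_detect <- function(v, rate, up = 30, down = -15, win_ms = 10,
                          min_peak = 0) {
  n <- length(v)
  dtms <- 1000 / rate
  slope <- numeric(n - 1)
  for (i in 1:(n - 1)) slope[i] <- (v[i + 1] - v[i]) / dtms
  ups <- integer(0)
  dns <- integer(0)
  for (i in 1:(n - 1)) {
    prev <- if (i == 1) -Inf else slope[i - 1]
    if (slope[i] >= up && prev < up) ups <- c(ups, i)
    prevd <- if (i == 1) Inf else slope[i - 1]
    if (slope[i] <= down && prevd > down) dns <- c(dns, i)
  }
  win_n <- round(win_ms / dtms)
  out <- NULL
  consumed <- 0
  for (u in ups) {
    if (u <= consumed) next
    d_found <- NA
    for (d in dns) {
      if (d > u && d <= u + win_n) { d_found <- d; break }
    }
    if (is.na(d_found)) next
    pk <- u
    for (i in u:(d_found + 1)) if (v[i] > v[pk]) pk <- i
    if (v[pk] <= min_peak) next
    out <- rbind(out, data.frame(
      upcross_time = (u - 1) / rate,
      peak_time = (pk - 1) / rate,
      peak_voltage = v[pk]
    ))
    consumed <- d_found
  }
  if (is.null(out)) {
    out <- data.frame(upcross_time = numeric(), peak_time = numeric(),
                      peak_voltage = numeric())
  }
  out
}

# Random trace containing a random number of triangular bumps with random
# amplitudes/widths (some violating the slope, window or peak criteria) on a
# slowly wandering baseline plus Gaussian noise.
random_spiky_trace <- function(n = 3000, rate = 10000) {
  v <- -60 + cumsum(rnorm(n, 0, 0.05))
  k <- sample(0:6, 1)
  if (k > 0) {
    for (pos in sort(sample(seq(50, n - 200), k))) {
      amp <- runif(1, 10, 110)          # some bumps peak below 0 mV
      w_samp <- sample(3:60, 1)          # some rise slower than 30 mV/ms
      bump <- c(seq(0, amp, length.out = w_samp + 1),
                seq(amp, -10, length.out = 2 * w_samp + 1)[-1])
      idx <- pos:(pos + length(bump) - 1)
      v[idx] <- v[idx] + bump
    }
  }
  v
}

# Direct Greenhouse-Geisser epsilon via an orthonormal contrast matrix
# applied to the pooled within-group covariance.
oracle_gg_epsilon <- function(wide, group) {
  k <- ncol(wide)
  s <- matrix(0, k, k)
  dof <- 0
  for (g in unique(group)) {
    m <- wide[group == g, , drop = FALSE]
    if (nrow(m) < 2) next
    mc <- sweep(m, 2, colMeans(m))
    s <- s + t(mc) %*% mc
    dof <- dof + nrow(m) - 1
  }
  s <- s / dof
  cm <- t(qr.Q(qr(cbind(1, contr.helmert(k))))[, -1])   # (k-1) x k orthonormal
  m <- cm %*% s %*% t(cm)
  lam <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  sum(lam)^2 / ((k - 1) * sum(lam^2))
}

# Small protocols for fast cohort-based tests.
quick_cc <- function(start = -100, stop = 480, by = 20, reps = 2) {
  current_clamp_protocol(start, stop, by, repetitions = reps,
                         pre_s = 0.05, step_s = 0.2, post_s = 0.1)
}
quick_vc <- function() {
  voltage_clamp_protocol(pre_s = 0.02, step_s = 0.12, post_s = 0.04)
}
quick_tp <- function() {
  test_pulse_protocol(pre_s = 0.02, step_s = 0.06, post_s = 0.02)
}
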