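#' Passive membrane properties from membrane-test pulses
#'
#' Test-pulse sweeps are averaged across repetitions, the baseline current is
#' taken from the pre-step epoch, and the step-evoked current is fitted (from
#' one sample after the step edge, to avoid the command discontinuity) with
#' the single-exponential membrane-test model
#' `I(t) = I_ss + (I_peak - I_ss) * exp(-t / tau)`, `t` measured from the
#' step onset. Then
#' `R_s = dV / (I_peak - I_baseline)`,
#' `R_in = dV / (I_ss - I_baseline) - R_s`, and
#' `C_m = tau * (R_in + R_s) / (R_in * R_s)`.
#' When the transient is too fast to resolve (shorter than one sample) the
#' input resistance is recovered from the steady state alone and the
#' capacitance and series resistance are flagged unreliable (`NA`).
#'
#' @param test_sweeps List of voltage-clamp sweeps at a single nonzero test
#'   pulse.
#' @param resting_potential Resting potential (mV) to pass through, or `NA`.
#' @return A list of class `"passive_properties"`: `r_input_MOhm`,
#'   `r_series_MOhm`, `c_m_pF`, `v_rest_mV`, `fit_rss`,
#'   `capacitance_reliable`.
#' @export
estimate_passive <- function(test_sweeps, resting_potential = NA_real_) {
  if (!length(test_sweeps)) stop("at least one test-pulse sweep is required")
  dv <- unique(vapply(test_sweeps, function(s) s$command_level, numeric(1)))
  if (length(dv) != 1L) stop("test-pulse sweeps must share one pulse amplitude")
  if (dv == 0) stop("test pulse amplitude must be nonzero")
  s1 <- test_sweeps[[1]]
  rate <- s1$sampling_rate
  avg <- Reduce(`+`, lapply(test_sweeps, function(s) s$samples)) /
    length(test_sweeps)

  t <- sweep_times(s1)
  pre <- which(t < s1$step_onset - 1e-12)
  step_idx <- step_window_indices(s1)
  i_base <- mean(avg[pre])
  n_late <- max(1L, as.integer(floor(length(step_idx) / 3)))
  i_ss0 <- mean(avg[tail(step_idx, n_late)])
  if (abs(i_ss0 - i_base) < 1e-12) {
    stop("steady-state current equals the baseline: infinite input resistance")
  }

  fit_idx <- step_idx[-1]                    # one sample after the edge
  trel <- t[fit_idx] - s1$step_onset
  y <- avg[fit_idx]

  # initial decay constant from the 1/e point of the transient
  a0 <- y[1] - i_ss0
  below <- which(abs(y - i_ss0) < abs(a0) / exp(1))
  tau0 <- if (length(below)) max(trel[below[1]], 2 / rate) else 5 / rate
  tau_max <- max(trel)
  tau0 <- min(tau0, tau_max / 3)
  b0 <- a0 * exp(trel[1] / tau0)

  transient_resolved <- abs(a0) >
    max(6 * sd(avg[pre]), 1e-9, 0.02 * abs(i_ss0 - i_base))
  fit <- NULL
  if (transient_resolved) {
    do_fit <- function(idx_sub) {
      tryCatch(
        minpack.lm::nlsLM(
          y[idx_sub] ~ iss + b * exp(-trel[idx_sub] / tau),
          start = list(iss = i_ss0, b = b0, tau = tau0),
          lower = c(iss = -Inf, b = -Inf, tau = 0.5 / rate),
          upper = c(iss = Inf, b = Inf, tau = tau_max),
          control = minpack.lm::nls.lm.control(ftol = 1e-12, maxiter = 200)
        ),
        error = function(e) NULL
      )
    }
    fit <- do_fit(seq_along(y))
    plausible <- function(f) {
      if (is.null(f)) return(FALSE)
      cf <- coef(f)
      sign(cf[["b"]]) == sign(dv) && cf[["tau"]] < tau_max / 3
    }
    if (!plausible(fit)) {
      # transient-dominated refit window: the first ~20 initial decay
      # constants, where the exponential carries the information
      n_win <- min(length(y), max(20L, as.integer(round(20 * tau0 * rate))))
      fit2 <- do_fit(seq_len(n_win))
      if (plausible(fit2)) fit <- fit2
    }
  }
  if (is.null(fit)) {
    r_total <- dv / (i_ss0 - i_base) * 1000          # MOhm
    out <- list(
      r_input_MOhm = r_total, r_series_MOhm = NA_real_, c_m_pF = NA_real_,
      v_rest_mV = resting_potential,
      fit_rss = sum((y - i_ss0)^2), capacitance_reliable = FALSE
    )
    class(out) <- "passive_properties"
    return(out)
  }
  cf <- coef(fit)
  i_ss <- cf[["iss"]]
  i_peak <- cf[["iss"]] + cf[["b"]]
  tau <- cf[["tau"]]
  r_s <- dv / (i_peak - i_base) * 1000               # mV/pA -> GOhm -> MOhm
  r_in <- dv / (i_ss - i_base) * 1000 - r_s
  if (!is.finite(r_s) || !is.finite(r_in) || r_s <= 0 || r_in <= 0) {
    stop("passive fit produced non-physical resistances; ",
         "transient may be non-decaying (R_s = ", signif(r_s, 4),
         ", R_in = ", signif(r_in, 4), " MOhm)")
  }
  c_m <- tau * (r_in + r_s) / (r_in * r_s) * 1e6     # s/MOhm -> pF
  out <- list(
    r_input_MOhm = r_in, r_series_MOhm = r_s, c_m_pF = c_m,
    v_rest_mV = resting_potential,
    fit_rss = sum(resid(fit)^2), capacitance_reliable = TRUE
  )
  class(out) <- "passive_properties"
  out
}

#' @export
print.passive_properties <- function(x, ...) {
  cat(sprintf(
    "<passive_properties> R_in = %.1f MOhm, R_s = %.1f MOhm, C_m = %.1f pF, V_rest = %.1f mV%s\n",
    x$r_input_MOhm, x$r_series_MOhm, x$c_m_pF, x$v_rest_mV,
    if (!x$capacitance_reliable) " [capacitance unreliable]" else ""
  ))
  invisible(x)
}
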