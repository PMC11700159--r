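#' Ohmic leak subtraction of voltage-clamp sweeps
#'
#' The smallest negative step (-10 mV) is taken as the measure of passive
#' current through leak channels and capacitance; its trace (averaged across
#' repetitions when present) is scaled linearly by the applied voltage and
#' subtracted from every sweep. The -10 mV sweep subtracted against itself
#' yields an identically zero trace.
#'
#' @param sweeps List of voltage-clamp sweeps from one protocol run,
#'   including the -10 mV injection.
#' @param leak_level Injection used as the leak measure, mV (default -10).
#' @return The sweeps with samples leak-subtracted; each carries attribute
#'   `leak_subtracted = TRUE`.
#' @export
leak_subtract <- function(sweeps, leak_level = -10) {
  lev <- vapply(sweeps, function(s) s$command_level, numeric(1))
  is_leak <- abs(lev - leak_level) < 1e-9
  if (!any(is_leak)) {
    stop("no ", leak_level, " mV leak step among the sweeps: ",
         "leak subtraction impossible")
  }
  leak_traces <- lapply(sweeps[is_leak], function(s) s$samples)
  leak <- Reduce(`+`, leak_traces) / length(leak_traces)
  lapply(sweeps, function(s) {
    s$samples <- s$samples - (s$command_level / leak_level) * leak
    attr(s, "leak_subtracted") <- TRUE
    s
  })
}

#' Zero a sweep on its pre-step baseline
#'
#' Subtracts the mean current of the pre-step epoch from the whole trace.
#'
#' @param sweep A voltage-clamp sweep with at least 10 ms of pre-step epoch.
#' @return The zeroed sweep, with attribute `zeroed = TRUE`.
#' @export
zero_baseline <- function(sweep) {
  if (sweep$step_onset < 0.010 - 1e-12) {
    stop("pre-step epoch shorter than 10 ms: cannot zero the baseline")
  }
  t <- sweep_times(sweep)
  pre <- which(t < sweep$step_onset - 1e-12)
  sweep$samples <- sweep$samples - mean(sweep$samples[pre])
  attr(sweep, "zeroed") <- TRUE
  sweep
}

#' Early extrema and late steady-state currents per voltage injection
#'
#' For each injection, the maximum inward (most negative, reported as <= 0)
#' and maximum outward (>= 0) currents within the first `early_ms` of the
#' step, and the mean current over the final `late_fraction` of the step.
#' Sweeps must already be leak-subtracted and zeroed; repetitions are
#' averaged.
#'
#' @param sweeps Leak-subtracted, zeroed voltage-clamp sweeps.
#' @param early_ms Early window length, ms (default 10).
#' @param late_fraction Trailing fraction of the step for the steady state
#'   (default 1/3).
#' @return A tibble sorted by injection: `injection_mV`, `early_inward_pA`,
#'   `early_outward_pA`, `late_mean_pA`.
#' @export
vclamp_features <- function(sweeps, early_ms = 10, late_fraction = 1 / 3) {
  ok <- vapply(sweeps, function(s) {
    isTRUE(attr(s, "leak_subtracted")) && isTRUE(attr(s, "zeroed"))
  }, logical(1))
  if (!all(ok)) {
    stop("sweeps must be leak-subtracted and zeroed before feature extraction")
  }
  rows <- lapply(sweeps, function(s) {
    rate <- s$sampling_rate
    step_idx <- step_window_indices(s)
    early_n <- as.integer(round(early_ms / 1000 * rate))
    if (length(step_idx) < early_n) {
      stop("voltage step shorter than the early window")
    }
    early <- s$samples[step_idx[seq_len(early_n)]]
    n_late <- as.integer(floor(length(step_idx) * late_fraction))
    late <- s$samples[tail(step_idx, n_late)]
    data.frame(
      injection_mV = s$command_level,
      early_inward_pA = min(0, min(early)),
      early_outward_pA = max(0, max(early)),
      late_mean_pA = mean(late)
    )
  })
  dt <- do.call(rbind, rows)
  agg <- aggregate(dt[-1], by = list(injection_mV = dt$injection_mV), mean)
  tibble::as_tibble(agg[order(agg$injection_mV), ])
}

#' Per-cell maximum inward and outward currents across injections
#'
#' The cell-level maximum inward current is the most negative early inward
#' current across the depolarizing injections (0 to 100 mV); the maximum
#' outward current is the largest early outward current. The -10 mV leak
#' step (identically zero after self-subtraction) is excluded.
#'
#' @param features Tibble from [vclamp_features()].
#' @return A list with `max_inward_pA` and `max_outward_pA`.
#' @export
cell_vclamp_summary <- function(features) {
  f <- features[features$injection_mV >= 0, , drop = FALSE]
  if (!nrow(f)) f <- features
  list(
    max_inward_pA = min(f$early_inward_pA),
    max_outward_pA = max(f$early_outward_pA)
  )
}

#' @importFrom stats aggregate
NULL
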