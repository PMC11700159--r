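#' Construct a step protocol
#'
#' A step protocol is the stimulus grid of an episodic recording: an ordered
#' set of step amplitudes (relative to holding), a common pre/step/post
#' timing, and a repetition count. The command equals the holding level
#' outside the half-open step window and holding + amplitude inside it.
#'
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param holding_level Holding current (pA) or potential (mV).
#' @param pre_s,step_s,post_s Durations in seconds; all must be positive.
#' @param amplitudes Strictly increasing, unique step amplitudes.
#' @param repetitions Number of repetitions of the full grid (>= 1).
#' @return An object of class `"step_protocol"`.
#' @export
step_protocol <- function(mode = c("current_clamp", "voltage_clamp"),
                          holding_level, pre_s, step_s, post_s,
                          amplitudes, repetitions = 1L) {
  mode <- match.arg(mode)
  amplitudes <- as.numeric(amplitudes)
  if (any(diff(amplitudes) <= 0)) {
    stop("protocol amplitudes must be strictly increasing and unique")
  }
  if (any(c(pre_s, step_s, post_s) <= 0)) stop("protocol durations must be > 0")
  if (repetitions < 1) stop("repetitions must be >= 1")
  structure(
    list(
      mode = mode, holding_level = as.numeric(holding_level),
      pre_s = as.numeric(pre_s), step_s = as.numeric(step_s),
      post_s = as.numeric(post_s), amplitudes = amplitudes,
      repetitions = as.integer(repetitions)
    ),
    class = "step_protocol"
  )
}

#' @export
print.step_protocol <- function(x, ...) {
  cat(sprintf(
    "<step_protocol> %s: %d amplitudes [%g .. %g] x %d repetitions, %g/%g/%g s pre/step/post, holding %g\n",
    x$mode, length(x$amplitudes), min(x$amplitudes), max(x$amplitudes),
    x$repetitions, x$pre_s, x$step_s, x$post_s, x$holding_level
  ))
  invisible(x)
}

protocol_duration <- function(p) p$pre_s + p$step_s + p$post_s

#' Current-clamp step protocol
#'
#' The default grid is 20 pA current steps spaced between -100 and 480 pA
#' (30 amplitudes), each repeated five times, delivered from the holding
#' current (0 pA injected). Step timing defaults (100 ms pre, 500 ms step,
#' 400 ms post) are package conventions, configurable per recording.
#'
#' @param start_pA,stop_pA,increment_pA Arithmetic amplitude grid in pA;
#'   the increment must divide the range exactly.
#' @param repetitions Repetitions of the grid.
#' @param pre_s,step_s,post_s Durations in seconds.
#' @param holding_pA Holding current in pA.
#' @return A [step_protocol()].
#' @export
current_clamp_protocol <- function(start_pA = -100, stop_pA = 480,
                                   increment_pA = 20, repetitions = 5,
                                   pre_s = 0.1, step_s = 0.5, post_s = 0.4,
                                   holding_pA = 0) {
  if (start_pA == stop_pA) {
    amps <- start_pA
  } else {
    if (increment_pA <= 0) stop("increment_pA must be positive")
    k <- (stop_pA - start_pA) / increment_pA
    if (abs(k - round(k)) > 1e-9) {
      stop("increment_pA must divide (stop_pA - start_pA) exactly")
    }
    amps <- start_pA + increment_pA * (0:round(k))
  }
  step_protocol(
    mode = "current_clamp", holding_level = holding_pA,
    pre_s = pre_s, step_s = step_s, post_s = post_s,
    amplitudes = amps, repetitions = repetitions
  )
}

#' Voltage-clamp step protocol
#'
#' Stepwise voltage injections relative to a -60 mV holding potential. The
#' default injections are the -10 mV leak step plus 0 to 100 mV in 10 mV
#' increments (absolute commands -70 through +40 mV). The -10 mV step is
#' mandatory: it is the measure of passive leak current used downstream by
#' [leak_subtract()].
#'
#' @param injections_mV Step amplitudes in mV relative to holding; must
#'   include -10.
#' @param holding_mV Holding potential in mV.
#' @param pre_s,step_s,post_s Durations in seconds.
#' @param repetitions Repetitions of the grid.
#' @return A [step_protocol()].
#' @export
voltage_clamp_protocol <- function(injections_mV = c(-10, seq(0, 100, 10)),
                                   holding_mV = -60,
                                   pre_s = 0.05, step_s = 0.3, post_s = 0.15,
                                   repetitions = 1) {
  if (!any(abs(injections_mV - (-10)) < 1e-9)) {
    stop("voltage-clamp protocol must include the -10 mV leak step ",
         "(leak subtraction is impossible without it)")
  }
  step_protocol(
    mode = "voltage_clamp", holding_level = holding_mV,
    pre_s = pre_s, step_s = step_s, post_s = post_s,
    amplitudes = sort(unique(injections_mV)), repetitions = repetitions
  )
}

#' Membrane-test pulse protocol
#'
#' A single small voltage pulse (default -5 mV from -60 mV holding) whose
#' current response is fitted by [estimate_passive()] for input resistance,
#' series resistance and capacitance.
#'
#' @param delta_mV Pulse amplitude in mV relative to holding; must be nonzero.
#' @param holding_mV Holding potential in mV.
#' @param pre_s,step_s,post_s Durations in seconds.
#' @param repetitions Repetitions to average.
#' @return A [step_protocol()].
#' @export
test_pulse_protocol <- function(delta_mV = -5, holding_mV = -60,
                                pre_s = 0.05, step_s = 0.15, post_s = 0.05,
                                repetitions = 3) {
  if (delta_mV == 0) stop("test pulse amplitude must be nonzero")
  step_protocol(
    mode = "voltage_clamp", holding_level = holding_mV,
    pre_s = pre_s, step_s = step_s, post_s = post_s,
    amplitudes = delta_mV, repetitions = repetitions
  )
}
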