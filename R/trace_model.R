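#' @importFrom stats median quantile rnorm runif sd setNames aov coef fitted
#'   kruskal.test lm pf pnorm pt p.adjust TukeyHSD wilcox.test complete.cases
#'   anova resid
#' @importFrom utils head tail
NULL

# Project-wide unit conventions: mV and pA for signals, ms for reported spike
# features, seconds for internal time, MOhm for resistances, pF for
# capacitance. Inward current is negative, outward positive.

#' Construct a single episodic sweep
#'
#' A sweep is one uniformly sampled response trace together with the command
#' step that evoked it. In current clamp the response is membrane potential
#' (mV) and the command a current step (pA); in voltage clamp the response is
#' membrane current (pA) and the command a voltage step (mV). The command
#' step is described relative to the holding level and occupies the half-open
#' window `[step_onset, step_offset)` in seconds from the start of the sweep.
#'
#' @param samples Numeric vector of response values (mV or pA by `mode`).
#'   Must be non-empty and finite.
#' @param sampling_rate Sampling rate in Hz.
#' @param command_level Step amplitude relative to holding (pA in current
#'   clamp, mV in voltage clamp).
#' @param step_onset,step_offset Step window in seconds from sweep start.
#' @param holding_level Holding current (pA) or potential (mV).
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param repetition_index 1-based repetition number of this step.
#' @return An object of class `"sweep"`.
#' @export
new_sweep <- function(samples, sampling_rate, command_level,
                      step_onset, step_offset, holding_level = 0,
                      mode = c("current_clamp", "voltage_clamp"),
                      repetition_index = 1L) {
  mode <- match.arg(mode)
  x <- structure(
    list(
      samples = as.numeric(samples),
      sampling_rate = as.numeric(sampling_rate),
      command_level = as.numeric(command_level),
      step_onset = as.numeric(step_onset),
      step_offset = as.numeric(step_offset),
      holding_level = as.numeric(holding_level),
      mode = mode,
      repetition_index = as.integer(repetition_index)
    ),
    class = "sweep"
  )
  validate_sweep(x)
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf(
    "<sweep> %s, %d samples @ %g Hz, step %g %s in [%g, %g) s\n",
    x$mode, length(x$samples), x$sampling_rate, x$command_level,
    if (x$mode == "current_clamp") "pA" else "mV",
    x$step_onset, x$step_offset
  ))
  invisible(x)
}

validate_sweep <- function(x) {
  if (!length(x$samples)) stop("sweep must contain at least one sample")
  if (!all(is.finite(x$samples))) stop("sweep samples must all be finite")
  if (!is.finite(x$sampling_rate) || x$sampling_rate <= 0) {
    stop("sampling_rate must be a positive number (Hz)")
  }
  dur <- length(x$samples) / x$sampling_rate
  if (!(x$step_onset < x$step_offset)) {
    stop("step_onset must precede step_offset")
  }
  if (x$step_offset > dur + 0.5 / x$sampling_rate) {
    stop("step_offset exceeds the trace duration")
  }
  if (!x$mode %in% c("current_clamp", "voltage_clamp")) {
    stop("unknown recording mode: ", x$mode)
  }
  x
}

#' Sample times of a sweep, in seconds from sweep start
#' @param sweep A [new_sweep()] object.
#' @return Numeric vector of times, one per sample.
#' @export
sweep_times <- function(sweep) {
  (seq_along(sweep$samples) - 1) / sweep$sampling_rate
}

#' Sample indices of the half-open step window `[step_onset, step_offset)`
#' @param sweep A sweep.
#' @return Integer vector of indices into `sweep$samples`.
#' @export
step_window_indices <- function(sweep) {
  t <- sweep_times(sweep)
  which(t >= sweep$step_onset - 1e-12 & t < sweep$step_offset - 1e-12)
}

#' The per-sample command trace of a sweep
#'
#' Equals `holding_level` outside the step window and
#' `holding_level + command_level` inside it, exactly.
#' @param sweep A sweep.
#' @return Numeric vector, one command value per sample.
#' @export
sweep_command <- function(sweep) {
  cmd <- rep(sweep$holding_level, length(sweep$samples))
  cmd[step_window_indices(sweep)] <- sweep$holding_level + sweep$command_level
  cmd
}

GENOTYPES <- c("WT", "Tau", "APP_PS1")
TREATMENTS <- c("vehicle", "AR")
CONDITIONS <- c("from_rest", "held_minus60")

#' Construct a cell recording
#'
#' All sweeps and metadata for one neuron under one recording condition:
#' current-clamp step sweeps, optional voltage-clamp step sweeps, and the
#' -5 mV membrane-test sweeps used for passive-property estimation.
#'
#' @param cell_id Character identifier, unique within a cohort.
#' @param genotype One of `"WT"`, `"Tau"`, `"APP_PS1"`.
#' @param treatment One of `"vehicle"`, `"AR"`.
#' @param condition `"from_rest"` (current clamp run from the cell's resting
#'   potential) or `"held_minus60"` (run while holding near -60 mV).
#' @param resting_potential Resting membrane potential in mV, as assessed at
#'   the start of the session.
#' @param sweeps Named list of sweep lists, keyed by protocol
#'   (`current_clamp`, `voltage_clamp`).
#' @param test_pulse_sweeps List of voltage-clamp sweeps at the -5 mV
#'   membrane-test pulse.
#' @param protocols Named list of [step_protocol()] objects matching `sweeps`.
#' @return An object of class `"cell_recording"`.
#' @export
new_cell_recording <- function(cell_id, genotype, treatment, condition,
                               resting_potential, sweeps,
                               test_pulse_sweeps = list(),
                               protocols = list()) {
  genotype <- match.arg(genotype, GENOTYPES)
  treatment <- match.arg(treatment, TREATMENTS)
  condition <- match.arg(condition, CONDITIONS)
  x <- structure(
    list(
      cell_id = as.character(cell_id),
      genotype = genotype,
      treatment = treatment,
      condition = condition,
      resting_potential = as.numeric(resting_potential),
      sweeps = sweeps,
      test_pulse_sweeps = test_pulse_sweeps,
      protocols = protocols
    ),
    class = "cell_recording"
  )
  validate_cell_recording(x)
}

validate_cell_recording <- function(x) {
  all_sweeps <- c(unlist(x$sweeps, recursive = FALSE), x$test_pulse_sweeps)
  if (length(all_sweeps)) {
    rates <- vapply(all_sweeps, function(s) s$sampling_rate, numeric(1))
    if (length(unique(rates)) > 1L) {
      stop("all sweeps of a recording must share one sampling rate")
    }
  }
  for (proto in names(x$sweeps)) {
    modes <- vapply(x$sweeps[[proto]], function(s) s$mode, character(1))
    if (length(unique(modes)) > 1L) {
      stop("sweeps within protocol '", proto, "' mix recording modes")
    }
  }
  x
}

#' @export
print.cell_recording <- function(x, ...) {
  n <- vapply(x$sweeps, length, integer(1))
  cat(sprintf(
    "<cell_recording> %s [%s, %s, %s] V_rest = %g mV; %s; %d test-pulse sweeps\n",
    x$cell_id, x$genotype, x$treatment, x$condition, x$resting_potential,
    paste(sprintf("%s: %d sweeps", names(n), n), collapse = ", "),
    length(x$test_pulse_sweeps)
  ))
  invisible(x)
}

#' Group label of a recording (genotype x treatment)
#' @param x A cell recording, or a character genotype plus treatment.
#' @param treatment Treatment, when `x` is a genotype string.
#' @return A label such as `"WT"`, `"WT+AR"`, `"Tau"`, `"Tau+AR"`.
#' @export
group_label <- function(x, treatment = NULL) {
  if (inherits(x, "cell_recording")) {
    genotype <- x$genotype
    treatment <- x$treatment
  } else {
    genotype <- x
  }
  if (treatment == "AR") paste0(genotype, "+AR") else genotype
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a cell recording to an on-disk container
#'
#' The container is one directory per cell holding a `meta.json` sidecar
#' (identity, genotype, treatment, condition, resting potential, sampling
#' rate, and the protocol descriptions) plus one CSV per protocol with
#' columns `sweep, repetition, time_s, command, response`. Numeric values are
#' written with 17 significant digits so that `read_recording()` returns
#' bit-identical samples.
#'
#' @param recording A [new_cell_recording()] object.
#' @param path Directory to create (one container per recording).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  validate_cell_recording(recording)
  if (file.exists(path) && !dir.exists(path)) {
    stop("path exists and is not a directory: ", path)
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  all_sweeps <- c(unlist(recording$sweeps, recursive = FALSE),
                  recording$test_pulse_sweeps)
  rate <- if (length(all_sweeps)) all_sweeps[[1]]$sampling_rate else NA_real_

  meta <- list(
    cell_id = recording$cell_id,
    genotype = recording$genotype,
    treatment = recording$treatment,
    condition = recording$condition,
    resting_potential = recording$resting_potential,
    sampling_rate = rate,
    protocols = lapply(recording$protocols, protocol_to_list)
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  tabs <- recording$sweeps
  if (length(recording$test_pulse_sweeps)) {
    tabs$test_pulse <- recording$test_pulse_sweeps
  }
  for (proto in names(tabs)) {
    sw <- tabs[[proto]]
    if (!length(sw)) next
    parts <- lapply(seq_along(sw), function(i) {
      s <- sw[[i]]
      data.table::data.table(
        sweep = i,
        repetition = s$repetition_index,
        time_s = fmt_num(sweep_times(s)),
        command = fmt_num(sweep_command(s)),
        response = fmt_num(s$samples)
      )
    })
    dt <- data.table::rbindlist(parts)
    data.table::fwrite(dt, file.path(path, paste0(proto, ".csv")))
  }
  invisible(path)
}

protocol_to_list <- function(p) {
  list(
    mode = p$mode, holding_level = p$holding_level,
    pre_s = p$pre_s, step_s = p$step_s, post_s = p$post_s,
    amplitudes = p$amplitudes, repetitions = p$repetitions
  )
}

protocol_from_list <- function(l) {
  step_protocol(
    mode = l$mode, holding_level = l$holding_level,
    pre_s = l$pre_s, step_s = l$step_s, post_s = l$post_s,
    amplitudes = unlist(l$amplitudes), repetitions = l$repetitions
  )
}

#' Read a cell recording from an on-disk container
#'
#' Inverse of [write_recording()]. Validates that the sidecar declares a
#' sampling rate and that each sweep's length matches the declared protocol
#' durations.
#'
#' @param path Container directory.
#' @return A [new_cell_recording()] object.
#' @export
read_recording <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    stop("container format error: missing meta.json sidecar in ", path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = FALSE)
  if (is.null(meta$sampling_rate) || !is.numeric(meta$sampling_rate)) {
    stop("container format error: meta.json declares no sampling_rate")
  }
  rate <- meta$sampling_rate
  protocols <- lapply(meta$protocols, protocol_from_list)

  sweeps <- list()
  test_pulse <- list()
  for (proto in names(protocols)) {
    csv <- file.path(path, paste0(proto, ".csv"))
    if (!file.exists(csv)) next
    p <- protocols[[proto]]
    dt <- data.table::fread(csv, colClasses = list(
      character = c("time_s", "command", "response")
    ))
    expected_n <- round((p$pre_s + p$step_s + p$post_s) * rate)
    sw <- lapply(split(dt, by = "sweep", sorted = TRUE), function(d) {
      response <- as.numeric(d$response)
      command <- as.numeric(d$command)
      if (length(response) != expected_n) {
        stop("container integrity error: sweep length ", length(response),
             " does not match protocol '", proto, "' (expected ", expected_n, ")")
      }
      mid <- command[round((p$pre_s + p$step_s / 2) * rate)]
      hold <- command[max(1, round(p$pre_s * rate / 2))]
      new_sweep(
        samples = response, sampling_rate = rate,
        command_level = mid - hold,
        step_onset = p$pre_s, step_offset = p$pre_s + p$step_s,
        holding_level = hold, mode = p$mode,
        repetition_index = d$repetition[1]
      )
    })
    names(sw) <- NULL
    if (proto == "test_pulse") test_pulse <- sw else sweeps[[proto]] <- sw
  }

  new_cell_recording(
    cell_id = meta$cell_id, genotype = meta$genotype,
    treatment = meta$treatment, condition = meta$condition,
    resting_potential = meta$resting_potential,
    sweeps = sweeps, test_pulse_sweeps = test_pulse,
    protocols = protocols
  )
}
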