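#' Ground-truth parameters of a synthetic cell
#'
#' The generator is a template-insertion model on top of exact leaky-RC
#' dynamics: subthreshold membrane potential follows
#' `dV/dt = (v_rest - V)/(r_input * c_m) + I/c_m`, and whenever V crosses
#' `spike_threshold` (outside refractoriness) a stereotyped triangular spike
#' waveform is inserted and logged. This gives analytically exact threshold,
#' amplitude and width ground truth for recovery testing of the analysis
#' pipeline; it is deliberately not a conductance-based membrane model.
#' Voltage-clamp responses are the sum of a two-compartment passive response
#' (leak plus capacitive transient through the series resistance), a
#' transient inward component, a delayed outward component, and a
#' depolarization-gated persistent component.
#'
#' @param v_rest Resting potential, mV.
#' @param r_input Input resistance, MOhm.
#' @param r_series Series (access) resistance, MOhm.
#' @param c_m Membrane capacitance, pF.
#' @param spike_threshold Voltage at which a spike is emitted, mV.
#' @param spike_amplitude Template amplitude threshold-to-peak, mV.
#' @param spike_width Template full width at half amplitude, ms.
#' @param spike_ahp Afterhyperpolarization depth below threshold, mV.
#' @param refractory Minimum gap between template end and the next permitted
#'   spike, ms.
#' @param adaptation_increment Adaptation current added per spike, pA; it
#'   opposes depolarization and decays exponentially.
#' @param adaptation_tau Decay time constant of the adaptation current, ms.
#' @param latency_jitter SD of the per-spike timing jitter, ms.
#' @param vg_inward Named vector `c(peak, half, slope, decay)`: transient
#'   inward current with peak amplitude `peak` pA at a 0 mV absolute command
#'   (Boltzmann activation with half-activation `half` mV and slope factor
#'   `slope` mV), decaying with time constant `decay` ms.
#' @param vg_outward Named vector `c(peak, half, slope, rise)`: delayed
#'   outward current with maximal amplitude `peak` pA, Boltzmann activation,
#'   rising with time constant `rise` ms.
#' @param persistent_pA_per_mV Persistent current per mV of depolarizing
#'   injection, pA/mV; zero for non-depolarizing steps.
#' @param noise_sd_mV Gaussian noise SD added to current-clamp traces, mV.
#' @param noise_sd_pA Gaussian noise SD added to voltage-clamp traces, pA.
#' @return An object of class `"cell_params"`.
#' @export
cell_params <- function(v_rest = -65, r_input = 150, r_series = 10,
                        c_m = 100, spike_threshold = -45,
                        spike_amplitude = 85, spike_width = 1.5,
                        spike_ahp = 12, refractory = 4,
                        adaptation_increment = 40, adaptation_tau = 120,
                        latency_jitter = 0.3,
                        vg_inward = c(peak = 2500, half = -30, slope = 6, decay = 4),
                        vg_outward = c(peak = 3000, half = -10, slope = 12, rise = 8),
                        persistent_pA_per_mV = 2,
                        noise_sd_mV = 0.3, noise_sd_pA = 10) {
  p <- structure(
    list(
      v_rest = v_rest, r_input = r_input, r_series = r_series, c_m = c_m,
      spike_threshold = spike_threshold, spike_amplitude = spike_amplitude,
      spike_width = spike_width, spike_ahp = spike_ahp,
      refractory = refractory,
      adaptation_increment = adaptation_increment,
      adaptation_tau = adaptation_tau,
      latency_jitter = latency_jitter,
      vg_inward = vg_inward, vg_outward = vg_outward,
      persistent_pA_per_mV = persistent_pA_per_mV,
      noise_sd_mV = noise_sd_mV, noise_sd_pA = noise_sd_pA
    ),
    class = "cell_params"
  )
  validate_cell_params(p)
}

validate_cell_params <- function(p) {
  if (p$r_input <= 0 || p$c_m <= 0 || p$r_series <= 0) {
    stop("r_input, r_series and c_m must be positive")
  }
  if (p$spike_amplitude <= 0) stop("spike_amplitude must be positive")
  if (p$noise_sd_mV < 0 || p$noise_sd_pA < 0) stop("noise SDs must be >= 0")
  rise_slope <- p$spike_amplitude / p$spike_width
  if (rise_slope <= 30) {
    warning("spike template rise slope ", signif(rise_slope, 3),
            " mV/ms does not exceed the 30 mV/ms detection criterion")
  }
  if (rise_slope <= 15) {
    warning("spike template fall slope does not exceed the 15 mV/ms criterion")
  }
  if (p$spike_threshold + p$spike_amplitude <= 0) {
    warning("spike template peak does not pass above 0 mV; ",
            "such spikes fail the detection peak criterion")
  }
  p
}

boltz <- function(v, half, slope) 1 / (1 + exp(-(v - half) / slope))

# Exact propagation of the leaky-RC state with a decaying adaptation current:
# dV/dt = (v_inf - V)/tau + (-Ia0 exp(-t/tau_a)) * R/tau, evaluated at
# relative sample times trel (seconds). Returns the voltage vector.
rc_propagate <- function(trel, v0, v_inf, tau, ia0, tau_a, r_gohm) {
  if (abs(tau_a - tau) < 1e-9 * tau) tau_a <- tau * (1 + 1e-6)
  b <- -ia0 * r_gohm * tau_a / (tau_a - tau)
  v_inf + b * exp(-trel / tau_a) + (v0 - v_inf - b) * exp(-trel / tau)
}

# Triangular spike template starting at threshold: linear rise to
# threshold + amplitude over `width` ms, symmetric linear fall continuing to
# threshold - ahp. Returns the sample vector (first sample == threshold).
spike_template <- function(threshold, amplitude, width, ahp, dt_ms) {
  nr <- max(1L, as.integer(round(width / dt_ms)))
  slope <- amplitude / width                      # mV/ms
  rise <- threshold + amplitude * (0:nr) / nr
  nd <- as.integer(ceiling((amplitude + ahp) / (slope * dt_ms)))
  fall <- pmax(threshold + amplitude - slope * dt_ms * seq_len(nd),
               threshold - ahp)
  c(rise, fall)
}

#' Simulate one current-clamp protocol for a synthetic cell
#'
#' Subthreshold dynamics are propagated in closed form on the sample grid;
#' spikes are inserted as templates and every insertion is logged to the
#' ground truth before Gaussian noise is added. Deterministic under a fixed
#' seed.
#'
#' @param params A [cell_params()] object.
#' @param protocol A current-clamp [step_protocol()].
#' @param seed Integer seed.
#' @param sampling_rate Hz; 10000 matches the acquisition convention.
#' @param baseline_mV Baseline potential imposed by a holding current; `NULL`
#'   (default) starts from `params$v_rest` with no holding current. Pass -60
#'   for the standardized held-near--60-mV condition.
#' @return A list with `sweeps` (list of [new_sweep()]) and `truth`
#'   (tibble of inserted spikes: amplitude_pA, repetition, threshold_time_s,
#'   threshold_mV, peak_time_s, amplitude_mV, width_ms, end_time_s,
#'   width_defined).
#' @export
simulate_current_clamp <- function(params, protocol, seed = 1,
                                   sampling_rate = 10000,
                                   baseline_mV = NULL) {
  if (protocol$mode != "current_clamp") {
    stop("simulate_current_clamp requires a current-clamp protocol")
  }
  set.seed(seed)
  dt <- 1 / sampling_rate
  dt_ms <- 1000 / sampling_rate
  r_g <- params$r_input / 1000          # GOhm
  tau <- r_g * (params$c_m / 1000)      # s
  if (tau < dt) {
    stop("membrane time constant shorter than the sampling interval: ",
         "unstable configuration (increase c_m or r_input)")
  }
  tau_a <- params$adaptation_tau / 1000
  v_base <- if (is.null(baseline_mV)) params$v_rest else baseline_mV
  i_hold <- (v_base - params$v_rest) / r_g     # pA
  n <- as.integer(round(protocol_duration(protocol) * sampling_rate))
  onset_i <- as.integer(round(protocol$pre_s * sampling_rate)) + 1L
  offset_i <- as.integer(round((protocol$pre_s + protocol$step_s) * sampling_rate))
  refr_n <- as.integer(round(params$refractory / dt_ms))

  sweeps <- list()
  truth <- list()
  for (rep_i in seq_len(protocol$repetitions)) {
    for (amp in protocol$amplitudes) {
      v <- numeric(n)
      epochs <- list(
        list(from = 1L, to = onset_i - 1L, i = 0),
        list(from = onset_i, to = offset_i, i = amp),
        list(from = offset_i + 1L, to = n, i = 0)
      )
      epochs <- Filter(function(e) e$from <= e$to, epochs)
      v0 <- v_base
      ia <- 0
      refract_until <- 0L
      cur <- 1L
      for (e in epochs) {
        i <- max(e$from, cur)
        v_inf <- v_base + r_g * e$i
        while (i <= e$to) {
          chunk_to <- min(e$to, i + 511L)
          idx <- i:chunk_to
          trel <- (idx - i) * dt
          seg <- rc_propagate(trel, v0, v_inf, tau, ia, tau_a, r_g)
          elig <- which(seg > params$spike_threshold & idx >= refract_until)
          if (!length(elig)) {
            v[idx] <- seg
            trel_next <- (chunk_to + 1L - i) * dt
            v0 <- rc_propagate(trel_next, v0, v_inf, tau, ia, tau_a, r_g)
            ia <- ia * exp(-trel_next / tau_a)
            i <- chunk_to + 1L
            cur <- i
            next
          }
          j <- idx[elig[1]]
          if (params$latency_jitter > 0) {
            shift <- as.integer(round(rnorm(1, 0, params$latency_jitter) / dt_ms))
            j <- min(max(j + shift, i, refract_until), chunk_to)
          }
          if (j > i) v[i:(j - 1L)] <- seg[seq_len(j - i)]
          tpl <- spike_template(params$spike_threshold, params$spike_amplitude,
                                params$spike_width, params$spike_ahp, dt_ms)
          tpl_end <- min(j + length(tpl) - 1L, n)
          v[j:tpl_end] <- tpl[seq_len(tpl_end - j + 1L)]
          nr <- max(1L, as.integer(round(params$spike_width / dt_ms)))
          end_i <- j + 2L * nr
          truth[[length(truth) + 1L]] <- data.frame(
            amplitude_pA = amp, repetition = rep_i,
            threshold_time_s = (j - 1L) * dt,
            threshold_mV = params$spike_threshold,
            peak_time_s = (j - 1L + nr) * dt,
            amplitude_mV = params$spike_amplitude,
            width_ms = params$spike_width,
            end_time_s = (j - 1L + nr) * dt + params$spike_width / 1000,
            width_defined = end_i < n
          )
          elapsed <- (tpl_end + 1L - j) * dt +
            if (j > i) (j - i) * dt else 0
          ia <- ia * exp(-elapsed / tau_a) + params$adaptation_increment
          v0 <- params$spike_threshold - params$spike_ahp
          refract_until <- tpl_end + 1L + refr_n
          i <- tpl_end + 1L
          cur <- i
          if (i > n) break
        }
        if (cur > n) break
      }
      if (params$noise_sd_mV > 0) v <- v + rnorm(n, 0, params$noise_sd_mV)
      sweeps[[length(sweeps) + 1L]] <- new_sweep(
        samples = v, sampling_rate = sampling_rate, command_level = amp,
        step_onset = protocol$pre_s,
        step_offset = protocol$pre_s + protocol$step_s,
        holding_level = i_hold, mode = "current_clamp",
        repetition_index = rep_i
      )
    }
  }
  truth <- if (length(truth)) {
    tibble::as_tibble(do.call(rbind, truth))
  } else {
    tibble::tibble(
      amplitude_pA = numeric(), repetition = integer(),
      threshold_time_s = numeric(), threshold_mV = numeric(),
      peak_time_s = numeric(), amplitude_mV = numeric(),
      width_ms = numeric(), end_time_s = numeric(), width_defined = logical()
    )
  }
  list(sweeps = sweeps, truth = truth)
}

# Noiseless voltage-clamp component traces for one injection, on the sample
# grid. Returns list(passive, active) in pA.
vclamp_components <- function(params, injection, v_hold, n, onset_i, offset_i,
                              sampling_rate) {
  dt <- 1 / sampling_rate
  rin_g <- params$r_input / 1000
  rs_g <- params$r_series / 1000
  c_nf <- params$c_m / 1000
  tau_m <- c_nf * rin_g * rs_g / (rin_g + rs_g)
  i_hold <- (v_hold - params$v_rest) / (rin_g + rs_g)

  passive <- rep(i_hold, n)
  step_idx <- onset_i:offset_i
  trel <- (step_idx - onset_i) * dt
  passive[step_idx] <- i_hold + injection / (rin_g + rs_g) *
    (1 + (rin_g / rs_g) * exp(-trel / tau_m))
  if (offset_i < n) {
    post_idx <- (offset_i + 1L):n
    tpost <- (post_idx - offset_i - 1L) * dt
    passive[post_idx] <- i_hold - injection / (rin_g + rs_g) *
      (rin_g / rs_g) * exp(-tpost / tau_m)
  }

  active <- numeric(n)
  if (injection > 0) {
    v_abs <- v_hold + injection
    inw <- params$vg_inward
    outw <- params$vg_outward
    gate_in <- boltz(v_abs, inw[["half"]], inw[["slope"]]) /
      boltz(0, inw[["half"]], inw[["slope"]])
    gate_out <- boltz(v_abs, outw[["half"]], outw[["slope"]])
    active[step_idx] <-
      -inw[["peak"]] * gate_in * exp(-trel / (inw[["decay"]] / 1000)) +
      outw[["peak"]] * gate_out * (1 - exp(-trel / (outw[["rise"]] / 1000))) +
      params$persistent_pA_per_mV * injection
  }
  list(passive = passive, active = active)
}

#' Simulate one voltage-clamp protocol for a synthetic cell
#'
#' The current response is the sum of a two-compartment passive response
#' (ohmic leak plus a capacitive transient decaying with the series-resistance
#' time constant, both exactly linear in the injection), a transient inward
#' component, a delayed outward component, and a persistent component; the
#' three voltage-gated components activate only for depolarizing injections,
#' so the -10 mV leak step carries purely passive current. The noiseless,
#' leak-free component sum is logged to the ground truth.
#'
#' @inheritParams simulate_current_clamp
#' @param protocol A voltage-clamp [step_protocol()] including the -10 mV
#'   leak step.
#' @return A list with `sweeps` and `truth`; `truth` is a tibble with one row
#'   per injection (`injection_mV`, `early_inward_pA`, `early_outward_pA`,
#'   `late_mean_pA`) computed from the noiseless leak-free components with
#'   the same windows the analysis uses (first 10 ms, last third).
#' @export
simulate_voltage_clamp <- function(params, protocol, seed = 1,
                                   sampling_rate = 10000) {
  if (protocol$mode != "voltage_clamp") {
    stop("simulate_voltage_clamp requires a voltage-clamp protocol")
  }
  set.seed(seed)
  n <- as.integer(round(protocol_duration(protocol) * sampling_rate))
  onset_i <- as.integer(round(protocol$pre_s * sampling_rate)) + 1L
  offset_i <- as.integer(round((protocol$pre_s + protocol$step_s) * sampling_rate))
  early_n <- as.integer(round(0.010 * sampling_rate))
  early_idx <- onset_i:min(onset_i + early_n - 1L, offset_i)
  nstep <- offset_i - onset_i + 1L
  late_idx <- (offset_i - as.integer(floor(nstep / 3)) + 1L):offset_i

  sweeps <- list()
  truth <- list()
  for (rep_i in seq_len(protocol$repetitions)) {
    for (dv in protocol$amplitudes) {
      comp <- vclamp_components(params, dv, protocol$holding_level, n,
                                onset_i, offset_i, sampling_rate)
      i_trace <- comp$passive + comp$active
      if (params$noise_sd_pA > 0) {
        i_trace <- i_trace + rnorm(n, 0, params$noise_sd_pA)
      }
      sweeps[[length(sweeps) + 1L]] <- new_sweep(
        samples = i_trace, sampling_rate = sampling_rate, command_level = dv,
        step_onset = protocol$pre_s,
        step_offset = protocol$pre_s + protocol$step_s,
        holding_level = protocol$holding_level, mode = "voltage_clamp",
        repetition_index = rep_i
      )
      if (rep_i == 1L) {
        truth[[length(truth) + 1L]] <- data.frame(
          injection_mV = dv,
          early_inward_pA = min(0, min(comp$active[early_idx])),
          early_outward_pA = max(0, max(comp$active[early_idx])),
          late_mean_pA = mean(comp$active[late_idx])
        )
      }
    }
  }
  list(sweeps = sweeps, truth = tibble::as_tibble(do.call(rbind, truth)))
}

#' Simulate membrane-test pulse sweeps
#'
#' Uses the same two-compartment passive model as [simulate_voltage_clamp()];
#' the -5 mV pulse evokes no voltage-gated current.
#'
#' @inheritParams simulate_voltage_clamp
#' @param protocol A [test_pulse_protocol()].
#' @return A list of sweeps.
#' @export
simulate_test_pulse <- function(params, protocol = test_pulse_protocol(),
                                seed = 1, sampling_rate = 10000) {
  simulate_voltage_clamp(params, protocol, seed = seed,
                         sampling_rate = sampling_rate)$sweeps
}

#' Phenotype presets for the synthetic cohorts
#'
#' Mean parameters per group together with their between-cell dispersion.
#' Magnitudes are package choices; only the effect directions are anchored to
#' the biology being emulated: tangle-bearing (Tau) neurons have elevated
#' input resistance, reduced capacitance, a depolarized resting potential,
#' reduced spike counts and spike amplitude, and smaller voltage-gated inward
#' and outward currents than wild type, while AdipoRon (AR) treatment
#' restores each property toward wild-type values and promotes robust
#' spiking. APP/PS1 neurons are electrophysiologically indistinguishable
#' from wild type.
#'
#' @return Named list of presets; each has `genotype`, `treatment`, `params`
#'   (a [cell_params()]), `cv` (lognormal coefficient of variation for
#'   positive-valued parameters) and `sd_mV` (additive SD for voltage-valued
#'   parameters).
#' @export
phenotype_presets <- function() {
  base_cv <- c(
    r_input = 0.12, r_series = 0.10, c_m = 0.12, spike_amplitude = 0.05,
    spike_width = 0.08, adaptation_increment = 0.15,
    vg_inward_peak = 0.15, vg_outward_peak = 0.15,
    persistent_pA_per_mV = 0.15
  )
  sd_mv <- c(v_rest = 1.5, spike_threshold = 1.0)
  wt <- cell_params(
    v_rest = -65, r_input = 150, c_m = 100, spike_threshold = -45,
    spike_amplitude = 85, spike_width = 1.5, adaptation_increment = 40,
    vg_inward = c(peak = 2500, half = -30, slope = 6, decay = 4),
    vg_outward = c(peak = 3000, half = -10, slope = 12, rise = 8),
    persistent_pA_per_mV = 2
  )
  wt_ar <- cell_params(
    v_rest = -65, r_input = 150, c_m = 100, spike_threshold = -45,
    spike_amplitude = 85, spike_width = 1.4, adaptation_increment = 20,
    vg_inward = c(peak = 2600, half = -30, slope = 6, decay = 4),
    vg_outward = c(peak = 3100, half = -10, slope = 12, rise = 8),
    persistent_pA_per_mV = 2
  )
  tau <- cell_params(
    v_rest = -57, r_input = 260, c_m = 60, spike_threshold = -38,
    spike_amplitude = 68, spike_width = 1.8, adaptation_increment = 220,
    refractory = 8,
    vg_inward = c(peak = 1100, half = -30, slope = 6, decay = 4),
    vg_outward = c(peak = 1500, half = -10, slope = 12, rise = 8),
    persistent_pA_per_mV = 1
  )
  # AR restores the tangle phenotype to wild-type values; the one residual
  # difference it leaves is a narrower spike at rheobase.
  tau_ar <- cell_params(
    v_rest = -65, r_input = 150, c_m = 100, spike_threshold = -45,
    spike_amplitude = 85, spike_width = 1.2, adaptation_increment = 40,
    vg_inward = c(peak = 2500, half = -30, slope = 6, decay = 4),
    vg_outward = c(peak = 3000, half = -10, slope = 12, rise = 8),
    persistent_pA_per_mV = 2
  )
  list(
    "WT" = list(genotype = "WT", treatment = "vehicle", params = wt,
                cv = base_cv, sd_mV = sd_mv),
    "WT+AR" = list(genotype = "WT", treatment = "AR", params = wt_ar,
                   cv = base_cv, sd_mV = sd_mv),
    "Tau" = list(genotype = "Tau", treatment = "vehicle", params = tau,
                 cv = base_cv, sd_mV = sd_mv),
    "Tau+AR" = list(genotype = "Tau", treatment = "AR", params = tau_ar,
                    cv = base_cv, sd_mV = sd_mv),
    "APP_PS1" = list(genotype = "APP_PS1", treatment = "vehicle", params = wt,
                     cv = base_cv, sd_mV = sd_mv)
  )
}

#' Build a cohort design
#'
#' @param n_per_group Named integer vector of cell counts; names must be
#'   preset labels from [phenotype_presets()]. The study-design default is
#'   WT 64, WT+AR 13, Tau 40, Tau+AR 31.
#' @return Named list of design entries (preset plus `n`).
#' @export
cohort_design <- function(n_per_group = c("WT" = 64, "WT+AR" = 13,
                                          "Tau" = 40, "Tau+AR" = 31)) {
  presets <- phenotype_presets()
  if (any(n_per_group < 1)) stop("each group needs at least one cell")
  bad <- setdiff(names(n_per_group), names(presets))
  if (length(bad)) stop("unknown preset group(s): ", paste(bad, collapse = ", "))
  lapply(setNames(names(n_per_group), names(n_per_group)), function(g) {
    c(presets[[g]], list(n = as.integer(n_per_group[[g]])))
  })
}

draw_cell_params <- function(preset) {
  p <- preset$params
  cv <- preset$cv
  sdv <- preset$sd_mV
  ln <- function(mean, cv) {
    sdlog <- sqrt(log(1 + cv^2))
    exp(rnorm(1, log(mean) - sdlog^2 / 2, sdlog))
  }
  vg_in <- p$vg_inward
  vg_out <- p$vg_outward
  vg_in[["peak"]] <- ln(vg_in[["peak"]], cv[["vg_inward_peak"]])
  vg_out[["peak"]] <- ln(vg_out[["peak"]], cv[["vg_outward_peak"]])
  cell_params(
    v_rest = rnorm(1, p$v_rest, sdv[["v_rest"]]),
    r_input = ln(p$r_input, cv[["r_input"]]),
    r_series = ln(p$r_series, cv[["r_series"]]),
    c_m = ln(p$c_m, cv[["c_m"]]),
    spike_threshold = rnorm(1, p$spike_threshold, sdv[["spike_threshold"]]),
    spike_amplitude = ln(p$spike_amplitude, cv[["spike_amplitude"]]),
    spike_width = ln(p$spike_width, cv[["spike_width"]]),
    spike_ahp = p$spike_ahp, refractory = p$refractory,
    adaptation_increment = ln(p$adaptation_increment,
                              cv[["adaptation_increment"]]),
    adaptation_tau = p$adaptation_tau,
    latency_jitter = p$latency_jitter,
    vg_inward = vg_in, vg_outward = vg_out,
    persistent_pA_per_mV = ln(p$persistent_pA_per_mV,
                              cv[["persistent_pA_per_mV"]]),
    noise_sd_mV = p$noise_sd_mV, noise_sd_pA = p$noise_sd_pA
  )
}

#' Simulate a cohort of synthetic cells
#'
#' Draws per-cell parameters from the design's group distributions and emits,
#' per cell, both current-clamp recording conditions (from rest and held near
#' -60 mV), the voltage-clamp protocol, and the membrane-test pulses,
#' together with the full ground truth. A single seeded stream is split
#' hierarchically per cell so cohorts are bit-reproducible.
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed.
#' @param cc_protocol,vc_protocol,tp_protocol Protocols; defaults are the
#'   project protocols.
#' @param sampling_rate Hz.
#' @param noiseless If `TRUE`, zero all noise SDs and the latency jitter in
#'   the drawn parameters (used for exact-recovery testing).
#' @param conditions Character vector of current-clamp conditions to emit.
#' @return An object of class `"cohort"`: list of `cells` (each with `id`,
#'   `group`, `params`, `recordings`, `truth`), plus `design` and `seed`.
#' @export
make_cohort <- function(design = cohort_design(), seed = 1,
                        cc_protocol = current_clamp_protocol(),
                        vc_protocol = voltage_clamp_protocol(),
                        tp_protocol = test_pulse_protocol(),
                        sampling_rate = 10000, noiseless = FALSE,
                        conditions = c("from_rest", "held_minus60")) {
  set.seed(seed)
  n_total <- sum(vapply(design, function(d) d$n, integer(1)))
  cell_seeds <- sample.int(.Machine$integer.max - 1L, n_total + 1L)
  cells <- list()
  k <- 0L
  for (g in names(design)) {
    d <- design[[g]]
    for (ci in seq_len(d$n)) {
      k <- k + 1L
      set.seed(cell_seeds[k])
      params <- draw_cell_params(d)
      if (noiseless) {
        params$noise_sd_mV <- 0
        params$noise_sd_pA <- 0
        params$latency_jitter <- 0
      }
      id <- sprintf("%s_cell%02d", gsub("[^A-Za-z0-9]", "", g), ci)
      sub_seeds <- sample.int(.Machine$integer.max - 1L, 4L)

      tp_sweeps <- simulate_test_pulse(params, tp_protocol,
                                       seed = sub_seeds[1],
                                       sampling_rate = sampling_rate)
      recordings <- list()
      spike_truth <- list()
      if ("from_rest" %in% conditions) {
        cc <- simulate_current_clamp(params, cc_protocol, seed = sub_seeds[2],
                                     sampling_rate = sampling_rate)
        recordings$from_rest <- new_cell_recording(
          cell_id = id, genotype = d$genotype, treatment = d$treatment,
          condition = "from_rest", resting_potential = params$v_rest,
          sweeps = list(current_clamp = cc$sweeps),
          test_pulse_sweeps = tp_sweeps,
          protocols = list(current_clamp = cc_protocol,
                           test_pulse = tp_protocol)
        )
        if (nrow(cc$truth)) {
          spike_truth[[length(spike_truth) + 1L]] <-
            cbind(condition = "from_rest", cc$truth)
        }
      }
      vc_truth <- NULL
      if ("held_minus60" %in% conditions) {
        cc60 <- simulate_current_clamp(params, cc_protocol,
                                       seed = sub_seeds[3],
                                       sampling_rate = sampling_rate,
                                       baseline_mV = -60)
        vc <- simulate_voltage_clamp(params, vc_protocol,
                                     seed = sub_seeds[4],
                                     sampling_rate = sampling_rate)
        recordings$held_minus60 <- new_cell_recording(
          cell_id = id, genotype = d$genotype, treatment = d$treatment,
          condition = "held_minus60", resting_potential = params$v_rest,
          sweeps = list(current_clamp = cc60$sweeps,
                        voltage_clamp = vc$sweeps),
          test_pulse_sweeps = tp_sweeps,
          protocols = list(current_clamp = cc_protocol,
                           voltage_clamp = vc_protocol,
                           test_pulse = tp_protocol)
        )
        if (nrow(cc60$truth)) {
          spike_truth[[length(spike_truth) + 1L]] <-
            cbind(condition = "held_minus60", cc60$truth)
        }
        vc_truth <- vc$truth
      }
      spikes <- if (length(spike_truth)) {
        tibble::as_tibble(do.call(rbind, spike_truth))
      } else {
        NULL
      }
      cells[[id]] <- list(
        id = id, group = g, genotype = d$genotype, treatment = d$treatment,
        params = params, recordings = recordings,
        truth = list(spikes = spikes, vclamp = vc_truth)
      )
    }
  }
  structure(list(cells = cells, design = design, seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  groups <- table(vapply(x$cells, function(c) c$group, character(1)))
  cat(sprintf("<cohort> %d cells (seed %d): %s\n", length(x$cells), x$seed,
              paste(names(groups), groups, sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Write every recording of a cohort as on-disk containers
#'
#' One container directory per cell and condition, named
#' `<cell_id>_<condition>`.
#'
#' @param cohort A [make_cohort()] result.
#' @param dir Output directory.
#' @return Character vector of container paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (cell in cohort$cells) {
    for (cond in names(cell$recordings)) {
      p <- file.path(dir, paste0(cell$id, "_", cond))
      write_recording(cell$recordings[[cond]], p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
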