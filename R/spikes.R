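#' Detect action potentials in a current-clamp sweep
#'
#' A spike is an up-crossing of the dV/dt criterion (first sample whose
#' forward finite-difference slope reaches `up_slope`), followed within
#' `pair_window` ms by a down-crossing of `down_slope`, whose maximum voltage
#' between the two crossings passes above `min_peak`. Slopes are first-order
#' finite differences of the stored trace scaled to mV/ms, with no
#' additional smoothing. Candidate pairs are resolved greedily left to
#' right: an up-cross consumed by an accepted event cannot seed another.
#'
#' @param sweep A current-clamp [new_sweep()].
#' @param up_slope Up-slope criterion, mV/ms (default 30).
#' @param down_slope Down-slope criterion, mV/ms (default -15).
#' @param pair_window Maximum up-to-down crossing separation, ms (default 10).
#' @param min_peak Minimum peak voltage, mV (default 0).
#' @return A tibble with one row per event: `upcross_time`, `peak_time`
#'   (seconds from sweep start), `peak_voltage` (mV), in time order.
#' @export
detect_spikes <- function(sweep, up_slope = 30, down_slope = -15,
                          pair_window = 10, min_peak = 0) {
  if (sweep$mode != "current_clamp") {
    stop("spike detection applies to current-clamp sweeps")
  }
  v <- sweep$samples
  n <- length(v)
  dt_ms <- 1000 / sweep$sampling_rate
  if ((n - 1) * dt_ms < pair_window) {
    stop("sweep shorter than the pairing window: cannot detect spikes")
  }
  slope <- diff(v) / dt_ms                    # slope[i] between samples i, i+1
  prev <- c(-Inf, slope[-length(slope)])
  up <- which(slope >= up_slope & prev < up_slope)
  prev_dn <- c(Inf, slope[-length(slope)])
  down <- which(slope <= down_slope & prev_dn > down_slope)
  win_n <- as.integer(round(pair_window / dt_ms))

  events <- list()
  consumed_until <- 0L
  for (u in up) {
    if (u <= consumed_until) next
    d_cand <- down[down > u & down <= u + win_n]
    if (!length(d_cand)) next
    d <- d_cand[1]
    seg_idx <- u:(d + 1L)
    pk_rel <- which.max(v[seg_idx])
    pk <- seg_idx[pk_rel]
    if (v[pk] <= min_peak) next
    events[[length(events) + 1L]] <- data.frame(
      upcross_time = (u - 1L) / sweep$sampling_rate,
      peak_time = (pk - 1L) / sweep$sampling_rate,
      peak_voltage = v[pk]
    )
    consumed_until <- d
  }
  if (!length(events)) {
    return(tibble::tibble(upcross_time = numeric(), peak_time = numeric(),
                          peak_voltage = numeric()))
  }
  tibble::as_tibble(do.call(rbind, events))
}

#' Classify detected spikes as evoked, spontaneous or rebound
#'
#' Spikes whose up-cross falls inside the half-open step window of a
#' depolarizing step (`command_level > 0`) are evoked; spikes before the
#' step onset are spontaneous; spikes at or after the step offset, or during
#' a non-depolarizing step, are rebound. Only evoked spikes enter the
#' downstream counts and rheobase analysis.
#'
#' @param events Tibble from [detect_spikes()].
#' @param sweep The sweep the events came from.
#' @return `events` with a `classification` column added.
#' @export
classify_spikes <- function(events, sweep) {
  cls <- character(nrow(events))
  if (nrow(events)) {
    before <- events$upcross_time < sweep$step_onset - 1e-12
    in_step <- !before & events$upcross_time < sweep$step_offset - 1e-12
    cls[before] <- "spontaneous"
    cls[in_step & sweep$command_level > 0] <- "evoked"
    cls[cls == ""] <- "rebound"
  }
  events$classification <- cls
  events
}

#' Spike threshold, latency, amplitude and width of detected events
#'
#' For each event the threshold is located at the maximum of the second
#' finite difference of the voltage within a window from 3 ms before the
#' up-cross to the up-cross (earliest sample wins ties); threshold voltage is
#' the original signal at that time. The spike end is the first sample after
#' the peak that falls back below the threshold voltage; latency is the time
#' from step onset to the threshold (ms); amplitude is threshold-to-peak
#' (mV); width is the full width at half amplitude, linearly interpolated
#' between samples (ms). When the voltage never re-crosses the threshold
#' before the sweep ends, `end_time` and `width` are `NA` and `width_defined`
#' is `FALSE`.
#'
#' @param events Tibble from [detect_spikes()] (optionally classified).
#' @param sweep The source sweep.
#' @param pre_window Threshold search window before the up-cross, ms.
#' @return `events` with columns `threshold_time`, `threshold_voltage`,
#'   `latency`, `amplitude`, `end_time`, `width`, `width_defined` added.
#' @export
spike_features <- function(events, sweep, pre_window = 3) {
  v <- sweep$samples
  n <- length(v)
  rate <- sweep$sampling_rate
  dt_ms <- 1000 / rate
  pre_n <- as.integer(round(pre_window / dt_ms))
  out <- events
  cols <- c("threshold_time", "threshold_voltage", "latency", "amplitude",
            "end_time", "width")
  for (cc in cols) out[[cc]] <- rep(NA_real_, nrow(events))
  out$width_defined <- rep(FALSE, nrow(events))
  if (!nrow(events)) return(out)

  d2 <- c(NA, diff(v, differences = 2), NA)   # aligned: d2[i] ~ v''(t_i)
  for (r in seq_len(nrow(events))) {
    u <- as.integer(round(events$upcross_time[r] * rate)) + 1L
    pk <- as.integer(round(events$peak_time[r] * rate)) + 1L
    lo <- max(2L, u - pre_n)
    win <- lo:max(lo, u)
    j <- win[which.max(d2[win])]
    thr_v <- v[j]
    amp <- v[pk] - thr_v
    out$threshold_time[r] <- (j - 1L) / rate
    out$threshold_voltage[r] <- thr_v
    out$latency[r] <- ((j - 1L) / rate - sweep$step_onset) * 1000
    out$amplitude[r] <- amp

    after <- if (pk < n) (pk + 1L):n else integer()
    end_rel <- which(v[after] < thr_v)
    if (!length(end_rel)) next
    e <- after[end_rel[1]]
    out$end_time[r] <- (e - 1L) / rate

    half <- thr_v + amp / 2
    ris <- j:pk
    iu <- ris[which(v[ris] >= half)[1]]
    t_up <- if (iu == j) (iu - 1L) / rate else {
      (iu - 2L) / rate + (half - v[iu - 1L]) / (v[iu] - v[iu - 1L]) / rate
    }
    fal <- pk:e
    id_ <- fal[which(v[fal] <= half)[1]]
    t_dn <- if (id_ == pk) (id_ - 1L) / rate else {
      (id_ - 2L) / rate + (v[id_ - 1L] - half) / (v[id_ - 1L] - v[id_]) / rate
    }
    out$width[r] <- (t_dn - t_up) * 1000
    out$width_defined[r] <- TRUE
  }
  out
}

#' Evoked-spike counts across the current-step grid (F-I curve)
#'
#' Per step amplitude, the evoked spike count averaged across repetitions,
#' together with the per-repetition proportions that fired at least one
#' spike and exactly one spike.
#'
#' @param recording A [new_cell_recording()] with current-clamp sweeps.
#' @param ... Passed to [detect_spikes()].
#' @return A tibble with `amplitude_pA`, `mean_spike_count`,
#'   `prop_one_or_more`, `prop_exactly_one`, `n_repetitions`.
#' @export
fi_curve <- function(recording, ...) {
  sweeps <- recording$sweeps$current_clamp
  if (is.null(sweeps)) stop("recording has no current-clamp sweeps")
  counts <- lapply(sweeps, function(s) {
    ev <- classify_spikes(detect_spikes(s, ...), s)
    data.frame(amplitude_pA = s$command_level,
               repetition = s$repetition_index,
               n_evoked = sum(ev$classification == "evoked"))
  })
  dt <- do.call(rbind, counts)
  amps <- sort(unique(dt$amplitude_pA))
  n_rep_full <- max(table(dt$amplitude_pA))
  res <- lapply(amps, function(a) {
    x <- dt$n_evoked[dt$amplitude_pA == a]
    if (length(x) < n_rep_full) {
      warning("amplitude ", a, " pA has only ", length(x),
              " repetition(s); counts use the available repetitions")
    }
    data.frame(
      amplitude_pA = a, mean_spike_count = mean(x),
      prop_one_or_more = mean(x >= 1), prop_exactly_one = mean(x == 1),
      n_repetitions = length(x)
    )
  })
  tibble::as_tibble(do.call(rbind, res))
}

#' Rheobase and first-spike features of a recording
#'
#' The rheobase is the minimum depolarizing step amplitude that elicits at
#' least one evoked spike in any repetition; the first repetition achieving
#' it supplies the first spike, whose threshold, latency, amplitude and width
#' are computed by [spike_features()]. Spikes that never re-cross their
#' threshold before the sweep ends have no width and are excluded from the
#' width statistics.
#'
#' @param recording A [new_cell_recording()] with current-clamp sweeps.
#' @param ... Passed to [detect_spikes()].
#' @return A list with `rheobase_pA` and `first_spike` (one-row tibble), or
#'   `NULL` when no evoked spike exists (the cell is excluded from rheobase
#'   statistics).
#' @export
rheobase_features <- function(recording, ...) {
  sweeps <- recording$sweeps$current_clamp
  if (is.null(sweeps)) stop("recording has no current-clamp sweeps")
  per_sweep <- lapply(sweeps, function(s) {
    ev <- classify_spikes(detect_spikes(s, ...), s)
    ev <- ev[ev$classification == "evoked", , drop = FALSE]
    list(sweep = s, events = ev)
  })
  has <- vapply(per_sweep, function(x) nrow(x$events) > 0, logical(1))
  if (!any(has)) return(NULL)
  amps <- vapply(per_sweep, function(x) x$sweep$command_level, numeric(1))
  rheo <- min(amps[has])
  cand <- per_sweep[has & amps == rheo]
  reps <- vapply(cand, function(x) x$sweep$repetition_index, integer(1))
  first <- cand[[which.min(reps)]]
  ev <- first$events[order(first$events$upcross_time), , drop = FALSE][1, , drop = FALSE]
  ev <- spike_features(ev, first$sweep)
  list(rheobase_pA = rheo, first_spike = tibble::as_tibble(ev))
}
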