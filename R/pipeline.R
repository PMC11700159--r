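#' Full per-recording analysis
#'
#' Runs passive-property estimation on the membrane-test sweeps, the
#' current-clamp spike pipeline (F-I curve and rheobase features), and, when
#' voltage-clamp sweeps are present, leak subtraction, baseline zeroing and
#' early/late current extraction.
#'
#' @param recording A [new_cell_recording()].
#' @return A list with `passive`, `fi`, `rheobase`, `vclamp` (per-injection
#'   features or `NULL`), `vclamp_summary`, and `spike_log` (detected spike
#'   counts per class, for exclusion bookkeeping).
#' @export
analyze_recording <- function(recording) {
  passive <- if (length(recording$test_pulse_sweeps)) {
    estimate_passive(recording$test_pulse_sweeps,
                     resting_potential = recording$resting_potential)
  } else {
    NULL
  }
  fi <- rheo <- NULL
  spike_log <- c(evoked = 0L, spontaneous = 0L, rebound = 0L)
  if (!is.null(recording$sweeps$current_clamp)) {
    for (s in recording$sweeps$current_clamp) {
      ev <- classify_spikes(detect_spikes(s), s)
      if (nrow(ev)) {
        tab <- table(factor(ev$classification,
                            levels = c("evoked", "spontaneous", "rebound")))
        spike_log <- spike_log + as.integer(tab)
      }
    }
    fi <- fi_curve(recording)
    rheo <- rheobase_features(recording)
  }
  vc <- vc_sum <- NULL
  if (!is.null(recording$sweeps$voltage_clamp)) {
    sub <- leak_subtract(recording$sweeps$voltage_clamp)
    sub <- lapply(sub, zero_baseline)
    vc <- vclamp_features(sub)
    vc_sum <- cell_vclamp_summary(vc)
  }
  list(passive = passive, fi = fi, rheobase = rheo,
       vclamp = vc, vclamp_summary = vc_sum, spike_log = spike_log)
}

#' Per-cell feature table of a cohort
#'
#' One row per cell and recording condition with the passive properties,
#' rheobase features and voltage-clamp summary currents used by the group
#' statistics.
#'
#' @param cohort A [make_cohort()] result.
#' @return A tibble.
#' @export
cohort_features <- function(cohort) {
  rows <- list()
  for (cell in cohort$cells) {
    for (cond in names(cell$recordings)) {
      rec <- cell$recordings[[cond]]
      an <- analyze_recording(rec)
      fs <- an$rheobase$first_spike
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cell_id = cell$id, group = cell$group,
        genotype = cell$genotype, treatment = cell$treatment,
        condition = cond,
        r_input_MOhm = an$passive$r_input_MOhm,
        r_series_MOhm = an$passive$r_series_MOhm,
        c_m_pF = an$passive$c_m_pF,
        v_rest_mV = rec$resting_potential,
        rheobase_pA = if (is.null(an$rheobase)) NA_real_ else an$rheobase$rheobase_pA,
        latency_ms = if (is.null(fs)) NA_real_ else fs$latency,
        threshold_mV = if (is.null(fs)) NA_real_ else fs$threshold_voltage,
        amplitude_mV = if (is.null(fs)) NA_real_ else fs$amplitude,
        width_ms = if (is.null(fs)) NA_real_ else fs$width,
        max_inward_pA = if (is.null(an$vclamp_summary)) NA_real_ else an$vclamp_summary$max_inward_pA,
        max_outward_pA = if (is.null(an$vclamp_summary)) NA_real_ else an$vclamp_summary$max_outward_pA,
        evoked_spikes = an$spike_log[["evoked"]],
        excluded_spikes = an$spike_log[["spontaneous"]] + an$spike_log[["rebound"]]
      )
    }
  }
  do.call(rbind, rows)
}

#' Long F-I table of a cohort (cell x amplitude x condition)
#'
#' @param cohort A [make_cohort()] result.
#' @return A tibble with `cell_id`, `group`, `condition`, `amplitude_pA`,
#'   `mean_spike_count`, `prop_one_or_more`, `prop_exactly_one`.
#' @export
cohort_fi_table <- function(cohort) {
  rows <- list()
  for (cell in cohort$cells) {
    for (cond in names(cell$recordings)) {
      rec <- cell$recordings[[cond]]
      if (is.null(rec$sweeps$current_clamp)) next
      fi <- fi_curve(rec)
      fi$cell_id <- cell$id
      fi$group <- cell$group
      fi$condition <- cond
      rows[[length(rows) + 1L]] <- fi
    }
  }
  do.call(rbind, rows)
}

#' Long IV table of a cohort (cell x injection)
#'
#' Leak-subtracted, zeroed per-injection features for every cell with
#' voltage-clamp sweeps.
#'
#' @param cohort A [make_cohort()] result.
#' @return A tibble with `cell_id`, `group`, `injection_mV`,
#'   `early_inward_pA`, `early_outward_pA`, `late_mean_pA`.
#' @export
cohort_iv_table <- function(cohort) {
  rows <- list()
  for (cell in cohort$cells) {
    for (cond in names(cell$recordings)) {
      rec <- cell$recordings[[cond]]
      if (is.null(rec$sweeps$voltage_clamp)) next
      sub <- lapply(leak_subtract(rec$sweeps$voltage_clamp), zero_baseline)
      vc <- vclamp_features(sub)
      vc$cell_id <- cell$id
      vc$group <- cell$group
      rows[[length(rows) + 1L]] <- vc
    }
  }
  do.call(rbind, rows)
}

#' Group comparison of a per-cell endpoint
#'
#' Applies ROUT outlier removal per group (Q = 0.05), then the
#' Kruskal-Wallis omnibus test with Dunn post-hoc comparisons. This is the
#' analysis used for the per-cell scalar endpoints (passive properties and
#' rheobase spike features) in four-group designs; use [mann_whitney()] for
#' two-group designs.
#'
#' @param features Tibble from [cohort_features()].
#' @param endpoint Column name of the endpoint.
#' @param condition Recording condition to filter on, or `NULL` for all.
#' @param rout_Q FDR for outlier removal; `NA` disables removal.
#' @return A list with `endpoint`, `groups` (cleaned samples), `n_removed`,
#'   and the [kruskal_dunn()] result.
#' @export
compare_groups <- function(features, endpoint, condition = NULL,
                           rout_Q = 0.05) {
  f <- features
  if (!is.null(condition)) f <- f[f$condition == condition, , drop = FALSE]
  f <- f[is.finite(f[[endpoint]]), , drop = FALSE]
  groups <- split(f[[endpoint]], f$group)
  n_removed <- 0L
  if (!is.na(rout_Q)) {
    groups <- lapply(groups, function(v) {
      r <- rout_outliers(v, Q = rout_Q)
      n_removed <<- n_removed + length(r$removed)
      r$kept
    })
  }
  test <- kruskal_dunn(groups)
  list(endpoint = endpoint, groups = groups, n_removed = n_removed,
       test = test)
}

#' Repeated-measures ANOVA of spike counts across the current-step grid
#'
#' Builds the subjects x steps table from [cohort_fi_table()] output
#' (depolarizing steps only) and runs [rm_anova_gg()] with group as the
#' between factor and current step as the within factor, plus Tukey
#' comparisons of the group means.
#'
#' @param fi_table Tibble from [cohort_fi_table()].
#' @param condition Recording condition to analyze.
#' @param response One of `"mean_spike_count"`, `"prop_one_or_more"`,
#'   `"prop_exactly_one"`.
#' @return A list with `anova` ([rm_anova_gg()] result) and `tukey`.
#' @export
spike_count_anova <- function(fi_table, condition = "from_rest",
                              response = "mean_spike_count") {
  d <- fi_table[fi_table$condition == condition &
                  fi_table$amplitude_pA > 0, , drop = FALSE]
  long <- data.frame(
    value = d[[response]], subject = d$cell_id,
    within = factor(d$amplitude_pA), between = d$group
  )
  res <- rm_anova_gg(long)
  tk <- tukey_groups(long)
  list(anova = res, tukey = tk)
}

#' Run the full simulate-analyze-test pipeline and write its outputs
#'
#' Deterministic under a fixed seed: simulates a cohort, writes the feature,
#' F-I and IV tables as CSV, runs the group statistics, and records
#' provenance (package version, seed, design sizes).
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param conditions Current-clamp conditions to simulate.
#' @return Invisibly, a list with the tables and statistics.
#' @export
run_pipeline <- function(design = cohort_design(), seed = 1,
                         out_dir = "results",
                         conditions = c("from_rest", "held_minus60"),
                         cc_protocol = current_clamp_protocol(),
                         vc_protocol = voltage_clamp_protocol(),
                         tp_protocol = test_pulse_protocol()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- make_cohort(design, seed = seed, conditions = conditions,
                        cc_protocol = cc_protocol,
                        vc_protocol = vc_protocol,
                        tp_protocol = tp_protocol)
  features <- cohort_features(cohort)
  fi <- cohort_fi_table(cohort)
  iv <- cohort_iv_table(cohort)
  data.table::fwrite(features, file.path(out_dir, "features.csv"))
  data.table::fwrite(fi, file.path(out_dir, "fi_curves.csv"))
  data.table::fwrite(iv, file.path(out_dir, "iv_curves.csv"))

  stats_rows <- list()
  for (ep in c("r_input_MOhm", "c_m_pF", "v_rest_mV", "rheobase_pA",
               "latency_ms", "amplitude_mV", "width_ms",
               "max_inward_pA", "max_outward_pA")) {
    cond <- if (ep %in% c("max_inward_pA", "max_outward_pA")) {
      "held_minus60"
    } else {
      "from_rest"
    }
    cg <- tryCatch(compare_groups(features, ep, condition = cond),
                   error = function(e) NULL)
    if (is.null(cg)) next
    stats_rows[[length(stats_rows) + 1L]] <- tibble::tibble(
      endpoint = ep, test = "kruskal_wallis", comparison = "omnibus",
      statistic = cg$test$H, df = cg$test$df, p = cg$test$p_value,
      adjusted_p = NA_real_, n_outliers_removed = cg$n_removed
    )
    stats_rows[[length(stats_rows) + 1L]] <- tibble::tibble(
      endpoint = ep, test = "dunn", comparison = cg$test$pairwise$comparison,
      statistic = cg$test$pairwise$z, df = NA_real_,
      p = cg$test$pairwise$p, adjusted_p = cg$test$pairwise$adjusted_p,
      n_outliers_removed = cg$n_removed
    )
  }
  anova_res <- list()
  for (cond in intersect(conditions, unique(fi$condition))) {
    sc <- spike_count_anova(fi, condition = cond)
    anova_res[[cond]] <- sc
    stats_rows[[length(stats_rows) + 1L]] <- tibble::tibble(
      endpoint = paste0("spike_count_", cond), test = "rm_anova_gg",
      comparison = sc$anova$effects$effect,
      statistic = sc$anova$effects$statistic,
      df = sc$anova$effects$df1_gg, p = sc$anova$effects$p_gg,
      adjusted_p = NA_real_, n_outliers_removed = 0L
    )
  }
  stats_tab <- do.call(rbind, stats_rows)
  data.table::fwrite(stats_tab, file.path(out_dir, "group_stats.csv"))

  provenance <- list(
    package_version = as.character(utils::packageVersion("wholecell")),
    seed = seed,
    groups = lapply(design, function(d) d$n),
    n_cells = length(cohort$cells),
    generated = "deterministic given seed"
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = cohort, features = features, fi = fi, iv = iv,
                 stats = stats_tab, anova = anova_res))
}
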