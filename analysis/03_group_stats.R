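#!/usr/bin/env Rscript
# Group-level statistics on the analyzed feature tables, mirroring the
# study's statistical plan: ROUT (Q = 0.05) outlier removal, then
# Kruskal-Wallis + Dunn for per-cell endpoints in the four-group design;
# repeated-measures two-way ANOVA with Greenhouse-Geisser correction and
# Tukey tests for spike counts across current steps; and origin-constrained
# one-phase association / straight-line F-tests for the firing-probability
# curves.

suppressPackageStartupMessages({
  library(wholecell)
  library(data.table)
})

features <- fread("results/features.csv")
fi <- fread("results/fi_curves.csv")

message("== Per-cell endpoints (ROUT + Kruskal-Wallis + Dunn) ==")
for (ep in c("r_input_MOhm", "c_m_pF", "v_rest_mV", "latency_ms",
             "amplitude_mV", "width_ms")) {
  cg <- compare_groups(features, ep, condition = "from_rest")
  message(sprintf("%-14s H = %6.2f, p = %.4g (removed %d outliers)",
                  ep, cg$test$H, cg$test$p_value, cg$n_removed))
  sig <- cg$test$pairwise[cg$test$pairwise$adjusted_p < 0.05, ]
  if (nrow(sig)) {
    message("   significant pairs: ",
            paste(sig$comparison, collapse = "; "))
  }
}

message("== Spike counts across steps (RM two-way ANOVA, GG-corrected) ==")
for (cond in c("from_rest", "held_minus60")) {
  sc <- spike_count_anova(fi, condition = cond)
  eff <- sc$anova$effects
  message(cond, ": epsilon-hat = ", round(sc$anova$epsilon, 3))
  for (i in seq_len(nrow(eff))) {
    message(sprintf("   %-15s F = %7.2f, GG df = (%.2f, %.2f), p = %.3g",
                    eff$effect[i], eff$statistic[i], eff$df1_gg[i],
                    eff$df2_gg[i], eff$p_gg[i]))
  }
  sig <- sc$tukey[sc$tukey$adjusted_p < 0.05, ]
  if (nrow(sig)) {
    message("   Tukey: ", paste(sig$comparison, collapse = "; "))
  }
}

message("== Firing-probability curves (origin-constrained F-tests) ==")
fr <- fi[fi$condition == "from_rest" & fi$amplitude_pA > 0]
one_plus <- one_phase_f_test(fr$amplitude_pA, fr$prop_one_or_more, fr$group)
message(sprintf(
  "one-or-more spikes ~ one-phase association: F = %.2f (df %d, %d), p = %.3g",
  one_plus$F, one_plus$df1, one_plus$df2, one_plus$p_value))
exactly1 <- line_f_test(fr$amplitude_pA, fr$prop_exactly_one, fr$group)
message(sprintf(
  "exactly-one spike ~ line through origin: F = %.2f (df %d, %d), p = %.3g",
  exactly1$F, exactly1$df1, exactly1$df2, exactly1$p_value))

out <- rbind(
  data.table(endpoint = "prop_one_or_more", test = "one_phase_f",
             statistic = one_plus$F, df1 = one_plus$df1, df2 = one_plus$df2,
             p = one_plus$p_value),
  data.table(endpoint = "prop_exactly_one", test = "line_f",
             statistic = exactly1$F, df1 = exactly1$df1, df2 = exactly1$df2,
             p = exactly1$p_value)
)
fwrite(out, "results/curve_ftests.csv")
message("Wrote results/curve_ftests.csv")
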