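#!/usr/bin/env Rscript
# Figures mirroring the study's panel logic: per-cell scatter with
# median/IQR for the passive properties, mean +/- SEM spike count versus
# current step, and early/late current-voltage curves.

suppressPackageStartupMessages({
  library(wholecell)
  library(data.table)
  library(ggplot2)
})

features <- fread("results/features.csv")
fi <- fread("results/fi_curves.csv")
iv <- fread("results/iv_curves.csv")
dir.create("results/figures", showWarnings = FALSE)

grp_levels <- c("WT", "WT+AR", "Tau", "Tau+AR")
features$group <- factor(features$group, grp_levels)
fi$group <- factor(fi$group, grp_levels)
iv$group <- factor(iv$group, grp_levels)

scatter_panel <- function(d, col, lab) {
  ggplot(d, aes(x = group, y = .data[[col]], colour = group)) +
    geom_jitter(width = 0.15, alpha = 0.7, size = 1.4) +
    stat_summary(fun = median, fun.min = function(x) quantile(x, 0.25),
                 fun.max = function(x) quantile(x, 0.75),
                 geom = "pointrange", colour = "black", linewidth = 0.7) +
    labs(x = NULL, y = lab) +
    theme_classic() + theme(legend.position = "none")
}
fr <- features[features$condition == "from_rest", ]
p <- scatter_panel(fr, "r_input_MOhm", "Input resistance (MOhm)")
ggsave("results/figures/passive_resistance.pdf", p, width = 4, height = 3)
p <- scatter_panel(fr, "c_m_pF", "Capacitance (pF)")
ggsave("results/figures/passive_capacitance.pdf", p, width = 4, height = 3)
p <- scatter_panel(fr, "v_rest_mV", "Resting potential (mV)")
ggsave("results/figures/passive_vrest.pdf", p, width = 4, height = 3)

fi_sum <- fi[, .(m = mean(mean_spike_count),
                 sem = sd(mean_spike_count) / sqrt(.N)),
             by = .(condition, group, amplitude_pA)]
p <- ggplot(fi_sum, aes(amplitude_pA, m, colour = group)) +
  geom_line() +
  geom_pointrange(aes(ymin = m - sem, ymax = m + sem), size = 0.2) +
  facet_wrap(~condition, ncol = 1) +
  labs(x = "Current step (pA)", y = "Spike count (mean +/- SEM)") +
  theme_classic()
ggsave("results/figures/fi_curves.pdf", p, width = 5, height = 6)

iv_sum <- iv[, .(inward = mean(early_inward_pA),
                 outward = mean(early_outward_pA),
                 late = mean(late_mean_pA),
                 sem_late = sd(late_mean_pA) / sqrt(.N)),
             by = .(group, injection_mV)]
p <- ggplot(iv_sum, aes(injection_mV - 60, inward, colour = group)) +
  geom_line() + geom_point() +
  labs(x = "Command voltage (mV)", y = "Maximum inward current (pA)") +
  theme_classic()
ggsave("results/figures/iv_inward.pdf", p, width = 5, height = 3.2)
p <- ggplot(iv_sum, aes(injection_mV - 60, outward, colour = group)) +
  geom_line() + geom_point() +
  labs(x = "Command voltage (mV)", y = "Maximum outward current (pA)") +
  theme_classic()
ggsave("results/figures/iv_outward.pdf", p, width = 5, height = 3.2)
p <- ggplot(iv_sum, aes(injection_mV - 60, late, colour = group)) +
  geom_line() +
  geom_pointrange(aes(ymin = late - sem_late, ymax = late + sem_late),
                  size = 0.2) +
  labs(x = "Command voltage (mV)", y = "Late (steady-state) current (pA)") +
  theme_classic()
ggsave("results/figures/iv_late.pdf", p, width = 5, height = 3.2)

message("Wrote 7 figures under results/figures/")
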