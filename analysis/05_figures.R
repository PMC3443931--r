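#!/usr/bin/env Rscript
# Stage 5 — figures.
#
# Regenerates the standard summary plots from the stage 3-4 tables:
# bias-corrected PSE vs conflict with the dominance lines, measured vs
# predicted PSEs, explained variance by age, the weight-weight scatter,
# and thresholds by age with the MLE prediction.

suppressPackageStartupMessages({
  library(avbisect)
  library(ggplot2)
})

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
age_levels <- c("6y", "8-9y", "10-12y", "adult")

for (domain in c("time", "space")) {
  unit <- if (domain == "time") "ms" else "deg"
  observers <- utils::read.csv(sprintf("results/observers_%s.csv", domain))
  pses <- utils::read.csv(sprintf("results/pses_%s.csv", domain))
  summary <- utils::read.csv(sprintf("results/group_summary_%s.csv", domain))
  pses$age_group <- factor(pses$age_group, age_levels)
  observers$age_group <- factor(observers$age_group, age_levels)
  summary$age_group <- factor(summary$age_group, age_levels)

  # PSE vs conflict: +1 line = total visual dominance, -1 = auditory
  p1 <- ggplot(pses, aes(conflict, pse_corrected)) +
    geom_abline(slope = 1, intercept = 0, colour = "red") +
    geom_abline(slope = -1, intercept = 0, colour = "darkgreen") +
    stat_summary(fun = mean, geom = "point") +
    stat_summary(fun.data = mean_se, geom = "errorbar", width = 0) +
    facet_wrap(~age_group, nrow = 1) +
    labs(x = sprintf("conflict (%s)", unit),
         y = sprintf("bias-corrected PSE (%s)", unit),
         title = sprintf("%s bisection: PSE vs conflict", domain)) +
    theme_minimal()
  ggsave(sprintf("results/figures/pse_vs_conflict_%s.png", domain), p1,
         width = 9, height = 2.8, dpi = 150)

  p2 <- ggplot(pses, aes(pse_predicted, pse_corrected)) +
    geom_abline(slope = 1, intercept = 0) +
    geom_point(alpha = 0.5) +
    facet_wrap(~age_group, nrow = 1) +
    labs(x = "predicted PSE", y = "measured PSE",
         title = sprintf("%s bisection: measured vs MLE-predicted PSE", domain)) +
    theme_minimal()
  ggsave(sprintf("results/figures/measured_vs_predicted_%s.png", domain), p2,
         width = 9, height = 2.8, dpi = 150)

  r2 <- do.call(rbind, lapply(age_levels, function(g) {
    pg <- pses[pses$age_group == g, ]
    data.frame(age_group = factor(g, age_levels),
               r2 = r_squared(pg$pse_corrected, pg$pse_predicted)$r_squared)
  }))
  p3 <- ggplot(r2, aes(age_group, r2, group = 1)) +
    geom_hline(yintercept = c(0, 1), linetype = "dotted") +
    geom_line() + geom_point(size = 2) +
    labs(x = "age group", y = expression(R^2),
         title = sprintf("%s bisection: variance explained by the MLE model",
                         domain)) +
    theme_minimal()
  ggsave(sprintf("results/figures/r_squared_%s.png", domain), p3,
         width = 4.5, height = 3, dpi = 150)

  p4 <- ggplot(observers, aes(w_A_slope, w_A_thresholds,
                              colour = age_group)) +
    geom_abline(slope = 1, intercept = 0) +
    geom_point() +
    coord_cartesian(xlim = c(-0.3, 1.3), ylim = c(0, 1)) +
    labs(x = "auditory weight from PSE slope",
         y = "auditory weight from thresholds",
         title = sprintf("%s bisection: weight estimates", domain)) +
    theme_minimal()
  ggsave(sprintf("results/figures/weights_%s.png", domain), p4,
         width = 5, height = 3.5, dpi = 150)

  thr <- rbind(
    data.frame(age_group = summary$age_group, what = "visual",
               m = summary$sigma_V, se = summary$sigma_V_sem),
    data.frame(age_group = summary$age_group, what = "auditory",
               m = summary$sigma_A, se = summary$sigma_A_sem),
    data.frame(age_group = summary$age_group, what = "bimodal",
               m = summary$sigma_bimodal, se = summary$sigma_bimodal_sem),
    data.frame(age_group = summary$age_group, what = "MLE prediction",
               m = summary$sigma_pred, se = summary$sigma_pred_sem))
  p5 <- ggplot(thr, aes(age_group, m, colour = what, group = what)) +
    geom_line() + geom_point() +
    geom_errorbar(aes(ymin = m - se, ymax = m + se), width = 0.1) +
    scale_colour_manual(values = c(visual = "red", auditory = "darkgreen",
                                   bimodal = "blue",
                                   `MLE prediction` = "grey50")) +
    labs(x = "age group", y = sprintf("threshold (%s)", unit), colour = NULL,
         title = sprintf("%s bisection: thresholds by age", domain)) +
    theme_minimal()
  ggsave(sprintf("results/figures/thresholds_%s.png", domain), p5,
         width = 5.5, height = 3.5, dpi = 150)
}
message("Figures written to results/figures/.")
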