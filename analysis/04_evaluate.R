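#!/usr/bin/env Rscript
# Stage 4 — group-level evaluation.
#
# Aggregates by age group: mean +/- SEM thresholds and weights, the
# explained-variance statistic over all children and conflicts of each
# group, and the one-tailed test of bimodal thresholds against the MLE
# prediction. Prints the developmental summary and writes the group
# tables.

suppressPackageStartupMessages({
  library(avbisect)
  library(jsonlite)
})

eval_out <- list()
for (domain in c("time", "space")) {
  observers <- utils::read.csv(sprintf("results/observers_%s.csv", domain))
  pses <- utils::read.csv(sprintf("results/pses_%s.csv", domain))
  agg <- aggregate_by_age(observers, pses)
  utils::write.csv(agg$summary, sprintf("results/group_summary_%s.csv", domain),
                   row.names = FALSE)
  message(sprintf("== %s bisection ==", domain))
  for (g in agg$summary$age_group) {
    r2 <- agg$r_squared[[g]]
    tt <- agg$threshold_tests[[g]]
    star <- if (tt$significant_01) "**" else if (tt$significant_05) "*" else ""
    message(sprintf(
      "  %-7s slope %+0.2f  w_A(thr) %.2f  w_A(slope) %.2f  R2 %+0.2f  bimodal %5.1f vs predicted %5.1f  p(one-tailed) %.3f %s",
      g,
      mean(observers$slope[observers$age_group == g]),
      agg$summary$w_A_thresholds[agg$summary$age_group == g],
      agg$summary$w_A_slope[agg$summary$age_group == g],
      r2$r_squared,
      agg$summary$sigma_bimodal[agg$summary$age_group == g],
      agg$summary$sigma_pred[agg$summary$age_group == g],
      tt$p_one_tailed, star))
    eval_out[[domain]][[g]] <- list(
      r_squared = r2$r_squared, t = tt$t_stat, p_one_tailed = tt$p_one_tailed,
      significant_05 = tt$significant_05, significant_01 = tt$significant_01)
  }
}
write_json(eval_out, "results/evaluation.json", auto_unbox = TRUE,
           pretty = TRUE, digits = NA)
message("Stars (bimodal threshold above the optimal prediction) mark the ",
        "capture groups; the optimal adult groups approach the harmonic ",
        "bound and the children's PSE slopes sit at the dominance lines.")
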