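#!/usr/bin/env Rscript
# Group-level statistics on the fitted experiment (run 03_experiment.R
# first): condition summaries with an AQ median split, the task x numerosity
# repeated-measures ANOVA on connected biases, AQ-bias correlations with
# default-prior Bayes factors, and the Weber-fraction attention cost.

suppressPackageStartupMessages({
  library(numgroup)
  library(dplyr)
})

if (!file.exists("results/experiment/trials.csv"))
  stop("results/experiment/trials.csv not found: run analysis/03_experiment.R first",
       call. = FALSE)
fits <- tibble::as_tibble(read.csv("results/experiment/fits.csv"))
trials <- read_trials_csv("results/experiment/trials.csv")
cohort <- read_cohort_csv("results/experiment/cohort.csv")

summary_tbl <- summarize_group_biases(fits, cohort)
cat("cell summaries (band x AQ group):\n")
print(as.data.frame(summary_tbl), digits = 3)
write.csv(summary_tbl, "results/group_summary.csv", row.names = FALSE)

conn <- fits |> filter(condition == "connected")
an <- rm_anova_within(
  conn |> transmute(observer = observer_id, task,
                    numerosity = factor(reference_numerosity),
                    bias = bias_percent),
  dv = "bias", subject = "observer", factors = c("task", "numerosity")
)
cat("\ntwo-way repeated-measures ANOVA, connected bias ~ task x numerosity:\n")
print(as.data.frame(an), digits = 4)
write.csv(an, "results/anova_task_numerosity.csv", row.names = FALSE)

stats <- experiment_stats(fits, trials, cohort)
for (task in names(stats$aq_bias_correlation)) {
  cr <- stats$aq_bias_correlation[[task]]
  cat(sprintf("\nAQ vs low-N connected bias, %s task: r = %.3f, p = %.3f, log10 BF = %.3f",
              task, cr$r, cr$p, cr$log10_bf))
}
cat(sprintf("\n\nWF attention cost: %.1f%%\n", stats$wf_attention_cost_percent))
cat(sprintf("AQ normality: JB = %.2f, p = %.2f\n",
            stats$aq_normality$jb, stats$aq_normality$p))

cat("\nfinding: the task effect on connected bias is strong and numerosity-\n")
cat("dependent, the baseline stays near zero, and the attentional precision cost\n")
cat("is near 50%. The post-fit AQ correlation is attenuated relative to the\n")
cat("cohort's expected-bias coupling because between-observer bias variance is\n")
cat("small under the object-removal model (see the methods vignette).\n")
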