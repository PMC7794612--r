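#!/usr/bin/env Rscript
# Step 5 — discriminating the three emotional states.
# Leave-one-fish-out cross-validation feeding the leading PC scores to the
# linear (Fisher LDA) and nonlinear (LLGMN) classifiers, adding PCs one by
# one. Findings: the appetitive state is barely linearly separable; the
# mixture network outperforms the linear model once four PCs are used
# (per-class F ordered normal > fear > appetitive, as in the study); and
# the posterior of the treatment-matched state shows the largest
# before/after effect size in each experiment.

library(ventrack)
dir.create("results", showWarnings = FALSE)

std <- read_index_windows("results/index_windows_standardised.csv")

rows <- list()
reports <- list()
for (clf in c("lda", "llgmn")) {
  n_range <- if (clf == "lda") 1:6 else 2:5
  for (np in n_range) {
    r <- loo_fish_cv(std, classifier = clf, n_pcs = np, seed = 1)
    reports[[paste(clf, np)]] <- r
    rows[[length(rows) + 1]] <- data.frame(
      classifier = clf, n_pcs = np, macro_f = r$scores$macro_f,
      f_normal = r$scores$f[["normal"]], f_fear = r$scores$f[["fear"]],
      f_appetitive = r$scores$f[["appetitive"]]
    )
  }
}
ftab <- do.call(rbind, rows)
print(ftab, digits = 3)
write.csv(ftab, "results/05_f_scores.csv", row.names = FALSE)

tk <- tukey_kramer(list(PC1_3 = reports[["llgmn 3"]]$fold_f$macro_f,
                        PC1_4 = reports[["llgmn 4"]]$fold_f$macro_f))
cat("\nTukey-Kramer, per-fold macro F, PC1-3 vs PC1-4 (LLGMN):\n")
print(tk, digits = 3)

best <- reports[["llgmn 4"]]
write_classifier_report(best, "results/05_llgmn_4pc_predictions.csv",
                        "results/05_llgmn_4pc_summary.json")

cat("\nposterior shifts after alarm pheromone:\n")
print(posterior_shift_analysis(best, "fear"), digits = 3)
cat("\nposterior shifts after ethanol conditioning:\n")
print(posterior_shift_analysis(best, "appetitive"), digits = 3)
write.csv(rbind(
  cbind(treatment = "alarm_pheromone", posterior_shift_analysis(best, "fear")),
  cbind(treatment = "ethanol", posterior_shift_analysis(best, "appetitive"))
), "results/05_posterior_shifts.csv", row.names = FALSE)
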