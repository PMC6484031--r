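#!/usr/bin/env Rscript
# Post-analysis of the benchmark design: pool every replicate/trait/method
# accuracy into one table and fit the linear mixed model with fixed
# Timepoint, Algorithm, Trait, Biom and all pairwise interactions, plus a
# random four-way interaction. Reports the Type III ANOVA and LS-means.

library(biomepred)

out <- "results/post"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cv <- read.csv("results/cv/cv_results.csv")
records <- assemble_table(cv)
cat(sprintf("accuracy records pooled: %d rows\n", nrow(records)))

fit <- fit_post_lmm(records)
tab <- type3_anova(fit)
print(tab, digits = 3)
write.csv(tab, file.path(out, "anova_type3.csv"), row.names = FALSE)

for (term in c("Biom", "Timepoint", "Algorithm", "Timepoint:Biom",
               "Algorithm:Biom")) {
  lsm <- ls_means(fit, term)
  cat("\nLS-means for", term, ":\n")
  print(lsm, digits = 3)
  write.csv(lsm, file.path(out, paste0(
    "ls_means_", gsub(":", "_x_", term), ".csv")), row.names = FALSE)
}

lsm_b <- ls_means(fit, "Biom")
cat(sprintf("\nmicrobiome inclusion effect: %+.3f (null %.3f -> biom %.3f)\n",
            diff(lsm_b$estimate), lsm_b$estimate[1], lsm_b$estimate[2]))
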