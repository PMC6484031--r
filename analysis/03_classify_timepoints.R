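#!/usr/bin/env Rscript
# Preliminary check that the three sampling times constitute distinct
# microbial communities: a random-forest classifier assigns each sample to
# its timepoint under the same sire-stratified repeated-split scheme used
# for trait prediction; the row-normalised confusion matrix is the summary.

library(biomepred)

seed <- 2026L
loaded <- read_tables("results/cohort")
out <- "results/classification"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pheno <- loaded$phenotypes
complete <- Reduce(intersect,
                   lapply(loaded$otu_tables, function(t) t$meta$animal_id))
keep <- pheno$animal_id %in% complete
folds <- make_folds(pheno$animal_id[keep], pheno$sire[keep],
                    n_repeats = 5, seed = stage_seed(seed, "classify"))

cm <- classify_timepoint(loaded$otu_tables, folds,
                         params = ensemble_params(n_trees = 500))
print(round(cm$confusion, 3))
cat(sprintf("mean per-class accuracy: %.3f\n", cm$accuracy))

write.csv(data.frame(truth = rownames(cm$confusion), cm$confusion,
                     check.names = FALSE),
          file.path(out, "confusion_matrix.csv"), row.names = FALSE)
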