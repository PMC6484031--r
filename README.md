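# biomepred

Can the fecal microbiome predict how a pig will grow? `biomepred` is an R
package and analysis workflow for benchmarking microbiome-wide phenotype
prediction in swine: it contrasts models that include fecal 16S OTU
abundances against fixed-effects-only baselines for growth and carcass
traits, across three sampling timepoints (weaning, week 15, week 22 of a
nursery-finishing trial), four predictor families, and a sire-stratified
repeated cross-validation design. It is aimed at quantitative geneticists
and microbiome researchers exploring microbiability — the microbiome
analogue of genomic prediction.

Because individual-level herd data of this kind are typically restricted,
the package ships a cohort simulator with known ground truth (28 sire
families x 6 replicates x single-sex pens, Dirichlet-multinomial OTU
tables with community-gradient co-abundance, trait variance shares you
control), so every stage of the benchmark is testable end to end.

## The models

For a trait vector **y**, the *null* model is

    y = mu + X b + e

with fixed effects for sex (2 levels), replicate (6), sire (28) and the
weaning-weight covariate. The *biom* model adds the microbiome, either as

    y = mu + X b + W o + e

where **W** is the centered and scaled OTU count matrix (scaling fitted on
training folds only) and **o** carries one effect per OTU under a
double-exponential (Bayesian Lasso) prior, sampled by Gibbs; or as

    y = mu + X b + u + e,   u ~ N(0, M sigma_u^2)

an RKHS (kernel mixed-model) regression whose covariance **M = 1 − JSD**
derives from pairwise Jensen-Shannon distances between samples
(base-2 logs, so distances live in [0, 1]); or as tree ensembles (random
forest; gradient boosting with depth 3, shrinkage 0.01, 1500 trees) on the
same features. Prediction accuracy is the Pearson correlation between
predicted and observed phenotypes in held-out test sets, averaged over
five sire-stratified 70/30 splits, with 90% CIs and a CI-overlap
significance flag for the biom-vs-null contrast. A linear mixed model over
the pooled accuracy table (fixed Timepoint, Algorithm, Trait, Biom and all
pairwise interactions; random four-way interaction) summarises the whole
design with a Type III ANOVA and LS-means.

## Worked example

```r
library(biomepred)

cfg <- cohort_config(n_sires = 14, n_replicates = 3, n_otus = 200,
                     depth = 2500, dropout_rate = 0, seed = 7)
specs <- default_trait_specs()[6, ]           # back fat at week 14
specs$microbiome_r2 <- 0.5                    # strong OTU signal
specs$fixed_r2 <- 0.10
bundle <- generate_cohort(cfg, specs = specs)

hy <- list(bl = bl_hyper(n_iter = 1500, burn_in = 300, thin = 3),
           rkhs = rkhs_hyper(n_iter = 1500, burn_in = 300, thin = 3),
           ensemble = ensemble_params(n_trees = 600))
cv <- run_cv(bundle, timepoints = "wk15", n_repeats = 3, hypers = hy,
             seed = 7)
subset(summarize_cv(cv)$model_average, select = -trait)
```

```
  timepoint algorithm  biom accuracy_mean   mse_mean
1      wk15       AVG FALSE     0.1837502 0.07726675
2      wk15       AVG  TRUE     0.3611889 0.06826614
```

Averaged over the four algorithms, including week-15 OTU abundances lifts
test-set accuracy from 0.18 to 0.36 (and lowers MSE) on this cohort — the
simulated trait carries half its variance in the microbiome, and the
benchmark recovers a gain of that order while the fixed-effects baseline
stays near the modest level its 10% variance share implies.

The numbered scripts under `analysis/` run the same machinery as a
narrative study: `01_simulate.R` (cohort), `02_preprocess_kernels.R`
(QC + JSD kernels), `03_classify_timepoints.R` (community distinctness),
`04_cross_validation.R` (the benchmark), `05_post_analysis.R` (mixed-model
summary), each writing its tables under `results/`.

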