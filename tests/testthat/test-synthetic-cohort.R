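test_that("generate_design emits the fully crossed sampled herd", {
  d <- generate_design(cohort_config(seed = 1))
  expect_equal(nrow(d), 28 * 6 * 2 * 4)
  # every pen is single-sex and single-sire, at sampled size
  pens <- split(d, d$pen)
  expect_true(all(vapply(pens, function(p)
    length(unique(p$sex)) == 1 && length(unique(p$sire)) == 1 &&
      nrow(p) == 4, TRUE)))
  # sire x replicate x sex fully crossed
  tab <- table(d$sire, d$replicate, d$sex)
  expect_true(all(tab == 4))
  # minimal design
  d2 <- generate_design(cohort_config(n_sires = 1, n_replicates = 1,
                                      seed = 1))
  expect_equal(nrow(d2), 8)
  expect_equal(length(unique(d2$pen)), 2)
  # determinism
  expect_identical(generate_design(cohort_config(seed = 7)),
                   generate_design(cohort_config(seed = 7)))
})

test_that("cohort_config validates its invariants", {
  expect_error(cohort_config(n_sires = 0), "positive")
  expect_error(cohort_config(dropout_rate = 1), "dropout_rate")
  expect_error(cohort_config(timepoints = c("a", "b")), "3 timepoints")
  expect_error(cohort_config(sampled_per_pen = 30), "exceed")
})

test_that("simulated OTU tables sum exactly to depth with dominant mass", {
  cfg <- cohort_config(n_sires = 2, n_replicates = 2, n_otus = 200,
                       depth = 3000, seed = 3)
  d <- generate_design(cfg)
  otus <- generate_microbiome(d, cfg, separation = 1)
  for (tp in names(otus))
    expect_true(all(rowSums(otus[[tp]]$counts) == 3000))
  # six dominant blocks carry ~96% of expected mass at every timepoint
  bases <- attr(otus, "baselines")
  block <- attr(bases, "block")
  for (tp in seq_len(3)) {
    mass <- sum(bases[[tp]][block > 0])
    expect_gte(mass, 0.95); expect_lte(mass, 0.98)
  }
  # realised sample-level dominant mass stays near the target
  rel <- to_relative(otus$wk15)
  expect_gt(mean(rowSums(rel[, block > 0])), 0.93)
  # separation = 0 gives identical baselines
  b0 <- attr(generate_microbiome(d, cfg, separation = 0), "baselines")
  expect_equal(b0[[1]], b0[[2]])
  expect_equal(b0[[2]], b0[[3]])
  # determinism
  o2 <- generate_microbiome(d, cfg, separation = 1)
  expect_identical(otus$wean$counts, o2$wean$counts)
})

test_that("phenotypes hit their trait means/SDs and variance partitions", {
  cfg <- cohort_config(n_otus = 150, depth = 2000, dropout_rate = 0,
                       seed = 5)
  d <- generate_design(cfg)
  otus <- generate_microbiome(d, cfg)
  specs <- default_trait_specs()
  ph <- generate_phenotypes(d, otus, specs)
  y <- ph$phenotypes$ADGBto14
  n <- length(y)
  # large-cohort sample moments close to the target 0.57 (0.08)
  expect_lt(abs(mean(y) - 0.57), 2 * 0.08 / sqrt(n))
  expect_lt(abs(sd(y) - 0.08), 0.012)
  # oracle regression on the true microbiome signal recovers its share
  tr <- ph$truth$traits$Week14BF
  r2 <- summary(lm(ph$phenotypes$Week14BF ~ tr$signal_biome))$r.squared
  expect_lt(abs(r2 - specs$microbiome_r2[specs$name == "Week14BF"]), 0.05)
  # and the fixed-effect share likewise
  r2f <- summary(lm(ph$phenotypes$Week14BF ~ tr$signal_fixed))$r.squared
  expect_lt(abs(r2f - specs$fixed_r2[specs$name == "Week14BF"]), 0.05)
})

test_that("zero microbiome share produces no OTU-phenotype association", {
  cfg <- cohort_config(n_sires = 6, n_replicates = 3, n_otus = 80,
                       depth = 1500, dropout_rate = 0, seed = 9)
  d <- generate_design(cfg)
  otus <- generate_microbiome(d, cfg)
  specs <- default_trait_specs()[1, ]
  specs$microbiome_r2 <- 0
  ph <- generate_phenotypes(d, otus, specs)
  expect_equal(ph$truth$traits$ADGBto14$otu_effects,
               rep(0, 80))
  # correlation with any OTU-derived signal is at noise level
  W <- scale(otus$wk15$counts)
  W[, !is.finite(colSums(W))] <- 0
  proj <- W %*% rnorm(80)
  r <- cor(ph$phenotypes$ADGBto14, proj)
  expect_lt(abs(r), 3 / sqrt(nrow(d)))
})

test_that("generate_phenotypes rejects invalid variance shares", {
  specs <- default_trait_specs()[1, ]
  specs$microbiome_r2 <- 0.7
  specs$fixed_r2 <- 0.5
  cfg <- cohort_config(n_sires = 1, n_replicates = 1, n_otus = 20,
                       depth = 500, seed = 2)
  d <- generate_design(cfg)
  otus <- generate_microbiome(d, cfg)
  expect_error(generate_phenotypes(d, otus, specs), "exceed")
})

test_that("generate_cohort applies calibrated dropout and is reproducible", {
  cfg <- cohort_config(seed = 13, n_otus = 60, depth = 800)
  b <- generate_cohort(cfg)
  n <- nrow(b$design)
  expect_equal(n, 1344)
  # complete-case count near 1039 within binomial noise
  p_complete <- 1 - cfg$dropout_rate
  se <- sqrt(n * p_complete * (1 - p_complete))
  expect_lt(abs(length(b$complete_animals) - 1039), 3 * se)
  # per-timepoint sample counts lie between complete and total
  for (tp in names(b$otu_tables)) {
    k <- nrow(b$otu_tables[[tp]]$counts)
    expect_gte(k, length(b$complete_animals)); expect_lte(k, n)
  }
  # identical config -> byte-identical bundle
  b2 <- generate_cohort(cfg)
  expect_identical(b$otu_tables$wk22$counts, b2$otu_tables$wk22$counts)
  expect_identical(b$phenotypes, b2$phenotypes)
  # different seed -> different tables, same shapes
  b3 <- generate_cohort(cohort_config(seed = 14, n_otus = 60, depth = 800))
  expect_false(identical(b$otu_tables$wean$counts,
                         b3$otu_tables$wean$counts))
  expect_equal(ncol(b$otu_tables$wean$counts),
               ncol(b3$otu_tables$wean$counts))
  expect_equal(nrow(b3$design), 1344)
})
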