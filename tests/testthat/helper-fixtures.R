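# shared in-code fixtures for the suite; everything is generated, nothing
# is read from disk

tiny_otu_table <- function(counts, timepoint = "wk15") {
  n <- nrow(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("OTU%03d", seq_len(ncol(counts)))
  meta <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                     animal_id = sprintf("a%02d", seq_len(n)),
                     timepoint = timepoint, stringsAsFactors = FALSE)
  biomepred:::new_otu_table(counts, meta)
}

random_compositions <- function(n, p, seed = 1) {
  set.seed(seed)
  P <- matrix(stats::rexp(n * p), n, p)
  P / rowSums(P)
}

small_cohort <- function(seed = 11, n_otus = 100, depth = 1500,
                         n_sires = 4, n_replicates = 2, ...) {
  generate_cohort(cohort_config(n_sires = n_sires,
                                n_replicates = n_replicates,
                                n_otus = n_otus, depth = depth,
                                seed = seed, ...))
}

fast_hypers <- function(trees = 100L) {
  list(bl = bl_hyper(n_iter = 600L, burn_in = 150L, thin = 2L),
       rkhs = rkhs_hyper(n_iter = 600L, burn_in = 150L, thin = 2L),
       ensemble = ensemble_params(n_trees = trees))
}

# batch-means Monte-Carlo standard error for a (possibly autocorrelated)
# chain; used as the yardstick in sampler-vs-oracle comparisons
mc_se <- function(chain, n_batches = 20) {
  n <- length(chain)
  b <- max(2, floor(n / n_batches))
  k <- floor(n / b)
  means <- vapply(seq_len(k), function(i) mean(chain[((i - 1) * b + 1):(i * b)]),
                  numeric(1))
  stats::sd(means) / sqrt(k)
}
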