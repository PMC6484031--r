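#' Cohort configuration for the synthetic herd generator
#'
#' Describes a nursery-finishing trial of purebred-sire families: each of
#' `n_sires` sires contributes, in each of `n_replicates` replicates, one pen
#' of females and one pen of castrated males (20 pigs per pen, of which 4 are
#' sampled for microbiome sequencing and carcass measurements). The defaults
#' reproduce a 28-sire, 6-replicate trial of 1344 sampled animals, with an
#' animal-level dropout rate calibrated so that roughly 1039 of them have
#' fecal samples at all three timepoints.
#'
#' @param n_sires number of sires (default 28).
#' @param n_replicates number of replicates of the basic block (default 6).
#' @param pens_per_sire_per_replicate pens per sire per replicate, one per
#'   sex (default 2).
#' @param pigs_per_pen physical pen size (default 20); only `sampled_per_pen`
#'   animals per pen enter the emitted design.
#' @param sampled_per_pen animals sampled per pen (default 4).
#' @param dropout_rate probability an animal misses at least one timepoint
#'   (default 0.2269, i.e. ~1039/1344 complete cases).
#' @param n_otus number of OTUs in the simulated table (default 1755).
#' @param depth per-sample sequencing depth after rarefaction (default 10000).
#' @param timepoints three ordered timepoint labels.
#' @param concentration Dirichlet concentration governing sample-to-sample
#'   overdispersion around the timepoint baseline composition (default 150).
#' @param gradient_sd spread of the per-sample community gradient: each
#'   sample's expected composition is tilted along a fixed OTU loading axis
#'   by a latent Normal(0, `gradient_sd`) score, inducing the co-abundance
#'   structure (enterotype-like gradients) seen in real 16S data (default
#'   0.4; 0 disables).
#' @param seed master seed for the cohort.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_sires = 28L, n_replicates = 6L,
                          pens_per_sire_per_replicate = 2L,
                          pigs_per_pen = 20L, sampled_per_pen = 4L,
                          dropout_rate = 0.2269, n_otus = 1755L,
                          depth = 10000L,
                          timepoints = c("wean", "wk15", "wk22"),
                          concentration = 150, gradient_sd = 0.4,
                          seed = 1L) {
  cfg <- list(n_sires = as.integer(n_sires),
              n_replicates = as.integer(n_replicates),
              pens_per_sire_per_replicate = as.integer(pens_per_sire_per_replicate),
              pigs_per_pen = as.integer(pigs_per_pen),
              sampled_per_pen = as.integer(sampled_per_pen),
              dropout_rate = dropout_rate,
              n_otus = as.integer(n_otus),
              depth = as.integer(depth),
              timepoints = as.character(timepoints),
              concentration = concentration,
              gradient_sd = gradient_sd,
              seed = as.integer(seed))
  counts <- c(cfg$n_sires, cfg$n_replicates, cfg$pens_per_sire_per_replicate,
              cfg$pigs_per_pen, cfg$sampled_per_pen, cfg$n_otus, cfg$depth)
  if (any(counts < 1L)) stop("all cohort counts must be positive")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (length(cfg$timepoints) != 3L)
    stop("exactly 3 timepoints are required")
  if (cfg$sampled_per_pen > cfg$pigs_per_pen)
    stop("sampled_per_pen cannot exceed pigs_per_pen")
  if (cfg$concentration <= 0) stop("concentration must be positive")
  if (cfg$gradient_sd < 0) stop("gradient_sd must be non-negative")
  class(cfg) <- "cohort_config"
  cfg
}

#' Default trait specifications
#'
#' The twelve growth and carcass traits of the benchmark, with means and
#' standard deviations of the phenotype summary of the source population:
#' average daily gains over four windows, and live weight, back fat, loin
#' depth and loin eye area at weeks 14 and 22. `microbiome_r2` and `fixed_r2`
#' are the target shares of phenotypic variance attributable to OTU effects
#' and to the design factors (sex, replicate, sire, weaning weight);
#' `n_causal_otus = 0` denotes dense OTU effects.
#'
#' Default `microbiome_r2` values follow the observed gradient in predictive
#' value: fatness and gain traits carry more microbiome signal than loin
#' traits.
#'
#' @return data.frame with one row per trait.
#' @export
default_trait_specs <- function() {
  data.frame(
    name = c("ADGBto14", "ADGWto14", "ADG14to22", "ADG14toMKT",
             "Week14Wt", "Week14BF", "Week14LD", "Week14LEA",
             "Week22Wt", "Week22BF", "Week22LD", "Week22LEA"),
    mean = c(0.57, 0.64, 0.86, 0.89, 68.78, 1.25, 4.24, 28.38,
             117.26, 2.00, 5.59, 43.90),
    sd   = c(0.08, 0.10, 0.16, 0.14, 9.88, 0.28, 0.48, 4.57,
             13.37, 0.53, 0.52, 5.69),
    microbiome_r2 = c(0.30, 0.30, 0.20, 0.20, 0.30, 0.35, 0.10, 0.15,
                      0.25, 0.30, 0.10, 0.15),
    fixed_r2 = rep(0.10, 12L),
    n_causal_otus = rep(0L, 12L),
    stringsAsFactors = FALSE
  )
}

validate_trait_specs <- function(specs) {
  stopifnot(is.data.frame(specs),
            all(c("name", "mean", "sd", "microbiome_r2", "fixed_r2",
                  "n_causal_otus") %in% names(specs)))
  if (any(specs$sd <= 0)) stop("trait sd must be positive")
  if (any(specs$microbiome_r2 < 0) || any(specs$fixed_r2 < 0))
    stop("variance shares must be non-negative")
  if (any(specs$microbiome_r2 + specs$fixed_r2 > 1))
    stop("microbiome_r2 + fixed_r2 must not exceed 1")
  if (anyDuplicated(specs$name)) stop("duplicate trait names")
  invisible(specs)
}

#' Generate the sampled herd design
#'
#' Emits one row per sampled animal of a fully crossed sire x replicate x sex
#' layout: every pen is single-sex and single-sire (pen mates are paternal
#' half-siblings of the same gender), and only the `sampled_per_pen` animals
#' chosen for measurement appear. Weaning weight is Normal around 5.6 kg with
#' an animal-level component that later feeds the early-gain traits.
#'
#' @param config a [cohort_config()].
#' @return data.frame: `animal_id`, `sire`, `replicate`, `sex` (F or C),
#'   `pen`, `weaning_weight`.
#' @export
generate_design <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  sexes <- c("F", "C")[seq_len(config$pens_per_sire_per_replicate)]
  if (config$pens_per_sire_per_replicate > 2L)
    sexes <- rep(c("F", "C"), length.out = config$pens_per_sire_per_replicate)
  grid <- expand.grid(sire = seq_len(config$n_sires),
                      replicate = seq_len(config$n_replicates),
                      pen_slot = seq_len(config$pens_per_sire_per_replicate),
                      KEEP.OUT.ATTRS = FALSE)
  grid$sex <- sexes[grid$pen_slot]
  grid$pen <- sprintf("s%02dr%d%s%d", grid$sire, grid$replicate, grid$sex,
                      grid$pen_slot)
  design <- grid[rep(seq_len(nrow(grid)), each = config$sampled_per_pen), ]
  n <- nrow(design)
  design$animal_id <- sprintf("a%05d", seq_len(n))
  with_seed(stage_seed(config$seed, "design"), {
    animal_eff <- stats::rnorm(n)
    design$weaning_weight <- round(5.6 + 0.8 * animal_eff +
                                     stats::rnorm(n, sd = 0.6), 3)
  })
  rownames(design) <- NULL
  design <- design[, c("animal_id", "sire", "replicate", "sex", "pen",
                       "weaning_weight")]
  attr(design, "config") <- config
  design
}

# timepoint baseline compositions: a shared log-normal abundance profile,
# perturbed per timepoint by `separation`, with six designated dominant-group
# OTU blocks rescaled to carry ~96% of the expected mass (the share of reads
# falling into the six major phyla of a commercial pig herd).
baseline_compositions <- function(config, separation) {
  n_otus <- config$n_otus
  with_seed(stage_seed(config$seed, "baselines"), {
    n_dom <- max(6L, round(0.85 * n_otus))
    block <- integer(n_otus)
    # six blocks with geometric-ish sizes, Firmicutes/Bacteroidetes-heavy
    w <- c(0.45, 0.30, 0.10, 0.07, 0.05, 0.03)
    sizes <- pmax(1L, round(w / sum(w) * n_dom))
    sizes[1] <- n_dom - sum(sizes[-1])
    block[seq_len(n_dom)] <- rep(seq_len(6L), times = sizes)
    logw <- stats::rnorm(n_otus, mean = 0, sd = 1.5)
    # dominant mass declines slowly over the trial; the drift scales with
    # the separation so that separation = 0 gives identical baselines
    drift <- min(separation, 1)
    dom_target <- 0.968 + drift * c(0.01, 0, -0.01)
    out <- vector("list", 3L)
    names(out) <- config$timepoints
    for (t in seq_len(3L)) {
      z <- stats::rnorm(n_otus)
      lw <- logw + separation * z
      p <- exp(lw - max(lw))
      p <- p / sum(p)
      dom <- block > 0L
      p[dom] <- p[dom] / sum(p[dom]) * dom_target[t]
      p[!dom] <- p[!dom] / sum(p[!dom]) * (1 - dom_target[t])
      out[[t]] <- p
    }
    attr(out, "block") <- block
    attr(out, "dominant_target") <- dom_target
    # shared community-gradient loading axis (co-abundance structure)
    attr(out, "gradient_loading") <- stats::rnorm(n_otus)
    out
  })
}

new_otu_table <- function(counts, meta) {
  stopifnot(is.matrix(counts), nrow(counts) == nrow(meta))
  storage.mode(counts) <- "integer"
  rownames(counts) <- meta$sample_id
  structure(list(counts = counts, meta = meta), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d OTUs (timepoints: %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$meta$timepoint), collapse = ", ")))
  invisible(x)
}

#' Simulate per-timepoint OTU tables for a herd design
#'
#' Counts are Dirichlet-multinomial around a timepoint-specific baseline
#' composition at the configured depth, so every sample sums exactly to
#' `config$depth`. `separation` controls how far the three timepoint
#' baselines diverge (0 = identical communities; the default 1 yields three
#' clearly distinct community states, as observed between weaning and the
#' later growth phases).
#'
#' @param design output of [generate_design()].
#' @param config the [cohort_config()].
#' @param separation non-negative divergence of timepoint baselines.
#' @return named list of `otu_table` objects, one per timepoint.
#' @export
generate_microbiome <- function(design, config, separation = 1) {
  stopifnot(inherits(config, "cohort_config"), separation >= 0)
  if (config$depth < 1L) stop("depth must be >= 1")
  bases <- baseline_compositions(config, separation)
  otu_ids <- sprintf("OTU%04d", seq_len(config$n_otus))
  n <- nrow(design)
  out <- vector("list", 3L)
  names(out) <- config$timepoints
  for (t in seq_along(config$timepoints)) {
    tp <- config$timepoints[t]
    v <- attr(bases, "gradient_loading")
    counts <- with_seed(stage_seed(config$seed, paste0("microbiome_", tp)), {
      base_log <- log(bases[[t]])
      m <- matrix(0L, nrow = n, ncol = config$n_otus)
      grad <- stats::rnorm(n, sd = config$gradient_sd %||% 0)
      for (i in seq_len(n)) {
        # tilt the baseline along the community gradient, then draw
        # Dirichlet-multinomial counts around the tilted composition
        lw <- base_log + grad[i] * v
        pi_i <- exp(lw - max(lw))
        pi_i <- pi_i / sum(pi_i)
        alpha <- config$concentration * pi_i
        g <- stats::rgamma(config$n_otus, shape = alpha, rate = 1)
        if (all(g == 0)) g <- pi_i
        m[i, ] <- as.integer(stats::rmultinom(1L, config$depth, g / sum(g)))
      }
      m
    })
    colnames(counts) <- otu_ids
    meta <- data.frame(sample_id = paste(design$animal_id, tp, sep = "_"),
                       animal_id = design$animal_id,
                       timepoint = tp, stringsAsFactors = FALSE)
    out[[tp]] <- new_otu_table(counts, meta)
  }
  attr(out, "baselines") <- bases
  out
}

#' Simulate phenotypes over a herd design with known ground truth
#'
#' Each trait is built as `y = mu + Xb + Wo + e`: a fixed-effect layer (sex,
#' replicate, sire effects plus a weaning-weight covariate), an OTU layer
#' through the centered/scaled counts `W` of the causal timepoint, and an
#' iid Gaussian residual. Effect layers are rescaled so the realised variance
#' shares match each trait's `microbiome_r2`/`fixed_r2`, and the generating
#' effects are returned for recovery tests.
#'
#' @param design output of [generate_design()].
#' @param otus list of `otu_table` objects from [generate_microbiome()].
#' @param specs trait specification data.frame ([default_trait_specs()]).
#' @param causal_timepoint which timepoint's OTU table drives the phenotypes
#'   (default `"wk15"`).
#' @param seed optional; defaults to the design's config seed.
#' @return list with `phenotypes` (data.frame) and `truth` (per-trait effect
#'   vectors and realised signal components).
#' @export
generate_phenotypes <- function(design, otus, specs = default_trait_specs(),
                                causal_timepoint = "wk15", seed = NULL) {
  validate_trait_specs(specs)
  config <- attr(design, "config")
  seed <- seed %||% stage_seed(config$seed %||% 1L, "phenotypes")
  if (inherits(otus, "otu_table")) {
    causal <- otus
  } else {
    if (!causal_timepoint %in% names(otus))
      stop("causal timepoint '", causal_timepoint, "' not found in OTU tables")
    causal <- otus[[causal_timepoint]]
  }
  idx <- match(design$animal_id, causal$meta$animal_id)
  if (anyNA(idx))
    stop("OTU table must cover every animal at the causal timepoint")
  W <- scale(causal$counts[idx, , drop = FALSE])
  W[, attr(W, "scaled:scale") == 0] <- 0
  n <- nrow(design)
  pheno <- design
  truth <- list(causal_timepoint = causal_timepoint, traits = list())
  with_seed(seed, {
    for (k in seq_len(nrow(specs))) {
      sp <- specs[k, ]
      sex_eff <- stats::rnorm(2L); names(sex_eff) <- c("F", "C")
      rep_eff <- stats::rnorm(config$n_replicates %||%
                                max(design$replicate))
      sire_eff <- stats::rnorm(max(design$sire))
      ww_beta <- stats::rnorm(1L)
      f_raw <- sex_eff[design$sex] + rep_eff[design$replicate] +
        sire_eff[design$sire] +
        ww_beta * as.numeric(scale(design$weaning_weight))
      f <- if (sp$fixed_r2 > 0 && stats::sd(f_raw) > 0) {
        as.numeric(scale(f_raw)) * sqrt(sp$fixed_r2) * sp$sd
      } else rep(0, n)
      p <- ncol(W)
      o <- stats::rnorm(p)
      if (sp$n_causal_otus > 0L) {
        keep <- sample.int(p, min(sp$n_causal_otus, p))
        o[-keep] <- 0
      }
      m_raw <- as.numeric(W %*% o)
      if (sp$microbiome_r2 > 0 && stats::sd(m_raw) > 0) {
        fac <- sqrt(sp$microbiome_r2) * sp$sd / stats::sd(m_raw)
        o <- o * fac
        m <- (m_raw - mean(m_raw)) * fac
      } else {
        o <- o * 0
        m <- rep(0, n)
      }
      res_sd <- sqrt(max(0, 1 - sp$microbiome_r2 - sp$fixed_r2)) * sp$sd
      e <- stats::rnorm(n, sd = res_sd)
      pheno[[sp$name]] <- sp$mean + f + m + e
      truth$traits[[sp$name]] <- list(
        fixed_effects = list(sex = sex_eff, replicate = rep_eff,
                             sire = sire_eff, weaning_weight = ww_beta),
        otu_effects = o,
        residual_sd = res_sd,
        signal_fixed = f, signal_biome = m)
    }
  })
  list(phenotypes = pheno, truth = truth)
}

#' Generate a complete synthetic cohort bundle
#'
#' Orchestrates [generate_design()], [generate_microbiome()] and
#' [generate_phenotypes()] under a single master seed, then applies
#' animal-level dropout: each animal independently misses at least one
#' timepoint with probability `config$dropout_rate` (one missing timepoint
#' four times out of five, two otherwise), so the default configuration
#' leaves ~1039 of 1344 animals complete.
#'
#' @param config a [cohort_config()].
#' @param specs trait specifications.
#' @param separation timepoint divergence passed to [generate_microbiome()].
#' @param causal_timepoint passed to [generate_phenotypes()].
#' @param write_dir optional directory; if given, tables are written as
#'   TSV/CSV via [write_cohort()].
#' @return list: `design`, `otu_tables` (after dropout), `phenotypes`,
#'   `truth`, `config`, `complete_animals`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            specs = default_trait_specs(),
                            separation = 1, causal_timepoint = "wk15",
                            write_dir = NULL) {
  design <- generate_design(config)
  otus <- generate_microbiome(design, config, separation = separation)
  ph <- generate_phenotypes(design, otus, specs,
                            causal_timepoint = causal_timepoint)
  # dropout: applied after phenotype generation so the causal layer is
  # defined for every animal; emulates failed swabs/sequencing QC
  with_seed(stage_seed(config$seed, "dropout"), {
    n <- nrow(design)
    miss <- stats::runif(n) < config$dropout_rate
    drop_map <- matrix(FALSE, n, 3L,
                       dimnames = list(design$animal_id, config$timepoints))
    for (i in which(miss)) {
      k <- if (stats::runif(1) < 0.8) 1L else 2L
      drop_map[i, sample.int(3L, k)] <- TRUE
    }
  })
  otus_out <- otus
  for (tp in config$timepoints) {
    keep <- !drop_map[otus[[tp]]$meta$animal_id, tp]
    otus_out[[tp]] <- new_otu_table(otus[[tp]]$counts[keep, , drop = FALSE],
                                    otus[[tp]]$meta[keep, , drop = FALSE])
  }
  complete <- design$animal_id[rowSums(drop_map) == 0L]
  bundle <- list(design = design, otu_tables = otus_out,
                 phenotypes = ph$phenotypes, truth = ph$truth,
                 config = config, complete_animals = complete)
  class(bundle) <- "cohort_bundle"
  if (!is.null(write_dir)) write_cohort(bundle, write_dir)
  bundle
}
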