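#' Sire-stratified repeated train/test splits
#'
#' The benchmark's "five-fold" scheme: `n_repeats` independent random splits
#' into ~70% training and ~30% test animals, stratified so each sire family
#' contributes `round(train_frac * n_offspring)` animals to training. A sire
#' with a single offspring goes to training with a warning.
#'
#' @param animals character vector of animal ids.
#' @param sires sire labels aligned with `animals`.
#' @param n_repeats number of repeated splits (default 5).
#' @param train_frac training fraction (default 0.70; must leave a nonempty
#'   test set).
#' @param seed RNG seed.
#' @return list of `n_repeats` folds, each `list(repeat_index, train, test,
#'   train_frac_by_sire)`.
#' @export
make_folds <- function(animals, sires, n_repeats = 5L, train_frac = 0.70,
                       seed = 1L) {
  stopifnot(length(animals) == length(sires), n_repeats >= 1)
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must be strictly between 0 and 1")
  if (anyDuplicated(animals)) stop("duplicate animal ids")
  singles <- names(which(table(sires) == 1L))
  if (length(singles))
    warning("sire(s) with a single offspring assigned to training: ",
            paste(singles, collapse = ", "))
  with_seed(seed, {
    folds <- lapply(seq_len(n_repeats), function(r) {
      train <- character(0)
      for (s in unique(sires)) {
        ids <- animals[sires == s]
        n_train <- if (length(ids) == 1L) 1L else
          min(length(ids) - 1L, max(1L, round(train_frac * length(ids))))
        train <- c(train, sample(ids, n_train))
      }
      test <- setdiff(animals, train)
      if (!length(test)) stop("empty test set; lower train_frac")
      frac <- vapply(unique(sires), function(s) {
        ids <- animals[sires == s]
        mean(ids %in% train)
      }, numeric(1))
      list(repeat_index = r, train = train, test = test,
           train_frac_by_sire = stats::setNames(frac, unique(sires)))
    })
  })
  folds
}

#' Pearson prediction accuracy
#'
#' @param pred predicted phenotypes.
#' @param obs observed phenotypes (non-constant, >= 3 pairs).
#' @return Pearson correlation; `NaN` (with a warning) for constant
#'   predictions, so the cell can be excluded from averages.
#' @export
accuracy_pearson <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  if (length(obs) < 3L) stop("need at least 3 prediction pairs")
  if (stats::sd(obs) == 0) stop("observed values are constant")
  if (stats::sd(pred) == 0) {
    warning("constant predictions; accuracy undefined")
    return(NaN)
  }
  stats::cor(pred, obs)
}

algo_registry <- function() c("BL", "RKHS", "RF", "GBM")

# fit one (algorithm, biom) cell on a training fold and predict the test fold
fit_cell <- function(algorithm, biom, y, X, Wtab, kernel, train_idx,
                     test_idx, hypers) {
  if (algorithm %in% c("BL", "RKHS") && !biom) {
    fit <- fit_null(y[train_idx], X[train_idx, , drop = FALSE])
    return(predict(fit, X[test_idx, , drop = FALSE]))
  }
  switch(
    algorithm,
    BL = {
      sm <- build_W(Wtab, reference = rownames(Wtab$counts)[train_idx])
      fit <- fit_bayesian_lasso(y[train_idx], X[train_idx, , drop = FALSE],
                                sm$W[train_idx, , drop = FALSE],
                                hyper = hypers$bl)
      predict(fit, X[test_idx, , drop = FALSE],
              sm$W[test_idx, , drop = FALSE])
    },
    RKHS = {
      fit <- fit_rkhs(y, X, kernel, hyper = hypers$rkhs,
                      train_idx = train_idx, test_idx = test_idx)
      fit$predictions
    },
    RF = {
      feats <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
      if (biom) {
        sm <- build_W(Wtab, reference = rownames(Wtab$counts)[train_idx])
        feats <- cbind(feats, sm$W)
      }
      fit <- fit_forest(y[train_idx], feats[train_idx, , drop = FALSE],
                        params = hypers$ensemble)
      predict(fit, feats[test_idx, , drop = FALSE])
    },
    GBM = {
      feats <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
      if (biom) {
        sm <- build_W(Wtab, reference = rownames(Wtab$counts)[train_idx])
        feats <- cbind(feats, sm$W)
      }
      fit <- fit_gbm(y[train_idx], feats[train_idx, , drop = FALSE],
                     params = hypers$ensemble)
      predict(fit, feats[test_idx, , drop = FALSE])
    },
    stop("unknown algorithm: ", algorithm)
  )
}

#' Run the cross-validation benchmark
#'
#' For every cell of the trait x timepoint x algorithm x \{null, biom\}
#' factorial, fits on the training animals of each repeated split and
#' records the Pearson accuracy and MSE on the test animals. The analysis
#' set is restricted to complete-case animals (those with samples at all
#' three timepoints); OTU scaling is recomputed within each training fold.
#' Null fits do not use OTU data, so each null cell is computed once per
#' trait/algorithm/repeat and shared across timepoints.
#'
#' @param bundle a cohort bundle from [generate_cohort()] (or an equivalent
#'   list with `phenotypes`, `otu_tables`, `complete_animals`).
#' @param traits trait names (default: all 12).
#' @param timepoints timepoint labels (default: all three tables).
#' @param algorithms subset of `c("BL", "RKHS", "RF", "GBM")`.
#' @param folds fold list from [make_folds()]; built from the bundle when
#'   `NULL`.
#' @param hypers list with `bl`, `rkhs`, `ensemble` hyperparameter objects.
#' @param select_bl_lambda if `TRUE`, rerun the lambda grid search inside
#'   each training fold (slow); default uses `hypers$bl$lambda` as fixed.
#' @param n_repeats,seed used when `folds` is `NULL`.
#' @return data.frame of class `cv_result`: one row per cell x repeat with
#'   `trait, timepoint, algorithm, biom, repeat_index, accuracy, mse`.
#' @export
run_cv <- function(bundle, traits = NULL, timepoints = NULL,
                   algorithms = algo_registry(), folds = NULL,
                   hypers = NULL, select_bl_lambda = FALSE,
                   n_repeats = 5L, seed = 1L) {
  pheno <- bundle$phenotypes
  otus <- bundle$otu_tables
  timepoints <- timepoints %||% names(otus)
  traits <- traits %||% setdiff(names(pheno),
                                c("animal_id", "sire", "replicate", "sex",
                                  "pen", "weaning_weight"))
  hypers <- hypers %||% list()
  hypers$bl <- hypers$bl %||% bl_hyper()
  hypers$rkhs <- hypers$rkhs %||% rkhs_hyper()
  hypers$ensemble <- hypers$ensemble %||% ensemble_params()
  complete <- Reduce(intersect,
                     lapply(otus[timepoints], function(t) t$meta$animal_id))
  if (!is.null(bundle$complete_animals))
    complete <- intersect(complete, bundle$complete_animals)
  pheno <- pheno[pheno$animal_id %in% complete, , drop = FALSE]
  pheno <- pheno[order(pheno$animal_id), , drop = FALSE]
  folds <- folds %||% make_folds(pheno$animal_id, pheno$sire,
                                 n_repeats = n_repeats, seed = seed)
  X <- build_fixed_design(pheno)
  rownames(X) <- pheno$animal_id

  # align OTU tables and kernels to the phenotype rows, once
  tabs <- list(); kernels <- list()
  for (tp in timepoints) {
    idx <- match(pheno$animal_id, otus[[tp]]$meta$animal_id)
    tab <- new_otu_table(otus[[tp]]$counts[idx, , drop = FALSE],
                         otus[[tp]]$meta[idx, , drop = FALSE])
    rownames(tab$counts) <- pheno$animal_id
    tabs[[tp]] <- tab
    if ("RKHS" %in% algorithms)
      kernels[[tp]] <- kernel_from_jsd(jsd_matrix(to_relative(tab)))
  }

  rows <- list()
  for (trait in traits) {
    y <- pheno[[trait]]
    for (f in folds) {
      tr <- which(pheno$animal_id %in% f$train)
      te <- which(pheno$animal_id %in% f$test)
      null_pred <- list()
      for (alg in algorithms) {
        null_pred[[alg]] <- tryCatch(
          fit_cell(alg, FALSE, y, X, NULL, NULL, tr, te, hypers),
          error = function(e) {
            warning("null fit failed (", alg, ", ", trait, "): ",
                    conditionMessage(e)); NULL
          })
      }
      for (tp in timepoints) {
        for (alg in algorithms) {
          h <- hypers
          if (alg == "BL" && select_bl_lambda) {
            sm <- build_W(tabs[[tp]], reference = pheno$animal_id[tr])
            sel <- select_lambda(y[tr], X[tr, , drop = FALSE],
                                 sm$W[tr, , drop = FALSE], hyper = h$bl,
                                 seed = seed + f$repeat_index)
            h$bl$lambda <- sel$lambda
          }
          biom_pred <- tryCatch(
            fit_cell(alg, TRUE, y, X, tabs[[tp]], kernels[[tp]], tr, te, h),
            error = function(e) {
              warning("biom fit failed (", alg, ", ", trait, ", ", tp,
                      "): ", conditionMessage(e)); NULL
            })
          for (bm in c(FALSE, TRUE)) {
            pred <- if (bm) biom_pred else null_pred[[alg]]
            if (is.null(pred)) next
            rows[[length(rows) + 1L]] <- data.frame(
              trait = trait, timepoint = tp, algorithm = alg,
              biom = bm, repeat_index = f$repeat_index,
              accuracy = suppressWarnings(accuracy_pearson(pred, y[te])),
              mse = mean((y[te] - pred)^2),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cv_result", class(out))
  out
}

#' Summarise cross-validation results
#'
#' Per cell (trait x timepoint x algorithm x biom): mean, SD and t-based 90%
#' confidence interval of the per-repeat accuracies (df = repeats - 1), the
#' same for MSE, and a significance flag marking biom cells whose 90% CI
#' does not overlap the matching null cell's CI. Model-averaged rows
#' (`algorithm = "AVG"`) average the per-algorithm mean accuracies within
#' each trait/timepoint/biom.
#'
#' @param results a `cv_result` data.frame from [run_cv()].
#' @param ci_level confidence level (default 0.90).
#' @return list: `cells` (per-cell summary with CI and significance flag),
#'   `model_average` (averaged across algorithms).
#' @export
summarize_cv <- function(results, ci_level = 0.90) {
  stopifnot(is.data.frame(results))
  key <- interaction(results$trait, results$timepoint, results$algorithm,
                     results$biom, drop = TRUE)
  agg <- do.call(rbind, lapply(split(results, key), function(d) {
    acc <- d$accuracy[is.finite(d$accuracy)]
    n <- length(acc)
    m <- mean(acc)
    s <- if (n > 1L) stats::sd(acc) else 0
    tq <- if (n > 1L) stats::qt(1 - (1 - ci_level) / 2, df = n - 1L) else 0
    half <- tq * s / sqrt(max(n, 1L))
    data.frame(trait = d$trait[1], timepoint = d$timepoint[1],
               algorithm = d$algorithm[1], biom = d$biom[1],
               n_repeats = n, accuracy_mean = m, accuracy_sd = s,
               ci_lower = m - half, ci_upper = m + half,
               mse_mean = mean(d$mse), mse_sd = stats::sd(d$mse),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  # biom significance: non-overlap of biom and null CIs within a cell pair
  agg$significant_vs_null <- FALSE
  for (i in which(agg$biom)) {
    j <- which(!agg$biom & agg$trait == agg$trait[i] &
                 agg$timepoint == agg$timepoint[i] &
                 agg$algorithm == agg$algorithm[i])
    if (length(j) == 1L)
      agg$significant_vs_null[i] <-
        agg$ci_lower[i] > agg$ci_upper[j] || agg$ci_upper[i] < agg$ci_lower[j]
  }
  avg_key <- interaction(agg$trait, agg$timepoint, agg$biom, drop = TRUE)
  avg <- do.call(rbind, lapply(split(agg, avg_key), function(d) {
    data.frame(trait = d$trait[1], timepoint = d$timepoint[1],
               algorithm = "AVG", biom = d$biom[1],
               accuracy_mean = mean(d$accuracy_mean),
               mse_mean = mean(d$mse_mean), stringsAsFactors = FALSE)
  }))
  rownames(avg) <- NULL
  list(cells = agg, model_average = avg)
}
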