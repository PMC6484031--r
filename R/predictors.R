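#' Build the fixed-effect incidence matrix
#'
#' Intercept plus reference-level-dropped dummies for sex, replicate and
#' sire, plus the weaning-weight covariate. Columns aliased on the supplied
#' rows are dropped with a warning so the matrix is full column rank.
#'
#' @param pheno phenotype/design data.frame with columns `sex`, `replicate`,
#'   `sire`, `weaning_weight`.
#' @param rows optional row indices (or logical) used for the rank check.
#' @return numeric matrix with an `(Intercept)` column.
#' @export
build_fixed_design <- function(pheno, rows = NULL) {
  stopifnot(all(c("sex", "replicate", "sire", "weaning_weight") %in%
                  names(pheno)))
  df <- data.frame(sex = factor(pheno$sex),
                   replicate = factor(pheno$replicate),
                   sire = factor(pheno$sire),
                   weaning_weight = pheno$weaning_weight)
  # single-level factors carry no information; keep the formula estimable
  terms <- c("sex", "replicate", "sire")[vapply(
    df[c("sex", "replicate", "sire")], function(f) nlevels(f) > 1L, TRUE)]
  f <- stats::as.formula(paste("~", paste(c(terms, "weaning_weight"),
                                          collapse = " + ")))
  X <- stats::model.matrix(f, df)
  rows <- rows %||% seq_len(nrow(X))
  qr_x <- qr(X[rows, , drop = FALSE])
  if (qr_x$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qr_x$pivot[seq_len(qr_x$rank)])
    warning("dropping aliased fixed-effect columns: ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
  }
  X
}

#' Fit the fixed-effects-only (null) model
#'
#' The baseline against which microbiome models are contrasted: for the
#' Bayesian families this is the flat-prior Bayesian linear model whose
#' posterior mean equals the least-squares solution, so it is computed
#' directly by least squares.
#'
#' @param y numeric response (training rows).
#' @param X fixed-effect design matrix (training rows), including intercept.
#' @return object of class `null_fit` with a `predict` method taking new
#'   design rows.
#' @export
fit_null <- function(y, X) {
  stopifnot(length(y) == nrow(X))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qr_x$pivot[seq_len(qr_x$rank)])
    warning("dropping aliased columns: ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
    qr_x <- qr(X)
  }
  beta <- qr.coef(qr_x, y)
  structure(list(coefficients = beta, columns = colnames(X)),
            class = "null_fit")
}

#' @export
predict.null_fit <- function(object, newX, ...) {
  if (!is.null(object$columns) && !is.null(colnames(newX)))
    newX <- newX[, object$columns, drop = FALSE]
  as.numeric(newX %*% object$coefficients)
}

#' Bayesian Lasso hyperparameters
#'
#' The residual variance prior is scaled-inverse-chi-square with
#' `df_e` degrees of freedom and scale `S_e = Var(y) (1 - R2_e) (df_e + 2)`;
#' OTU effects get a double-exponential prior represented as a scale mixture
#' of normals with OTU-specific variances `tau2_j * sigma2_e`,
#' `tau2_j ~ Exp(lambda^2 / 2)`, `lambda` fixed (chosen by grid search).
#'
#' @param lambda regularisation hyperparameter (> 0).
#' @param df_e residual prior degrees of freedom (default 5).
#' @param R2_e expected residual variance share (default 0.60 residual,
#'   i.e. prior guess that 40% of variance is explained).
#' @param n_iter,burn_in,thin MCMC settings.
#' @param seed RNG seed.
#' @return `bl_hyper` list.
#' @export
bl_hyper <- function(lambda = 25, df_e = 5, R2_e = 0.60,
                     n_iter = 12000L, burn_in = 2000L, thin = 5L,
                     seed = 1L) {
  stopifnot(lambda > 0, df_e > 0, R2_e > 0, R2_e < 1,
            n_iter > burn_in, thin >= 1)
  structure(list(lambda = lambda, df_e = df_e, R2_e = R2_e,
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "bl_hyper")
}

#' Residual prior scale from a variance share
#'
#' `S = Var(y) * (1 - R2) * (df + 2)`, the sum-of-squares scale putting the
#' prior mode of the scaled-inverse-chi-square at `Var(y) * (1 - R2)`.
#'
#' @param var_y sample variance of the response.
#' @param R2 variance share expected to be explained by the modelled terms.
#' @param df prior degrees of freedom.
#' @return the prior scale.
#' @export
prior_scale <- function(var_y, R2, df) var_y * (1 - R2) * (df + 2)

#' Fit the Bayesian Lasso regression by Gibbs sampling
#'
#' Model `y = X b + W o + e` with flat prior on `b`,
#' `o_j | tau2_j, sigma2_e ~ N(0, tau2_j sigma2_e)`,
#' `tau2_j ~ Exp(lambda^2/2)` and scaled-inverse-chi-square residual
#' variance. Returns posterior means (and SDs) of all parameters and a
#' predictor for new rows.
#'
#' @param y training response.
#' @param X fixed-effect matrix (training rows, incl. intercept).
#' @param W centered/scaled OTU matrix (training rows).
#' @param hyper a [bl_hyper()].
#' @param fix_sigma2,fix_tau2 optional positive values freezing the residual
#'   variance / all mixture variances (conjugate-check use); `NULL` = sample.
#' @param keep_samples store post-burn-in draws (small problems only).
#' @return `bl_fit` object.
#' @export
fit_bayesian_lasso <- function(y, X, W, hyper = bl_hyper(),
                               fix_sigma2 = NULL, fix_tau2 = NULL,
                               keep_samples = FALSE) {
  stopifnot(inherits(hyper, "bl_hyper"), length(y) == nrow(X),
            length(y) == nrow(W))
  # residual prior mode sits at Var(y) * (1 - R2_e)
  S_e <- prior_scale(stats::var(y), hyper$R2_e, hyper$df_e)
  fit <- with_seed(hyper$seed, .bl_gibbs_cpp(
    as.numeric(y), as.matrix(X), as.matrix(W),
    lambda = hyper$lambda, df_e = hyper$df_e, S_e = S_e,
    n_iter = hyper$n_iter, burn_in = hyper$burn_in, thin = hyper$thin,
    fix_sigma2 = fix_sigma2 %||% -1, fix_tau2 = fix_tau2 %||% -1,
    keep_samples = keep_samples))
  structure(c(fit, list(hyper = hyper, S_e = S_e,
                        columns_X = colnames(X), columns_W = colnames(W))),
            class = "bl_fit")
}

#' @export
predict.bl_fit <- function(object, newX, newW, ...) {
  as.numeric(newX %*% object$b_mean + newW %*% object$o_mean)
}

#' Select the Bayesian Lasso lambda by internal cross-validation
#'
#' Grid search minimising mean validation MSE over internal folds of the
#' training data; ties resolve to the smaller lambda.
#'
#' @param y,X,W training data as in [fit_bayesian_lasso()].
#' @param grid candidate lambda values.
#' @param n_folds internal folds (default 5).
#' @param hyper base hyperparameters (lambda is overridden).
#' @param seed RNG seed for fold assignment.
#' @return list: `lambda`, `cv_mse` (named by grid value).
#' @export
select_lambda <- function(y, X, W, grid = c(1, 5, 10, 25, 50, 100, 200),
                          n_folds = 5L, hyper = bl_hyper(), seed = 1L) {
  stopifnot(length(grid) >= 1L)
  if (length(grid) == 1L)
    return(list(lambda = grid, cv_mse = stats::setNames(NA_real_,
                                                        as.character(grid))))
  n <- length(y)
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  mse <- sapply(sort(grid), function(lam) {
    h <- hyper
    h$lambda <- lam
    errs <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      fit <- fit_bayesian_lasso(y[tr], X[tr, , drop = FALSE],
                                W[tr, , drop = FALSE], h)
      pred <- predict(fit, X[!tr, , drop = FALSE], W[!tr, , drop = FALSE])
      mean((y[!tr] - pred)^2)
    }, numeric(1))
    mean(errs)
  })
  names(mse) <- as.character(sort(grid))
  list(lambda = sort(grid)[which.min(mse)], cv_mse = mse)
}

#' RKHS hyperparameters
#'
#' Variance priors are scaled-inverse-chi-square with scales derived from
#' variance shares: `S_u = Var(y) R2_u (df_u + 2)` for the kernel animal
#' effect (default share 0.3) and `S_e = Var(y) R2_e (df_e + 2)` for the
#' residual (default share 0.6).
#'
#' @param df_u,R2_u prior df and variance share of the animal effect.
#' @param df_e,R2_e prior df and variance share of the residual.
#' @param n_iter,burn_in,thin,seed MCMC settings.
#' @return `rkhs_hyper` list.
#' @export
rkhs_hyper <- function(df_u = 5, R2_u = 0.3, df_e = 5, R2_e = 0.6,
                       n_iter = 12000L, burn_in = 2000L, thin = 5L,
                       seed = 1L) {
  stopifnot(df_u > 0, df_e > 0, R2_u > 0, R2_e > 0, n_iter > burn_in)
  structure(list(df_u = df_u, R2_u = R2_u, df_e = df_e, R2_e = R2_e,
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "rkhs_hyper")
}

#' Fit the Jensen-Shannon kernel RKHS regression
#'
#' Model `y = X b + u + e` on the training animals with
#' `u ~ N(0, M sigma2_u)`, `M` the similarity kernel (1 - JSD). The sampler
#' works in the eigenbasis of the training submatrix of `M`; test animals
#' are predicted by the conditional (kriging) mean
#' `u_test = M[test, train] M[train, train]^{-1} u_train` plus their fixed
#' effects.
#'
#' @param y full response vector, named or aligned with `ids`.
#' @param X full fixed-effect matrix (train and test rows).
#' @param M kernel matrix (or `kernel_matrix` object) over all animals.
#' @param hyper an [rkhs_hyper()].
#' @param train_idx,test_idx integer row indices into `y`/`X`/`M`.
#' @param fix_sigma2u,fix_sigma2e optional frozen variances.
#' @return `rkhs_fit`: posterior means of `b`, `u` (train), variances,
#'   `predictions` for the test rows.
#' @export
fit_rkhs <- function(y, X, M, hyper = rkhs_hyper(), train_idx,
                     test_idx = integer(0), fix_sigma2u = NULL,
                     fix_sigma2e = NULL) {
  if (inherits(M, "kernel_matrix")) M <- M$M
  stopifnot(nrow(M) == length(y), nrow(X) == length(y))
  ytr <- y[train_idx]
  Xtr <- X[train_idx, , drop = FALSE]
  Mtt <- M[train_idx, train_idx, drop = FALSE]
  n <- length(ytr)
  eig <- eigen(Mtt, symmetric = TRUE)
  keep <- eig$values > max(eig$values) * 1e-10
  V <- eig$vectors[, keep, drop = FALSE]
  lam <- eig$values[keep]
  r <- length(lam)
  vy <- stats::var(ytr)
  # scales put the prior mass of each variance at its expected share
  S_u <- vy * hyper$R2_u * (hyper$df_u + 2)
  S_e <- vy * hyper$R2_e * (hyper$df_e + 2)
  # work entirely in the eigenbasis of M[train, train]: y~ = V'y, X~ = V'X;
  # components with eigenvalue ~0 carry no animal effect
  Vf <- eig$vectors
  lamf <- pmax(eig$values, 0)
  q <- ncol(Xtr)
  Xt_full <- crossprod(Vf, Xtr)            # n x q in eigenbasis
  yt_full <- as.numeric(crossprod(Vf, ytr))

  with_seed(hyper$seed, {
    delta <- rep(0, r)
    sig2u <- if (is.null(fix_sigma2u)) max(vy * hyper$R2_u, 1e-8) else fix_sigma2u
    sig2e <- if (is.null(fix_sigma2e)) max(vy * hyper$R2_e, 1e-8) else fix_sigma2e
    b <- qr.coef(qr(Xtr), ytr)
    b[is.na(b)] <- 0
    b_acc <- 0 * b
    delta_acc <- rep(0, r)
    s2u_acc <- s2e_acc <- 0
    s2u_acc2 <- 0
    n_kept <- 0L
    for (it in seq_len(hyper$n_iter)) {
      # fixed effects | variances, with u integrated out (collapsed draw):
      # marginally y~ ~ N(X~ b, diag(sig2u*lam + sig2e))
      w <- 1 / (sig2u * lamf + sig2e)
      XtWX <- crossprod(Xt_full * w, Xt_full)
      cholA <- chol(XtWX + diag(1e-12, q))
      mean_b <- backsolve(cholA, forwardsolve(t(cholA),
                                              crossprod(Xt_full * w,
                                                        yt_full)))
      b <- as.numeric(mean_b + backsolve(cholA, stats::rnorm(q)))
      # animal-effect components | b, variances
      z <- yt_full[seq_len(r)] - as.numeric(Xt_full[seq_len(r), ,
                                                    drop = FALSE] %*% b)
      post_var <- 1 / (1 / sig2e + 1 / (lam * sig2u))
      post_mean <- post_var * z / sig2e
      delta <- stats::rnorm(r, post_mean, sqrt(post_var))
      e_eig <- yt_full - as.numeric(Xt_full %*% b)
      e_eig[seq_len(r)] <- e_eig[seq_len(r)] - delta
      if (is.null(fix_sigma2u))
        sig2u <- (S_u + sum(delta^2 / lam)) /
          stats::rchisq(1L, df = hyper$df_u + r)
      if (is.null(fix_sigma2e))
        sig2e <- (S_e + sum(e_eig^2)) / stats::rchisq(1L, df = hyper$df_e + n)
      if (!is.finite(sig2u) || !is.finite(sig2e))
        stop("RKHS sampler diverged")
      if (it > hyper$burn_in && (it - hyper$burn_in - 1L) %% hyper$thin == 0L) {
        b_acc <- b_acc + b
        delta_acc <- delta_acc + delta
        s2u_acc <- s2u_acc + sig2u
        s2u_acc2 <- s2u_acc2 + sig2u^2
        s2e_acc <- s2e_acc + sig2e
        n_kept <- n_kept + 1L
      }
    }
  })
  b_mean <- b_acc / n_kept
  u_mean <- as.numeric(V %*% (delta_acc / n_kept))
  s2u_mean <- s2u_acc / n_kept
  s2e_mean <- s2e_acc / n_kept
  preds <- NULL
  if (length(test_idx)) {
    Mst <- M[test_idx, train_idx, drop = FALSE]
    # solve on the eigenbasis with the same eigenvalue floor
    alpha <- V %*% ((crossprod(V, u_mean)) / lam)
    u_test <- as.numeric(Mst %*% alpha)
    preds <- as.numeric(X[test_idx, , drop = FALSE] %*% b_mean) + u_test
  }
  structure(list(b_mean = b_mean, u_mean = u_mean,
                 sigma2u_mean = s2u_mean, sigma2e_mean = s2e_mean,
                 sigma2u_sd = sqrt(max(0, s2u_acc2 / n_kept - s2u_mean^2)),
                 predictions = preds, train_idx = train_idx,
                 test_idx = test_idx, hyper = hyper, n_kept = n_kept),
            class = "rkhs_fit")
}

#' Ensemble hyperparameters
#'
#' Defaults follow the benchmark settings: 1500 trees; random-forest
#' feature subset of size `floor(sqrt(p))` per split with MSE split
#' criterion and unrestricted depth; boosting with interaction depth 3,
#' shrinkage 0.01, squared-error loss, and 0.5 bagging fraction.
#'
#' @param n_trees number of trees / boosting iterations.
#' @param gbm_depth boosting interaction depth.
#' @param gbm_shrinkage boosting learning rate.
#' @param gbm_bag_fraction per-iteration subsample fraction.
#' @param seed RNG seed.
#' @return `ensemble_params` list.
#' @export
ensemble_params <- function(n_trees = 1500L, gbm_depth = 3L,
                            gbm_shrinkage = 0.01, gbm_bag_fraction = 0.5,
                            seed = 1L) {
  stopifnot(n_trees >= 0, gbm_depth >= 1, gbm_shrinkage >= 0,
            gbm_bag_fraction > 0, gbm_bag_fraction <= 1)
  structure(list(n_trees = as.integer(n_trees),
                 gbm_depth = as.integer(gbm_depth),
                 gbm_shrinkage = gbm_shrinkage,
                 gbm_bag_fraction = gbm_bag_fraction,
                 seed = as.integer(seed)),
            class = "ensemble_params")
}

#' Fit a bagged random forest regression
#'
#' @param y training response.
#' @param features numeric feature matrix (one-hot factors and/or OTU
#'   columns).
#' @param params an [ensemble_params()].
#' @return `rf_fit` with a `predict` method.
#' @export
fit_forest <- function(y, features, params = ensemble_params()) {
  stopifnot(nrow(features) == length(y))
  if (ncol(features) == 0L) stop("no features supplied")
  df <- data.frame(..y = y, features, check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = "..y", data = df,
    num.trees = params$n_trees,
    mtry = max(1L, floor(sqrt(ncol(features)))),
    min.node.size = 1L, splitrule = "variance",
    seed = params$seed, num.threads = 1L, respect.unordered.factors = TRUE)
  structure(list(model = fit, columns = colnames(features)),
            class = "rf_fit")
}

#' @export
predict.rf_fit <- function(object, new_features, ...) {
  nd <- data.frame(new_features[, object$columns, drop = FALSE],
                   check.names = FALSE)
  as.numeric(predict(object$model, data = nd, num.threads = 1L)$predictions)
}

#' Fit a gradient boosting machine regression
#'
#' Squared-error boosting where each shallow tree is fitted to the residual
#' of the committee formed so far, with per-iteration bagging.
#'
#' @inheritParams fit_forest
#' @return `gbm_fit` with a `predict` method supporting staged predictions.
#' @export
fit_gbm <- function(y, features, params = ensemble_params()) {
  stopifnot(nrow(features) == length(y))
  if (ncol(features) == 0L) stop("no features supplied")
  mu <- mean(y)
  if (params$n_trees == 0L || params$gbm_shrinkage == 0) {
    return(structure(list(model = NULL, base = mu,
                          columns = colnames(features), params = params),
                     class = "gbm_fit"))
  }
  dtrain <- xgboost::xgb.DMatrix(as.matrix(features), label = y - mu)
  fit <- with_seed(params$seed, xgboost::xgb.train(
    params = list(objective = "reg:squarederror",
                  eta = params$gbm_shrinkage,
                  max_depth = params$gbm_depth,
                  subsample = params$gbm_bag_fraction,
                  colsample_bytree = 1, lambda = 0, alpha = 0,
                  base_score = 0, nthread = 1),
    data = dtrain, nrounds = params$n_trees, verbose = 0))
  structure(list(model = fit, base = mu, columns = colnames(features),
                 params = params),
            class = "gbm_fit")
}

# iteration_range: optional c(1, k) truncating the committee at k boosting
# iterations (staged predictions)
#' @export
predict.gbm_fit <- function(object, new_features, iteration_range = NULL,
                            ...) {
  m <- as.matrix(new_features[, object$columns, drop = FALSE])
  if (is.null(object$model)) return(rep(object$base, nrow(m)))
  p <- if (is.null(iteration_range)) {
    predict(object$model, newdata = m)
  } else {
    predict(object$model, newdata = m, iterationrange = iteration_range)
  }
  object$base + as.numeric(p)
}

#' Random-forest timepoint classifier with confusion matrix
#'
#' Classifies each microbiome sample into its sampling timepoint under the
#' same repeated sire-stratified split scheme used for trait prediction, and
#' returns the row-normalised confusion matrix averaged over repeats.
#'
#' @param otus named list of `otu_table`s, one per timepoint.
#' @param folds fold assignments from [make_folds()] over animal ids.
#' @param params an [ensemble_params()].
#' @return list of class `timepoint_confusion`: `confusion` (rows sum to 1),
#'   `accuracy` (overall mean per-class accuracy).
#' @export
classify_timepoint <- function(otus, folds, params = ensemble_params()) {
  tps <- names(otus)
  stopifnot(length(tps) == 3L)
  feats <- do.call(rbind, lapply(otus, to_relative))
  labs <- factor(unlist(lapply(otus, function(t) t$meta$timepoint)),
                 levels = tps)
  animals <- unlist(lapply(otus, function(t) t$meta$animal_id))
  conf_sum <- matrix(0, 3L, 3L, dimnames = list(tps, tps))
  for (f in folds) {
    tr <- animals %in% f$train
    te <- animals %in% f$test
    if (any(table(labs[tr]) < 2L) || any(table(labs[te]) < 1L))
      stop("a timepoint class is (nearly) absent from a fold")
    df <- data.frame(..y = labs[tr], feats[tr, , drop = FALSE],
                     check.names = FALSE)
    fit <- ranger::ranger(dependent.variable.name = "..y", data = df,
                          num.trees = params$n_trees,
                          mtry = max(1L, floor(sqrt(ncol(feats)))),
                          seed = params$seed, num.threads = 1L)
    pred <- predict(fit, data = data.frame(feats[te, , drop = FALSE],
                                           check.names = FALSE),
                    num.threads = 1L)$predictions
    tab <- table(truth = labs[te], pred = factor(pred, levels = tps))
    conf_sum <- conf_sum + sweep(unclass(tab), 1L, rowSums(tab), "/")
  }
  conf <- conf_sum / length(folds)
  structure(list(confusion = conf, accuracy = mean(diag(conf))),
            class = "timepoint_confusion")
}
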