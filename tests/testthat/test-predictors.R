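test_that("fit_null reproduces exact linear structure", {
  set.seed(1)
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(50), x2 = rnorm(50))
  beta <- c(2, 1, -3)
  y <- as.numeric(X %*% beta)
  fit <- fit_null(y, X)
  expect_equal(unname(coef(lm(y ~ X - 1))), unname(fit$coefficients),
               tolerance = 1e-10)
  Xte <- cbind(`(Intercept)` = 1, x1 = rnorm(10), x2 = rnorm(10))
  expect_equal(predict(fit, Xte), as.numeric(Xte %*% beta),
               tolerance = 1e-10)
  # intercept-only -> training mean
  X0 <- matrix(1, 50, 1, dimnames = list(NULL, "(Intercept)"))
  y2 <- rnorm(50)
  expect_equal(predict(fit_null(y2, X0), matrix(1, 3, 1)),
               rep(mean(y2), 3))
  # aliased columns dropped with warning, fit unchanged
  Xa <- cbind(X, x3 = X[, "x1"] * 2)
  expect_warning(fa <- fit_null(y, Xa), "aliased")
  expect_equal(predict(fa, Xa[1:5, colnames(Xa) %in% fa$columns]),
               y[1:5], tolerance = 1e-10)
})

test_that("Bayesian Lasso prior scale follows the variance-share formula", {
  expect_equal(prior_scale(1, 0.6, 5), 2.8)
  expect_equal(prior_scale(4, 0.5, 4), 4 * 0.5 * 6)
})

test_that("Bayesian Lasso matches the conjugate ridge oracle", {
  set.seed(42)
  n <- 12; p <- 2
  W <- matrix(rnorm(n * p), n)
  X <- matrix(1, n, 1)
  y <- as.numeric(0.5 + W %*% c(1, -0.5) + rnorm(n, sd = 0.5))
  h <- bl_hyper(lambda = 10, n_iter = 12000, burn_in = 2000, thin = 2,
                seed = 7)
  fit <- fit_bayesian_lasso(y, X, W, h, fix_sigma2 = 0.25, fix_tau2 = 4,
                            keep_samples = TRUE)
  # with fixed variances the posterior is Gaussian: joint ridge solve
  # with no penalty on the intercept
  A <- cbind(X, W)
  beta <- solve(crossprod(A) + diag(c(0, rep(1 / 4, p))),
                crossprod(A, y))
  se <- apply(fit$o_draws, 2, mc_se)
  expect_true(all(abs(fit$o_mean - beta[-1]) < 3 * se))
  expect_lt(abs(fit$b_mean - beta[1]), 3 * mc_se(fit$b_draws[, 1]))
})

test_that("huge lambda shrinks the Bayesian Lasso onto the null model", {
  set.seed(10)
  n <- 60; p <- 15
  W <- scale(matrix(rnorm(n * p), n))
  X <- cbind(1, rnorm(n))
  y <- as.numeric(X %*% c(1, 0.4) + W %*% rnorm(p, sd = 0.3) + rnorm(n))
  h <- bl_hyper(lambda = 1e6, n_iter = 3000, burn_in = 500, seed = 2)
  fit <- fit_bayesian_lasso(y, X, W, h)
  expect_lt(sqrt(sum(fit$o_mean^2)), 0.02)
  null_pred <- predict(fit_null(y, X), X)
  expect_lt(max(abs(predict(fit, X, W) - null_pred)), 0.05)
})

test_that("Bayesian Lasso posterior means are stable across seeds", {
  set.seed(3)
  n <- 80; p <- 10
  W <- scale(matrix(rnorm(n * p), n))
  X <- matrix(1, n, 1)
  y <- as.numeric(1 + W %*% rnorm(p, sd = 0.4) + rnorm(n))
  h1 <- bl_hyper(lambda = 10, n_iter = 8000, burn_in = 1000, thin = 2,
                 seed = 1)
  h2 <- h1; h2$seed <- 99L
  f1 <- fit_bayesian_lasso(y, X, W, h1, keep_samples = TRUE)
  f2 <- fit_bayesian_lasso(y, X, W, h2)
  se <- apply(f1$o_draws, 2, mc_se)
  expect_true(all(abs(f1$o_mean - f2$o_mean) < 4 * se))
  # identical seeds are exactly reproducible
  f3 <- fit_bayesian_lasso(y, X, W, h1)
  expect_identical(f1$o_mean, f3$o_mean)
})

test_that("select_lambda prefers stronger shrinkage for pure noise", {
  set.seed(21)
  n <- 60; p <- 30
  W <- scale(matrix(rnorm(n * p), n))
  X <- matrix(1, n, 1)
  h <- bl_hyper(n_iter = 400, burn_in = 100, seed = 5)
  grid <- c(1, 5, 25, 125)
  # single-value grid short-circuits
  expect_equal(select_lambda(rnorm(n), X, W, grid = 50)$lambda, 50)
  picks <- vapply(1:5, function(r) {
    set.seed(100 + r)
    y_noise <- rnorm(n)
    select_lambda(y_noise, X, W, grid = grid, hyper = h,
                  seed = r)$lambda
  }, numeric(1))
  expect_gte(mean(picks >= 25), 0.8)
  # strong dense signal selects weaker shrinkage than noise (paired)
  set.seed(77)
  y_sig <- as.numeric(W %*% rnorm(p, sd = 0.6) + rnorm(n, sd = 0.3))
  pick_sig <- select_lambda(y_sig, X, W, grid = grid, hyper = h,
                            seed = 1)$lambda
  expect_lt(pick_sig, max(picks))
})

test_that("RKHS matches the Henderson mixed-model-equations oracle", {
  set.seed(3)
  n <- 60
  P <- random_compositions(n, 30, seed = 3)
  K <- kernel_from_jsd(jsd_matrix(P))$M
  X <- cbind(1, rnorm(n))
  L <- chol(K + diag(1e-8, n))
  u <- as.numeric(t(L) %*% rnorm(n)) * sqrt(2)
  y <- as.numeric(X %*% c(1, 0.5)) + u + rnorm(n)
  tr <- 1:45
  h <- rkhs_hyper(n_iter = 8000, burn_in = 1000, thin = 2, seed = 5)
  fit <- fit_rkhs(y, X, K, h, train_idx = tr, test_idx = 46:60,
                  fix_sigma2u = 2, fix_sigma2e = 1)
  # oracle: MME solve at the same fixed variance ratio
  Kinv <- solve(K[tr, tr])
  Xt <- X[tr, ]
  C <- rbind(cbind(crossprod(Xt), t(Xt)),
             cbind(Xt, diag(length(tr)) + 0.5 * Kinv))
  sol <- solve(C, c(crossprod(Xt, y[tr]), y[tr]))
  expect_lt(max(abs(fit$b_mean - sol[1:2])), 0.05)
  expect_lt(max(abs(fit$u_mean - sol[-(1:2)])), 0.08)
  expect_equal(length(fit$predictions), 15)
})

test_that("identity kernel makes RKHS collapse onto the null model", {
  set.seed(6)
  n <- 40
  X <- cbind(1, rnorm(n))
  y <- as.numeric(X %*% c(2, 1)) + rnorm(n)
  tr <- 1:30; te <- 31:40
  fit <- fit_rkhs(y, X, diag(n),
                  rkhs_hyper(n_iter = 4000, burn_in = 500, seed = 2),
                  train_idx = tr, test_idx = te)
  null_pred <- predict(fit_null(y[tr], X[tr, ]), X[te, ])
  # no information is shared across animals: u_test = 0
  expect_lt(max(abs(fit$predictions - null_pred)), 0.05)
})

test_that("ensemble defaults and degenerate settings behave as specified", {
  expect_equal(floor(sqrt(1755)), 41)  # features per split at full p
  set.seed(2)
  n <- 120
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- 2 * X[, 1]^2 + rnorm(n, sd = 0.1)
  # constant response -> constant predictions
  fc <- fit_forest(rep(3, n), X, ensemble_params(n_trees = 50))
  expect_equal(predict(fc, X), rep(3, n), tolerance = 1e-10)
  # noiseless single-feature signal is learned
  f1 <- fit_forest(2 * X[, 1], X, ensemble_params(n_trees = 300))
  expect_gt(cor(predict(f1, X), 2 * X[, 1])^2, 0.95)
  # forest determinism under fixed seed
  f2 <- fit_forest(y, X, ensemble_params(n_trees = 100, seed = 9))
  f3 <- fit_forest(y, X, ensemble_params(n_trees = 100, seed = 9))
  expect_identical(predict(f2, X), predict(f3, X))
  # GBM degenerate settings return the training mean
  g0 <- fit_gbm(y, X, ensemble_params(n_trees = 0))
  expect_equal(predict(g0, X), rep(mean(y), n))
  gs <- fit_gbm(y, X, ensemble_params(gbm_shrinkage = 0))
  expect_equal(predict(gs, X), rep(mean(y), n))
  expect_error(fit_forest(y, X[, 0]), "features")
})

test_that("GBM training loss is non-increasing over the staged committee", {
  set.seed(4)
  n <- 150
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- as.numeric(1.5 * X[, 1] - X[, 2] + rnorm(n, sd = 0.2))
  g <- fit_gbm(y, X, ensemble_params(n_trees = 300))
  loss <- vapply(seq(10, 300, by = 10), function(k)
    mean((y - predict(g, X, iteration_range = c(1, k)))^2), numeric(1))
  expect_true(all(diff(loss) <= 1e-10))
  expect_lt(loss[length(loss)], loss[1])
})

test_that("timepoint classifier tracks community separation", {
  cfg <- cohort_config(n_sires = 3, n_replicates = 2, n_otus = 120,
                       depth = 1500, dropout_rate = 0, seed = 17)
  d <- generate_design(cfg)
  folds <- make_folds(d$animal_id, d$sire, n_repeats = 2, seed = 1)
  # strongly separated timepoints classify nearly perfectly
  otus <- generate_microbiome(d, cfg, separation = 1)
  cm <- classify_timepoint(otus, folds,
                           params = ensemble_params(n_trees = 200))
  expect_equal(unname(rowSums(cm$confusion)), rep(1, 3), tolerance = 1e-12)
  expect_true(all(diag(cm$confusion) >= 0.95))
  # no separation -> chance-level diagonal
  otus0 <- generate_microbiome(d, cfg, separation = 0)
  cm0 <- classify_timepoint(otus0, folds,
                            params = ensemble_params(n_trees = 200))
  n_per_class <- nrow(d)
  se <- sqrt(1 / 3 * 2 / 3 / n_per_class)
  expect_true(all(abs(diag(cm0$confusion) - 1 / 3) < 5 * se))
})
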