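test_that("lambda at or above lambda_max gives the all-zero penalized fit", {
  set.seed(10)
  n <- 60; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  Z <- cbind(rnorm(n))
  y <- rnorm(n) + 0.5 * Z[, 1]
  prob <- lasso_problem(X, y, covariates = Z, grid_size = 20)
  lmax <- prob$lambda_grid[1]
  prob2 <- lasso_problem(X, y, covariates = Z,
                         lambda_grid = c(2 * lmax, 1.0001 * lmax))
  path <- fit_lasso_path(prob2)
  expect_true(all(path$beta == 0))
  # strictly below lambda_max at least one feature activates
  path3 <- fit_lasso_path(prob)
  expect_gt(sum(path3$beta[, length(prob$lambda_grid)] != 0), 0)
})

test_that("a single standardized feature reproduces the soft-threshold
           closed form", {
  prob <- single_feature_problem(target = 0.5, lambda = 0.2)
  path <- fit_lasso_path(prob)
  expect_equal(unname(path$beta[1, 1]), 0.3, tolerance = 1e-10)
  # thresholded to zero once lambda exceeds the correlation
  prob0 <- single_feature_problem(target = 0.5, lambda = 0.6)
  expect_equal(unname(fit_lasso_path(prob0)$beta[1, 1]), 0)
})

test_that("the objective is monotone over coordinate-descent sweeps", {
  set.seed(11)
  n <- 50; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  X[, 2] <- X[, 1] + rnorm(n, sd = 0.05)  # near-collinear pair
  y <- X[, 1] - X[, 3] + rnorm(n)
  Xs <- scale(X) * sqrt(n / (n - 1))
  ys <- y - mean(y)
  res <- memoscore:::cd_lasso_single(Xs, ys, 0.05, numeric(p), 1e-9, 500)
  expect_true(res$converged)
  expect_true(all(diff(res$objective) <= 1e-12))
})

test_that("coordinate descent matches the exact enumeration oracle and
           glmnet on small instances", {
  skip_if_not_installed("glmnet")
  set.seed(12)
  for (p in c(3, 6, 8)) {
    n <- 40
    X <- matrix(rnorm(n * p), n, p)
    Z <- cbind(age = rnorm(n))
    beta_true <- c(1, numeric(p - 1))
    y <- X %*% beta_true + 0.5 * Z[, 1] + rnorm(n)
    prob <- lasso_problem(X, y, covariates = Z, grid_size = 8,
                          lambda_min_ratio = 0.05, tol = 1e-10)
    path <- fit_lasso_path(prob)
    for (l in seq_along(prob$lambda_grid)) {
      lam <- prob$lambda_grid[l]
      oracle <- oracle_lasso_enum(prob$X, prob$y, prob$Z, lam)
      obj_cd <- lasso_objective(prob$X, prob$y, prob$Z, path$beta[, l], lam)
      expect_lt(abs(obj_cd - oracle$objective), 1e-6)
    }
    # independent reference implementation at one mid-grid lambda
    # (glmnet rescales penalty factors to sum to nvars, hence the p/(p+1))
    lam <- prob$lambda_grid[4]
    gn <- glmnet::glmnet(cbind(prob$Z[, -1], prob$X), prob$y,
                         lambda = lam * p / (p + 1), standardize = FALSE,
                         penalty.factor = c(0, rep(1, p)),
                         thresh = 1e-14)
    b_gn <- as.numeric(gn$beta)[-1]
    obj_gn <- lasso_objective(prob$X, prob$y, prob$Z, b_gn, lam)
    obj_cd <- lasso_objective(prob$X, prob$y, prob$Z, path$beta[, 4], lam)
    expect_lt(abs(obj_cd - obj_gn), 1e-6)
  }
})

test_that("KKT conditions hold along the path and selection shrinks with
           lambda on orthogonal designs", {
  set.seed(13)
  n <- 64
  X <- qr.Q(qr(matrix(rnorm(n * n), n)))[, 1:10] * sqrt(n)  # orthonormal/n
  y <- X[, 1] * 0.8 + X[, 2] * 0.4 + rnorm(n, sd = 0.5)
  prob <- lasso_problem(X, y, grid_size = 25, tol = 1e-9)
  path <- fit_lasso_path(prob)
  expect_true(all(path$kkt_max <= 1e-8))
  expect_true(all(diff(path$n_selected) >= 0))  # grid is decreasing
})

test_that("unpenalized covariates equal the exact least-squares solve", {
  set.seed(14)
  n <- 80; p <- 15
  X <- matrix(rnorm(n * p), n, p)
  Z <- cbind(caide = rpois(n, 6), age = runif(n, 57, 70))
  y <- X[, 1] + 0.3 * Z[, 1] - 0.2 * Z[, 2] + rnorm(n)
  prob <- lasso_problem(X, y, covariates = Z, grid_size = 10)
  path <- fit_lasso_path(prob)
  for (l in c(1, 5, 10)) {
    resid_target <- prob$y - prob$X %*% path$beta[, l]
    a_exact <- drop(qr.coef(qr(prob$Z), resid_target))
    expect_equal(unname(path$unpen[, l]), unname(a_exact),
                 tolerance = 1e-10)
  }
})

test_that("split tuning rejects noise and recovers a strong feature", {
  # under a pure-noise outcome the minimum-validation-MSE rule picks the
  # empty model in about half the replicates (the validation curve is
  # noisy at n_val = 60) and otherwise only small models; under a strong
  # single feature (R2 ~ 0.5) that feature is essentially always kept
  n <- 300; p <- 1000
  n_null <- integer(20)
  selected_signal <- logical(20)
  for (s in 1:20) {
    set.seed(1000 + s)
    X <- matrix(rnorm(n * p), n, p)
    y_null <- rnorm(n)
    prob <- lasso_problem(X, y_null, grid_size = 30)
    fit <- tune_by_split(prob, seed = s)
    n_null[s] <- fit$n_selected
    y_sig <- X[, 7] + rnorm(n)
    prob2 <- lasso_problem(X, y_sig, grid_size = 30)
    fit2 <- tune_by_split(prob2, seed = s)
    selected_signal[s] <- fit2$coef_pen["f7"] != 0
  }
  expect_gte(mean(n_null == 0), 0.3)
  expect_lt(mean(n_null) / p, 0.05)
  expect_gte(mean(selected_signal), 0.95)
})

test_that("split tuning is deterministic given the seed", {
  set.seed(15)
  X <- matrix(rnorm(100 * 50), 100, 50)
  y <- X[, 3] + rnorm(100)
  prob <- lasso_problem(X, y, grid_size = 20)
  f1 <- tune_by_split(prob, seed = 42)
  f2 <- tune_by_split(prob, seed = 42)
  expect_identical(f1$lambda, f2$lambda)
  expect_identical(f1$coef_pen, f2$coef_pen)
})

test_that("leave-one-out CV equals the brute-force enumeration oracle", {
  set.seed(16)
  n <- 10; p <- 3
  X <- matrix(rnorm(n * p), n, p)
  y <- X[, 1] * 0.8 + rnorm(n, sd = 0.5)
  prob <- lasso_problem(X, y, grid_size = 12, lambda_min_ratio = 0.05,
                        tol = 1e-13)
  fit <- tune_by_cv(prob, k = n, seed = 3)
  oracle_mse <- rep(0, length(prob$lambda_grid))
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    for (l in seq_along(prob$lambda_grid)) {
      sol <- oracle_lasso_enum(prob$X[keep, , drop = FALSE], prob$y[keep],
                               prob$Z[keep, , drop = FALSE],
                               prob$lambda_grid[l])
      a <- qr.coef(qr(prob$Z[keep, , drop = FALSE]),
                   prob$y[keep] - prob$X[keep, , drop = FALSE] %*% sol$beta)
      pred <- prob$Z[i, , drop = FALSE] %*% a +
        prob$X[i, , drop = FALSE] %*% sol$beta
      oracle_mse[l] <- oracle_mse[l] + (prob$y[i] - pred)^2 / n
    }
  }
  expect_equal(fit$tuning_curve$loss, oracle_mse, tolerance = 1e-10)
})

test_that("CV recovers most causal metabolites at study-like scale", {
  hits <- integer(10)
  for (s in 1:10) {
    cfg <- small_cfg(seed = 100 + s, n_samples = 700L, n_variants = 12L,
                     n_blocks = 2L, n_metabolites = 137L,
                     n_causal_metabolites = 15L, n_metab_blocks = 10L,
                     h2_genetic = 0, var_metabolic = 0.25)
    sim <- simulate_cohort(cfg)
    prob <- lasso_problem(sim$metabolites, sim$cohort$em_score,
                          covariates = cbind(caide = sim$cohort$caide,
                                             age = sim$cohort$age_at_test),
                          grid_size = 30)
    fit <- tune_by_cv(prob, k = 10, seed = s)
    hits[s] <- length(intersect(names(which(fit$coef_pen != 0)),
                                sim$truth$causal_metabolite_ids))
  }
  expect_gte(median(hits), 10)
})

test_that("a length-one lambda grid forces that choice", {
  set.seed(17)
  X <- matrix(rnorm(60 * 5), 60, 5)
  y <- rnorm(60)
  prob <- lasso_problem(X, y, lambda_grid = 0.07)
  fit <- tune_by_cv(prob, k = 5, seed = 1)
  expect_equal(fit$lambda, 0.07)
})

test_that("exported weights are on the raw per-unit scale", {
  set.seed(18)
  n <- 90
  x_raw <- rnorm(n, mean = 5, sd = 3)  # non-unit raw scale
  X <- cbind(a = x_raw, b = rnorm(n))
  y <- 0.4 * x_raw + rnorm(n, sd = 0.4)
  prob <- lasso_problem(X, y, grid_size = 25)
  fit <- tune_by_cv(prob, k = 5, seed = 2)
  w <- export_weights(fit, NULL, "MRS")
  expect_true(all(w$effect_allele == ""))
  sd_pop <- sqrt(mean((x_raw - mean(x_raw))^2))
  expect_equal(w$weight[w$feature_id == "a"],
               unname(fit$coef_pen["a"]) / sd_pop)
  # refitting on pre-standardized features reproduces the same raw weight
  Xs <- scale(X, scale = apply(X, 2, function(c) sqrt(mean((c - mean(c))^2))))
  prob_s <- lasso_problem(Xs, y, lambda_grid = prob$lambda_grid)
  fit_s <- tune_by_cv(prob_s, k = 5, seed = 2)
  expect_equal(unname(fit_s$coef_pen["a"]) / sd_pop,
               w$weight[w$feature_id == "a"], tolerance = 1e-8)

  # an all-zero fit exports an empty table and scores to zero
  prob0 <- lasso_problem(X, rnorm(n), lambda_grid = 10)
  fit0 <- tune_by_cv(prob0, k = 5, seed = 1)
  w0 <- export_weights(fit0, NULL, "MRS")
  expect_equal(nrow(w0), 0L)
  expect_equal(unname(score_metabolic(w0, Xs)), rep(0, n))
})

test_that("degenerate inputs are rejected with informative errors", {
  set.seed(19)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- rnorm(40)
  prob <- lasso_problem(X, y, grid_size = 5)
  expect_error(tune_by_split(prob, train_frac = 0.001), "degenerate")
  expect_error(tune_by_cv(prob, k = 1), "k")
  expect_error(lasso_problem(X, y, lambda_grid = c(0.1, 0.2)),
               "decreasing")
  expect_message(lasso_problem(cbind(X, const = 1), y, grid_size = 5),
                 "zero-variance")
})
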