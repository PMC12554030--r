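#' Define a partially penalized LASSO problem
#'
#' Sets up the objective
#' \deqn{\frac{1}{2n}\lVert y - Z a - X b\rVert^2 + \lambda \lVert b\rVert_1}
#' where the covariate block `Z` (always including an intercept) is never
#' penalized. Penalized columns are mean-imputed, column-standardized with
#' the population (1/n) variance convention, and zero-variance columns are
#' dropped with a log entry. Because the covariates are solved exactly at
#' the optimum, the problem is fit on the covariate-residualized design;
#' covariate coefficients are recovered afterwards by an exact
#' least-squares solve. The lambda grid defaults to `grid_size` log-spaced
#' values from `lambda_max` (the smallest lambda with an all-zero penalized
#' fit) down to `lambda_min_ratio * lambda_max`.
#'
#' @param X Numeric matrix of penalized features (dosages or metabolites),
#'   samples x features.
#' @param y Numeric outcome vector.
#' @param covariates Optional numeric matrix/data.frame of unpenalized
#'   covariates (intercept added automatically).
#' @param lambda_grid Optional decreasing positive grid; computed if `NULL`.
#' @param grid_size,lambda_min_ratio Grid resolution and depth. The default
#'   depth follows the reference convention for penalized paths: `0.001`
#'   when there are at least as many samples as features, `0.01` otherwise
#'   (the interpolation limit makes deeper grids ill-conditioned when
#'   features outnumber samples).
#' @param tol Coordinate-descent convergence tolerance.
#' @param max_iter Maximum coordinate-descent sweeps per lambda.
#' @return An object of class `lasso_problem`.
#' @export
lasso_problem <- function(X, y, covariates = NULL, lambda_grid = NULL,
                          grid_size = 100L, lambda_min_ratio = NULL,
                          tol = 1e-7, max_iter = 100000L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  stopifnot(is.numeric(y), nrow(X) == length(y))
  if (anyNA(y)) stop("lasso_problem: `y` must be complete", call. = FALSE)
  n <- nrow(X)
  X <- impute_col_means(X)
  mu <- colMeans(X)
  s <- col_sd_pop(X)
  drop <- which(s == 0)
  if (length(drop)) {
    ms_log("lasso_problem: dropping %d zero-variance feature(s): %s",
           length(drop), paste(head(colnames(X)[drop], 5), collapse = ", "))
    X <- X[, -drop, drop = FALSE]
    mu <- mu[-drop]; s <- s[-drop]
  }
  Xs <- sweep(sweep(X, 2, mu), 2, s, "/")
  Z <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (is.null(colnames(cv))) colnames(cv) <- paste0("c", seq_len(ncol(cv)))
    if (anyNA(cv)) stop("lasso_problem: covariates must be complete",
                        call. = FALSE)
    Z <- cbind(Z, cv)
  }
  if (qr(Z)$rank < ncol(Z)) {
    stop("lasso_problem: covariate block is rank deficient", call. = FALSE)
  }
  if (is.null(lambda_min_ratio)) {
    # deep grids are only well-conditioned comfortably away from the
    # interpolation limit; the 1.5 margin keeps cross-validation folds
    # overdetermined too
    lambda_min_ratio <- if (n >= 1.5 * ncol(Xs)) 0.001 else 0.01
  }
  if (is.null(lambda_grid)) {
    qz <- qr(Z)
    # hair above the exact threshold so the top of the path is exactly null
    lmax <- max(abs(crossprod(qr.resid(qz, Xs), qr.resid(qz, y)))) / n *
      (1 + 1e-6)
    lambda_grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                           length.out = grid_size))
  }
  if (any(diff(lambda_grid) >= 0) || any(lambda_grid <= 0)) {
    stop("lasso_problem: `lambda_grid` must be strictly decreasing and ",
         "positive", call. = FALSE)
  }
  structure(list(X = Xs, y = as.numeric(y), Z = Z,
                 feature_names = colnames(Xs), feature_mean = mu,
                 feature_sd = s, lambda_grid = lambda_grid,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "lasso_problem")
}

#' @export
print.lasso_problem <- function(x, ...) {
  cat(sprintf(paste0("<lasso_problem> %d samples, %d penalized features, ",
                     "%d covariate column(s), %d lambdas\n"),
              nrow(x$X), ncol(x$X), ncol(x$Z), length(x$lambda_grid)))
  invisible(x)
}

# internal: residualize the standardized design and outcome against the
# covariates on the given rows and run the coordinate-descent path
cd_fit_rows <- function(problem, rows, lambda) {
  Xr <- problem$X[rows, , drop = FALSE]
  Zr <- problem$Z[rows, , drop = FALSE]
  yr <- problem$y[rows]
  qz <- qr(Zr)
  MX <- qr.resid(qz, Xr)
  My <- qr.resid(qz, yr)
  res <- cd_lasso_path(MX, My, lambda, problem$tol, problem$max_iter)
  if (!all(res$converged)) {
    bad <- which(!res$converged)[1]
    stop(sprintf(paste0("coordinate descent did not converge at lambda = ",
                        "%.6g within %d sweeps"),
                 lambda[bad], problem$max_iter), call. = FALSE)
  }
  # exact unpenalized solve for the covariates at each lambda
  fitted_pen <- Xr %*% res$beta
  a <- qr.coef(qz, yr - fitted_pen)
  list(beta = res$beta, unpen = as.matrix(a), sweeps = res$sweeps,
       qz = qz, MX = MX, My = My)
}

#' Fit the LASSO regularization path
#'
#' Cyclic coordinate descent (soft-thresholding updates) with warm starts
#' along the decreasing lambda grid; covariates are refit exactly at every
#' lambda. Every returned fit satisfies the Karush-Kuhn-Tucker conditions at
#' the problem tolerance: `|x_j' r / n| <= lambda + tol` for zero
#' coefficients and `= lambda +/- tol` for active ones.
#'
#' @param problem A [lasso_problem()].
#' @param rows Optional integer subset of samples to fit on (used by the
#'   tuning protocols); default all.
#' @return An object of class `lasso_path`: `lambda`, `beta`
#'   (features x lambdas, standardized scale), `unpen` (covariates x
#'   lambdas), `n_selected`, `kkt_max` (worst KKT violation per lambda).
#' @export
fit_lasso_path <- function(problem, rows = NULL) {
  stopifnot(inherits(problem, "lasso_problem"))
  if (is.null(rows)) rows <- seq_len(nrow(problem$X))
  fit <- cd_fit_rows(problem, rows, problem$lambda_grid)
  n <- length(rows)
  r <- fit$My - fit$MX %*% fit$beta
  grad <- crossprod(fit$MX, r) / n
  kkt <- vapply(seq_along(problem$lambda_grid), function(l) {
    g <- grad[, l]; b <- fit$beta[, l]; lam <- problem$lambda_grid[l]
    viol0 <- max(0, max(abs(g[b == 0]) - lam, -Inf))
    viol1 <- if (any(b != 0)) {
      max(abs(abs(g[b != 0]) - lam))
    } else 0
    max(viol0, viol1)
  }, numeric(1))
  structure(list(lambda = problem$lambda_grid, beta = fit$beta,
                 unpen = fit$unpen, rows = rows,
                 n_selected = colSums(fit$beta != 0),
                 sweeps = fit$sweeps, kkt_max = kkt,
                 feature_names = problem$feature_names),
            class = "lasso_path")
}

# internal: validation predictions for every lambda of a fitted path
predict_path <- function(problem, fit, rows) {
  problem$Z[rows, , drop = FALSE] %*% fit$unpen +
    problem$X[rows, , drop = FALSE] %*% fit$beta
}

# internal: assemble the chosen-lambda refit into a `lasso_fit`
finalize_fit <- function(problem, lambda_star, tuning_curve, method) {
  grid <- problem$lambda_grid[problem$lambda_grid >= lambda_star]
  if (!length(grid) || tail_ne(grid, lambda_star)) {
    grid <- c(grid, lambda_star)
  }
  full <- cd_fit_rows(problem, seq_len(nrow(problem$X)), grid)
  L <- length(grid)
  coef_pen <- setNames(full$beta[, L], problem$feature_names)
  structure(list(lambda = lambda_star,
                 coef_pen = coef_pen,
                 coef_unpen = setNames(full$unpen[, L], colnames(problem$Z)),
                 n_selected = sum(coef_pen != 0),
                 tuning_curve = tuning_curve,
                 method = method,
                 feature_mean = problem$feature_mean,
                 feature_sd = problem$feature_sd),
            class = "lasso_fit")
}

tail_ne <- function(x, v) abs(x[length(x)] - v) > 1e-15

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("<lasso_fit> lambda = %.5g (%s), %d feature(s) selected\n",
              x$lambda, x$method, x$n_selected))
  invisible(x)
}

#' Tune the penalty by a single training/validation split
#'
#' Fits the path on a random `train_frac` share of the samples, picks the
#' lambda minimizing validation mean squared error (largest lambda on ties),
#' and refits at that lambda on the full sample. Deterministic given `seed`.
#'
#' @param problem A [lasso_problem()].
#' @param train_frac Training fraction in `(0, 1)`.
#' @param seed Integer seed for the split.
#' @return A `lasso_fit` with the validation `tuning_curve`.
#' @export
tune_by_split <- function(problem, train_frac = 0.8, seed = 1L) {
  stopifnot(inherits(problem, "lasso_problem"),
            train_frac > 0, train_frac < 1)
  n <- nrow(problem$X)
  set.seed(seed)
  tr <- sort(sample.int(n, floor(train_frac * n)))
  va <- setdiff(seq_len(n), tr)
  if (!length(tr) || !length(va)) {
    stop("tune_by_split: degenerate split (one side empty)", call. = FALSE)
  }
  fit <- cd_fit_rows(problem, tr, problem$lambda_grid)
  pred <- predict_path(problem, fit, va)
  mse <- colMeans((problem$y[va] - pred)^2)
  best <- which.min(mse)  # ties resolve to the largest lambda
  curve <- data.frame(lambda = problem$lambda_grid, loss = mse)
  finalize_fit(problem, problem$lambda_grid[best], curve, "split")
}

#' Tune the penalty by k-fold cross-validation
#'
#' Pools per-sample held-out squared errors over `k` seeded folds into a
#' cross-validation curve, picks the lambda at the minimum (largest lambda
#' on ties), and refits on all samples. With `k = n` this is exact
#' leave-one-out cross-validation.
#'
#' @param problem A [lasso_problem()].
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed for fold assignment.
#' @return A `lasso_fit` with the cross-validation `tuning_curve`.
#' @export
tune_by_cv <- function(problem, k = 10L, seed = 1L) {
  stopifnot(inherits(problem, "lasso_problem"))
  n <- nrow(problem$X)
  if (k < 2L || k > n) stop("tune_by_cv: need 2 <= k <= n", call. = FALSE)
  set.seed(seed)
  folds <- sample(rep_len(seq_len(k), n))
  sqerr <- matrix(NA_real_, n, length(problem$lambda_grid))
  for (f in seq_len(k)) {
    hold <- which(folds == f)
    train <- which(folds != f)
    if (var(problem$y[train]) == 0) {
      stop("tune_by_cv: fold ", f, " has zero outcome variance in training",
           call. = FALSE)
    }
    fit <- cd_fit_rows(problem, train, problem$lambda_grid)
    pred <- predict_path(problem, fit, hold)
    sqerr[hold, ] <- (problem$y[hold] - pred)^2
  }
  mse <- colMeans(sqerr)
  best <- which.min(mse)
  curve <- data.frame(lambda = problem$lambda_grid, loss = mse)
  finalize_fit(problem, problem$lambda_grid[best], curve, "cv")
}

#' Export a fitted LASSO model as a risk-score weight table
#'
#' One row per nonzero penalized coefficient, back-transformed from the
#' standardized fitting scale to the per-unit scale of the raw feature
#' (per-allele for dosages): a standardized coefficient `b` on a feature
#' with raw standard deviation `s` is emitted as `b / s`.
#'
#' @param fit A `lasso_fit`.
#' @param panel_meta Optional [genotype_panel()] (or `data.frame` with
#'   `variant_id`/`effect_allele`) supplying effect alleles for variant
#'   features; metabolite rows carry an empty effect allele.
#' @param label Score label: `"LASSO-PRS"`, `"MRS"` or `"GWAMA-PRS"`.
#' @return A [weight_table()] (possibly empty).
#' @export
export_weights <- function(fit, panel_meta = NULL, label = "LASSO-PRS") {
  stopifnot(inherits(fit, "lasso_fit"))
  nz <- which(fit$coef_pen != 0)
  ids <- names(fit$coef_pen)[nz]
  w <- fit$coef_pen[nz] / fit$feature_sd[nz]
  ea <- rep("", length(nz))
  if (!is.null(panel_meta)) {
    if (inherits(panel_meta, "genotype_panel")) {
      ea <- panel_meta$effect_allele[match(ids, panel_meta$variant_ids)]
    } else {
      ea <- panel_meta$effect_allele[match(ids, panel_meta$variant_id)]
    }
    ea[is.na(ea)] <- ""
  }
  weight_table(ids, ea, unname(w),
               rep(label, length(nz)))
}
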