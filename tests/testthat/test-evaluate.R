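fake_cohort <- function(n = 104, seed = 50) {
  set.seed(seed)
  data.frame(sample_id = sprintf("s%03d", 1:n),
             em_score = rnorm(n, 20, 4),
             age_at_test = runif(n, 57, 70),
             draw_interval = rnorm(n, 2.2, 0.6),
             PC1 = rnorm(n), PC2 = rnorm(n), PC3 = rnorm(n),
             caide = rpois(n, 6), mrs = rnorm(n), lasso_prs = rnorm(n),
             gwama_prs = rnorm(n),
             stroke_before_test = c(rep(TRUE, 3), rep(FALSE, n - 3)),
             stringsAsFactors = FALSE)
}

test_that("model fits match closed-form Gaussian-likelihood oracles", {
  dat <- data.frame(sample_id = letters[1:4], em_score = c(1, 2, 3, 5),
                    x = c(1, 2, 3, 4))
  fit <- fit_model(model_spec("toy", character(), background = "x"), dat)
  n <- 4
  b <- cov(dat$x, dat$em_score) / var(dat$x)
  a <- mean(dat$em_score) - b * mean(dat$x)
  rss <- sum((dat$em_score - a - b * dat$x)^2)
  tss <- sum((dat$em_score - mean(dat$em_score))^2)
  r2_oracle <- 1 - rss / tss
  aic_oracle <- n * log(2 * pi * rss / n) + n + 2 * 3  # q = k + 2 = 3
  bic_oracle <- n * log(2 * pi * rss / n) + n + 3 * log(n)
  expect_equal(fit$r2, r2_oracle, tolerance = 1e-8)
  expect_equal(fit$aic, aic_oracle, tolerance = 1e-8)
  expect_equal(fit$bic, bic_oracle, tolerance = 1e-8)
  expect_equal(fit$adj_r2, 1 - (1 - r2_oracle) * (n - 1) / (n - 1 - 1),
               tolerance = 1e-8)

  # outcome equal to a covariate: numerically perfect fit
  dat$dup <- dat$em_score
  fit2 <- suppressWarnings(  # summary.lm flags the essentially perfect fit
    fit_model(model_spec("perfect", character(), "dup"), dat))
  expect_gte(fit2$r2, 1 - 1e-10)
})

test_that("a pure-noise regressor raises R2 but lowers adjusted R2 in
           expectation", {
  set.seed(51)
  d_r2 <- d_adj <- numeric(200)
  for (s in 1:200) {
    n <- 40
    dat <- data.frame(sample_id = seq_len(n), em_score = rnorm(n),
                      x = rnorm(n), noise = rnorm(n))
    base <- fit_model(model_spec("b", character(), "x"), dat)
    ext <- fit_model(model_spec("e", character(), c("x", "noise")), dat)
    d_r2[s] <- ext$r2 - base$r2
    d_adj[s] <- ext$adj_r2 - base$adj_r2
  }
  expect_true(all(d_r2 >= -1e-12))
  expect_lt(mean(d_adj), 0)
})

test_that("the model grid has 12 specs, never combines PRSs, and always
           includes age", {
  grid <- build_model_grid()
  expect_length(grid, 12L)
  expect_identical(names(grid), sort(names(grid)))
  for (s in grid) {
    expect_false(all(c("lasso_prs", "gwama_prs") %in% s$risk_terms))
    expect_true("age_at_test" %in% s$background)
  }
  expect_error(model_spec("bad", c("lasso_prs", "gwama_prs")),
               "never combines")
})

test_that("nested comparisons report nonnegative incremental R2 and carry
           added-term p-values", {
  dat <- fake_cohort()
  grid <- build_model_grid()
  fits <- lapply(grid, fit_model, cohort = dat)
  for (ext_label in c("caide", "caide+mrs", "caide+lasso_prs+mrs")) {
    cmp <- compare_nested(fits$background, fits[[ext_label]])
    expect_gte(cmp$delta_r2_pp, 0)
    expect_true(is.finite(cmp$delta_aic) && is.finite(cmp$delta_bic))
  }
  cmp <- compare_nested(fits$caide, fits$`caide+lasso_prs`)
  expect_equal(cmp$added_terms, "lasso_prs")
  expect_equal(cmp$added_p_min,
               fits$`caide+lasso_prs`$coef$p[
                 fits$`caide+lasso_prs`$coef$term == "lasso_prs"])
  # identical specs give zero deltas; disjoint specs are rejected
  self <- compare_nested(fits$caide, fits$caide)
  expect_equal(self$delta_r2_pp, 0)
  expect_equal(self$delta_aic, 0)
  expect_error(compare_nested(fits$mrs, fits$`caide+lasso_prs`),
               "not nested")
  # duplicated column upstream is rejected as rank deficient
  dat$mrs_copy <- dat$mrs
  expect_error(
    fit_model(model_spec("dup", "mrs", c("age_at_test", "mrs_copy")), dat),
    "collinear")
})

test_that("a planted incremental signal is recovered at the study's test
           size", {
  # ~5% incremental variance at n = 104; the median incremental R2 over
  # 200 replicates brackets the planted value
  set.seed(52)
  d <- numeric(200)
  for (s in 1:200) {
    n <- 104
    prs <- rnorm(n)
    y <- sqrt(0.05) * prs + rnorm(n, 0, sqrt(0.95))
    dat <- data.frame(sample_id = seq_len(n), em_score = y,
                      age_at_test = runif(n, 57, 70), prs = prs)
    base <- fit_model(model_spec("b", character(), "age_at_test"), dat)
    ext <- fit_model(model_spec("e", character(),
                                c("age_at_test", "prs")), dat)
    d[s] <- (ext$r2 - base$r2) * 100
  }
  expect_gte(median(d), 3)
  expect_lte(median(d), 9)
})

test_that("BH adjustment matches the independent step-up oracle", {
  tab <- data.frame(term = "caide", model = "m", dataset = "d",
                    p = c(0.01, 0.02, 0.03))
  out <- fdr_layers(tab, "within_layer")
  expect_equal(out$p_adj, c(0.03, 0.03, 0.03))

  one <- fdr_layers(data.frame(term = "mrs", model = "m", dataset = "d",
                               p = 0.2), "within_layer")
  expect_equal(one$p_adj, 0.2)

  set.seed(53)
  for (rep in 1:1000) {
    m <- sample(1:20, 1)
    p <- runif(m)
    tab <- data.frame(term = "lasso_prs", model = seq_len(m),
                      dataset = "d", p = p)
    out <- fdr_layers(tab, "within_layer")
    expect_equal(out$p_adj, oracle_bh(p))
    expect_true(all(out$p_adj >= p))
  }
})

test_that("the two FDR schemes pool the right families", {
  tab <- expand.grid(term = c("caide", "mrs", "lasso_prs", "gwama_prs"),
                     model = c("m1", "m2"), dataset = c("d1", "d2"),
                     stringsAsFactors = FALSE)
  set.seed(54)
  tab$p <- runif(nrow(tab))
  within <- fdr_layers(tab, "within_layer")
  expect_setequal(unique(within$family), c("caide", "mrs", "genomics"))
  gen <- within[within$family == "genomics", ]
  expect_equal(gen$p_adj, oracle_bh(gen$p))

  per <- fdr_layers(tab, "per_prs")
  expect_setequal(unique(per$family),
                  c("caide", "mrs", "lasso_prs", "gwama_prs"))
  lp <- per[per$family == "lasso_prs", ]
  expect_equal(lp$p_adj, oracle_bh(lp$p))

  tab$p[1] <- 0
  expect_error(fdr_layers(tab, "within_layer"), "\\(0, 1\\]")
})

test_that("within-layer BH controls the family error under the global null",
{
  set.seed(55)
  # 9 PRS p-values per layer and dataset pair, all null, 500 replicates
  fp <- logical(500)
  for (r in 1:500) {
    p <- runif(18)
    tab <- data.frame(term = rep(c("lasso_prs", "gwama_prs"), 9),
                      model = rep(1:9, each = 2), dataset = "d", p = p)
    out <- fdr_layers(tab, "within_layer")
    fp[r] <- any(out$p_adj < 0.05)
  }
  expect_lte(mean(fp), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 500))
})

test_that("stroke exclusion drops flagged rows idempotently", {
  dat <- fake_cohort()
  out <- sensitivity_exclude(dat)
  expect_equal(nrow(out), 101L)
  expect_identical(sensitivity_exclude(out), out)
  none <- dat; none$stroke_before_test <- FALSE
  expect_identical(nrow(sensitivity_exclude(none)), nrow(none))
  all_flag <- dat; all_flag$stroke_before_test <- TRUE
  expect_error(sensitivity_exclude(all_flag), "empties")
  expect_error(sensitivity_exclude(dat, "age_at_test"), "logical")
})
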