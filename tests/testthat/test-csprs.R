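# helpers: hand-built identity LD references and marginal tables on the
# standardized scale (sd = 1 so emitted weights equal standardized
# posterior means)
identity_ld <- function(ids, block_size = length(ids)) {
  splits <- split(ids, ceiling(seq_along(ids) / block_size))
  blocks <- lapply(splits, function(b) {
    R <- diag(length(b))
    dimnames(R) <- list(b, b)
    list(variant_ids = b, R = R)
  })
  structure(list(blocks = unname(blocks),
                 sd = setNames(rep(1, length(ids)), ids),
                 freq = setNames(rep(0.25, length(ids)), ids),
                 effect_allele = setNames(rep("A", length(ids)), ids),
                 source_n = 1000L),
            class = "ld_reference")
}

marginal_table <- function(ids, beta_std, n) {
  data.frame(variant_id = ids, effect_allele = "A", other_allele = "G",
             beta_meta = beta_std, se_meta = 1 / sqrt(n),
             z = beta_std * sqrt(n),
             p = pmax(2 * pnorm(-abs(beta_std) * sqrt(n)), 1e-300),
             n_total = n, n_cohorts = 2, stringsAsFactors = FALSE)
}

test_that("the compiled GIG sampler matches Bessel-function moments", {
  set.seed(31)
  cases <- list(c(p = 0.5, a = 2, b = 1), c(p = -0.5, a = 1, b = 3),
                c(p = 2, a = 0.5, b = 0.5))
  for (cs in cases) {
    draws <- memoscore:::gig_rnd(rep(cs["p"], 2e4), rep(cs["a"], 1),
                                 rep(cs["b"], 1))
    m <- gig_mean_theory(cs["p"], cs["a"], cs["b"])
    expect_lt(abs(mean(draws) - m) / m, 3 * sd(draws) / sqrt(2e4) / m + 0.01)
  }
  # chi -> 0 limit degenerates to a Gamma draw
  d0 <- memoscore:::gig_rnd(rep(1.5, 2e4), rep(2, 1), rep(0, 1))
  expect_lt(abs(mean(d0) - 1.5 / 1), 0.05)  # Gamma(1.5, rate 1) mean
})

test_that("LD reference estimates block correlations and floors eigenvalues",
{
  cfg <- small_cfg(seed = 32, n_samples = 3000L, ld_rho = 0,
                   n_variants = 30L, n_blocks = 3L)
  panel <- simulate_genotypes(cfg)
  ld <- build_ld_reference(panel)
  off <- unlist(lapply(ld$blocks, function(b) b$R[upper.tri(b$R)]))
  expect_lt(max(abs(off)), 3 / sqrt(3000) + 0.03)

  # duplicated variant column: correlation 1 handled by the PSD floor
  dup <- cbind(panel$dosages[, 1:3], panel$dosages[, 3])
  pd <- genotype_panel(panel$sample_ids, c("a", "b", "c", "c_dup"),
                       rep(1, 4), 1:4, rep("A", 4), rep("G", 4), dup)
  ld_dup <- build_ld_reference(pd, blocks = rep(1L, 4))
  ev <- eigen(ld_dup$blocks[[1]]$R, symmetric = TRUE, only.values = TRUE)
  expect_gte(min(ev$values), 1e-6 - 1e-12)

  # AR(0.8) block: adjacent reference correlations match the
  # thresholding Monte-Carlo oracle
  cfg2 <- small_cfg(seed = 33, n_samples = 5000L, ld_rho = 0.8,
                    n_variants = 10L, n_blocks = 1L)
  panel2 <- simulate_genotypes(cfg2)
  ld2 <- build_ld_reference(panel2)
  maf <- attr(panel2, "maf")
  set.seed(1)
  target <- oracle_dosage_cor(maf[4], maf[5], 0.8, ndraw = 1e6)
  expect_lt(abs(ld2$blocks[[1]]$R[4, 5] - target), 0.07)
})

test_that("null marginal effects give posterior means indistinguishable
           from zero", {
  ids <- sprintf("v%03d", 1:50)
  meta <- marginal_table(ids, rep(0, 50), n = 1000)
  cfg <- cs_config(phi = 0.01, n_iter = 1500, n_burnin = 500, thin = 1,
                   store_draws = TRUE, seed = 7)
  w <- sample_posterior_effects(meta, identity_ld(ids, block_size = 25),
                                cfg)
  post <- attr(w, "post_mean_std")
  draws <- attr(w, "draws")
  # batch-means Monte-Carlo SE (20 batches of 50)
  nb <- 20; bs <- nrow(draws) / nb
  for (j in seq_along(ids)) {
    bm <- tapply(draws[, j], rep(seq_len(nb), each = bs), mean)
    mcse <- sd(bm) / sqrt(nb)
    expect_lt(abs(post[j]), 3 * mcse + 1e-12)
  }
})

test_that("the single-variant posterior mean matches 1-D quadrature within
           2 percent", {
  n <- 1000
  # the weaker signal (z ~ 2.5) sits in the shrink/keep transition where
  # the chain mixes slowly, so its estimate pools independent chains
  cases <- list(list(bhat = 0.08, iters = 80000, seeds = 8:10),
                list(bhat = 0.15, iters = 42000, seeds = 8))
  for (cs in cases) {
    oracle <- oracle_cs_posterior_mean(cs$bhat, n = n, a = 1, b = 0.5,
                                       phi = 0.01, sigma2 = 1)
    post <- mean(vapply(cs$seeds, function(sd) {
      cfg <- cs_config(phi = 0.01, sigma2 = 1, psi_max = Inf,
                       n_iter = cs$iters, n_burnin = 2000, thin = 1,
                       seed = sd)
      w <- sample_posterior_effects(marginal_table("v1", cs$bhat, n),
                                    identity_ld("v1"), cfg)
      attr(w, "post_mean_std")
    }, numeric(1)))
    expect_lt(abs(post - oracle) / abs(oracle), 0.02)
  }
})

test_that("null effects are shrunk harder than causal ones", {
  set.seed(34)
  n <- 20000
  ids <- sprintf("v%03d", 1:60)
  truth <- c(rep(0, 40), rnorm(20, 0, 0.05))
  bhat <- truth + rnorm(60, 0, 1 / sqrt(n))
  cfg <- cs_config(n_iter = 1200, n_burnin = 400, thin = 2, seed = 9)
  w <- sample_posterior_effects(marginal_table(ids, bhat, n),
                                identity_ld(ids, block_size = 30), cfg)
  post <- attr(w, "post_mean_std")
  # group-aggregate shrinkage factors (per-variant ratios are undefined
  # when a null marginal lands near zero)
  ratio_null <- mean(abs(post[1:40])) / mean(abs(bhat[1:40]))
  ratio_causal <- mean(abs(post[41:60])) / mean(abs(bhat[41:60]))
  expect_lt(ratio_null, ratio_causal)
  expect_lte(ratio_null, 1.05)
  expect_lte(ratio_causal, 1.05)
})

test_that("shrinkage is monotone in the global parameter phi", {
  set.seed(35)
  n <- 5000
  ids <- sprintf("v%03d", 1:40)
  bhat <- rnorm(40, 0, sqrt(0.002))
  means <- sapply(c(1e-6, 1e-4, 1e-2), function(phi) {
    cfg <- cs_config(phi = phi, n_iter = 1200, n_burnin = 400, thin = 2,
                     seed = 10)
    w <- sample_posterior_effects(marginal_table(ids, bhat, n),
                                  identity_ld(ids, block_size = 20), cfg)
    mean(abs(attr(w, "post_mean_std")))
  })
  expect_true(all(diff(means) > 0))
})

test_that("posterior means are invariant to variant order within a block", {
  set.seed(36)
  n <- 2000
  m <- 6
  ids <- sprintf("v%d", 1:m)
  R <- 0.6^abs(outer(1:m, 1:m, "-"))
  dimnames(R) <- list(ids, ids)
  ld <- structure(list(
    blocks = list(list(variant_ids = ids, R = R)),
    sd = setNames(rep(1, m), ids),
    freq = setNames(rep(0.3, m), ids),
    effect_allele = setNames(rep("A", m), ids),
    source_n = 1000L), class = "ld_reference")
  bhat <- c(0.08, 0, 0.05, -0.06, 0, 0.02)
  meta <- marginal_table(ids, bhat, n)
  cfg <- cs_config(n_iter = 16000, n_burnin = 1000, thin = 1, seed = 11)
  w1 <- sample_posterior_effects(meta, ld, cfg)
  perm <- c(4, 1, 6, 2, 5, 3)
  ld_p <- ld
  ld_p$blocks[[1]] <- list(variant_ids = ids[perm],
                           R = R[perm, perm])
  ld_p$sd <- ld$sd[perm]; ld_p$freq <- ld$freq[perm]
  ld_p$effect_allele <- ld$effect_allele[perm]
  w2 <- sample_posterior_effects(meta, ld_p, cfg)
  p1 <- attr(w1, "post_mean_std")
  p2 <- attr(w2, "post_mean_std")[names(attr(w1, "post_mean_std"))]
  expect_equal(unname(p1), unname(p2), tolerance = 0.08)
  expect_lt(max(abs(p1 - p2)), 0.005)
})

test_that("auto-phi adapts to architecture sparsity and reports its chain",
{
  set.seed(37)
  n <- 20000
  ids <- sprintf("v%03d", 1:60)
  smaller <- logical(10)
  for (s in 1:10) {
    set.seed(200 + s)
    sparse <- c(rnorm(4, 0, 0.08), rep(0, 56))
    dense <- rnorm(60, 0, sqrt(sum(sparse^2) / 60))
    run_phi <- function(truth, seed) {
      bhat <- truth + rnorm(60, 0, 1 / sqrt(n))
      cfg <- cs_config(phi = "auto", n_iter = 600, n_burnin = 200,
                       thin = 2, seed = seed)
      w <- sample_posterior_effects(marginal_table(ids, bhat, n),
                                    identity_ld(ids, block_size = 30), cfg)
      auto_phi_summary(w)$median
    }
    smaller[s] <- run_phi(sparse, s) < run_phi(dense, s + 500)
  }
  expect_gte(mean(smaller), 0.6)

  # chain bookkeeping and the fixed-phi guard
  meta <- marginal_table(ids, rep(0, 60), n)
  cfg <- cs_config(phi = "auto", n_iter = 1000, n_burnin = 500, thin = 5,
                   seed = 3)
  w <- sample_posterior_effects(meta, identity_ld(ids, 30), cfg)
  expect_equal(auto_phi_summary(w)$chain_length, 100L)
  cfg_fix <- cs_config(phi = 0.01, n_iter = 200, n_burnin = 100, seed = 3)
  w_fix <- sample_posterior_effects(meta, identity_ld(ids, 30), cfg_fix)
  expect_error(auto_phi_summary(w_fix), "fixed")
})

test_that("the sampler is deterministic given its seed and drops variants
           absent from the LD reference", {
  ids <- sprintf("v%03d", 1:20)
  meta <- marginal_table(c(ids, "missing1"), c(rnorm(20, 0, 0.02), 0.1),
                         n = 5000)
  cfg <- cs_config(n_iter = 300, n_burnin = 100, seed = 12)
  expect_message(
    w1 <- sample_posterior_effects(meta, identity_ld(ids, 10), cfg),
    "absent")
  w2 <- suppressMessages(
    sample_posterior_effects(meta, identity_ld(ids, 10), cfg))
  expect_identical(w1$weight, w2$weight)
  expect_false("missing1" %in% w1$feature_id)
})
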