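# Shared small-scale configurations and constructors for the suite.

small_cfg <- function(seed = 1L, ...) {
  args <- list(n_samples = 120L, n_variants = 60L, n_blocks = 6L,
               n_causal_variants = 4L, n_metabolites = 20L,
               n_causal_metabolites = 3L, n_metab_blocks = 4L,
               n_external_cohorts = 2L, external_n_per_cohort = 150L,
               seed = seed)
  do.call(sim_config, modifyList(args, list(...)))
}

# A tiny hand-built panel for scoring/harmonization tests.
toy_panel <- function() {
  genotype_panel(
    sample_ids = c("s1", "s2", "s3"),
    variant_ids = c("v1", "v2", "v3", "v4"),
    chrom = c(1, 1, 2, 2), pos = c(10, 20, 10, 20),
    effect_allele = c("C", "C", "A", "G"),
    other_allele = c("A", "T", "T", "T"),
    dosages = matrix(c(2, 1, 0,
                       0, 1, 2,
                       1, 1, 1,
                       2, 0, 1), nrow = 3))
}

# A standardized single-feature LASSO problem with x'y/n fixed at `target`.
single_feature_problem <- function(target = 0.5, lambda = 0.2, n = 40) {
  set.seed(99)
  x <- rnorm(n)
  xs <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  y <- target * xs
  lasso_problem(matrix(x, ncol = 1), y, lambda_grid = lambda)
}
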