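#' Emulate the per-cohort inputs of an external meta-analysis
#'
#' Simulates `n_external_cohorts` independent cohorts from the same variant
#' universe and genetic architecture as the internal study (sizes vary
#' uniformly within +/-20% of `external_n_per_cohort`), regresses the
#' outcome on each variant via [run_gwas()], and returns one
#' summary-statistics table per cohort. Each external outcome is the fixed
#' causal genetic component (coefficients taken from `truth`, not rescaled
#' per cohort, so effects are homogeneous across cohorts) plus Gaussian
#' noise completing unit variance.
#'
#' @param cfg A [sim_config()].
#' @param truth The `true_model` from [simulate_cohort()] on the same
#'   config (same variant universe).
#' @return A list of summary-statistics `data.frame`s.
#' @export
simulate_external_sumstats <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "true_model"))
  if (!identical(names(truth$variant_effects),
                 variant_universe(cfg)$variant_id)) {
    stop("simulate_external_sumstats: truth does not match the variant ",
         "universe of `cfg`", call. = FALSE)
  }
  beta_std <- truth$variant_effects / truth$outcome_scale
  planted <- if (any(beta_std != 0)) cfg$h2_genetic else 0
  out <- vector("list", cfg$n_external_cohorts)
  for (k in seq_len(cfg$n_external_cohorts)) {
    set.seed(derive_seed(cfg$seed, paste0("external-size-", k)))
    nk <- max(30L, as.integer(round(cfg$external_n_per_cohort *
                                      runif(1, 0.8, 1.2))))
    panel <- simulate_genotypes(cfg, n = nk,
                                seed_label = paste0("external-geno-", k))
    set.seed(derive_seed(cfg$seed, paste0("external-pheno-", k)))
    g <- as.vector(panel$dosages %*% beta_std)
    y <- g + rnorm(nk, 0, sqrt(max(1 - planted, 0.05)))
    cohort <- data.frame(sample_id = panel$sample_ids, em_score = y,
                         stringsAsFactors = FALSE)
    ss <- run_gwas(panel, cohort)
    ss$monomorphic <- NULL
    out[[k]] <- ss
  }
  out
}
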