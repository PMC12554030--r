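#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles every parameter of the synthetic study: genotype panel geometry and
#' linkage-disequilibrium (LD) structure, the sparse genetic architecture of
#' episodic memory, the correlated metabolome, the CAIDE contribution, and the
#' emulated external meta-analysis. Defaults mirror the study conditions the
#' package emulates: 1001 adults split into 897 training and 104 test samples,
#' a 5000-variant panel in 50 LD blocks standing in for ~1M imputed SNPs,
#' heritability 0.30 concentrated in 10 causal variants, 137 Nightingale-style
#' metabolic measures of which 15 carry signal, and an external meta-analysis
#' of 23 cohorts averaging 1278 samples each (total ~29,400).
#'
#' @param n_samples Number of adult samples (training + test).
#' @param n_variants Number of genetic variants on the panel.
#' @param n_blocks Number of disjoint contiguous LD blocks.
#' @param ld_rho First-order autoregressive correlation of the latent
#'   haplotype liabilities within a block, in `[0, 1)`.
#' @param maf_range Length-2 numeric; minor allele frequencies are drawn
#'   uniformly from this interval (each in `(0, 0.5]`).
#' @param n_causal_variants Number of variants with nonzero effect.
#' @param h2_genetic Fraction of phenotypic variance explained by genetics,
#'   in `[0, 1)`.
#' @param n_metabolites Number of metabolic measures (default 137).
#' @param n_causal_metabolites Number of metabolites with nonzero effect
#'   (default 15).
#' @param metab_cor Within-block equicorrelation of metabolites, in `[0, 1)`.
#' @param n_metab_blocks Number of metabolite correlation blocks.
#' @param var_metabolic Fraction of phenotypic variance from metabolites.
#' @param var_caide Fraction of phenotypic variance from the CAIDE score.
#' @param n_external_cohorts Number of emulated external GWAS cohorts.
#' @param external_n_per_cohort Average sample size per external cohort.
#' @param stroke_frac Fraction of samples flagged with stroke before the
#'   memory assessment.
#' @param seed Integer seed; all generated data are deterministic given it.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_samples = 100, n_variants = 60, n_blocks = 6, seed = 1)
sim_config <- function(n_samples = 1001L,
                       n_variants = 5000L,
                       n_blocks = 50L,
                       ld_rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       n_causal_variants = 10L,
                       h2_genetic = 0.3,
                       n_metabolites = 137L,
                       n_causal_metabolites = 15L,
                       metab_cor = 0.4,
                       n_metab_blocks = 10L,
                       var_metabolic = 0.05,
                       var_caide = 0.02,
                       n_external_cohorts = 23L,
                       external_n_per_cohort = 1278L,
                       stroke_frac = 0.03,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    n_variants = as.integer(n_variants),
    n_blocks = as.integer(n_blocks),
    ld_rho = as.numeric(ld_rho),
    maf_range = as.numeric(maf_range),
    n_causal_variants = as.integer(n_causal_variants),
    h2_genetic = as.numeric(h2_genetic),
    n_metabolites = as.integer(n_metabolites),
    n_causal_metabolites = as.integer(n_causal_metabolites),
    metab_cor = as.numeric(metab_cor),
    n_metab_blocks = as.integer(n_metab_blocks),
    var_metabolic = as.numeric(var_metabolic),
    var_caide = as.numeric(var_caide),
    n_external_cohorts = as.integer(n_external_cohorts),
    external_n_per_cohort = as.integer(external_n_per_cohort),
    stroke_frac = as.numeric(stroke_frac),
    seed = as.integer(seed)
  )
  counts <- c("n_samples", "n_variants", "n_blocks", "n_metabolites",
              "n_metab_blocks", "n_external_cohorts", "external_n_per_cohort")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] <= 0L) {
      stop("sim_config: `", nm, "` must be a positive count", call. = FALSE)
    }
  }
  if (cfg$n_causal_variants < 0L || cfg$n_causal_variants > cfg$n_variants) {
    stop("sim_config: `n_causal_variants` must lie in [0, n_variants]",
         call. = FALSE)
  }
  if (cfg$n_causal_metabolites < 0L ||
      cfg$n_causal_metabolites > cfg$n_metabolites) {
    stop("sim_config: `n_causal_metabolites` must lie in [0, n_metabolites]",
         call. = FALSE)
  }
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) {
    stop("sim_config: `ld_rho` must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$metab_cor < 0 || cfg$metab_cor >= 1) {
    stop("sim_config: `metab_cor` must lie in [0, 1)", call. = FALSE)
  }
  if (length(cfg$maf_range) != 2L || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("sim_config: `maf_range` must be an increasing pair in (0, 0.5]",
         call. = FALSE)
  }
  for (nm in c("h2_genetic", "var_metabolic", "var_caide")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] >= 1) {
      stop("sim_config: `", nm, "` must lie in [0, 1)", call. = FALSE)
    }
  }
  if (cfg$h2_genetic + cfg$var_metabolic + cfg$var_caide >= 1) {
    stop("sim_config: variance budget h2_genetic + var_metabolic + var_caide ",
         "must be < 1", call. = FALSE)
  }
  if (cfg$n_blocks > cfg$n_variants) {
    stop("sim_config: cannot split ", cfg$n_variants, " variants into ",
         cfg$n_blocks, " blocks of at least one variant", call. = FALSE)
  }
  if (cfg$stroke_frac < 0 || cfg$stroke_frac >= 1) {
    stop("sim_config: `stroke_frac` must lie in [0, 1)", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  samples: %d, variants: %d in %d LD blocks (rho = %.2f)\n",
              x$n_samples, x$n_variants, x$n_blocks, x$ld_rho))
  cat(sprintf("  architecture: %d causal variants, h2 = %.2f\n",
              x$n_causal_variants, x$h2_genetic))
  cat(sprintf("  metabolome: %d measures (%d causal), var = %.2f\n",
              x$n_metabolites, x$n_causal_metabolites, x$var_metabolic))
  cat(sprintf("  CAIDE variance: %.2f; external: %d cohorts x ~%d\n",
              x$var_caide, x$n_external_cohorts, x$external_n_per_cohort))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
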