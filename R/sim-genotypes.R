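# Variant universe shared by the internal cohort and all emulated external
# cohorts: ids, block membership, chromosome/position, allele pair and MAF are
# all derived from the config seed alone, so independently simulated cohorts
# are guaranteed to live on the same panel.
variant_universe <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  p <- cfg$n_variants
  set.seed(derive_seed(cfg$seed, "variant-universe"))
  maf <- runif(p, cfg$maf_range[1], cfg$maf_range[2])
  # non-palindromic allele pairs only; strand-ambiguous variants are covered
  # by hand-built fixtures in the harmonization tests
  pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"),
                 c("C", "A"), c("G", "A"), c("T", "C"), c("T", "G"))
  pick <- sample.int(nrow(pairs), p, replace = TRUE)
  block <- sort(rep_len(seq_len(cfg$n_blocks), p))
  chrom <- ((block - 1L) %% 22L) + 1L
  pos <- integer(p)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- seq_along(idx) * 1000L
  }
  list(
    variant_id = sprintf("rs%06d", seq_len(p)),
    chrom = chrom,
    pos = pos,
    effect_allele = pairs[pick, 1],
    other_allele = pairs[pick, 2],
    maf = maf,
    block = block
  )
}

#' Simulate a genotype dosage panel with block LD structure
#'
#' Variants are partitioned into contiguous LD blocks. Within a block, two
#' latent haplotype liabilities per sample follow a first-order autoregressive
#' (AR(1)) Gaussian process across variants with correlation `ld_rho`; each
#' liability is thresholded at the normal quantile of the variant's minor
#' allele frequency to yield an allele, and the dosage is the sum of the two
#' alleles. Genotypes therefore satisfy Hardy-Weinberg frequencies exactly at
#' the drawn MAFs, while adjacent-variant dosage correlation equals `ld_rho`
#' attenuated by the double thresholding.
#'
#' @param cfg A [sim_config()].
#' @param n Number of samples (defaults to `cfg$n_samples`).
#' @param seed_label Stage label mixed into the seed, so that independent
#'   cohorts on the same variant universe can be generated.
#' @return A [genotype_panel()] with per-variant `maf` and `block` attributes.
#' @export
#' @examples
#' panel <- simulate_genotypes(sim_config(n_samples = 20, n_variants = 12,
#'                                        n_blocks = 3, seed = 7))
#' dim(panel$dosages)
simulate_genotypes <- function(cfg, n = cfg$n_samples,
                               seed_label = "genotypes") {
  stopifnot(inherits(cfg, "sim_config"))
  uni <- variant_universe(cfg)
  set.seed(derive_seed(cfg$seed, seed_label))
  p <- cfg$n_variants
  dos <- matrix(0, n, p)
  thr <- qnorm(uni$maf)
  rho <- cfg$ld_rho
  innov <- sqrt(1 - rho^2)
  for (b in unique(uni$block)) {
    idx <- which(uni$block == b)
    m <- length(idx)
    thr_blk <- matrix(thr[idx], n, m, byrow = TRUE)
    g <- matrix(0L, n, m)
    for (h in 1:2) {
      z <- matrix(rnorm(n * m), n, m)
      if (rho > 0 && m > 1L) {
        # stationary AR(1) across variants, vectorized over samples
        for (j in 2:m) z[, j] <- rho * z[, j - 1L] + innov * z[, j]
      }
      g <- g + (z <= thr_blk)
    }
    dos[, idx] <- g
  }
  genotype_panel(
    sample_ids = sprintf("S%05d", seq_len(n)),
    variant_ids = uni$variant_id,
    chrom = uni$chrom,
    pos = uni$pos,
    effect_allele = uni$effect_allele,
    other_allele = uni$other_allele,
    dosages = dos,
    maf = uni$maf,
    block = uni$block
  )
}
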