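#' Simulate a full adult cohort: genotypes, metabolome, covariates, outcome
#'
#' Generates a [simulate_genotypes()] panel, a block-equicorrelated Gaussian
#' metabolome, CAIDE components from plausible late-adulthood marginals
#' (age ~ U(57, 70); education ~ N(10, 3) truncated at 4 years;
#' SBP ~ N(140, 18) mmHg; BMI ~ N(27, 4) kg/m2; cholesterol ~ N(5.8, 1.0)
#' mmol/L; inactivity ~ Bernoulli(0.3); male sex ~ Bernoulli(0.45)), a
#' blood-draw-to-test interval ~ N(2.2, 0.6) years, and a stroke flag for a
#' small configurable fraction. The continuous episodic-memory outcome is
#'
#' \deqn{y = X\beta_g + M\beta_m + \gamma \cdot \mathrm{CAIDE} + \epsilon}
#'
#' with each component rescaled on the realized sample so its variance
#' fraction equals `h2_genetic`, `var_metabolic` and `var_caide`. The CAIDE
#' score enters through the integer score, with a negative sign (more risk
#' factors, poorer memory). The reported score is `20 + 4 * y` (word-list
#' scale); a clipped integer 0-30 version is provided alongside.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `panel` ([genotype_panel()]), `cohort`
#'   (`data.frame`, one row per sample, including the computed `caide`
#'   column), `metabolites` (samples x metabolites matrix), and `truth` (the
#'   generating model: causal ids, per-feature effects on the reported score
#'   scale, per-sample genetic/metabolic components, noise SD).
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_samples = 50, n_variants = 40,
#'                                   n_blocks = 4, seed = 3))
#' names(sim)
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  panel <- simulate_genotypes(cfg)
  n <- cfg$n_samples
  set.seed(derive_seed(cfg$seed, "cohort"))

  age <- runif(n, 57, 70)
  sex <- ifelse(runif(n) < 0.45, "male", "female")
  education <- pmax(4, rnorm(n, 10, 3))
  sbp <- rnorm(n, 140, 18)
  bmi <- rnorm(n, 27, 4)
  total_chol <- rnorm(n, 5.8, 1.0)
  inactive <- runif(n) < 0.3
  draw_interval <- pmax(0.25, rnorm(n, 2.2, 0.6))
  stroke <- runif(n) < cfg$stroke_frac

  cohort <- data.frame(sample_id = panel$sample_ids, age_at_test = age,
                       sex = sex, education = education, sbp = sbp,
                       bmi = bmi, total_chol = total_chol,
                       inactive = inactive, draw_interval = draw_interval,
                       stroke_before_test = stroke,
                       stringsAsFactors = FALSE)
  cohort$caide <- caide_score(cohort)

  # metabolome: equicorrelated within blocks via a one-factor construction
  pm <- cfg$n_metabolites
  mblock <- sort(rep_len(seq_len(cfg$n_metab_blocks), pm))
  M <- matrix(rnorm(n * pm), n, pm)
  if (cfg$metab_cor > 0) {
    for (b in unique(mblock)) {
      idx <- which(mblock == b)
      f <- rnorm(n)
      M[, idx] <- sqrt(cfg$metab_cor) * f +
        sqrt(1 - cfg$metab_cor) * M[, idx]
    }
  }
  colnames(M) <- sprintf("met_%03d", seq_len(pm))
  rownames(M) <- panel$sample_ids

  # sparse architectures
  causal_v <- sort(sample.int(cfg$n_variants, cfg$n_causal_variants))
  causal_m <- sort(sample.int(pm, cfg$n_causal_metabolites))
  beta_v <- numeric(cfg$n_variants)
  beta_m <- numeric(pm)

  g_comp <- numeric(n)
  if (cfg$h2_genetic > 0 && cfg$n_causal_variants > 0) {
    raw <- rnorm(cfg$n_causal_variants)
    g_raw <- as.vector(panel$dosages[, causal_v, drop = FALSE] %*% raw)
    s <- sqrt(cfg$h2_genetic) / sd(g_raw)
    beta_v[causal_v] <- raw * s
    g_comp <- (g_raw - mean(g_raw)) * s
  } else {
    # null heritability: the causal set is empty and all effects are zero
    causal_v <- integer(0)
  }
  m_comp <- numeric(n)
  if (cfg$var_metabolic > 0 && cfg$n_causal_metabolites > 0) {
    raw <- rnorm(cfg$n_causal_metabolites)
    m_raw <- as.vector(M[, causal_m, drop = FALSE] %*% raw)
    s <- sqrt(cfg$var_metabolic) / sd(m_raw)
    beta_m[causal_m] <- raw * s
    m_comp <- (m_raw - mean(m_raw)) * s
  } else if (cfg$n_causal_metabolites > 0) {
    # null metabolome: the causal set is still recorded with zero effects
    causal_m <- integer(0)
  }
  c_comp <- numeric(n)
  caide_eff <- 0
  if (cfg$var_caide > 0 && sd(cohort$caide) > 0) {
    caide_eff <- -sqrt(cfg$var_caide) / sd(cohort$caide)
    c_comp <- (cohort$caide - mean(cohort$caide)) * caide_eff
  }
  resid_var <- 1 - cfg$h2_genetic - cfg$var_metabolic - cfg$var_caide
  noise <- rnorm(n, 0, sqrt(resid_var))
  y <- g_comp + m_comp + c_comp + noise

  scale_out <- 4  # word-list-learning points per unit of latent y
  cohort$em_score <- 20 + scale_out * y
  cohort$em_score_int <- pmin(30L, pmax(0L, as.integer(round(cohort$em_score))))

  truth <- structure(list(
    causal_variant_ids = panel$variant_ids[causal_v],
    variant_effects = setNames(beta_v * scale_out, panel$variant_ids),
    causal_metabolite_ids = colnames(M)[causal_m],
    metabolite_effects = setNames(beta_m * scale_out, colnames(M)),
    caide_effect = caide_eff * scale_out,
    noise_sd = sqrt(resid_var) * scale_out,
    genetic_value = setNames(g_comp * scale_out, panel$sample_ids),
    metabolic_value = setNames(m_comp * scale_out, panel$sample_ids),
    outcome_scale = scale_out
  ), class = "true_model")

  list(panel = panel, cohort = cohort, metabolites = M, truth = truth)
}

#' @export
print.true_model <- function(x, ...) {
  cat(sprintf(paste0("<true_model> %d causal variants, %d causal ",
                     "metabolites, caide effect %.3f, noise sd %.3f\n"),
              length(x$causal_variant_ids), length(x$causal_metabolite_ids),
              x$caide_effect, x$noise_sd))
  invisible(x)
}

#' Simulate a child validation cohort on the shared variant universe
#'
#' Emulates the transfer experiment: a pediatric cohort genotyped on a panel
#' covering only a fraction of the adult variant universe, with child
#' covariates (age at assessment, sex, maternal education) and an
#' episodic-memory score that by default carries no adult-derived genetic
#' signal (`h2_shared = 0`).
#'
#' @param cfg The adult [sim_config()] (fixes the variant universe).
#' @param truth The adult `true_model` (used when `h2_shared > 0`).
#' @param n Number of children.
#' @param age_mean,age_sd Age at assessment (years).
#' @param overlap Fraction of the adult variant universe present on the
#'   child panel.
#' @param h2_shared Variance fraction of the child outcome driven by the
#'   adult causal effects.
#' @param label Cohort label (also seeds the stage).
#' @return A list with `panel`, `cohort`.
#' @export
simulate_children <- function(cfg, truth, n = 309L, age_mean = 11.9,
                              age_sd = 0.5, overlap = 0.93, h2_shared = 0,
                              label = "children") {
  stopifnot(inherits(cfg, "sim_config"))
  panel <- simulate_genotypes(cfg, n = n,
                              seed_label = paste0("child-", label))
  set.seed(derive_seed(cfg$seed, paste0("child-cohort-", label)))
  g_comp <- numeric(n)
  if (h2_shared > 0) {
    eff <- truth$variant_effects / truth$outcome_scale
    g_raw <- as.vector(panel$dosages %*% eff)
    if (sd(g_raw) > 0) g_comp <- (g_raw - mean(g_raw)) *
        sqrt(h2_shared) / sd(g_raw)
  }
  y <- g_comp + rnorm(n, 0, sqrt(1 - h2_shared))
  cohort <- data.frame(
    sample_id = paste0(toupper(substr(label, 1, 1)), panel$sample_ids),
    em_score = 10 + 3 * y,
    age_at_test = rnorm(n, age_mean, age_sd),
    sex = ifelse(runif(n) < 0.5, "male", "female"),
    maternal_education = pmax(4, rnorm(n, 13, 3)),
    stringsAsFactors = FALSE)
  keep <- sort(sample.int(cfg$n_variants,
                          max(1L, round(overlap * cfg$n_variants))))
  panel <- subset_panel(panel, variants = keep)
  panel$sample_ids <- cohort$sample_id
  rownames(panel$dosages) <- cohort$sample_id
  list(panel = panel, cohort = cohort)
}

# internal: subset a panel by variant / sample index
subset_panel <- function(panel, variants = NULL, samples = NULL) {
  if (!is.null(variants)) {
    panel$variant_ids <- panel$variant_ids[variants]
    panel$chrom <- panel$chrom[variants]
    panel$pos <- panel$pos[variants]
    panel$effect_allele <- panel$effect_allele[variants]
    panel$other_allele <- panel$other_allele[variants]
    panel$dosages <- panel$dosages[, variants, drop = FALSE]
    if (!is.null(attr(panel, "maf"))) {
      attr(panel, "maf") <- attr(panel, "maf")[variants]
    }
    if (!is.null(attr(panel, "block"))) {
      attr(panel, "block") <- attr(panel, "block")[variants]
    }
  }
  if (!is.null(samples)) {
    panel$sample_ids <- panel$sample_ids[samples]
    panel$dosages <- panel$dosages[samples, , drop = FALSE]
  }
  panel
}
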