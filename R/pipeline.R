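#' Default end-to-end study configuration
#'
#' The configuration tree consumed by [run_study()]: synthetic-cohort
#' parameters (see [sim_config()]), the common test split (n = 104 by
#' default, with genomic/metabolomic training subsets of 742 and 706),
#' tuning-protocol settings for the two LASSO analyses, the
#' continuous-shrinkage sampler settings, and the two child validation
#' cohorts with deliberately incomplete variant overlap (0.930 / 0.945).
#'
#' @param seed Top-level integer seed; all stage seeds derive from it.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    sim = list(),  # overrides for sim_config()
    test_n = 104L,
    n_lasso_gwas = 742L,
    n_lasso_mwas = 706L,
    n_pcs = 3L,
    penalized = list(train_frac = 0.8, k = 10L, grid_size = 100L,
                     lambda_min_ratio = NULL, tol = 1e-7),
    csprs = list(a = 1, b = 0.5, phi = "auto", n_iter = 1000L,
                 n_burnin = 500L, thin = 5L),
    gwas_threshold = 5e-8,
    children = list(
      enabled = TRUE,
      h2_shared = 0,
      cohorts = list(
        children_a = list(n = 309L, age_mean = 11.9, overlap = 0.930),
        children_b = list(n = 443L, age_mean = 8.6, overlap = 0.945)))
  )
}

# internal: recursive list merge (user values override defaults)
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

# internal: standardize a score, tolerating degenerate all-equal scores
# (e.g. an empty weight table) by emitting zeros with a log entry
standardize_or_zero <- function(scores, label) {
  if (sd(scores) == 0) {
    ms_log("score `%s` has zero variance in this dataset; set to 0", label)
    return(scores * 0)
  }
  standardize_scores(scores)
}

#' Run the full synthetic multiomics study
#'
#' Executes the study end to end: simulate the adult cohort; compute
#' ancestry PCs and the CAIDE score; draw the common test sample; fit the
#' genome-wide LASSO (split-tuned) and metabolome-wide LASSO (CV-tuned) on
#' the non-test samples; emulate the external per-cohort GWAS tables,
#' meta-analyze them and filter genome-wide-significant hits; draw
#' continuous-shrinkage posterior weights against an LD reference from the
#' training genotypes; score and standardize all risk scores in the test
#' dataset and its stroke-excluded sensitivity copy; fit the 12-model
#' evaluation grid on both, with both FDR schemes; and (when enabled) score
#' and evaluate the PRSs in the two child cohorts. All stage outputs plus a
#' manifest with derived seeds are written when `out_dir` is given.
#'
#' @param config A configuration list (see [default_config()]) or the path
#'   to a YAML file of overrides.
#' @param out_dir Optional output directory; created if needed.
#' @return Invisibly, a list with all intermediate and final results.
#' @export
run_study <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- merge_config(default_config(), config)
  seed <- config$seed
  cfg <- do.call(sim_config, merge_config(config$sim, list(seed = seed)))

  ms_log("simulating adult cohort (%d samples, %d variants)",
         cfg$n_samples, cfg$n_variants)
  sim <- simulate_cohort(cfg)
  cohort <- sim$cohort
  pcs <- compute_ancestry_pcs(sim$panel, k = config$n_pcs)
  cohort <- cbind(cohort, as.data.frame(pcs))

  n <- nrow(cohort)
  if (config$test_n >= n) stop("run_study: test_n must be below n_samples",
                               call. = FALSE)
  set.seed(derive_seed(seed, "test-split"))
  test_rows <- sort(sample.int(n, config$test_n))
  train_rows <- setdiff(seq_len(n), test_rows)
  set.seed(derive_seed(seed, "omics-subsets"))
  gwas_rows <- sort(sample(train_rows,
                           min(config$n_lasso_gwas, length(train_rows))))
  mwas_rows <- sort(sample(train_rows,
                           min(config$n_lasso_mwas, length(train_rows))))

  pen <- config$penalized
  pc_names <- colnames(pcs)

  ms_log("fitting genome-wide LASSO on %d samples", length(gwas_rows))
  prob_g <- lasso_problem(
    sim$panel$dosages[gwas_rows, , drop = FALSE],
    cohort$em_score[gwas_rows],
    covariates = as.matrix(cohort[gwas_rows, c("caide", "age_at_test",
                                               pc_names)]),
    grid_size = pen$grid_size, lambda_min_ratio = pen$lambda_min_ratio,
    tol = pen$tol)
  fit_g <- tune_by_split(prob_g, train_frac = pen$train_frac,
                         seed = derive_seed(seed, "lasso-gwas"))
  w_lasso <- export_weights(fit_g, sim$panel, "LASSO-PRS")

  ms_log("fitting metabolome-wide LASSO on %d samples", length(mwas_rows))
  prob_m <- lasso_problem(
    sim$metabolites[mwas_rows, , drop = FALSE],
    cohort$em_score[mwas_rows],
    covariates = as.matrix(cohort[mwas_rows, c("caide", "age_at_test",
                                               "draw_interval")]),
    grid_size = pen$grid_size, lambda_min_ratio = pen$lambda_min_ratio,
    tol = pen$tol)
  fit_m <- tune_by_cv(prob_m, k = pen$k,
                      seed = derive_seed(seed, "lasso-mwas"))
  w_mrs <- export_weights(fit_m, NULL, "MRS")

  ms_log("emulating external meta-analysis (%d cohorts)",
         cfg$n_external_cohorts)
  external <- simulate_external_sumstats(cfg, sim$truth)
  meta <- meta_fixed(external)
  hits <- top_hits(meta, config$gwas_threshold)

  ms_log("sampling continuous-shrinkage posterior effects")
  train_panel <- subset_panel(sim$panel, samples = train_rows)
  ld <- build_ld_reference(train_panel)
  cs_cfg <- do.call(cs_config, merge_config(
    config$csprs, list(seed = derive_seed(seed, "csprs"))))
  w_gwama <- sample_posterior_effects(meta, ld, cs_cfg)

  score_dataset <- function(rows) {
    pt <- subset_panel(sim$panel, samples = rows)
    dat <- cohort[rows, , drop = FALSE]
    sg <- score_genetic(w_lasso, pt)
    sgw <- score_genetic(w_gwama, pt)
    sm <- score_metabolic(w_mrs, sim$metabolites[rows, , drop = FALSE])
    dat$lasso_prs <- standardize_or_zero(sg$score, "lasso_prs")
    dat$gwama_prs <- standardize_or_zero(sgw$score, "gwama_prs")
    dat$mrs <- standardize_or_zero(unname(sm), "mrs")
    list(data = dat, coverage = list(lasso_prs = sg$coverage,
                                     gwama_prs = sgw$coverage))
  }
  test_full <- score_dataset(test_rows)
  sens_rows <- test_rows[!cohort$stroke_before_test[test_rows]]
  test_sens <- score_dataset(sens_rows)

  grid <- build_model_grid(background = c("age_at_test", "draw_interval",
                                          pc_names))
  datasets <- list(test_main = test_full$data,
                   test_no_stroke = test_sens$data)
  fits <- list()
  comparisons <- list()
  pt_rows <- list()
  for (ds in names(datasets)) {
    dat <- datasets[[ds]]
    degenerate <- Filter(function(t) sd(dat[[t]]) == 0,
                         c("caide", "mrs", "lasso_prs", "gwama_prs"))
    grid_ds <- grid
    if (length(degenerate)) {
      ms_log("dataset `%s`: skipping models with constant score(s): %s",
             ds, paste(degenerate, collapse = ", "))
      grid_ds <- Filter(function(s) !any(s$risk_terms %in% degenerate),
                        grid)
    }
    dfits <- lapply(grid_ds, fit_model, cohort = dat)
    fits[[ds]] <- dfits
    for (b in names(dfits)) {
      for (e in names(dfits)) {
        bt <- dfits[[b]]$spec$risk_terms
        et <- dfits[[e]]$spec$risk_terms
        if (length(bt) < length(et) && all(bt %in% et)) {
          cmp <- compare_nested(dfits[[b]], dfits[[e]])
          cmp$dataset <- ds
          comparisons[[length(comparisons) + 1L]] <- cmp
        }
      }
    }
    for (m in names(dfits)) {
      ct <- dfits[[m]]$coef
      keep <- ct$term %in% c("caide", "mrs", "lasso_prs", "gwama_prs")
      if (any(keep)) {
        pt_rows[[length(pt_rows) + 1L]] <-
          data.frame(term = ct$term[keep], model = m, dataset = ds,
                     p = ct$p[keep], stringsAsFactors = FALSE)
      }
    }
  }
  comparisons <- do.call(rbind, comparisons)
  ptable <- do.call(rbind, pt_rows)
  fdr_within <- fdr_layers(ptable, "within_layer")
  fdr_per_prs <- fdr_layers(ptable, "per_prs")

  children <- NULL
  if (isTRUE(config$children$enabled)) {
    children <- list()
    child_p <- list()
    for (nm in names(config$children$cohorts)) {
      cc <- config$children$cohorts[[nm]]
      ms_log("scoring child cohort `%s` (n = %d)", nm, cc$n)
      ch <- simulate_children(cfg, sim$truth, n = cc$n,
                              age_mean = cc$age_mean, overlap = cc$overlap,
                              h2_shared = config$children$h2_shared,
                              label = nm)
      sg <- score_genetic(w_lasso, ch$panel)
      sgw <- score_genetic(w_gwama, ch$panel)
      dat <- ch$cohort
      dat$lasso_prs <- standardize_or_zero(sg$score, "lasso_prs")
      dat$gwama_prs <- standardize_or_zero(sgw$score, "gwama_prs")
      bg <- c("age_at_test", "sex", "maternal_education")
      cfits <- list(
        background = fit_model(model_spec("background", character(), bg),
                               dat),
        lasso_prs = fit_model(model_spec("lasso_prs", "lasso_prs", bg), dat),
        gwama_prs = fit_model(model_spec("gwama_prs", "gwama_prs", bg), dat))
      cmp <- rbind(compare_nested(cfits$background, cfits$lasso_prs),
                   compare_nested(cfits$background, cfits$gwama_prs))
      cmp$dataset <- nm
      for (term in c("lasso_prs", "gwama_prs")) {
        ct <- cfits[[term]]$coef
        child_p[[length(child_p) + 1L]] <-
          data.frame(term = term, model = term, dataset = nm,
                     p = ct$p[ct$term == term], stringsAsFactors = FALSE)
      }
      children[[nm]] <- list(fits = cfits, comparisons = cmp,
                             coverage = list(lasso_prs = sg$coverage,
                                             gwama_prs = sgw$coverage))
    }
    child_ptable <- do.call(rbind, child_p)
    children$fdr <- fdr_layers(child_ptable, "per_prs")
  }

  results <- list(config = config, sim_config = cfg,
                  truth = sim$truth,
                  cohort = cohort,
                  test_rows = test_rows, train_rows = train_rows,
                  lasso_fit = fit_g, mwas_fit = fit_m,
                  weights = list(lasso_prs = w_lasso, mrs = w_mrs,
                                 gwama_prs = w_gwama),
                  meta = meta, top_hits = hits,
                  datasets = datasets,
                  coverage = test_full$coverage,
                  fits = fits, comparisons = comparisons,
                  fdr = list(within_layer = fdr_within,
                             per_prs = fdr_per_prs),
                  children = children)

  if (!is.null(out_dir)) write_study_outputs(results, out_dir)
  invisible(results)
}

# internal: flatten model fits to a table
fits_to_df <- function(fits) {
  rows <- list()
  for (ds in names(fits)) {
    for (m in names(fits[[ds]])) {
      f <- fits[[ds]][[m]]
      rows[[length(rows) + 1L]] <-
        data.frame(dataset = ds, model = m, n = f$n, r2 = f$r2,
                   adj_r2 = f$adj_r2, aic = f$aic, bic = f$bic,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# internal: write all stage outputs and a reproducibility manifest
write_study_outputs <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  write_cohort(results$datasets$test_main, fp("test_cohort.tsv"))
  write_weights(results$weights$lasso_prs, fp("weights_lasso_prs.tsv"))
  write_weights(results$weights$mrs, fp("weights_mrs.tsv"))
  write_weights(results$weights$gwama_prs, fp("weights_gwama_prs.tsv"))
  data.table::fwrite(results$meta, fp("meta_analysis.tsv"), sep = "\t")
  data.table::fwrite(results$top_hits, fp("top_hits.tsv"), sep = "\t")
  data.table::fwrite(fits_to_df(results$fits), fp("model_fits.tsv"),
                     sep = "\t")
  data.table::fwrite(results$comparisons, fp("comparisons.tsv"), sep = "\t")
  data.table::fwrite(results$fdr$within_layer, fp("fdr_within_layer.tsv"),
                     sep = "\t")
  data.table::fwrite(results$fdr$per_prs, fp("fdr_per_prs.tsv"), sep = "\t")
  if (!is.null(results$children)) {
    data.table::fwrite(results$children$fdr, fp("fdr_children.tsv"),
                       sep = "\t")
  }
  seed <- results$config$seed
  manifest <- list(
    package_version = as.character(packageVersion("memoscore")),
    seed = seed,
    stage_seeds = list(
      test_split = derive_seed(seed, "test-split"),
      omics_subsets = derive_seed(seed, "omics-subsets"),
      lasso_gwas = derive_seed(seed, "lasso-gwas"),
      lasso_mwas = derive_seed(seed, "lasso-mwas"),
      csprs = derive_seed(seed, "csprs")),
    model_specs = names(build_model_grid()),
    fdr_schemes = c("within_layer", "per_prs"),
    n_selected = list(
      lasso_prs = nrow(results$weights$lasso_prs),
      mrs = nrow(results$weights$mrs)),
    coverage = results$coverage,
    config = results$config)
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write the small deterministic fixtures used by the test suite
#'
#' Produces, under `out_dir`: a 50-sample x 60-variant genotype panel (TSV
#' and PLINK dialects), its cohort and metabolite tables, a univariate
#' association table, and a hand-built weight/panel pair exercising every
#' allele-harmonization branch (one flip, one strand-ambiguous drop, one
#' missing variant).
#'
#' @param seed Integer seed.
#' @param out_dir Writable output directory.
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(seed = 1L, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(n_samples = 50L, n_variants = 60L, n_blocks = 6L,
                    n_metabolites = 10L, n_causal_metabolites = 3L,
                    n_causal_variants = 4L, n_metab_blocks = 2L,
                    n_external_cohorts = 2L, external_n_per_cohort = 60L,
                    seed = seed)
  sim <- simulate_cohort(cfg)
  fp <- function(...) file.path(out_dir, ...)
  write_genotypes(sim$panel, fp("panel.tsv"), "tsv")
  write_genotypes(sim$panel, fp("panel"), "plink")
  write_cohort(sim$cohort, fp("cohort.tsv"))
  met <- data.frame(sample_id = rownames(sim$metabolites),
                    sim$metabolites, check.names = FALSE)
  data.table::fwrite(met, fp("metabolites.tsv"), sep = "\t")
  ss <- run_gwas(sim$panel, sim$cohort)
  ss$monomorphic <- NULL
  write_sumstats(ss, fp("sumstats.tsv"))
  write_caide_table(caide_point_table(), fp("caide_points.yaml"))
  # harmonization toy pair: match, flip, ambiguous, missing
  toy_panel <- genotype_panel(
    sample_ids = c("t1", "t2"), variant_ids = c("v1", "v2", "v3"),
    chrom = c(1, 1, 1), pos = c(100, 200, 300),
    effect_allele = c("C", "C", "A"), other_allele = c("A", "T", "T"),
    dosages = matrix(c(2, 1, 0, 2, 1, 1), 2, 3))
  write_genotypes(toy_panel, fp("toy_panel.tsv"), "tsv")
  toy_w <- weight_table(c("v1", "v2", "v3", "v9"), c("A", "C", "A", "G"),
                        c(0.5, -0.25, 1, 2),
                        rep("LASSO-PRS", 4))
  write_weights(toy_w, fp("toy_weights.tsv"))
  invisible(list.files(out_dir, full.names = TRUE))
}
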