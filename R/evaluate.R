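#' Specify one linear model of the evaluation grid
#'
#' @param label Model label.
#' @param risk_terms Character subset of `{"caide", "mrs", "lasso_prs",
#'   "gwama_prs"}`; a model never contains both PRSs.
#' @param background Background covariate names (must include
#'   `age_at_test`).
#' @param outcome Outcome column (default `em_score`).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(label, risk_terms = character(),
                       background = "age_at_test", outcome = "em_score") {
  risk_terms <- as.character(risk_terms)
  allowed <- c("caide", "mrs", "lasso_prs", "gwama_prs")
  if (!all(risk_terms %in% allowed)) {
    stop("model_spec: unknown risk term(s): ",
         paste(setdiff(risk_terms, allowed), collapse = ", "), call. = FALSE)
  }
  if (all(c("lasso_prs", "gwama_prs") %in% risk_terms)) {
    stop("model_spec: a model never combines both PRSs", call. = FALSE)
  }
  structure(list(label = label, outcome = outcome,
                 background = as.character(background),
                 risk_terms = risk_terms),
            class = "model_spec")
}

#' Build the evaluation grid of nested linear models
#'
#' The full grid of the study: background covariates only; background plus
#' each single risk score (CAIDE, MRS, LASSO-PRS, GWAMA-PRS); CAIDE plus
#' each PRS and/or the MRS; and MRS plus each PRS - 12 specifications, none
#' combining the two PRSs. The background covariate set (age at assessment,
#' blood-draw interval, ancestry PCs) is fixed across all models of a
#' dataset so that R-squared differences are attributable to the scores
#' alone.
#'
#' @param background Character covariate names applied to every model.
#' @return A named list of 12 [model_spec()]s, label-sorted.
#' @export
build_model_grid <- function(background = c("age_at_test", "draw_interval",
                                            "PC1", "PC2", "PC3")) {
  combos <- list(
    background = character(),
    caide = "caide",
    mrs = "mrs",
    lasso_prs = "lasso_prs",
    gwama_prs = "gwama_prs",
    `caide+mrs` = c("caide", "mrs"),
    `caide+lasso_prs` = c("caide", "lasso_prs"),
    `caide+gwama_prs` = c("caide", "gwama_prs"),
    `caide+lasso_prs+mrs` = c("caide", "lasso_prs", "mrs"),
    `caide+gwama_prs+mrs` = c("caide", "gwama_prs", "mrs"),
    `mrs+lasso_prs` = c("mrs", "lasso_prs"),
    `mrs+gwama_prs` = c("mrs", "gwama_prs"))
  combos <- combos[order(names(combos))]
  specs <- lapply(names(combos), function(nm) {
    model_spec(nm, combos[[nm]], background)
  })
  setNames(specs, names(combos))
}

#' Fit one model of the grid by least squares
#'
#' Complete-case ordinary least squares with \eqn{R^2 = 1 - RSS/TSS},
#' adjusted \eqn{R^2 = 1 - (1 - R^2)(n-1)/(n-k-1)} (k non-intercept terms),
#' and AIC/BIC under the full Gaussian log-likelihood convention
#' (`stats::AIC`/`BIC`): \eqn{AIC = n\ln(2\pi RSS/n) + n + 2q} with
#' \eqn{q = k + 2} parameters (intercept and variance included).
#'
#' @param spec A [model_spec()].
#' @param cohort A `data.frame` containing the outcome, background and risk
#'   columns.
#' @return An object of class `model_fit`: `spec`, `n`, `r2`, `adj_r2`,
#'   `aic`, `bic`, `coef` (term, estimate, se, t, p), `sample_ids`.
#' @export
fit_model <- function(spec, cohort) {
  stopifnot(inherits(spec, "model_spec"))
  terms <- c(spec$background, spec$risk_terms)
  need <- c(spec$outcome, terms)
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("fit_model: column(s) missing from cohort: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dat <- cohort[, need, drop = FALSE]
  cc <- complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  form <- as.formula(paste(spec$outcome, "~",
                           if (length(terms)) paste(terms, collapse = " + ")
                           else "1"))
  fit <- lm(form, data = dat)
  if (anyNA(coef(fit))) {
    stop("fit_model: rank-deficient design; collinear term(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  sm <- summary(fit)
  ct <- as.data.frame(sm$coefficients)
  names(ct) <- c("estimate", "se", "t", "p")
  ct <- cbind(term = rownames(ct), ct)
  rownames(ct) <- NULL
  structure(list(spec = spec, n = nrow(dat),
                 r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                 aic = AIC(fit), bic = BIC(fit), coef = ct,
                 sample_ids = if ("sample_id" %in% names(cohort)) {
                   cohort$sample_id[cc]
                 } else which(cc)),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s: n = %d, R2 = %.4f (adj %.4f), AIC = %.1f\n",
              x$spec$label, x$n, x$r2, x$adj_r2, x$aic))
  invisible(x)
}

#' Compare a nested model pair
#'
#' The incremental explained variance is the extended model's R-squared
#' minus the baseline's, reported in percentage points (clamped at zero
#' against floating-point jitter; for genuinely nested pairs on identical
#' samples it is nonnegative by construction). AIC/BIC deltas are extended
#' minus baseline and may take either sign; the added terms carry their
#' extended-model p-values.
#'
#' @param baseline,extended `model_fit`s on identical samples with
#'   `baseline` risk terms a strict subset of `extended`'s.
#' @return A one-row `data.frame`: `baseline_label`, `extended_label`,
#'   `delta_r2_pp`, `delta_aic`, `delta_bic`, `added_terms`, `added_p_min`.
#' @export
compare_nested <- function(baseline, extended) {
  stopifnot(inherits(baseline, "model_fit"), inherits(extended, "model_fit"))
  bt <- baseline$spec$risk_terms
  et <- extended$spec$risk_terms
  if (!all(bt %in% et) ||
      !identical(baseline$spec$background, extended$spec$background)) {
    stop("compare_nested: models are not nested", call. = FALSE)
  }
  if (!identical(baseline$sample_ids, extended$sample_ids)) {
    stop("compare_nested: models were fitted on different samples",
         call. = FALSE)
  }
  added <- setdiff(et, bt)
  pv <- extended$coef$p[match(added, extended$coef$term)]
  data.frame(baseline_label = baseline$spec$label,
             extended_label = extended$spec$label,
             delta_r2_pp = max(0, (extended$r2 - baseline$r2)) * 100,
             delta_aic = extended$aic - baseline$aic,
             delta_bic = extended$bic - baseline$bic,
             added_terms = paste(added, collapse = "+"),
             added_p_min = if (length(pv)) min(pv) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Layered Benjamini-Hochberg false-discovery-rate control
#'
#' Two correction schemes over risk-score p-values pooled across models and
#' test datasets. `within_layer` forms one family per data layer - CAIDE
#' terms (epidemiology), MRS terms (metabolomics), and both PRS terms
#' together (genomics). `per_prs` forms one family per term, which for the
#' PRSs corresponds to correcting each PRS separately. Adjustment is the BH
#' step-up `adj_i = min_{j >= i} (m p_(j) / j)` capped at 1 (via
#' `stats::p.adjust`).
#'
#' @param ptable A `data.frame` with columns `term`, `model`, `dataset`,
#'   `p` (each p in `(0, 1]`).
#' @param scheme `"within_layer"` or `"per_prs"`.
#' @return `ptable` with `family` and `p_adj` columns appended.
#' @export
fdr_layers <- function(ptable, scheme = c("within_layer", "per_prs")) {
  scheme <- match.arg(scheme)
  need <- c("term", "model", "dataset", "p")
  miss <- setdiff(need, names(ptable))
  if (length(miss)) {
    stop("fdr_layers: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(ptable$p)) || any(ptable$p <= 0 | ptable$p > 1)) {
    stop("fdr_layers: p-values must lie in (0, 1]", call. = FALSE)
  }
  layer_map <- c(caide = "caide", mrs = "mrs",
                 lasso_prs = "genomics", gwama_prs = "genomics")
  fam <- if (scheme == "within_layer") {
    unname(layer_map[ptable$term])
  } else {
    ptable$term
  }
  fam[is.na(fam)] <- ptable$term[is.na(fam)]
  out <- ptable
  out$family <- fam
  out$p_adj <- NA_real_
  for (f in unique(fam)) {
    idx <- which(fam == f)
    out$p_adj[idx] <- p.adjust(out$p[idx], method = "BH")
  }
  out
}

#' Exclude flagged samples for a sensitivity analysis
#'
#' Removes rows whose flag column is `TRUE` (e.g. stroke before the memory
#' assessment); the evaluation grid is then re-run on the subset. The
#' operation is idempotent.
#'
#' @param cohort A cohort `data.frame`.
#' @param flag Name of a logical column.
#' @return The cohort without the flagged rows.
#' @export
sensitivity_exclude <- function(cohort, flag = "stroke_before_test") {
  if (!flag %in% names(cohort)) {
    stop("sensitivity_exclude: no column `", flag, "`", call. = FALSE)
  }
  fl <- cohort[[flag]]
  if (!is.logical(fl)) {
    stop("sensitivity_exclude: `", flag, "` must be logical", call. = FALSE)
  }
  out <- cohort[!fl, , drop = FALSE]
  if (!nrow(out)) {
    stop("sensitivity_exclude: exclusion empties the cohort", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}
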