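#' Per-variant univariate association scan
#'
#' For every variant, ordinary least squares of the episodic-memory score on
#' dosage plus covariates plus intercept. Computed by the
#' Frisch-Waugh-Lovell decomposition: outcome and dosages are residualized
#' against the covariate design once, then each variant is a simple
#' regression on its residualized dosage, which reproduces the joint-model
#' coefficient, standard error and t-test exactly. Missing dosages are
#' mean-imputed per variant; monomorphic variants are emitted with missing
#' estimates and flagged.
#'
#' @param panel A [genotype_panel()].
#' @param cohort A `data.frame` with `sample_id`, `em_score` and any
#'   covariate columns; rows are matched to the panel by sample id.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @return A summary-statistics `data.frame`: `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `p`, `n`, `monomorphic`.
#' @export
run_gwas <- function(panel, cohort, covariates = character()) {
  stopifnot(inherits(panel, "genotype_panel"))
  ids <- intersect(panel$sample_ids, cohort$sample_id)
  if (length(ids) < 10L) {
    stop("run_gwas: need at least 10 samples shared between panel and cohort",
         call. = FALSE)
  }
  rows <- match(ids, panel$sample_ids)
  crows <- match(ids, cohort$sample_id)
  miss <- setdiff(covariates, names(cohort))
  if (length(miss)) {
    stop("run_gwas: covariate column(s) not in cohort: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- length(ids)
  Z <- cbind(`(Intercept)` = rep(1, n))
  for (cv in covariates) {
    v <- cohort[[cv]][crows]
    if (is.character(v) || is.factor(v)) v <- as.numeric(factor(v)) - 1
    Z <- cbind(Z, as.numeric(v))
    colnames(Z)[ncol(Z)] <- cv
  }
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    dropped <- colnames(Z)[qz$pivot[(qz$rank + 1L):ncol(Z)]]
    stop("run_gwas: collinear covariates: ", paste(dropped, collapse = ", "),
         call. = FALSE)
  }
  y <- cohort$em_score[crows]
  G <- impute_col_means(panel$dosages[rows, , drop = FALSE])
  mono <- col_sd_pop(G) == 0
  ry <- qr.resid(qz, y)
  # residualize dosages by explicit projection (covariate blocks are small
  # and well conditioned, and this stays in level-3 BLAS)
  RG <- G - Z %*% solve(crossprod(Z), crossprod(Z, G))
  sgg <- colSums(RG * RG)
  sgy <- drop(crossprod(RG, ry))
  syy <- sum(ry * ry)
  df <- n - ncol(Z) - 1L
  beta <- ifelse(mono, NA_real_, sgy / sgg)
  rss <- pmax(syy - beta^2 * sgg, 0)
  se <- sqrt(rss / df / sgg)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df)
  p <- pmax(p, .Machine$double.xmin)
  out <- data.frame(variant_id = panel$variant_ids,
                    effect_allele = panel$effect_allele,
                    other_allele = panel$other_allele,
                    beta = beta, se = ifelse(mono, NA_real_, se),
                    p = ifelse(mono, NA_real_, p), n = n,
                    monomorphic = mono, stringsAsFactors = FALSE)
  if (any(mono)) {
    ms_log("run_gwas: %d monomorphic variant(s) flagged", sum(mono))
  }
  out
}
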