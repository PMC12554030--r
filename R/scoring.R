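#' Apply a variant weight table to a genotype panel
#'
#' Per-sample weighted sum of effect-allele dosages,
#' \eqn{score_i = \sum_j w_j g_{ij}}, with flipped-allele rows applied to
#' `2 - g` and missing dosages contributing the variant mean. Weights are
#' harmonized first (see [harmonize_alleles()]) unless the table already
#' carries a `flip` column from a previous harmonization.
#'
#' @param weights A [weight_table()] of variant weights.
#' @param panel A [genotype_panel()].
#' @return A list with `score` (named numeric, one per sample) and
#'   `coverage` (the harmonization report plus `fraction`, the share of
#'   weight variants matched).
#' @export
score_genetic <- function(weights, panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  n_weights <- nrow(weights)
  if (n_weights == 0L) {
    warning("score_genetic: empty weight table; returning zero scores")
    return(list(score = setNames(numeric(length(panel$sample_ids)),
                                 panel$sample_ids),
                coverage = list(matched = 0L, flipped = 0L,
                                ambiguous_dropped = 0L, missing = 0L,
                                fraction = 0)))
  }
  if (!"flip" %in% names(weights)) {
    h <- harmonize_alleles(weights, panel)
    weights <- h$weights
    report <- h$report
  } else {
    report <- list(matched = nrow(weights), flipped = sum(weights$flip),
                   ambiguous_dropped = 0L, missing = 0L)
  }
  idx <- match(weights$feature_id, panel$variant_ids)
  G <- impute_col_means(panel$dosages[, idx, drop = FALSE])
  if (any(weights$flip)) {
    G[, weights$flip] <- 2 - G[, weights$flip, drop = FALSE]
  }
  score <- as.vector(G %*% weights$weight)
  report$fraction <- report$matched / n_weights
  list(score = setNames(score, panel$sample_ids), coverage = report)
}

#' Apply a metabolite weight table to a metabolite matrix
#'
#' Unlike variant scoring, every weighted metabolite must be present: a
#' missing column raises an error naming it (measurements are assumed to be
#' on the scale used at fit time).
#'
#' @param weights A [weight_table()] of metabolite weights.
#' @param metabolites Numeric matrix, samples x metabolites, with column
#'   names.
#' @return Named numeric vector of per-sample scores.
#' @export
score_metabolic <- function(weights, metabolites) {
  stopifnot(is.matrix(metabolites))
  if (nrow(weights) == 0L) {
    return(setNames(numeric(nrow(metabolites)), rownames(metabolites)))
  }
  miss <- setdiff(weights$feature_id, colnames(metabolites))
  if (length(miss)) {
    stop("score_metabolic: metabolite column(s) missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  M <- metabolites[, weights$feature_id, drop = FALSE]
  setNames(as.vector(M %*% weights$weight), rownames(metabolites))
}

#' Standardize a score vector within the evaluation sample
#'
#' Centers to mean 0 and scales to standard deviation 1 (n-1 denominator),
#' so downstream regression coefficients are per-SD effects within that
#' sample.
#'
#' @param scores Numeric vector with positive variance.
#' @return The standardized vector.
#' @export
standardize_scores <- function(scores) {
  stopifnot(is.numeric(scores))
  s <- sd(scores)
  if (!is.finite(s) || s == 0) {
    stop("standardize_scores: score variance must be positive",
         call. = FALSE)
  }
  (scores - mean(scores)) / s
}
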