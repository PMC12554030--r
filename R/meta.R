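#' Inverse-variance fixed-effect meta-analysis of summary statistics
#'
#' Per variant, cohort estimates are combined with weights \eqn{w_i =
#' 1/se_i^2}: \eqn{\beta_{meta} = \sum w_i \beta_i / \sum w_i},
#' \eqn{se_{meta} = (\sum w_i)^{-1/2}}, \eqn{z = \beta_{meta}/se_{meta}},
#' with a standard-normal two-sided p-value. Cochran's Q and the I-squared
#' heterogeneity proportion are reported but not acted on. Alleles are
#' reconciled to the first cohort in which a variant appears (swapped pairs
#' flip the sign of beta; irreconcilable pairs are dropped with a log
#' entry). Variants present in only some cohorts are meta-analyzed over the
#' cohorts that carry them; rows with missing estimates (monomorphic) are
#' skipped.
#'
#' @param tables A list of summary-statistics `data.frame`s (one per
#'   cohort), each with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `p`, `n`.
#' @return A `data.frame` with `variant_id`, `effect_allele`,
#'   `other_allele`, `beta_meta`, `se_meta`, `z`, `p`, `n_total`,
#'   `n_cohorts`, `q`, `i2`.
#' @export
meta_fixed <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  stopifnot(length(tables) >= 1L)
  ref <- NULL  # reference alleles: first occurrence wins
  rows <- vector("list", length(tables))
  for (k in seq_along(tables)) {
    tab <- as.data.frame(tables[[k]])
    validate_sumstats(tab)
    keep <- !is.na(tab$beta) & !is.na(tab$se)
    tab <- tab[keep, , drop = FALSE]
    if (is.null(ref)) {
      ref <- tab[, c("variant_id", "effect_allele", "other_allele")]
    } else {
      new <- !(tab$variant_id %in% ref$variant_id)
      if (any(new)) {
        ref <- rbind(ref,
                     tab[new, c("variant_id", "effect_allele",
                                "other_allele")])
      }
    }
    i <- match(tab$variant_id, ref$variant_id)
    same <- tab$effect_allele == ref$effect_allele[i] &
      tab$other_allele == ref$other_allele[i]
    swap <- tab$effect_allele == ref$other_allele[i] &
      tab$other_allele == ref$effect_allele[i]
    bad <- !(same | swap)
    if (any(bad)) {
      ms_log("meta_fixed: dropping %d variant row(s) with irreconcilable %s",
             sum(bad), "allele pairs")
      tab <- tab[!bad, , drop = FALSE]
      same <- same[!bad]; swap <- swap[!bad]
    }
    tab$beta[swap] <- -tab$beta[swap]
    rows[[k]] <- data.table::data.table(variant_id = tab$variant_id,
                                        beta = tab$beta, se = tab$se,
                                        n = tab$n)
  }
  all <- data.table::rbindlist(rows)
  w <- b <- se <- n <- variant_id <- NULL  # appease R CMD check
  all[, w := 1 / se^2]
  agg <- all[, {
    sw <- sum(w)
    bm <- sum(w * beta) / sw
    q <- sum(w * (beta - bm)^2)
    k <- .N
    list(beta_meta = bm, se_meta = 1 / sqrt(sw),
         q = q, i2 = if (k > 1L && q > 0) max(0, (q - (k - 1)) / q) else 0,
         n_total = sum(n), n_cohorts = k)
  }, by = variant_id]
  agg <- agg[match(ref$variant_id, agg$variant_id), ]
  agg <- agg[!is.na(agg$variant_id), ]
  out <- as.data.frame(agg)
  i <- match(out$variant_id, ref$variant_id)
  out$effect_allele <- ref$effect_allele[i]
  out$other_allele <- ref$other_allele[i]
  out$z <- out$beta_meta / out$se_meta
  out$p <- pmax(2 * pnorm(-abs(out$z)), .Machine$double.xmin)
  out[, c("variant_id", "effect_allele", "other_allele", "beta_meta",
          "se_meta", "z", "p", "n_total", "n_cohorts", "q", "i2")]
}

#' Filter meta-analysis results to genome-wide-significant hits
#'
#' Strict comparison (`p < threshold`), sorted by ascending p-value.
#'
#' @param meta Output of [meta_fixed()].
#' @param threshold P-value threshold in `(0, 1)`; the conventional
#'   genome-wide level is `5e-8`.
#' @return The significant subset of `meta`.
#' @export
top_hits <- function(meta, threshold = 5e-8) {
  stopifnot(threshold > 0, threshold <= 1)
  keep <- if (threshold >= 1) !is.na(meta$p) else
    !is.na(meta$p) & meta$p < threshold
  out <- meta[keep, , drop = FALSE]
  out[order(out$p), , drop = FALSE]
}
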