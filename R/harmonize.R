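PALINDROMIC <- c("A/T", "T/A", "C/G", "G/C")

#' Harmonize a variant weight table against a genotype panel
#'
#' Matches weight rows to panel variants by id and reconciles effect alleles:
#' when the weight's effect allele equals the panel's other allele, the row is
#' marked for flipping (its weight is applied to `2 - dosage`).
#' Strand-ambiguous variants (panel allele pair A/T or C/G) are dropped, as
#' are weight rows absent from the panel or with an allele matching neither
#' panel allele.
#'
#' The operation is idempotent: re-harmonizing an aligned table yields the
#' same table and report counts.
#'
#' @param weights A [weight_table()] with variant rows.
#' @param panel A [genotype_panel()].
#' @return A list with `weights` (the aligned table, with a logical `flip`
#'   column) and `report` (counts: `matched`, `flipped`, `ambiguous_dropped`,
#'   `missing`).
#' @export
harmonize_alleles <- function(weights, panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  w <- as.data.frame(weights)
  idx <- match(w$feature_id, panel$variant_ids)
  present <- !is.na(idx)
  pair <- paste0(panel$effect_allele[idx[present]], "/",
                 panel$other_allele[idx[present]])
  ambiguous <- pair %in% PALINDROMIC
  ea <- w$effect_allele[present]
  same <- ea == panel$effect_allele[idx[present]]
  flipped <- ea == panel$other_allele[idx[present]]
  keep_present <- !ambiguous & (same | flipped)
  keep <- present
  keep[present] <- keep_present
  n_missing <- sum(!present) + sum(!ambiguous & !same & !flipped)
  n_ambiguous <- sum(ambiguous)
  if (!any(keep)) {
    stop("harmonize_alleles: no weight variants matched the panel",
         call. = FALSE)
  }
  out <- w[keep, , drop = FALSE]
  out$flip <- flipped[keep_present]
  rownames(out) <- NULL
  class(out) <- c("weight_table", "data.frame")
  report <- list(matched = sum(keep),
                 flipped = sum(out$flip),
                 ambiguous_dropped = n_ambiguous,
                 missing = n_missing)
  list(weights = out, report = report)
}
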