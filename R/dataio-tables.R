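#' Construct a risk-score weight table
#'
#' One row per scored feature: a variant (with its effect allele) or a
#' metabolite (empty effect allele). Weights are on the per-unit scale of the
#' raw feature (per allele for variants).
#'
#' @param feature_id Character feature ids (unique).
#' @param effect_allele Character; `""` for metabolites.
#' @param weight Finite numeric weights.
#' @param source_label One of `"LASSO-PRS"`, `"GWAMA-PRS"`, `"MRS"`.
#' @return A `data.frame` with class `weight_table`.
#' @export
weight_table <- function(feature_id, effect_allele, weight, source_label) {
  feature_id <- as.character(feature_id)
  if (anyDuplicated(feature_id)) {
    stop("weight_table: duplicated feature id: ",
         feature_id[duplicated(feature_id)][1], call. = FALSE)
  }
  if (length(weight) && any(!is.finite(weight))) {
    stop("weight_table: weights must be finite", call. = FALSE)
  }
  source_label <- as.character(source_label)
  ok <- source_label %in% c("LASSO-PRS", "GWAMA-PRS", "MRS")
  if (length(source_label) && !all(ok)) {
    stop("weight_table: unknown source_label: ", source_label[!ok][1],
         call. = FALSE)
  }
  out <- data.frame(feature_id = feature_id,
                    effect_allele = as.character(effect_allele),
                    weight = as.numeric(weight),
                    source_label = source_label,
                    stringsAsFactors = FALSE)
  class(out) <- c("weight_table", "data.frame")
  out
}

#' Read / write a weight table (TSV)
#'
#' Schema: `feature_id`, `effect_allele`, `weight`, `source_label`.
#'
#' @param path File path.
#' @return [read_weights()] returns a `weight_table`.
#' @export
read_weights <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE,
                          colClasses = list(character = "effect_allele"))
  need <- c("feature_id", "effect_allele", "weight", "source_label")
  if (!all(need %in% names(dt))) {
    stop("read_weights: missing columns: ",
         paste(setdiff(need, names(dt)), collapse = ", "), call. = FALSE)
  }
  dt$effect_allele[is.na(dt$effect_allele)] <- ""
  weight_table(dt$feature_id, dt$effect_allele, dt$weight, dt$source_label)
}

#' @param x A `weight_table`.
#' @rdname read_weights
#' @export
write_weights <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write GWAS summary statistics (TSV)
#'
#' Schema: `variant_id`, `effect_allele`, `other_allele`, `beta`, `se`, `p`,
#' `n`. Validates `se > 0` and `p` in `(0, 1]` on read (rows flagged
#' monomorphic may carry `NA`).
#'
#' @param path File path.
#' @return A `data.frame` of summary statistics.
#' @export
read_sumstats <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  need <- c("variant_id", "effect_allele", "other_allele", "beta", "se",
            "p", "n")
  if (!all(need %in% names(dt))) {
    stop("read_sumstats: missing columns: ",
         paste(setdiff(need, names(dt)), collapse = ", "), call. = FALSE)
  }
  validate_sumstats(dt)
  dt
}

#' @param x Summary-statistics `data.frame`.
#' @rdname read_sumstats
#' @export
write_sumstats <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     na = "NA")
  invisible(path)
}

validate_sumstats <- function(x) {
  if (anyDuplicated(x$variant_id)) {
    stop("summary statistics: duplicated variant id: ",
         x$variant_id[duplicated(x$variant_id)][1], call. = FALSE)
  }
  ok <- !is.na(x$se)
  if (any(x$se[ok] <= 0)) {
    stop("summary statistics: `se` must be > 0", call. = FALSE)
  }
  okp <- !is.na(x$p)
  if (any(x$p[okp] <= 0 | x$p[okp] > 1)) {
    stop("summary statistics: `p` must lie in (0, 1]", call. = FALSE)
  }
  invisible(x)
}

#' Read / write a phenotype and covariate table (TSV)
#'
#' A cohort table holds one row per sample: the episodic-memory score,
#' CAIDE components, the blood-draw-to-test interval, the stroke flag, and
#' any appended score or ancestry-PC columns.
#'
#' @param path File path.
#' @return A `data.frame`, one row per sample.
#' @export
read_cohort <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  if (!"sample_id" %in% names(dt)) {
    stop("read_cohort: missing `sample_id` column", call. = FALSE)
  }
  if (anyDuplicated(dt$sample_id)) {
    stop("read_cohort: duplicated sample id: ",
         dt$sample_id[duplicated(dt$sample_id)][1], call. = FALSE)
  }
  dt
}

#' @param x Cohort `data.frame`.
#' @rdname read_cohort
#' @export
write_cohort <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     na = "NA")
  invisible(path)
}
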