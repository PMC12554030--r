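#' Ancestry principal components from a genotype panel
#'
#' Columns of the dosage matrix are mean-imputed, centered and scaled;
#' zero-variance (or all-missing) variants are dropped with a log message.
#' The top `k` left singular vectors of the standardized matrix are returned,
#' each rescaled to unit variance, with the sign fixed so that the
#' largest-magnitude variant loading of each component is positive.
#'
#' @param panel A [genotype_panel()].
#' @param k Number of components; must be below `min(n_samples, n_variants)`.
#' @return A numeric matrix (samples x k) with columns `PC1..PCk`, zero mean
#'   and unit variance.
#' @export
compute_ancestry_pcs <- function(panel, k = 3L) {
  stopifnot(inherits(panel, "genotype_panel"))
  X <- impute_col_means(panel$dosages)
  sds <- apply(X, 2, sd)
  drop <- which(sds == 0 | !is.finite(sds))
  if (length(drop)) {
    ms_log("compute_ancestry_pcs: dropping %d zero-variance variant(s): %s",
           length(drop),
           paste(head(panel$variant_ids[drop], 5), collapse = ", "))
    X <- X[, -drop, drop = FALSE]
    sds <- sds[-drop]
  }
  n <- nrow(X)
  if (k >= min(n, ncol(X))) {
    stop("compute_ancestry_pcs: k must be < min(n_samples, n_variants)",
         call. = FALSE)
  }
  S <- scale(X)
  sv <- svd(S, nu = k, nv = k)
  scores <- sv$u[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- sv$v[, j]
    if (load[which.max(abs(load))] < 0) {
      scores[, j] <- -scores[, j]
    }
    scores[, j] <- scores[, j] / sd(scores[, j])
  }
  dimnames(scores) <- list(panel$sample_ids, paste0("PC", seq_len(k)))
  scores
}
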