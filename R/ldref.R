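#' Build an LD reference from a genotype panel
#'
#' Per disjoint block, the Pearson correlation matrix of the standardized
#' (mean-imputed) dosages, eigenvalue-floored at `1e-6` to guarantee positive
#' semidefiniteness even for duplicated or perfectly collinear variants.
#' Per-variant dosage standard deviations and allele frequencies are stored
#' for back-transforming standardized posterior effects to the per-allele
#' scale.
#'
#' @param panel A [genotype_panel()].
#' @param blocks Either an integer/factor vector assigning each panel variant
#'   to a block, or a list of variant-id vectors. Defaults to the panel's
#'   `block` attribute.
#' @return An object of class `ld_reference`: a list of blocks (each with
#'   `variant_ids` and correlation matrix `R`), per-variant `sd` and `freq`,
#'   and `source_n`.
#' @export
build_ld_reference <- function(panel, blocks = attr(panel, "block")) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(blocks)) {
    stop("build_ld_reference: no block assignment given and the panel ",
         "carries none", call. = FALSE)
  }
  if (!is.list(blocks)) {
    blocks <- split(panel$variant_ids, blocks)
  }
  missing <- setdiff(unlist(blocks), panel$variant_ids)
  if (length(missing)) {
    stop("build_ld_reference: block variant(s) absent from panel: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  X <- impute_col_means(panel$dosages)
  sds <- apply(X, 2, sd)
  out_blocks <- list()
  keep_ids <- character(0)
  for (b in seq_along(blocks)) {
    ids <- blocks[[b]]
    zv <- ids[sds[ids] == 0]
    if (length(zv)) {
      ms_log("build_ld_reference: dropping %d zero-variance variant(s) %s",
             length(zv), paste(head(zv, 5), collapse = ", "))
      ids <- setdiff(ids, zv)
    }
    if (!length(ids)) next
    R <- cor(X[, ids, drop = FALSE])
    ev <- eigen(R, symmetric = TRUE)
    if (min(ev$values) < 1e-6) {
      R <- ev$vectors %*% (pmax(ev$values, 1e-6) * t(ev$vectors))
      R <- (R + t(R)) / 2
      dimnames(R) <- list(ids, ids)
    }
    out_blocks[[length(out_blocks) + 1L]] <- list(variant_ids = ids, R = R)
    keep_ids <- c(keep_ids, ids)
  }
  structure(list(blocks = out_blocks,
                 sd = sds[keep_ids],
                 freq = colMeans(X[, keep_ids, drop = FALSE]) / 2,
                 effect_allele = setNames(
                   panel$effect_allele[match(keep_ids, panel$variant_ids)],
                   keep_ids),
                 source_n = length(panel$sample_ids)),
            class = "ld_reference")
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf("<ld_reference> %d block(s), %d variants, from %d samples\n",
              length(x$blocks), length(x$sd), x$source_n))
  invisible(x)
}

#' Write / read an LD reference (per-block matrix files plus JSON manifest)
#'
#' @param ld An `ld_reference`.
#' @param dir Output directory (created if needed).
#' @return [read_ld_reference()] returns an `ld_reference`.
#' @export
write_ld_reference <- function(ld, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(ld$blocks))
  for (b in seq_along(ld$blocks)) {
    files[b] <- sprintf("block_%04d.tsv", b)
    m <- ld$blocks[[b]]$R
    dt <- data.table::data.table(variant_id = ld$blocks[[b]]$variant_ids)
    dt <- cbind(dt, as.data.frame(m))
    data.table::fwrite(dt, file.path(dir, files[b]), sep = "\t")
  }
  manifest <- list(blocks = files, source_n = ld$source_n,
                   variant_id = names(ld$sd), sd = unname(ld$sd),
                   freq = unname(ld$freq),
                   effect_allele = unname(ld$effect_allele))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_ld_reference
#' @export
read_ld_reference <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  blocks <- lapply(manifest$blocks, function(f) {
    dt <- data.table::fread(file.path(dir, f), data.table = FALSE)
    ids <- dt$variant_id
    R <- as.matrix(dt[, -1, drop = FALSE])
    dimnames(R) <- list(ids, ids)
    list(variant_ids = ids, R = R)
  })
  structure(list(blocks = blocks,
                 sd = setNames(manifest$sd, manifest$variant_id),
                 freq = setNames(manifest$freq, manifest$variant_id),
                 effect_allele = setNames(manifest$effect_allele,
                                          manifest$variant_id),
                 source_n = manifest$source_n),
            class = "ld_reference")
}
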