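#' Construct a genotype dosage panel
#'
#' The central genotype container: a samples-by-variants dosage matrix in
#' `[0, 2]` (missing allowed) together with per-variant metadata. Dosages
#' count copies of the effect allele.
#'
#' @param sample_ids Character vector of unique sample ids.
#' @param variant_ids Character vector of unique variant ids.
#' @param chrom Per-variant chromosome labels.
#' @param pos Per-variant 1-based positions.
#' @param effect_allele,other_allele Per-variant allele pair (must differ).
#' @param dosages Numeric matrix, samples x variants, entries in `[0, 2]` or
#'   `NA`.
#' @param maf Optional per-variant allele frequency (attribute).
#' @param block Optional per-variant LD block index (attribute).
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(sample_ids, variant_ids, chrom, pos,
                           effect_allele, other_allele, dosages,
                           maf = NULL, block = NULL) {
  sample_ids <- as.character(sample_ids)
  variant_ids <- as.character(variant_ids)
  if (anyDuplicated(sample_ids)) {
    stop("genotype_panel: duplicated sample id: ",
         sample_ids[duplicated(sample_ids)][1], call. = FALSE)
  }
  if (anyDuplicated(variant_ids)) {
    stop("genotype_panel: duplicated variant id: ",
         variant_ids[duplicated(variant_ids)][1], call. = FALSE)
  }
  p <- length(variant_ids)
  stopifnot(length(chrom) == p, length(pos) == p,
            length(effect_allele) == p, length(other_allele) == p,
            is.matrix(dosages), nrow(dosages) == length(sample_ids),
            ncol(dosages) == p)
  if (any(effect_allele == other_allele)) {
    stop("genotype_panel: effect and other allele identical for variant ",
         variant_ids[which(effect_allele == other_allele)[1]], call. = FALSE)
  }
  rng <- if (anyNA(dosages)) {
    suppressWarnings(range(dosages, na.rm = TRUE))
  } else {
    range(dosages)
  }
  if (!all(is.finite(rng))) rng <- c(0, 0)
  if (rng[1] < 0 || rng[2] > 2) {
    stop("genotype_panel: dosages must lie in [0, 2]", call. = FALSE)
  }
  dimnames(dosages) <- list(sample_ids, variant_ids)
  out <- list(sample_ids = sample_ids, variant_ids = variant_ids,
              chrom = chrom, pos = as.integer(pos),
              effect_allele = as.character(effect_allele),
              other_allele = as.character(other_allele),
              dosages = dosages)
  if (!is.null(maf)) attr(out, "maf") <- maf
  if (!is.null(block)) attr(out, "block") <- block
  structure(out, class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d variants\n",
              length(x$sample_ids), length(x$variant_ids)))
  invisible(x)
}

#' Read a genotype panel
#'
#' Supported dialects: `tsv` (header `sample_id` then variant ids, one row
#' per sample; an optional sidecar `<path>.vars` TSV carries variant
#' metadata), `plink` (bed/bim/fam prefix; hard calls), and `vcf` (dosage
#' from the `DS` FORMAT field when present, otherwise summed genotype hard
#' calls; effect allele is ALT).
#'
#' @param path File path (for `plink`, the prefix without extension).
#' @param dialect One of `"tsv"`, `"plink"`, `"vcf"`.
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path, dialect = c("tsv", "plink", "vcf")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         tsv = read_genotypes_tsv(path),
         plink = read_genotypes_plink(path),
         vcf = read_genotypes_vcf(path))
}

#' Write a genotype panel
#'
#' @param panel A [genotype_panel()].
#' @param path Output path (for `plink`, prefix without extension).
#' @param dialect `"tsv"` (dosages plus a `<path>.vars` metadata sidecar) or
#'   `"plink"` (bed/bim/fam; dosages are rounded to hard calls).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path, dialect = c("tsv", "plink")) {
  stopifnot(inherits(panel, "genotype_panel"))
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    dt <- data.table::data.table(sample_id = panel$sample_ids)
    dos <- as.data.frame(panel$dosages)
    names(dos) <- panel$variant_ids
    dt <- cbind(dt, dos)
    data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
    vars <- data.table::data.table(
      variant_id = panel$variant_ids, chrom = panel$chrom, pos = panel$pos,
      effect_allele = panel$effect_allele, other_allele = panel$other_allele)
    data.table::fwrite(vars, paste0(path, ".vars"), sep = "\t", quote = FALSE)
  } else {
    write_genotypes_plink(panel, path)
  }
  invisible(path)
}

read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) stop("read_genotypes: no such file: ", path,
                               call. = FALSE)
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE),
    error = function(e) stop("read_genotypes: malformed TSV at ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (names(dt)[1] != "sample_id") {
    stop("read_genotypes: first column must be `sample_id` (line 1)",
         call. = FALSE)
  }
  vids <- names(dt)[-1]
  if (anyDuplicated(vids)) {
    stop("read_genotypes: duplicated variant id: ",
         vids[duplicated(vids)][1], call. = FALSE)
  }
  dos <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(dos)) {
    bad <- which(!vapply(dt[-1], is.numeric, logical(1)))[1]
    # locate the first offending record for the error message
    col <- dt[[bad + 1L]]
    line <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1]
    stop("read_genotypes: non-numeric dosage in column `", vids[bad],
         "` near line ", line + 1L, call. = FALSE)
  }
  varpath <- paste0(path, ".vars")
  if (file.exists(varpath)) {
    vars <- data.table::fread(varpath, sep = "\t", data.table = FALSE)
    vars <- vars[match(vids, vars$variant_id), ]
    chrom <- vars$chrom; pos <- vars$pos
    ea <- vars$effect_allele; oa <- vars$other_allele
  } else {
    chrom <- rep(NA_integer_, length(vids))
    pos <- seq_along(vids)
    ea <- rep("A", length(vids)); oa <- rep("G", length(vids))
  }
  genotype_panel(dt$sample_id, vids, chrom, pos, ea, oa, dos)
}

# PLINK 1 .bed codec (variant-major). Two-bit codes, counting effect (A1)
# alleles: 00 -> 2, 10 -> 1, 11 -> 0, 01 -> missing.
write_genotypes_plink <- function(panel, prefix) {
  n <- length(panel$sample_ids)
  p <- length(panel$variant_ids)
  bim <- data.table::data.table(
    chrom = ifelse(is.na(panel$chrom), 0L, panel$chrom),
    id = panel$variant_ids, cm = 0, pos = panel$pos,
    a1 = panel$effect_allele, a2 = panel$other_allele)
  data.table::fwrite(bim, paste0(prefix, ".bim"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  fam <- data.table::data.table(
    fid = panel$sample_ids, iid = panel$sample_ids, pat = 0L, mat = 0L,
    sex = 0L, pheno = -9L)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  codes <- c(`2` = 0L, `1` = 2L, `0` = 3L)  # two-bit values; NA -> 1L
  bytes_per_var <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  hard <- round(panel$dosages)
  for (j in seq_len(p)) {
    g <- hard[, j]
    two <- ifelse(is.na(g), 1L, codes[as.character(g)])
    two <- c(two, integer(bytes_per_var * 4L - n))
    m <- matrix(two, nrow = 4L)
    byte <- m[1, ] + m[2, ] * 4L + m[3, ] * 16L + m[4, ] * 64L
    writeBin(as.raw(byte), con)
  }
  invisible(prefix)
}

read_genotypes_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  for (ext in c(".bed", ".bim", ".fam")) {
    if (!file.exists(paste0(prefix, ext))) {
      stop("read_genotypes: missing ", paste0(prefix, ext), call. = FALSE)
    }
  }
  bim <- data.table::fread(paste0(prefix, ".bim"), sep = "\t", header = FALSE,
                           data.table = FALSE)
  fam <- data.table::fread(paste0(prefix, ".fam"), sep = "\t", header = FALSE,
                           data.table = FALSE)
  n <- nrow(fam); p <- nrow(bim)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("read_genotypes: not a PLINK bed file (bad magic bytes): ", bed,
         call. = FALSE)
  }
  if (raw[3] != as.raw(0x01)) {
    stop("read_genotypes: only variant-major bed files are supported",
         call. = FALSE)
  }
  body <- as.integer(raw[-(1:3)])
  bytes_per_var <- ceiling(n / 4)
  # decode all two-bit fields at once
  two <- rbind(body %% 4L, (body %/% 4L) %% 4L,
               (body %/% 16L) %% 4L, (body %/% 64L) %% 4L)
  lookup <- c(2, NA, 1, 0)  # codes 0,1,2,3
  dos <- matrix(NA_real_, n, p)
  for (j in seq_len(p)) {
    off <- (j - 1L) * bytes_per_var
    vals <- as.vector(two[, (off + 1L):(off + bytes_per_var)])[seq_len(n)]
    dos[, j] <- lookup[vals + 1L]
  }
  genotype_panel(fam[[2]], bim[[2]], bim[[1]], bim[[4]], bim[[5]], bim[[6]],
                 dos)
}

read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("read_genotypes: no such file: ", path,
                               call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (!is.matrix(fix)) {  # single-record files drop to a named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  if (anyDuplicated(ids)) {
    stop("read_genotypes: duplicated variant id: ", ids[duplicated(ids)][1],
         call. = FALSE)
  }
  fmt <- v@gt[, 1]
  has_ds <- all(vapply(strsplit(fmt, ":"), function(f) "DS" %in% f,
                       logical(1)))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    dos <- t(ds)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
      sum(strsplit(g, "[/|]")[[1]] == "1")
    }
    dos <- t(apply(gt, c(1, 2), count_alt))
  }
  genotype_panel(rownames(dos), ids, fix[, "CHROM"],
                 as.integer(fix[, "POS"]), fix[, "ALT"], fix[, "REF"], dos)
}
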