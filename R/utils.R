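#' Derive a stage seed from a top-level seed
#'
#' All randomized stages draw their own seed deterministically from one
#' top-level integer seed plus a stage label, so that any single stage can be
#' reproduced in isolation from the run manifest.
#'
#' @param seed Integer top-level seed.
#' @param label Character stage label.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- as.double(abs(seed) %% 2147483647)
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% 2147483629
  }
  as.integer(h)
}

# data.table non-standard evaluation inside this package
.datatable.aware <- TRUE

# internal: consistent progress/log messages
ms_log <- function(fmt, ...) {
  message(sprintf(paste0("[memoscore] ", fmt), ...))
}

# internal: population (1/n) standard deviation per column
col_sd_pop <- function(x) {
  mu <- colMeans(x)
  sqrt(pmax(colMeans(x * x) - mu * mu, 0))
}

# internal: mean-impute missing values per column
impute_col_means <- function(x) {
  if (!anyNA(x)) return(x)
  nas <- which(colSums(is.na(x)) > 0L)
  for (j in nas) {
    v <- x[, j]
    m <- mean(v, na.rm = TRUE)
    if (is.nan(m)) m <- 0
    v[is.na(v)] <- m
    x[, j] <- v
  }
  x
}
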