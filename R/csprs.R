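#' Configuration for the continuous-shrinkage posterior sampler
#'
#' Parameters of the gamma-gamma global-local shrinkage hierarchy
#' \deqn{\beta_j \sim N(0, \sigma^2 \psi_j / n), \quad
#'       \psi_j \sim \mathrm{Gamma}(a, \delta_j), \quad
#'       \delta_j \sim \mathrm{Gamma}(b, \phi)}
#' and of the Gibbs chain. Defaults `a = 1`, `b = 0.5`, 1000 iterations with
#' 500 burn-in and thinning 5 mirror the reference settings of
#' continuous-shrinkage polygenic-score software; desk-scale analyses may
#' shorten the chain.
#'
#' @param a Local shape parameter (> 0).
#' @param b Local rate-shape parameter (> 0).
#' @param phi Global shrinkage: a positive real, or `"auto"` for the fully
#'   Bayesian update.
#' @param n_iter,n_burnin,thin Chain length, burn-in (`< n_iter`) and
#'   thinning interval.
#' @param psi_max Cap on the local scales (reference-implementation
#'   convention; set `Inf` to disable).
#' @param sigma2 Fix the residual variance at this value instead of sampling
#'   it (`NULL` samples it).
#' @param store_draws Keep the thinned post-burn-in beta draws (memory heavy
#'   for large panels; used by diagnostics).
#' @param seed Integer seed.
#' @return An object of class `cs_config`.
#' @export
cs_config <- function(a = 1, b = 0.5, phi = "auto", n_iter = 1000L,
                      n_burnin = 500L, thin = 5L, psi_max = 1,
                      sigma2 = NULL, store_draws = FALSE, seed = 1L) {
  stopifnot(a > 0, b > 0, n_iter > 0, n_burnin >= 0, thin >= 1)
  if (n_burnin >= n_iter) {
    stop("cs_config: `n_burnin` must be smaller than `n_iter`",
         call. = FALSE)
  }
  if (!identical(phi, "auto")) {
    phi <- as.numeric(phi)
    stopifnot(is.finite(phi), phi > 0)
  }
  structure(list(a = a, b = b, phi = phi, n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 psi_max = psi_max, sigma2 = sigma2,
                 store_draws = isTRUE(store_draws), seed = as.integer(seed)),
            class = "cs_config")
}

#' Posterior-mean variant effects under a continuous-shrinkage prior
#'
#' Gibbs sampler over the hierarchical model of [cs_config()] given
#' meta-analyzed marginal effects and a block LD reference. Marginal effects
#' are converted to the standardized (unit genotype variance, unit trait
#' variance) scale via `z / sqrt(n)`; per block, the effect vector is drawn
#' from its multivariate-normal full conditional
#' \eqn{N(A^{-1}\hat\beta,\ (\sigma^2/n) A^{-1})} with
#' \eqn{A = R + \mathrm{diag}(1/\psi)}; the residual variance and the local
#' rates use conjugate inverse-gamma/gamma updates, the local scales
#' \eqn{\psi_j} use generalized-inverse-Gaussian draws, and with
#' `phi = "auto"` the global parameter gets its fully Bayesian gamma update.
#' Posterior means are averaged after burn-in and thinning and
#' back-transformed to the per-allele scale using the LD reference dosage
#' standard deviations.
#'
#' @param meta Output of [meta_fixed()] (or any summary-statistics table
#'   with `variant_id`, `effect_allele`, `beta_meta`/`beta`, `se_meta`/`se`,
#'   `n_total`/`n`). Variants must be a subset of the LD reference.
#' @param ld An [build_ld_reference()] object.
#' @param cfg A [cs_config()].
#' @return A [weight_table()] (label `GWAMA-PRS`, one row per variant kept)
#'   with attributes: `post_mean_std`, `post_sd_std` (standardized scale),
#'   `phi_chain` (when `phi = "auto"`), `sigma2_chain`, `draws` (if
#'   requested) and `cfg`.
#' @export
sample_posterior_effects <- function(meta, ld, cfg = cs_config()) {
  stopifnot(inherits(ld, "ld_reference"), inherits(cfg, "cs_config"))
  meta <- as.data.frame(meta)
  beta_col <- if ("beta_meta" %in% names(meta)) "beta_meta" else "beta"
  se_col <- if ("se_meta" %in% names(meta)) "se_meta" else "se"
  n_col <- if ("n_total" %in% names(meta)) "n_total" else "n"
  keep <- !is.na(meta[[beta_col]]) & !is.na(meta[[se_col]])
  meta <- meta[keep, , drop = FALSE]
  in_ld <- meta$variant_id %in% names(ld$sd)
  if (any(!in_ld)) {
    ms_log("sample_posterior_effects: dropping %d variant(s) absent %s",
           sum(!in_ld), "from the LD reference")
    meta <- meta[in_ld, , drop = FALSE]
  }
  if (!nrow(meta)) {
    stop("sample_posterior_effects: no variants shared with the LD ",
         "reference", call. = FALSE)
  }
  n <- stats::median(meta[[n_col]])
  z <- meta[[beta_col]] / meta[[se_col]]
  bhat_all <- setNames(z / sqrt(meta[[n_col]]), meta$variant_id)

  # block bookkeeping restricted to variants present in `meta`
  blocks <- list()
  order_ids <- character(0)
  for (blk in ld$blocks) {
    ids <- intersect(blk$variant_ids, meta$variant_id)
    if (!length(ids)) next
    R <- blk$R[ids, ids, drop = FALSE]
    blocks[[length(blocks) + 1L]] <-
      list(ids = ids, R = R, idx = seq_along(ids) + length(order_ids))
    order_ids <- c(order_ids, ids)
  }
  p <- length(order_ids)
  bhat <- bhat_all[order_ids]

  set.seed(cfg$seed)
  auto_phi <- identical(cfg$phi, "auto")
  phi <- if (auto_phi) 1 else cfg$phi
  sigma2 <- if (is.null(cfg$sigma2)) 1 else cfg$sigma2
  beta <- numeric(p)
  psi <- rep(1, p)
  n_store <- (cfg$n_iter - cfg$n_burnin) %/% cfg$thin
  sum_b <- numeric(p); sum_b2 <- numeric(p)
  phi_chain <- if (auto_phi) numeric(n_store) else NULL
  sigma2_chain <- numeric(n_store)
  draws <- if (cfg$store_draws) matrix(NA_real_, n_store, p) else NULL
  stored <- 0L

  for (it in seq_len(cfg$n_iter)) {
    quad <- 0
    for (blk in blocks) {
      m <- length(blk$idx)
      if (m == 1L) {
        a_sc <- 1 + 1 / psi[blk$idx]
        mu <- bhat[blk$idx] / a_sc
        beta[blk$idx] <- mu + sqrt(sigma2 / (n * a_sc)) * rnorm(1)
        quad <- quad + beta[blk$idx]^2 * a_sc
      } else {
        A <- blk$R
        diag(A) <- diag(A) + 1 / psi[blk$idx]
        U <- chol(A)
        mu <- backsolve(U, forwardsolve(t(U), bhat[blk$idx]))
        bdraw <- mu + sqrt(sigma2 / n) * backsolve(U, rnorm(m))
        beta[blk$idx] <- bdraw
        quad <- quad + sum((U %*% bdraw)^2)
      }
    }
    if (any(!is.finite(beta))) {
      stop("sample_posterior_effects: non-finite effect update at ",
           "iteration ", it, call. = FALSE)
    }
    if (is.null(cfg$sigma2)) {
      err <- max(n / 2 * (1 - 2 * sum(beta * bhat) + quad),
                 n / 2 * sum(beta^2 / psi))
      sigma2 <- 1 / rgamma(1, shape = (n + p) / 2, rate = err)
    }
    delta <- rgamma(p, shape = cfg$a + cfg$b, rate = psi + phi)
    psi <- gig_rnd(rep(cfg$a - 0.5, p), 2 * delta, n * beta^2 / sigma2)
    if (is.finite(cfg$psi_max)) psi <- pmin(psi, cfg$psi_max)
    psi <- pmax(psi, 1e-12)
    if (auto_phi) {
      w <- rgamma(1, shape = 1, rate = phi + 1)
      phi <- rgamma(1, shape = p * cfg$b + 0.5, rate = sum(delta) + w)
    }
    if (it > cfg$n_burnin && (it - cfg$n_burnin) %% cfg$thin == 0L) {
      stored <- stored + 1L
      sum_b <- sum_b + beta
      sum_b2 <- sum_b2 + beta^2
      if (auto_phi) phi_chain[stored] <- phi
      sigma2_chain[stored] <- sigma2
      if (cfg$store_draws) draws[stored, ] <- beta
    }
  }
  post_mean <- sum_b / stored
  post_sd <- sqrt(pmax(sum_b2 / stored - post_mean^2, 0))
  w_allele <- post_mean / ld$sd[order_ids]
  out <- weight_table(order_ids, ld$effect_allele[order_ids],
                      unname(w_allele),
                      rep("GWAMA-PRS", p))
  attr(out, "post_mean_std") <- setNames(post_mean, order_ids)
  attr(out, "post_sd_std") <- setNames(post_sd, order_ids)
  attr(out, "phi_chain") <- phi_chain
  attr(out, "sigma2_chain") <- sigma2_chain
  attr(out, "draws") <- draws
  attr(out, "cfg") <- cfg
  attr(out, "n_draws") <- stored
  out
}

#' Posterior summary of the global shrinkage parameter
#'
#' Only available for samplers run with `phi = "auto"`.
#'
#' @param fit A [sample_posterior_effects()] result.
#' @return A list: `median`, `q05`, `q95`, `chain_length`.
#' @export
auto_phi_summary <- function(fit) {
  chain <- attr(fit, "phi_chain")
  if (is.null(chain)) {
    stop("auto_phi_summary: phi was fixed for this run (not sampled)",
         call. = FALSE)
  }
  list(median = stats::median(chain),
       q05 = unname(quantile(chain, 0.05)),
       q95 = unname(quantile(chain, 0.95)),
       chain_length = length(chain))
}
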