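# Independent oracles used across the suite. These deliberately avoid the
# package's own solvers: exact enumeration for the L1 problem, hand-rolled
# step-up for BH, Monte-Carlo for the thresholded-liability LD attenuation,
# and 1-D quadrature for the continuous-shrinkage posterior.

# Objective of the partially penalized problem with covariates solved
# exactly at the given penalized coefficients.
lasso_objective <- function(X, y, Z, beta, lambda) {
  qz <- qr(Z)
  a <- qr.coef(qz, y - X %*% beta)
  r <- y - Z %*% a - X %*% beta
  sum(r^2) / (2 * length(y)) + lambda * sum(abs(beta))
}

# Exact LASSO solution by enumeration of active sets and sign patterns
# (feasible for <= 8 penalized features). Covariates are profiled out by
# QR residualization, which is exact for unpenalized blocks.
oracle_lasso_enum <- function(X, y, Z, lambda) {
  n <- nrow(X); p <- ncol(X)
  stopifnot(p <= 8)
  qz <- qr(Z)
  MX <- qr.resid(qz, X)
  My <- qr.resid(qz, y)
  best <- NULL
  best_obj <- Inf
  for (mask in 0:(2^p - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    if (!length(S)) {
      g <- abs(crossprod(MX, My)) / n
      if (all(g <= lambda + 1e-9)) {
        obj <- sum(My^2) / (2 * n)
        if (obj < best_obj) { best_obj <- obj; best <- numeric(p) }
      }
      next
    }
    Xs <- MX[, S, drop = FALSE]
    G <- crossprod(Xs) / n
    if (rcond(G) < 1e-12) next
    cvec <- crossprod(Xs, My) / n
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(S))))
    for (si in seq_len(nrow(signs))) {
      s <- signs[si, ]
      b <- solve(G, cvec - lambda * s)
      if (any(sign(b) != s)) next
      r <- My - Xs %*% b
      out <- setdiff(seq_len(p), S)
      if (length(out)) {
        g <- abs(crossprod(MX[, out, drop = FALSE], r)) / n
        if (any(g > lambda + 1e-9)) next
      }
      beta <- numeric(p); beta[S] <- b
      obj <- sum(r^2) / (2 * n) + lambda * sum(abs(b))
      if (obj < best_obj) { best_obj <- obj; best <- beta }
    }
  }
  list(beta = best, objective = best_obj)
}

# Benjamini-Hochberg step-up: adj_i = min_{j >= i} (m * p_(j) / j), capped.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Monte-Carlo oracle for the dosage correlation implied by thresholding two
# AR(1)-correlated haplotype liabilities at the given MAFs.
oracle_dosage_cor <- function(maf1, maf2, rho, ndraw = 1e6) {
  g1 <- numeric(ndraw); g2 <- numeric(ndraw)
  for (h in 1:2) {
    z1 <- rnorm(ndraw)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(ndraw)
    g1 <- g1 + (z1 <= qnorm(maf1))
    g2 <- g2 + (z2 <= qnorm(maf2))
  }
  cor(g1, g2)
}

# 1-D quadrature oracle for the single-variant continuous-shrinkage
# posterior mean with fixed global parameter and residual variance:
# E[beta | bhat] = bhat * E[psi/(1+psi) | bhat] under
# p(psi | bhat) ~ (1+psi)^(-1/2) exp(-n bhat^2/(2 s2 (1+psi)))
#                 psi^(a-1) (psi+phi)^(-(a+b)).
oracle_cs_posterior_mean <- function(bhat, n, a, b, phi, sigma2 = 1) {
  f <- function(psi) {
    exp(-0.5 * log1p(psi) - n * bhat^2 / (2 * sigma2 * (1 + psi)) +
          (a - 1) * log(psi) - (a + b) * log(psi + phi))
  }
  num <- stats::integrate(function(x) x / (1 + x) * f(x), 0, Inf,
                          rel.tol = 1e-10)$value
  den <- stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value
  bhat * num / den
}

# Mean of a GIG(p, a, b) distribution via Bessel functions (used to validate
# the compiled sampler).
gig_mean_theory <- function(p, a, b) {
  omega <- sqrt(a * b)
  sqrt(b / a) * besselK(omega, p + 1) / besselK(omega, p)
}
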