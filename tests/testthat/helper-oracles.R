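# Independent oracles used across the suite.  Each reimplements the checked
# quantity by a different route than the package (enumeration, brute force,
# direct formula), so agreement is informative.

# strip all attributes except dim: compare matrix values only
bare <- function(x) matrix(as.numeric(x), nrow(x), ncol(x))

# exact HWE p-value by full enumeration of heterozygote counts using the
# closed-form conditional probability (lgamma route, no recurrence)
oracle_hwe_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  R <- 2 * min(n_AA, n_aa) + n_Aa           # rare allele count
  if (R == 0) return(1)
  hs <- seq.int(R %% 2, min(R, 2 * n - R), by = 2)
  logp <- vapply(hs, function(h) {
    hr <- (R - h) / 2
    hc <- n - h - hr
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
      h * log(2) + lfactorial(R) + lfactorial(2 * n - R) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hs)]
  sum(p[p <= obs * (1 + 1e-12)])
}

# brute-force GRM: explicit double loop over pairs
oracle_grm <- function(dosages) {
  p <- colMeans(dosages, na.rm = TRUE) / 2
  Z <- sweep(dosages, 2, 2 * p, "-")
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  n <- nrow(Z)
  m <- ncol(Z)
  G <- matrix(NA_real_, n, n)
  for (j in seq_len(n))
    for (k in seq_len(n))
      G[j, k] <- sum(Z[j, ] * Z[k, ]) / m
  G
}

# restricted log-likelihood via orthonormal error contrasts K'X = 0:
# an algebraically different route than the package's P-matrix formula
oracle_restricted_loglik <- function(y, X, A_list, sigma2) {
  n <- length(y)
  p <- ncol(X)
  V <- diag(sigma2[length(sigma2)], n)
  for (i in seq_along(A_list)) V <- V + sigma2[i] * A_list[[i]]
  K <- qr.Q(qr(X), complete = TRUE)[, (p + 1):n, drop = FALSE]
  KVK <- crossprod(K, V %*% K)
  Ky <- drop(crossprod(K, y))
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                       determinant(KVK, logarithm = TRUE)$modulus +
                       drop(crossprod(Ky, solve(KVK, Ky)))))
}

# a small genotype fixture guaranteed polymorphic in-sample
make_genotypes <- function(n, m, seed = 1, maf = c(0.1, 0.5)) {
  set.seed(seed)
  p <- runif(2 * m, maf[1], maf[2])
  d <- matrix(rbinom(n * 2 * m, 2, rep(p, each = n)), n, 2 * m)
  f <- colMeans(d) / 2
  d <- d[, f > 0 & f < 1, drop = FALSE][, seq_len(m), drop = FALSE]
  genotype_matrix(d, sprintf("s%03d", seq_len(n)), sprintf("v%03d", seq_len(m)))
}

# small covariance-exact phenotype draw on given matrices
draw_vc_pheno <- function(fracs, mats, n) {
  y <- sqrt(1 - sum(fracs)) * rnorm(n)
  for (nm in names(fracs)) {
    eg <- eigen(as.matrix(mats[[nm]]), symmetric = TRUE)
    y <- y + sqrt(fracs[[nm]]) *
      drop(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * rnorm(n)))
  }
  y
}
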