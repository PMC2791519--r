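# Independent oracles, deliberately unoptimised and kept separate from the
# package's own code paths.

# Brute-force transcription of the variational scheme: elementwise loops,
# no max-subtraction, run to a tight tolerance.
rfxFitNaive <- function(lev, alpha0 = rep(1, ncol(lev)), tol = 1e-10,
                        maxIter = 10000L) {
  alpha <- alpha0
  n <- nrow(lev)
  k <- ncol(lev)
  g <- matrix(0, n, k)
  beta <- numeric(k)
  for (it in seq_len(maxIter)) {
    u <- matrix(0, n, k)
    for (i in seq_len(n)) {
      for (j in seq_len(k)) {
        u[i, j] <- exp(lev[i, j] + digamma(alpha[j]) - digamma(sum(alpha)))
      }
    }
    for (i in seq_len(n)) g[i, ] <- u[i, ] / sum(u[i, ])
    for (j in seq_len(k)) beta[j] <- sum(g[, j])
    alphaNew <- alpha0 + beta
    if (max(abs(alphaNew - alpha)) < tol) {
      alpha <- alphaNew
      break
    }
    alpha <- alphaNew
  }
  list(alpha = alpha, g = g, beta = beta,
       expectedR = alpha / sum(alpha))
}

# Monte-Carlo exceedance oracle for K = 2 via Beta marginal draws.
epMonteCarloK2 <- function(alpha, nSamples = 1e6, seed = 1) {
  withr::local_seed(seed)
  mean(rbeta(nSamples, alpha[1L], alpha[2L]) > 0.5)
}

# 2-D numerical integration of the Dirichlet density over the region where
# component `which` is strictly largest (K = 3 only). Parameterised by
# (r_w, r_a) with the remaining component 1 - r_w - r_a.
epIntegrateK3 <- function(alpha, which = 1L) {
  perm <- c(which, setdiff(1:3, which))
  a <- alpha[perm]
  lconst <- lgamma(sum(a)) - sum(lgamma(a))
  f <- function(x, y) {
    z <- 1 - x - y
    out <- exp(lconst + (a[1] - 1) * log(x) + (a[2] - 1) * log(y) +
                 (a[3] - 1) * log(z))
    out[z <= 0 | y >= x | z >= x] <- 0
    out
  }
  pracma::integral2(f, 1 / 3, 1, 0, function(x) pmin(x, 1 - x),
                    reltol = 1e-8)$Q
}

# Small fixture: a heterogeneous two-model group with mixed evidence.
mixedGroup <- function(n = 6) {
  LogEvidenceMatrix(cbind(
    c(2, -1, 0.5, -2, 3, 1.2, 4, -3)[seq_len(n)],
    rep(0, n)
  ))
}
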