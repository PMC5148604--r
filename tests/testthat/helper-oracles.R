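# Independent oracles used across tests.  These are deliberately naive
# re-implementations (explicit inverses, enumeration, sort-based trimming)
# kept separate from the package's own computational paths.

# GLS by explicit matrix inversion and the multivariate-normal density.
naive_gls <- function(y, X, V) {
  n <- length(y)
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  beta <- drop(solve(XtVi %*% X) %*% XtVi %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Vi %*% r)
  sigma2 <- rss / n
  loglik <- -n / 2 * log(2 * pi) -
    0.5 * determinant(sigma2 * V, logarithm = TRUE)$modulus -
    0.5 * rss / sigma2
  se <- sqrt(diag(rss / (n - ncol(X)) * solve(XtVi %*% X)))
  list(beta = beta, se = se, sigma2 = sigma2, loglik = as.numeric(loglik))
}

# Brute-force TMM pair factor with sort-based double trimming; mirrors the
# documented algorithm but shares no code with the package.
brute_tmm_factor <- function(obs, ref, trim_m = 0.30, trim_a = 0.05) {
  n_obs <- sum(obs); n_ref <- sum(ref)
  ok <- obs > 0 & ref > 0
  obs <- obs[ok]; ref <- ref[ok]
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * (log2(obs / n_obs) + log2(ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

brute_tmm <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  q75 <- apply(counts, 2, quantile, probs = 0.75) / lib
  ref <- which.min(abs(q75 - mean(q75)))
  f <- sapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) 1 else brute_tmm_factor(counts[, j], counts[, ref],
                                          trim_m, trim_a)
  })
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

# Benjamini-Hochberg step-up by hand.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}

# Upper-tail hypergeometric probability by direct summation.
hyper_tail <- function(k, K, N, n) {
  j <- max(0, n + K - N):min(n, K)
  sum(choose(K, j[j >= k]) * choose(N - K, n - j[j >= k])) / choose(N, n)
}

# Two-sided Fisher p by enumerating all tables with the observed margins.
fisher_enum <- function(a, b, c, d) {
  n <- a + b + c + d
  K <- a + b; m <- a + c
  js <- max(0, K + m - n):min(K, m)
  probs <- choose(m, js) * choose(n - m, K - js) / choose(n, K)
  pk <- probs[js == a]
  sum(probs[probs <= pk * (1 + 1e-7)])
}

# Two-step verification by brute-force exclusion loops over
# fit_trait_models (the public single-fit path).
brute_two_step <- function(y, x, tree) {
  common <- sort(Reduce(intersect, list(names(y), names(x), tree$tip.label)))
  ploo <- sapply(common, function(s) {
    keep <- setdiff(common, s)
    fit_trait_models(y[keep], x[keep], tree)$best_fit$p[2]
  })
  out <- common[which.min(ploo)]
  rest <- setdiff(common, out)
  p2 <- sapply(rest, function(s) {
    keep <- setdiff(rest, s)
    fit_trait_models(y[keep], x[keep], tree)$best_fit$p[2]
  })
  list(outlier = out, p_robust = unname(min(ploo)), p_max = unname(max(p2)))
}

# Random positive-definite covariance for GLS tests.
random_spd <- function(n) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) + diag(n) * 0.5
}
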