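# Generalized least squares under a fixed residual covariance structure.
# The overall residual variance sigma2 is profiled out analytically, so V
# only needs to encode the correlation structure up to scale.

# Core fit given the upper Cholesky factor U of V (V = U'U) and log|V|.
# Shared by the public gls_fit and the model-selection profile loops.
gls_core <- function(y, X, U, logdet) {
  n <- length(y)
  p <- ncol(X)
  yt <- backsolve(U, y, transpose = TRUE)
  Xt <- backsolve(U, X, transpose = TRUE)
  XtX <- crossprod(Xt)
  XtXinv <- tryCatch(solve(XtX), error = function(e) {
    stop("rank-deficient design (X'V^-1X singular)", call. = FALSE)
  })
  beta <- drop(XtXinv %*% crossprod(Xt, yt))
  r <- yt - Xt %*% beta
  rss <- sum(r * r)
  sigma2_ml <- max(rss / n, 1e-300)
  loglik <- -n / 2 * (log(2 * pi) + log(sigma2_ml) + 1) - logdet / 2
  sigma2_ub <- rss / (n - p)
  se <- sqrt(pmax(sigma2_ub * diag(XtXinv), 0))
  tstat <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  pval <- pmax(2 * pt(abs(tstat), n - p, lower.tail = FALSE),
               .Machine$double.xmin)
  list(beta = beta, se = se, t = tstat, p = pval, sigma2_ml = sigma2_ml,
       loglik = loglik, df_resid = n - p, n = n)
}

#' Generalized least squares with a known covariance structure
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma2 * V)`, by maximum likelihood with
#' `sigma2` profiled out: `beta = (X'V^-1X)^-1 X'V^-1 y`,
#' `sigma2_ml = r'V^-1 r / n`, and
#' `loglik = -n/2 (log 2 pi + log sigma2_ml + 1) - log|V| / 2`.
#' Standard errors use the unbiased variance `r'V^-1 r / (n - p)`; the
#' slope p-value is two-sided from a t distribution with `n - p` degrees of
#' freedom.  With `V` the identity this is ordinary least squares.
#'
#' @param y Response vector (aligned to the rows of `X` and `V`).
#' @param X Design matrix (first column typically the intercept).
#' @param V Positive-definite covariance structure, e.g. from
#'   [bm_covariance()]; may be scaled arbitrarily.
#' @return Object of class `gls_fit`: list with `beta`, `se`, `t`, `p`,
#'   `sigma2_ml`, `loglik`, `df_resid`, `n`.
#' @export
gls_fit <- function(y, X, V) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  V <- as.matrix(V)
  n <- length(y)
  if (nrow(X) != n || nrow(V) != n || ncol(V) != n) {
    stop("y, X and V must have matching dimensions", call. = FALSE)
  }
  if (n <= ncol(X)) stop("need more observations than coefficients", call. = FALSE)
  U <- tryCatch(chol(V), error = function(e) {
    stop("V is not positive definite", call. = FALSE)
  })
  fit <- gls_core(y, X, U, 2 * sum(log(diag(U))))
  class(fit) <- "gls_fit"
  fit
}

#' @export
print.gls_fit <- function(x, ...) {
  cat("<gls_fit>\n  beta:", signif(x$beta, 6),
      "\n  se:  ", signif(x$se, 6),
      "\n  loglik:", signif(x$loglik, 8),
      " sigma2_ml:", signif(x$sigma2_ml, 6), "\n")
  invisible(x)
}
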