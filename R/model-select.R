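# Maximum-likelihood selection among four residual-covariance models:
# independent residuals ("null"), Brownian motion, Pagel's lambda, and
# Ornstein-Uhlenbeck.  lambda and alpha are profiled on a coarse grid and
# refined by Brent search; sigma2 and beta are profiled analytically, so a
# profile point costs one generalized-least-squares solve.
#
# Numerical scheme: with S = diag(sqrt(T_i)) and R = S^-1 Vbm S^-1 the
# Brownian correlation matrix, the lambda family is
# V(lambda) = S (lambda R + (1 - lambda) I) S, so a single symmetric
# eigendecomposition R = Q M Q' turns every lambda evaluation (and the
# null / Brownian special cases lambda = 0, 1 on ultrametric trees) into
# O(n) weighted least squares on rotated coordinates.  OU covariances are
# not simultaneously diagonalizable in alpha, so they go through Cholesky
# factors memoised per grid point.

LAMBDA_GRID <- seq(0, 1, by = 0.05)
ALPHA_GRID <- exp(seq(log(1e-4), log(50), length.out = 25))

# A model-selection context for one species subset; reused across features
# in a screen so grid decompositions are shared.
ms_context <- function(Vbm, D) {
  env <- new.env(parent = emptyenv())
  env$Vbm <- Vbm
  env$D <- D
  env$n <- nrow(Vbm)
  env$depth <- mean(diag(Vbm))
  S <- sqrt(diag(Vbm))
  env$S <- S
  R <- Vbm / tcrossprod(S)
  ed <- eigen((R + t(R)) / 2, symmetric = TRUE)
  env$Q <- ed$vectors
  env$mu <- pmax(ed$values, 0)
  env$logdetS2 <- 2 * sum(log(S))
  env$ou_grid <- ALPHA_GRID / env$depth
  env$cache <- new.env(parent = emptyenv())
  env
}

# Assemble a gls_core-shaped fit from weighted normal-equation pieces.
# With `full = FALSE` only the pieces the profile search needs (loglik,
# slope) are computed; standard errors and p-values wait for the final fit.
ms_assemble <- function(a11, a12, a22, b1, b2, yy, n, logdet, full = TRUE) {
  det2 <- a11 * a22 - a12 * a12
  if (!is.finite(det2) || det2 <= 0) {
    stop("rank-deficient design (X'V^-1X singular)", call. = FALSE)
  }
  beta <- c((a22 * b1 - a12 * b2) / det2, (a11 * b2 - a12 * b1) / det2)
  rss <- max(yy - beta[1] * b1 - beta[2] * b2, 0)
  sigma2_ml <- max(rss / n, 1e-300)
  loglik <- -n / 2 * (log(2 * pi) + log(sigma2_ml) + 1) - logdet / 2
  if (!full) return(list(loglik = loglik))
  sigma2_ub <- rss / (n - 2)
  se <- sqrt(pmax(sigma2_ub * c(a22, a11) / det2, 0))
  tstat <- beta / se
  tstat[se == 0] <- sign(beta[se == 0]) * Inf
  pval <- pmax(2 * pt(abs(tstat), n - 2, lower.tail = FALSE),
               .Machine$double.xmin)
  list(beta = beta, se = se, t = tstat, p = pval, sigma2_ml = sigma2_ml,
       loglik = loglik, df_resid = n - 2, n = n)
}

# One lambda-family evaluation on rotated coordinates (y2 = Q'S^-1 y etc.).
lambda_eval <- function(ctx, y2, x21, x22, lam, full = TRUE) {
  w <- (1 - lam) + lam * ctx$mu
  if (w[ctx$n] < 1e-12) w[w < 1e-12] <- 1e-12
  iw <- 1 / w
  ms_assemble(sum(x21 * x21 * iw), sum(x21 * x22 * iw), sum(x22 * x22 * iw),
              sum(x21 * y2 * iw), sum(x22 * y2 * iw), sum(y2 * y2 * iw),
              ctx$n, ctx$logdetS2 + sum(log(w)), full)
}

# Plain OLS (identity covariance) for the "null" model.
null_eval <- function(ctx, y, X, full = TRUE) {
  x1 <- X[, 1]; x2 <- X[, 2]
  ms_assemble(sum(x1 * x1), sum(x1 * x2), sum(x2 * x2),
              sum(x1 * y), sum(x2 * y), sum(y * y), ctx$n, 0, full)
}

# OU evaluation through a memoised Cholesky factor; the design-matrix
# solves are cached alongside (x is constant across features in a screen).
ou_entry <- function(ctx, alpha, cache = TRUE) {
  key <- sprintf("ou:%.12g", alpha)
  ent <- if (cache) ctx$cache[[key]] else NULL
  if (is.null(ent)) {
    V <- ou_cov_from_parts(ctx$Vbm, ctx$D, alpha)
    U <- tryCatch(chol(V), error = function(e) chol(V + diag(1e-10, ctx$n)))
    ent <- new.env(parent = emptyenv())
    ent$U <- U
    ent$logdet <- 2 * sum(log(diag(U)))
    if (cache) ctx$cache[[key]] <- ent
  }
  ent
}

ou_eval <- function(ctx, y, X, alpha, cache = TRUE, full = TRUE) {
  ent <- ou_entry(ctx, alpha, cache)
  if (is.null(ent$Xt) || !identical(ent$x_ref, X[, 2])) {
    ent$Xt <- backsolve(ent$U, X, transpose = TRUE)
    ent$x_ref <- X[, 2]
  }
  yt <- backsolve(ent$U, y, transpose = TRUE)
  Xt <- ent$Xt
  ms_assemble(sum(Xt[, 1]^2), sum(Xt[, 1] * Xt[, 2]), sum(Xt[, 2]^2),
              sum(Xt[, 1] * yt), sum(Xt[, 2] * yt), sum(yt * yt),
              ctx$n, ent$logdet, full)
}

# Grid-then-Brent profile maximization.  `f(param, full)` returns a fit list.
ms_profile <- function(f, grid, log_scale = FALSE, tol = 1e-6) {
  ll <- vapply(grid, function(p) f(p, FALSE)$loglik, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  best_p <- grid[i]
  best_ll <- ll[i]
  if (hi > lo) {
    obj <- if (log_scale) {
      function(lp) f(exp(lp), FALSE)$loglik
    } else {
      function(p) f(p, FALSE)$loglik
    }
    opt <- optimize(obj, if (log_scale) log(c(lo, hi)) else c(lo, hi),
                    maximum = TRUE, tol = tol)
    if (opt$objective > best_ll) {
      best_p <- if (log_scale) exp(opt$maximum) else opt$maximum
      best_ll <- opt$objective
    }
  }
  fit <- f(best_p, TRUE)
  fit$param <- best_p
  fit
}

# Fit all four models for one centered (y, x) pair on a context.
ms_fit_models <- function(ctx, y, x) {
  X <- cbind(1, x)
  iS <- 1 / ctx$S
  y2 <- crossprod(ctx$Q, y * iS)[, 1]
  x21 <- crossprod(ctx$Q, iS)[, 1]
  x22 <- crossprod(ctx$Q, x * iS)[, 1]
  fits <- list(
    null = null_eval(ctx, y, X),
    brownian = lambda_eval(ctx, y2, x21, x22, 1),
    lambda = ms_profile(function(l, full = TRUE)
                          lambda_eval(ctx, y2, x21, x22, l, full),
                        LAMBDA_GRID, tol = 1e-6),
    ou = ms_profile(function(a, full = TRUE)
                      ou_eval(ctx, y, X, a, cache = a %in% ctx$ou_grid, full),
                    ctx$ou_grid, log_scale = TRUE, tol = 1e-4)
  )
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  best <- names(fits)[which.max(ll)]  # ties resolve to the simpler model
  list(fits = fits, best = best,
       best_params = switch(best,
                            lambda = c(lambda = fits$lambda$param),
                            ou = c(alpha = fits$ou$param),
                            NULL),
       best_fit = fits[[best]])
}

# Align y, x and tree tips on their common species (sorted for determinism).
align_species <- function(y, x, tips) {
  if (is.null(names(y)) || is.null(names(x))) {
    stop("`y` and `x` must be named by species", call. = FALSE)
  }
  sort(Reduce(intersect, list(names(y), names(x), tips)))
}

#' Fit four trait-evolution models and select by maximum likelihood
#'
#' Regresses a feature value on a trait (both expected on the log10 scale;
#' both are centered internally) by generalized least squares under each of
#' four residual-covariance models -- independent residuals, Brownian
#' motion, Pagel's lambda, and Ornstein-Uhlenbeck -- with lambda in
#' `[0, 1]` and alpha optimized by profile likelihood (coarse grid plus
#' Brent refinement), and reports the model with the highest maximized
#' likelihood.  Selection is by raw maximum likelihood; set `aic = TRUE` to
#' penalize the extra parameter of the lambda and OU models instead.
#'
#' @param y Named numeric vector of feature values per species (log scale).
#' @param x Named numeric vector of trait values per species (log10 scale).
#' @param tree Rooted [ape::phylo] tree covering the species.
#' @param aic Select by AIC instead of raw likelihood.
#' @return List of class `model_selection` with `fits` (one `gls_fit`-style
#'   list per model), `best`, `best_params` and `best_fit`.
#' @export
fit_trait_models <- function(y, x, tree, aic = FALSE) {
  check_phylo(tree, rooted = TRUE)
  common <- align_species(y, x, tree$tip.label)
  if (length(common) < 4) stop("need >= 4 species shared by y, x and tree",
                               call. = FALSE)
  Vbm <- ape::vcv(tree)[common, common]
  D <- stats::cophenetic(tree)[common, common]
  ctx <- ms_context(Vbm, D)
  yc <- y[common] - mean(y[common])
  xc <- x[common] - mean(x[common])
  sel <- ms_fit_models(ctx, yc, xc)
  if (aic) {
    k <- c(null = 3, brownian = 3, lambda = 4, ou = 4)
    ll <- vapply(sel$fits, `[[`, numeric(1), "loglik")
    aics <- 2 * k[names(ll)] - 2 * ll
    best <- names(ll)[which.min(aics)]
    sel$best <- best
    sel$best_fit <- sel$fits[[best]]
    sel$best_params <- switch(best,
                              lambda = c(lambda = sel$fits$lambda$param),
                              ou = c(alpha = sel$fits$ou$param),
                              NULL)
  }
  sel$species <- common
  class(sel) <- "model_selection"
  sel
}

#' @export
print.model_selection <- function(x, ...) {
  ll <- vapply(x$fits, `[[`, numeric(1), "loglik")
  cat("<model_selection> best:", x$best)
  if (!is.null(x$best_params)) {
    cat(sprintf(" (%s = %.4g)", names(x$best_params), x$best_params))
  }
  cat("\n  loglik:", paste(sprintf("%s %.3f", names(ll), ll), collapse = ", "),
      "\n  slope:", signif(x$best_fit$beta[2], 5),
      " p:", signif(x$best_fit$p[2], 4), "\n")
  invisible(x)
}
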