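# Phylogenetic residual covariance matrices for the four trait-evolution
# models used in the screen.  All builders return a symmetric matrix whose
# rows/columns are ordered by tip label, with attributes "model" and
# "params" so downstream fits can report the structure used.

cov_result <- function(V, model, params) {
  V <- (V + t(V)) / 2  # enforce exact symmetry against rounding
  attr(V, "model") <- model
  attr(V, "params") <- params
  V
}

#' Brownian-motion covariance of tip values
#'
#' Under Brownian motion with rate `sigma2`, the covariance of two tips is
#' `sigma2` times the shared root-to-MRCA path length, and the variance of a
#' tip is `sigma2` times its root-to-tip depth.
#'
#' @param tree Rooted [ape::phylo] tree with branch lengths.
#' @param sigma2 Brownian rate (variance per unit branch length).
#' @return Covariance matrix with tip labels as dimnames.
#' @export
bm_covariance <- function(tree, sigma2 = 1) {
  check_phylo(tree, rooted = TRUE)
  check_positive_scalar(sigma2, "sigma2")
  cov_result(sigma2 * ape::vcv(tree), "brownian", list(sigma2 = sigma2))
}

#' Pagel's lambda covariance
#'
#' Multiplies the off-diagonal Brownian covariances by `lambda` in `[0, 1]`,
#' interpolating between independent tips (`lambda = 0`, up to unequal
#' depths) and full Brownian structure (`lambda = 1`).
#'
#' @inheritParams bm_covariance
#' @param lambda Phylogenetic-signal multiplier in `[0, 1]`.
#' @export
lambda_covariance <- function(tree, lambda, sigma2 = 1) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("`lambda` must be in [0, 1]", call. = FALSE)
  }
  check_phylo(tree, rooted = TRUE)
  check_positive_scalar(sigma2, "sigma2")
  V <- sigma2 * ape::vcv(tree)
  d <- diag(V)
  V <- lambda * V
  diag(V) <- d
  cov_result(V, "lambda", list(lambda = lambda, sigma2 = sigma2))
}

#' Ornstein-Uhlenbeck covariance
#'
#' Non-stationary (Hansen) form with the root at the optimum and zero root
#' variance: `V_ij = sigma2/(2*alpha) * exp(-alpha*d_ij) *
#' (1 - exp(-2*alpha*t_ij))` where `d_ij` is the patristic distance between
#' tips and `t_ij` the shared root-to-MRCA path.  This form reduces to
#' Brownian motion as `alpha -> 0`, which keeps the model nested for
#' likelihood-based selection.
#'
#' @inheritParams bm_covariance
#' @param alpha Strength of mean reversion (`> 0`).
#' @export
ou_covariance <- function(tree, alpha, sigma2 = 1) {
  check_positive_scalar(alpha, "alpha")
  check_phylo(tree, rooted = TRUE)
  check_positive_scalar(sigma2, "sigma2")
  Vbm <- ape::vcv(tree)
  D <- stats::cophenetic(tree)[rownames(Vbm), colnames(Vbm)]
  cov_result(ou_cov_from_parts(Vbm, D, alpha, sigma2), "ou",
             list(alpha = alpha, sigma2 = sigma2))
}

# Matrix-level builders used by the fitting engine, where covariances for
# arbitrary species subsets are taken as submatrices of the full-tree shared
# path (Vbm) and patristic distance (D) matrices; restricting to a subset
# cannot change MRCA depths or path lengths among the retained tips.
ou_cov_from_parts <- function(Vbm, D, alpha, sigma2 = 1) {
  sigma2 / (2 * alpha) * exp(-alpha * D) * (1 - exp(-2 * alpha * Vbm))
}

lambda_cov_from_parts <- function(Vbm, lambda) {
  V <- lambda * Vbm
  diag(V) <- diag(Vbm)
  V
}
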