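# Species-level aggregation, feature standardization and PCA projection.

#' Average replicate samples to species level
#'
#' Collapses replicate columns to per-species means using the matrix's
#' sample-to-species map and reports per-species standard errors of the
#' mean.  Missing cells are dropped from both the mean and the SE.
#'
#' @param x [omics_matrix] with a species map.
#' @return Species-level [omics_matrix] (columns named by species) with
#'   attribute `"se"`, a matrix of per-species standard errors (`NA` where a
#'   species has a single replicate).
#' @export
average_replicates <- function(x) {
  om <- as_omics(x)
  if (is.null(om$species)) stop("sample-to-species map required", call. = FALSE)
  m <- as.matrix(om)
  species <- unique(om$species)
  mean_mat <- matrix(NA_real_, nrow(m), length(species),
                     dimnames = list(rownames(m), species))
  se_mat <- mean_mat
  for (s in species) {
    cols <- names(om$species)[om$species == s]
    sub <- m[, cols, drop = FALSE]
    k <- rowSums(!is.na(sub))
    mean_mat[, s] <- rowMeans(sub, na.rm = TRUE)
    se_mat[, s] <- ifelse(k > 1, apply(sub, 1, sd, na.rm = TRUE) / sqrt(k), NA_real_)
  }
  out <- omics_update(om, mean_mat, "average_replicates",
                      species = setNames(species, species))
  attr(out, "se") <- se_mat
  out
}

#' Standardize features to mean zero and unit standard deviation
#'
#' Per-feature centering and scaling using the sample (n-1) standard
#' deviation; constant features are dropped with a warning.
#'
#' @param x [omics_matrix] or matrix.
#' @return Standardized [omics_matrix].
#' @export
standardize_features <- function(x) {
  om <- as_omics(x)
  m <- as.matrix(om)
  mu <- rowMeans(m, na.rm = TRUE)
  s <- apply(m, 1, sd, na.rm = TRUE)
  bad <- is.na(s) | s == 0
  if (any(bad)) {
    warning("dropping zero-variance feature(s): ",
            paste(head(rownames(m)[bad], 5), collapse = ", "),
            if (sum(bad) > 5) " ..." else "")
    m <- m[!bad, , drop = FALSE]
    mu <- mu[!bad]; s <- s[!bad]
  }
  if (nrow(m) == 0) stop("no features with positive variance", call. = FALSE)
  omics_update(om, (m - mu) / s, "standardize_features")
}

#' Project samples onto principal components
#'
#' PCA of the samples (columns) of a features-by-samples matrix; intended to
#' be run on standardized values.  Components are sign-fixed so the loading
#' with the largest magnitude on each axis is positive.
#'
#' @param x [omics_matrix] or matrix.
#' @param n_components Number of components to return.
#' @return List with `coordinates` (samples x components), `var_frac`
#'   (variance fractions) and `loadings` (features x components).
#' @export
pca_project <- function(x, n_components = 3) {
  om <- as_omics(x)
  m <- as.matrix(om)
  if (any(is.na(m))) stop("PCA requires a complete matrix", call. = FALSE)
  if (ncol(m) < n_components) {
    stop("need at least `n_components` samples", call. = FALSE)
  }
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-12)
  k <- n_components
  if (k > rank) {
    warning(sprintf("rank %d < n_components; returning %d components", rank, rank))
    k <- rank
  }
  coords <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      coords[, j] <- -coords[, j]
    }
  }
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = coords, var_frac = var_frac[seq_len(k)], loadings = load)
}
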