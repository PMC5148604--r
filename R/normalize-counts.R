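# Count-level processing: pathological-gene filters, TMM scale factors, and
# log10 + quantile normalization.

#' Filter pathological genes from a count matrix
#'
#' Removes features dominating a library (counts exceeding 5% of any one
#' sample's column total) and features too lowly expressed to analyse
#' (fewer than 10 counts in four or more samples).  The high-count rule is
#' evaluated per sample: exceeding the threshold in any single sample is
#' enough for removal.
#'
#' @param x [omics_matrix] or matrix of nonnegative integer counts.
#' @param high_frac Column-total fraction above which a feature is removed.
#' @param low_count,low_samples A feature is removed when it has fewer than
#'   `low_count` counts in at least `low_samples` samples.
#' @return Filtered [omics_matrix]; attribute `"removed"` lists the feature
#'   IDs dropped by each rule.
#' @export
filter_counts <- function(x, high_frac = 0.05, low_count = 10, low_samples = 4) {
  om <- as_omics(x)
  m <- as.matrix(om)
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  totals <- colSums(m)
  high <- rownames(m)[apply(m > rep(high_frac * totals, each = nrow(m)), 1, any)]
  low <- rownames(m)[rowSums(m < low_count) >= low_samples]
  drop <- union(high, low)
  keep <- setdiff(rownames(m), drop)
  out <- omics_update(om, m[keep, , drop = FALSE], "filter_counts")
  attr(out, "removed") <- list(high = high, low = low)
  out
}

#' Trimmed-mean-of-M-values (TMM) scale factors
#'
#' Between-sample scale factors from doubly trimmed, precision-weighted mean
#' log-ratios of counts against a reference sample.  The reference is the
#' sample whose 75th-percentile count fraction is closest to the mean of
#' those fractions.  For each sample, genes with zero counts in either the
#' sample or the reference are excluded; the per-gene log2 ratio of
#' proportions (M) and average log2 proportion (A) are rank-trimmed by
#' `trim_m` and `trim_a` from each tail; the factor is 2 to the
#' inverse-variance-weighted mean of the retained M values.  Factors are
#' rescaled to unit product so they only redistribute depth.
#'
#' @param x [omics_matrix] or matrix of nonnegative counts (post-filtering).
#' @param trim_m,trim_a Tail fractions trimmed from the M and A statistics.
#' @return Named numeric vector of positive per-sample factors (product 1);
#'   attribute `"ref_sample"` names the reference.
#' @export
tmm_factors <- function(x, trim_m = 0.30, trim_a = 0.05) {
  m <- as.matrix(as_omics(x))
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  lib <- colSums(m)
  if (any(lib == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(m)[lib == 0], collapse = ", "), call. = FALSE)
  }
  q75 <- apply(m, 2, quantile, probs = 0.75) / lib
  ref <- which.min(abs(q75 - mean(q75)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    if (j == ref) return(1)
    tmm_pair_factor(m[, j], m[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(m)
  attr(f, "ref_sample") <- colnames(m)[ref]
  f
}

# One sample vs reference: weighted trimmed mean of M on the log2 scale.
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  if (length(M) == 0) return(1)
  if (max(abs(M)) < 1e-6) return(1)  # identical compositions: no adjustment
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

# Quantile normalization with optional missing cells.  Each column's sorted
# values are replaced by the mean sorted profile; with missing cells a
# column's ranks are mapped onto the reference curve by linear
# interpolation, and ties receive the mean of the reference quantiles they
# span.  With complete data this reduces exactly to mean-of-sorted-columns.
quantile_normalize_matrix <- function(m) {
  n <- nrow(m)
  cols <- seq_len(ncol(m))
  grid <- seq(0, 1, length.out = n)
  col_curves <- lapply(cols, function(j) {
    v <- sort(m[, j])  # drops NA
    if (length(v) == n) v else approx(seq(0, 1, length.out = length(v)), v,
                                      xout = grid, rule = 2)$y
  })
  ref <- rowMeans(do.call(cbind, col_curves))
  out <- m
  for (j in cols) {
    v <- m[, j]
    ok <- which(!is.na(v))
    nj <- length(ok)
    mapped <- if (nj == n) ref else {
      approx(grid, ref, xout = seq(0, 1, length.out = nj), rule = 2)$y
    }
    o <- order(v[ok])
    assigned <- numeric(nj)
    assigned[o] <- mapped
    # average within tie groups (grouped by exact value identity)
    grp <- match(v[ok], v[ok])
    means <- vapply(split(assigned, grp), mean, numeric(1))
    out[ok, j] <- means[as.character(grp)]
  }
  out
}

#' Scale, log10-transform and quantile-normalize a count matrix
#'
#' Counts are converted to counts-per-million using effective library sizes
#' (column total times TMM factor), log10-transformed, and
#' quantile-normalized so that every column shares the mean sorted profile.
#' A pseudo-offset can be added before scaling to admit zeros.
#'
#' @param x [omics_matrix] or matrix of counts (or already-positive values).
#' @param factors Per-sample scale factors, e.g. from [tmm_factors()];
#'   defaults to all 1.
#' @param offset Pseudo-count added before scaling (0 disables).
#' @param lib_size Divide by effective library size and report per million
#'   (set `FALSE` for inputs already on a comparable scale).
#' @param log Apply `log10` before quantile normalization.
#' @return Normalized [omics_matrix].
#' @export
log_quantile_normalize <- function(x, factors = NULL, offset = 0.5,
                                   lib_size = TRUE, log = TRUE) {
  om <- as_omics(x)
  m <- as.matrix(om)
  if (is.null(factors)) factors <- rep(1, ncol(m))
  if (length(factors) != ncol(m) || any(factors <= 0)) {
    stop("`factors` must be positive, one per sample", call. = FALSE)
  }
  if (offset != 0) m <- m + offset
  if (lib_size) {
    eff <- colSums(as.matrix(om)) * factors
    m <- sweep(m, 2, eff, "/") * 1e6
  } else {
    m <- sweep(m, 2, factors, "/")
  }
  if (log) {
    bad <- which(m <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("nonpositive value at feature '%s', sample '%s'; set `offset`",
                   rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
    }
    m <- log10(m)
  }
  m <- quantile_normalize_matrix(m)
  omics_update(om, m, "log_quantile_normalize")
}
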