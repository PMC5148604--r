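#' Normalize a raw metabolite intensity table
#'
#' Per acquisition mode, each sample's intensities are divided first by that
#' sample's internal-standard value and then by the sample's total signal
#' within the mode, cancelling multiplicative batch effects.  Metabolites
#' with 10% or more missing values are dropped, the remainder are
#' log10-transformed and quantile-normalized across samples; missing cells
#' stay masked (`NA`) and are excluded from the quantile pools rather than
#' imputed.
#'
#' @param raw Numeric matrix, metabolites x samples, `NA` for missing cells.
#' @param mode_map Named character vector assigning each metabolite to one
#'   of three modes.
#' @param standards Numeric matrix, modes x samples, of internal-standard
#'   intensities (no missing values allowed).
#' @param max_missing Metabolites with a missing fraction `>=` this are
#'   dropped.
#' @return Normalized [omics_matrix]; attribute `"dropped"` lists the
#'   metabolites removed by the missingness filter.
#' @export
normalize_metabolites <- function(raw, mode_map, standards, max_missing = 0.10) {
  raw <- as.matrix(raw)
  modes <- rownames(standards)
  if (length(modes) != 3L) stop("`standards` must have three mode rows", call. = FALSE)
  if (!all(rownames(raw) %in% names(mode_map))) {
    stop("every metabolite needs a mode assignment", call. = FALSE)
  }
  if (!all(mode_map[rownames(raw)] %in% modes)) {
    stop("mode_map contains modes absent from `standards`", call. = FALSE)
  }
  if (!all(colnames(raw) %in% colnames(standards))) {
    stop("missing internal standard for sample(s): ",
         paste(setdiff(colnames(raw), colnames(standards)), collapse = ", "),
         call. = FALSE)
  }
  std <- standards[, colnames(raw), drop = FALSE]
  if (any(!is.finite(std)) || any(std <= 0)) {
    stop("internal standards must be positive and complete", call. = FALSE)
  }
  norm <- raw
  for (m in modes) {
    rows <- rownames(raw)[mode_map[rownames(raw)] == m]
    if (!length(rows)) next
    sub <- sweep(raw[rows, , drop = FALSE], 2, std[m, ], "/")
    tot <- colSums(sub, na.rm = TRUE)
    norm[rows, ] <- sweep(sub, 2, tot, "/")
  }
  miss_frac <- rowMeans(is.na(norm))
  dropped <- rownames(norm)[miss_frac >= max_missing]
  norm <- norm[miss_frac < max_missing, , drop = FALSE]
  if (nrow(norm) == 0) stop("all metabolites dropped by missingness filter", call. = FALSE)
  if (any(norm <= 0, na.rm = TRUE)) {
    stop("nonpositive intensities after scaling", call. = FALSE)
  }
  vals <- quantile_normalize_matrix(log10(norm))
  out <- omics_matrix(vals,
                      provenance = c("internal_standard", "mode_total",
                                     "missingness_filter", "log10", "quantile"))
  attr(out, "dropped") <- dropped
  out
}
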