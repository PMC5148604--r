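#' Features-by-samples omics matrix with sample-to-species mapping
#'
#' A light container used throughout the pipeline: a numeric matrix with
#' unique feature (row) and sample (column) identifiers, an optional
#' sample-to-species map, and an append-only provenance log recording the
#' transforms applied so far.  Missing values are carried as `NA` and stay
#' masked through normalization.
#'
#' @param values Numeric matrix; rownames are feature IDs, colnames sample IDs.
#' @param species Optional character vector mapping samples to species; either
#'   named by sample ID or in column order.
#' @param provenance Character vector of transforms already applied.
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, species = NULL, provenance = character()) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("f%04d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) stop("duplicate feature IDs", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate sample IDs", call. = FALSE)
  if (!is.null(species)) {
    if (is.null(names(species))) {
      if (length(species) != ncol(values)) {
        stop("`species` must have one entry per sample", call. = FALSE)
      }
      names(species) <- colnames(values)
    }
    missing <- setdiff(colnames(values), names(species))
    if (length(missing)) {
      stop("samples without species assignment: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    species <- species[colnames(values)]
  }
  structure(
    list(values = values, species = species, provenance = as.character(provenance)),
    class = "omics_matrix"
  )
}

#' @export
as.matrix.omics_matrix <- function(x, ...) x$values

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$species)) {
    cat(sprintf("  species: %d (%s...)\n", length(unique(x$species)),
                paste(head(unique(x$species), 3), collapse = ", ")))
  }
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

# Coerce matrix-or-omics_matrix input; returns omics_matrix.
as_omics <- function(x) {
  if (inherits(x, "omics_matrix")) x else omics_matrix(x)
}

# Append a provenance step, keeping everything else.
omics_update <- function(x, values, step, species = NULL) {
  omics_matrix(values,
               species = if (is.null(species)) {
                 sp <- x$species
                 if (!is.null(sp)) sp[intersect(colnames(values), names(sp))] else NULL
               } else species,
               provenance = c(x$provenance, step))
}
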