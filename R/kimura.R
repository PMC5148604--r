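#' Kimura two-parameter nucleotide distance
#'
#' Corrects pairwise sequence divergence separately for transitions
#' (A<->G, C<->T) and transversions.  Sites where either sequence carries a
#' non-ACGT symbol are excluded pairwise.  With transition proportion `P`
#' and transversion proportion `Q`, the distance is
#' `d = -1/2 * log(1 - 2P - Q) - 1/4 * log(1 - 2Q)`; when either log
#' argument is nonpositive the sequences are saturated and the distance is
#' undefined.
#'
#' @param seqA,seqB Nucleotide strings of equal length (case-insensitive).
#' @return List with components `P`, `Q`, `d`, `n_sites`.
#' @export
kimura_2p <- function(seqA, seqB) {
  a <- strsplit(toupper(seqA), "")[[1]]
  b <- strsplit(toupper(seqB), "")[[1]]
  if (length(a) != length(b)) stop("sequences must have equal length", call. = FALSE)
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n == 0) stop("no comparable ACGT sites", call. = FALSE)
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop("saturation: Kimura 2-parameter distance undefined (1-2P-Q or 1-2Q <= 0)",
         call. = FALSE)
  }
  list(P = P, Q = Q, d = -0.5 * log(w1) - 0.25 * log(w2), n_sites = n)
}
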