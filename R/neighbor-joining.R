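#' Correlation distance between samples
#'
#' Distance used for expression/metabolite phylograms: one minus the Pearson
#' correlation between sample columns, giving values in `[0, 2]`.
#' Missing cells are excluded pairwise.
#'
#' @param x An [omics_matrix] or numeric matrix (features x samples).
#' @return Symmetric square matrix with zero diagonal, labelled by sample.
#' @export
correlation_distance <- function(x) {
  m <- as.matrix(as_omics(x))
  if (nrow(m) < 2) stop("need at least 2 features", call. = FALSE)
  sds <- apply(m, 2, sd, na.rm = TRUE)
  bad <- colnames(m)[is.na(sds) | sds == 0]
  if (length(bad)) {
    stop("zero-variance sample column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  D <- 1 - cor(m, use = "pairwise.complete.obs")
  diag(D) <- 0
  (D + t(D)) / 2
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the Studier-Keppler selection criterion.
#' On an additive distance matrix the patristic distances of the returned
#' tree reproduce the input exactly.  Negative estimated branch lengths are
#' clamped to zero with the deficit moved to the sibling branch so the pair
#' distance is preserved; ties in the selection criterion are broken by the
#' smallest (row, column) index pair so the result is deterministic.
#'
#' @param D Symmetric numeric matrix with labels and zero diagonal.
#' @return Unrooted [ape::phylo] tree (binary up to the basal trifurcation).
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 labels", call. = FALSE)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- sprintf("t%d", 1:n)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8, check.attributes = FALSE))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  D <- (D + t(D)) / 2
  fmt <- function(x) sprintf("%.17g", x)
  # each active cluster carries a newick fragment; joins nest fragments
  frag <- rownames(D)
  active <- seq_len(n)
  while (length(active) > 3) {
    m <- length(active)
    d <- D[active, active, drop = FALSE]
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    # smallest (row, col) pair among minima, scanning column-major upper pairs
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    i <- idx[1]; j <- idx[2]
    dij <- d[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- dij - bi
    if (bi < 0) { bi <- 0; bj <- dij }
    if (bj < 0) { bj <- 0; bi <- dij }
    ai <- active[i]; aj <- active[j]
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[ai], fmt(bi), frag[aj], fmt(bj))
    # distances from the new node to every other active cluster
    others <- active[-c(i, j)]
    dnew <- (D[ai, others] + D[aj, others] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    u <- nrow(D)
    D[u, others] <- dnew
    D[others, u] <- dnew
    frag <- c(frag, new_frag)
    active <- c(others, u)
  }
  a <- active[1]; b <- active[2]; c3 <- active[3]
  ba <- max(0, (D[a, b] + D[a, c3] - D[b, c3]) / 2)
  bb <- max(0, (D[a, b] + D[b, c3] - D[a, c3]) / 2)
  bc <- max(0, (D[a, c3] + D[b, c3] - D[a, b]) / 2)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[a], fmt(ba), frag[b], fmt(bb), frag[c3], fmt(bc))
  ape::read.tree(text = txt)
}

# Nontrivial bipartitions of an unrooted tree as canonical keys: each split
# is represented by the tip set on the side NOT containing the first label
# (alphabetically) of the full tip set.
tree_splits <- function(tree) {
  labs <- sort(tree$tip.label)
  anchor <- labs[1]
  parts <- ape::prop.part(tree)
  keys <- character(0)
  node_of <- integer(0)
  for (k in seq_along(parts)) {
    side <- tree$tip.label[parts[[k]]]
    if (length(side) %in% c(0L, length(labs))) next
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) < 2 || length(side) > length(labs) - 2) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
    node_of <- c(node_of, k)
  }
  list(keys = keys, node_index = node_of)
}

#' Bootstrap support for a correlation-distance phylogram
#'
#' Resamples features (rows) with replacement, recomputes the correlation
#' distance and neighbor-joining tree for each replicate, and reports for
#' every internal edge of the point-estimate tree the fraction of replicates
#' containing the same bipartition.
#'
#' @inheritParams correlation_distance
#' @param n_boot Number of bootstrap replicates.
#' @param seed RNG seed.
#' @return The point-estimate tree with `node.label` set to support values in
#'   `[0, 1]` (empty for the basal node and trivial splits) and an attribute
#'   `"support"` holding the per-split fractions.
#' @export
bootstrap_support <- function(x, n_boot, seed = 1L) {
  om <- as_omics(x)
  m <- as.matrix(om)
  if (nrow(m) < 2) stop("need at least 2 features", call. = FALSE)
  n_boot <- check_count(n_boot, "n_boot")
  point <- neighbor_joining(correlation_distance(m))
  sp <- tree_splits(point)
  hits <- setNames(numeric(length(sp$keys)), sp$keys)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      rows <- sample.int(nrow(m), nrow(m), replace = TRUE)
      mb <- m[rows, , drop = FALSE]
      rownames(mb) <- NULL  # resampling duplicates feature IDs
      rep_tree <- neighbor_joining(correlation_distance(mb))
      rep_keys <- tree_splits(rep_tree)$keys
      ok <- sp$keys %in% rep_keys
      hits[ok] <- hits[ok] + 1
    }
  })
  support <- hits / n_boot
  node.label <- rep("", point$Nnode)
  node.label[sp$node_index] <- sprintf("%.4g", support)
  point$node.label <- node.label
  attr(point, "support") <- support
  point
}
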