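# Over-representation statistics for pathway/category annotation sets.

#' Odds ratio and expected overlap for a 2x2 enrichment table
#'
#' For `k` hits in a set of size `K`, with `n` hits drawn from a universe of
#' `N` features: the sample odds ratio is
#' `k (N - K - n + k) / ((n - k) (K - k))` (0/0 returns `Inf`, flagged by the
#' caller as undefined) and the expected overlap is `n K / N`.
#'
#' @param k Observed overlap.
#' @param n Number of hits.
#' @param K Set size within the universe.
#' @param N Universe size.
#' @return List with `odds_ratio` and `expected`.
#' @export
odds_expected <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N ||
      k < max(0, n + K - N)) {
    stop("inconsistent 2x2 margins: need max(0, n+K-N) <= k <= min(n, K) <= N",
         call. = FALSE)
  }
  num <- k * (N - K - n + k)
  den <- (n - k) * (K - k)
  or <- if (den == 0) {
    if (num == 0) Inf else Inf
  } else {
    num / den
  }
  list(odds_ratio = or, expected = n * K / N)
}

#' Hypergeometric over-representation test across annotation sets
#'
#' Each annotation set is intersected with the universe, size-filtered
#' (default: at least `min_size` but at most `max_size` members), and
#' tested for over-representation among the hits with the upper-tail
#' hypergeometric probability `P(X >= k)`.
#'
#' @param hits Character vector of hit features (subset of `universe`).
#' @param annotation Named list of character vectors (set name -> features).
#' @param universe Character vector of all testable features.
#' @param min_size,max_size Inclusive size bounds applied after
#'   intersection with the universe.
#' @return Data frame sorted by p with columns `set`, `N`, `K`, `n`, `k`,
#'   `p`, `odds_ratio`, `expected`, `or_undefined`.
#' @export
hypergeom_enrich <- function(hits, annotation, universe,
                             min_size = 5, max_size = 99) {
  universe <- unique(universe)
  hits <- unique(hits)
  extra <- setdiff(hits, universe)
  if (length(extra)) {
    stop("hits not in universe: ", paste(head(extra, 5), collapse = ", "),
         call. = FALSE)
  }
  N <- length(universe)
  n <- length(hits)
  sets <- lapply(annotation, intersect, universe)
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size
  sets <- sets[keep]
  if (!length(sets)) {
    return(data.frame(set = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), p = numeric(0),
                      odds_ratio = numeric(0), expected = numeric(0),
                      or_undefined = logical(0)))
  }
  rows <- lapply(names(sets), function(nm) {
    K <- length(sets[[nm]])
    k <- length(intersect(hits, sets[[nm]]))
    oe <- odds_expected(k, n, K, N)
    data.frame(set = nm, N = N, K = K, n = n, k = k,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               odds_ratio = oe$odds_ratio, expected = oe$expected,
               or_undefined = (n - k) * (K - k) == 0 &
                 k * (N - K - n + k) == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p, out$set), , drop = FALSE]
}

#' Fisher's exact test for overlap of two feature sets
#'
#' Two-sided exact p-value (summing the probabilities of all tables at
#' least as extreme under the hypergeometric null) for the overlap between
#' two sets within a common background, plus the sample odds ratio of the
#' 2x2 table.
#'
#' @param setA,setB Character vectors, subsets of `background`.
#' @param background Character vector of all features considered.
#' @return List with `p` (two-sided), `odds_ratio` (sample OR; `Inf` when a
#'   zero cell makes it unbounded) and `table` (the 2x2 matrix).
#' @export
fisher_overlap <- function(setA, setB, background) {
  background <- unique(background)
  if (!length(background)) stop("empty background", call. = FALSE)
  setA <- unique(setA); setB <- unique(setB)
  bad <- c(setdiff(setA, background), setdiff(setB, background))
  if (length(bad)) {
    stop("set members not in background: ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  a <- length(intersect(setA, setB))
  b <- length(setdiff(setA, setB))
  c_ <- length(setdiff(setB, setA))
  d <- length(background) - a - b - c_
  tab <- matrix(c(a, b, c_, d), 2, 2,
                dimnames = list(inA = c("yes", "no"), inB = c("yes", "no")))
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c_)
  }
  list(p = min(p, 1), odds_ratio = or, table = tab)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT-format gene-set file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  setNames(lapply(lines, function(x) unique(x[-(1:2)])),
           vapply(lines, `[[`, character(1), 1))
}
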