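test_that("newick round-trip preserves topology and branch lengths", {
  tree <- parse_newick("((a:1,b:1):1,c:2);")
  expect_equal(ape::Ntip(tree), 3)
  expect_equal(max(ape::node.depth.edgelength(tree)), 2)
  rt <- parse_newick(write_newick(tree))
  expect_equal(stats::cophenetic(rt)[c("a", "b", "c"), c("a", "b", "c")],
               stats::cophenetic(tree)[c("a", "b", "c"), c("a", "b", "c")],
               tolerance = 1e-12)

  t15 <- gen_tree(15, seed = 1)
  rt15 <- parse_newick(write_newick(t15))
  expect_equal(stats::cophenetic(rt15)[t15$tip.label, t15$tip.label],
               stats::cophenetic(t15), tolerance = 1e-12)

  expect_error(parse_newick("((a:1,a:1):1,c:2);"), "duplicate")
  expect_error(parse_newick("((a:1,b:1:1,c:2);"), "parse")
})

test_that("Brownian covariance is shared path length times rate", {
  cherry <- parse_newick("(a:1,b:1);")
  expect_equal(unclass(bm_covariance(cherry, 1)),
               matrix(c(1, 0, 0, 1), 2, dimnames = list(c("a", "b"), c("a", "b"))),
               ignore_attr = TRUE)
  tree <- parse_newick("((a:1,b:1):1,c:2);")
  V <- bm_covariance(tree, 1)
  expect_equal(V["a", "b"], 1)
  expect_equal(V["a", "c"], 0)
  expect_equal(V["a", "a"], 2)
  # linear in branch lengths
  tree2 <- tree; tree2$edge.length <- 3 * tree$edge.length
  expect_equal(unclass(bm_covariance(tree2, 1)), unclass(3 * V),
               ignore_attr = TRUE)
})

test_that("lambda covariance scales off-diagonals only", {
  tree <- parse_newick("((a:1,b:1):1,c:2);")
  expect_equal(unclass(lambda_covariance(tree, 1)),
               unclass(bm_covariance(tree)), ignore_attr = TRUE)
  V0 <- lambda_covariance(tree, 0)
  expect_true(all(V0[upper.tri(V0)] == 0))
  expect_equal(diag(V0), diag(bm_covariance(tree)))
  Vh <- lambda_covariance(tree, 0.5)
  expect_equal(Vh["a", "b"], 0.5)
  expect_equal(Vh["a", "a"], 2)
  expect_error(lambda_covariance(tree, 1.2), "lambda")
})

test_that("OU covariance has the BM limit and exponential decay", {
  tree <- gen_tree(12, seed = 2)
  Vbm <- bm_covariance(tree)
  Vou <- ou_covariance(tree, alpha = 1e-4)
  expect_lt(max(abs(Vou - Vbm) / max(Vbm)), 1e-3)
  # large alpha: off-diagonals vanish
  Vbig <- ou_covariance(tree, alpha = 500)
  off <- Vbig[upper.tri(Vbig)]
  expect_lt(max(abs(off)) / max(diag(Vbig)), 1e-6)
  # variance formula at zero distance
  Vt <- ou_covariance(tree, alpha = 2, sigma2 = 3)
  expect_equal(unname(diag(Vt)), rep(3 / 4 * (1 - exp(-4)), 12))
  expect_error(ou_covariance(tree, alpha = -1), "alpha")
})

test_that("covariance builders yield Cholesky-factorizable matrices", {
  tree <- gen_tree(10, seed = 4)
  for (V in list(bm_covariance(tree), lambda_covariance(tree, 0.3),
                 ou_covariance(tree, 1.5))) {
    expect_silent(chol(unclass(V) + diag(1e-10, nrow(V))))
    expect_equal(unclass(V), t(unclass(V)))
  }
})

test_that("correlation distance matches hand-computed Pearson values", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(1, 3, 2), s3 = c(1, 2, 3),
             s4 = c(3, 2, 1))
  D <- correlation_distance(m)
  expect_equal(D["s1", "s2"], 0.5)  # r = 0.5
  expect_equal(D["s1", "s3"], 0)
  expect_equal(D["s1", "s4"], 2)
  expect_error(correlation_distance(cbind(a = c(1, 1, 1), b = c(1, 2, 3))),
               "zero-variance.*a")
})

test_that("neighbor joining solves additive matrices exactly", {
  D <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tree <- neighbor_joining(D)
  expect_equal(stats::cophenetic(tree)[letters[1:4], letters[1:4]], D,
               tolerance = 1e-12)
  internal <- tree$edge.length[tree$edge[, 2] > ape::Ntip(tree)]
  expect_equal(sort(internal), 2, tolerance = 1e-12)

  # 3 taxa: closed-form star resolution
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(D3)
  cp <- stats::cophenetic(t3)
  expect_equal(cp["a", "b"], 3, tolerance = 1e-12)
  expect_equal(cp["a", "c"], 4, tolerance = 1e-12)

  # label-order invariance
  perm <- c("c", "a", "d", "b")
  t_perm <- neighbor_joining(D[perm, perm])
  expect_equal(stats::cophenetic(t_perm)[letters[1:4], letters[1:4]], D,
               tolerance = 1e-12)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2)), "3 labels")
})

test_that("NJ recovers random binary trees from their patristic matrices", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    tr <- ape::rtree(n)
    D <- stats::cophenetic(tr)
    rec <- neighbor_joining(D)
    expect_equal(stats::cophenetic(rec)[rownames(D), colnames(D)], D,
                 tolerance = 1e-10)
  }
})

test_that("bootstrap support is 1 for clean block structure and deterministic", {
  # hierarchical structure in which every internal edge is supported by its
  # own abundant marker block, and tips carry small unique signatures so no
  # two samples are exactly interchangeable
  set.seed(1)
  blocks <- list(s12 = 1:2, s34 = 3:4, s56 = 5:6, s78 = 7:8, left = 1:4)
  base <- matrix(0, 110, 8, dimnames = list(NULL, paste0("s", 1:8)))
  rowi <- 1
  for (b in blocks) {
    for (k in 1:20) {
      base[rowi, b] <- rnorm(1, 5, 1)
      rowi <- rowi + 1
    }
  }
  for (tip in 1:8) {
    base[rowi, tip] <- rnorm(1, 0.3, 0.02)
    rowi <- rowi + 1
  }
  base[rowi:nrow(base), ] <- rnorm(8 * (nrow(base) - rowi + 1), 0, 0.01)
  bt <- bootstrap_support(base, n_boot = 20, seed = 3)
  expect_true(all(attr(bt, "support") == 1))
  bt2 <- bootstrap_support(base, n_boot = 20, seed = 3)
  expect_identical(attr(bt, "support"), attr(bt2, "support"))
  b1 <- bootstrap_support(base, n_boot = 1, seed = 4)
  expect_true(all(attr(b1, "support") %in% c(0, 1)))
})

test_that("Kimura 2-parameter distance matches the closed form", {
  same <- kimura_2p("ACGTACGT", "ACGTACGT")
  expect_equal(same$d, 0)
  expect_equal(same$n_sites, 8)

  # P = 0.1, Q = 0.05 on 100 sites
  a <- paste(rep("A", 100), collapse = "")
  bvec <- rep("A", 100); bvec[1:10] <- "G"; bvec[11:15] <- "C"
  res <- kimura_2p(a, paste(bvec, collapse = ""))
  expect_equal(res$P, 0.1)
  expect_equal(res$Q, 0.05)
  expect_equal(res$d, -0.5 * log(1 - 0.25) - 0.25 * log(1 - 0.1))
  expect_equal(res$d, 0.170181, tolerance = 1e-6)

  # non-ACGT sites excluded pairwise
  resN <- kimura_2p("ANGT", "AAGT")
  expect_equal(resN$n_sites, 3)

  expect_error(kimura_2p("AG", "GG"), "saturation")
  expect_error(kimura_2p("ACG", "AC"), "equal length")
})
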