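test_that("count filters remove exactly the rule-violating features", {
  m <- rbind(low = c(9, 9, 9, 9, 50),
             ok1 = c(20, 30, 40, 50, 60),
             ok2 = c(15, 25, 35, 45, 55),
             ok3 = c(11, 12, 13, 14, 15),
             big = c(100, 10, 10, 10, 10))
  colnames(m) <- paste0("s", 1:5)
  # "big" holds 100/155 ~ 65% of column 1
  out <- filter_counts(m)
  removed <- attr(out, "removed")
  expect_true("low" %in% removed$low)
  expect_true("big" %in% removed$high)
  expect_setdiff_empty <- setdiff(rownames(as.matrix(out)), c("ok1", "ok2", "ok3"))
  expect_length(expect_setdiff_empty, 0)

  # compliant matrix (each gene well below 5% of totals) passes unchanged
  # and the filter is idempotent
  clean <- matrix(50:169, 30, 4,
                  dimnames = list(paste0("g", 1:30), paste0("s", 1:4)))
  out2 <- filter_counts(clean)
  expect_equal(as.matrix(out2), clean)
  expect_equal(as.matrix(filter_counts(out2)), as.matrix(out2))
  expect_error(filter_counts(matrix(-1, 2, 2)), "nonnegative")
})

test_that("TMM factors agree with the brute-force trimming oracle", {
  # identical columns and pure depth scaling both give factors of 1
  base <- matrix(rep(c(100L, 200L, 50L, 400L, 25L, 800L), 4), 6, 4,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  expect_equal(as.numeric(tmm_factors(base)), rep(1, 4))
  scaled <- base
  scaled[, 2] <- base[, 2] * 2L
  expect_equal(as.numeric(tmm_factors(scaled)), rep(1, 4), tolerance = 1e-12)

  # 20-gene toy with 4 genes inflated 8x in one sample
  set.seed(7)
  toy <- matrix(rnbinom(20 * 4, mu = 200, size = 10), 20, 4,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:4)))
  toy[1:4, 2] <- toy[1:4, 2] * 8L
  expect_equal(as.numeric(tmm_factors(toy)), unname(brute_tmm(toy)),
               tolerance = 1e-10)

  # random matrices vs oracle, and the unit-product invariant
  for (i in 1:10) {
    set.seed(100 + i)
    m <- matrix(rnbinom(50 * 6, mu = exp(rnorm(50 * 6, 5, 1)), size = 5),
                50, 6, dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
    f <- tmm_factors(m)
    expect_equal(as.numeric(f), unname(brute_tmm(m)), tolerance = 1e-10)
    expect_equal(prod(f), 1, tolerance = 1e-12)
  }
  expect_error(tmm_factors(cbind(a = c(0, 0), b = c(1, 2))), "all-zero")
})

test_that("TMM factors track the edgeR reference implementation", {
  set.seed(11)
  m <- matrix(rnbinom(200 * 5, mu = exp(rnorm(200 * 5, 5, 1)), size = 5) + 1L,
              200, 5, dimnames = list(paste0("g", 1:200), paste0("s", 1:5)))
  ours <- tmm_factors(m)
  theirs <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(as.numeric(ours), unname(theirs), tolerance = 1e-6)
})

test_that("quantile normalization equalizes column distributions", {
  m <- cbind(a = c(2, 4, 6), b = c(1, 3, 8))
  qn <- as.matrix(log_quantile_normalize(m, offset = 0, lib_size = FALSE,
                                         log = FALSE))
  expect_equal(unname(qn[, "a"]), c(1.5, 3.5, 7.0))
  expect_equal(unname(qn[, "b"]), c(1.5, 3.5, 7.0))

  # identical columns unchanged; sorted columns exactly shared
  same <- cbind(a = c(5, 1, 9), b = c(5, 1, 9))
  expect_equal(as.matrix(log_quantile_normalize(same, offset = 0,
                                                lib_size = FALSE, log = FALSE)),
               same, ignore_attr = TRUE)
  set.seed(3)
  r <- matrix(rlnorm(60), 15, 4, dimnames = list(NULL, paste0("s", 1:4)))
  qr_ <- as.matrix(log_quantile_normalize(r, offset = 0, lib_size = FALSE))
  sorted <- apply(qr_, 2, sort)
  for (j in 2:4) expect_identical(sorted[, j], sorted[, 1])

  # complete-data case agrees with limma's implementation
  expect_equal(unname(as.matrix(
    log_quantile_normalize(r, offset = 0, lib_size = FALSE, log = FALSE))),
    unname(limma::normalizeQuantiles(r, ties = TRUE)))

  expect_error(log_quantile_normalize(cbind(a = c(0, 1), b = c(1, 2)),
                                      offset = 0, lib_size = FALSE),
               "nonpositive")
})

test_that("full count chain preserves within-sample rank order", {
  g <- gen_counts(80, 6, lib_sizes = c(2, 1, 3, 1, 2, 1) * 1e5, seed = 9)
  filt <- filter_counts(g$counts)
  f <- tmm_factors(filt)
  norm <- as.matrix(log_quantile_normalize(filt, factors = f))
  raw <- as.matrix(filt)
  for (j in seq_len(ncol(raw))) {
    expect_equal(order(norm[, j]), order(raw[, j] + seq_len(nrow(raw)) * 1e-9))
  }
})

test_that("metabolite normalization cancels batch factors exactly", {
  gm <- gen_metabolites(45, 12, missing_rate = 0.03, seed = 21,
                        n_planted_missing = 3)
  with_batch <- normalize_metabolites(gm$intensities, gm$mode_map, gm$standards)
  no_batch <- normalize_metabolites(gm$intensities_nobatch, gm$mode_map,
                                    outer(rep(1e5, 3), rep(1, 12),
                                          FUN = function(a, b) a * b) |>
                                      `dimnames<-`(dimnames(gm$standards)))
  expect_equal(as.matrix(with_batch), as.matrix(no_batch), tolerance = 1e-10)
  expect_true(all(gm$planted_missing %in% attr(with_batch, "dropped")))

  # a metabolite missing in 2 of 12 samples (16.7%) is dropped
  raw <- gm$intensities
  expect_false(any(rownames(as.matrix(with_batch)) %in% gm$planted_missing))

  # missing internal standard errors out
  bad_std <- gm$standards[, 1:11]
  expect_error(normalize_metabolites(gm$intensities, gm$mode_map, bad_std),
               "standard")
})

test_that("replicate averaging reports means and standard errors", {
  m <- cbind(a_r1 = c(1, 5), a_r2 = c(3, 5), b_r1 = c(2, 2))
  rownames(m) <- c("g1", "g2")
  om <- omics_matrix(m, species = c(a_r1 = "a", a_r2 = "a", b_r1 = "b"))
  avg <- average_replicates(om)
  expect_equal(as.matrix(avg)[, "a"], c(g1 = 2, g2 = 5))
  expect_equal(as.matrix(avg)[, "b"], c(g1 = 2, g2 = 2))
  se <- attr(avg, "se")
  expect_equal(se["g1", "a"], 1)        # sd(1,3)/sqrt(2) = sqrt(2)/sqrt(2)
  expect_equal(se["g2", "a"], 0)
  expect_true(is.na(se["g1", "b"]))
})

test_that("feature standardization and PCA behave as documented", {
  m <- rbind(f1 = c(1, 2, 3), f2 = c(4, 4, 4), f3 = c(0, 10, 20))
  colnames(m) <- paste0("s", 1:3)
  expect_warning(std <- standardize_features(m), "zero-variance")
  sm <- as.matrix(std)
  expect_equal(unname(sm["f1", ]), c(-1, 0, 1))
  expect_equal(unname(apply(sm, 1, sd)), rep(1, 2))
  expect_equal(as.matrix(standardize_features(sm)), sm, tolerance = 1e-12)

  # rank-1 matrix: PC1 explains everything
  r1 <- outer(c(1, 2, 3, 4), c(1, 0, 2, 1, 3))
  rownames(r1) <- paste0("f", 1:4); colnames(r1) <- paste0("s", 1:5)
  p <- pca_project(r1, n_components = 1)
  expect_equal(unname(p$var_frac[1]), 1, tolerance = 1e-12)

  # two-cluster data separates on PC1
  set.seed(5)
  cl <- matrix(rnorm(30 * 8, sd = 0.1), 30, 8)
  cl[, 1:4] <- cl[, 1:4] + 3
  colnames(cl) <- paste0("s", 1:8)
  pc <- pca_project(cl, n_components = 2)
  expect_true(all(pc$coordinates[1:4, 1] * pc$coordinates[5:8, 1] < 0) ||
              all(sign(pc$coordinates[1:4, 1]) != sign(pc$coordinates[5:8, 1])))
  # rotating the feature space leaves variance fractions unchanged
  q <- qr.Q(qr(matrix(rnorm(900), 30)))
  rot <- t(q) %*% cl
  colnames(rot) <- colnames(cl)
  pc_rot <- pca_project(rot, n_components = 2)
  expect_equal(pc$var_frac, pc_rot$var_frac, tolerance = 1e-8)
})
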