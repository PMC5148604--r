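# Fixture: a tree, a structured trait, and residual generators shared by
# the model-selection tests.
ms_fixture <- function(n_tips = 15, seed = 1) {
  tree <- gen_tree(n_tips, seed = seed)
  traits <- gen_traits(tree, seed = seed + 1)
  list(tree = tree, x = log10(setNames(traits$ML, traits$species)),
       trait = setNames(traits$ML, traits$species))
}

test_that("each model's fit matches explicit-covariance GLS", {
  fx <- ms_fixture()
  cfg <- sim_config(n_species = 15, n_genes = 1, frac_associated = 1,
                    slope_mean = 1.5, seed = 2)
  y <- as.matrix(gen_expression(fx$tree, fx$trait, cfg)$matrix)[1, ]
  names(y) <- sub("_r1$", "", names(y))
  sel <- fit_trait_models(y, fx$x, fx$tree)
  common <- sel$species
  yc <- y[common] - mean(y[common])
  xc <- fx$x[common] - mean(fx$x[common])
  X <- cbind(1, xc)
  checks <- list(
    null = diag(length(common)),
    brownian = unclass(bm_covariance(fx$tree))[common, common],
    lambda = unclass(lambda_covariance(fx$tree,
                                       sel$fits$lambda$param))[common, common],
    ou = unclass(ou_covariance(fx$tree, sel$fits$ou$param))[common, common]
  )
  for (mod in names(checks)) {
    ref <- gls_fit(yc, X, checks[[mod]])
    expect_equal(sel$fits[[mod]]$loglik, ref$loglik, tolerance = 1e-8)
    expect_equal(unname(sel$fits[[mod]]$beta), unname(ref$beta),
                 tolerance = 1e-8)
    expect_equal(unname(sel$fits[[mod]]$p), unname(ref$p), tolerance = 1e-6)
  }
})

test_that("likelihoods agree with the naive multivariate-normal oracle", {
  fx <- ms_fixture(10, seed = 5)
  set.seed(6)
  y <- setNames(rnorm(10), names(fx$x))
  sel <- fit_trait_models(y, fx$x, fx$tree)
  common <- sel$species
  yc <- y[common] - mean(y[common])
  xc <- fx$x[common] - mean(fx$x[common])
  V <- unclass(bm_covariance(fx$tree))[common, common]
  oracle <- naive_gls(yc, cbind(1, xc), V)
  expect_equal(sel$fits$brownian$loglik, oracle$loglik, tolerance = 1e-8)
})

test_that("the lambda family nests the null and Brownian models", {
  fx <- ms_fixture(12, seed = 7)
  set.seed(8)
  for (i in 1:5) {
    y <- setNames(rnorm(12), names(fx$x))
    sel <- fit_trait_models(y, fx$x, fx$tree)
    ll <- vapply(sel$fits, `[[`, numeric(1), "loglik")
    expect_gte(ll["lambda"], ll["brownian"] - 1e-8)
    expect_gte(ll["lambda"], ll["null"] - 1e-8)  # unit-depth ultrametric tree
    expect_true(ll[sel$best] == max(ll))
    if (!is.null(sel$best_params) && sel$best == "lambda") {
      expect_true(sel$best_params >= 0 && sel$best_params <= 1)
    }
  }
})

test_that("lambda at its boundary reproduces the Brownian likelihood", {
  fx <- ms_fixture(15, seed = 9)
  cfg <- sim_config(n_species = 15, n_genes = 1, frac_associated = 1,
                    slope_mean = 2, evo_model = "brownian",
                    evo_params = list(sigma2 = 0.2), seed = 10)
  y <- as.matrix(gen_expression(fx$tree, fx$trait, cfg)$matrix)[1, ]
  names(y) <- sub("_r1$", "", names(y))
  sel <- fit_trait_models(y, fx$x, fx$tree)
  if (sel$fits$lambda$param == 1) {
    expect_equal(sel$fits$lambda$loglik, sel$fits$brownian$loglik,
                 tolerance = 1e-8)
  } else {
    expect_gte(sel$fits$lambda$loglik, sel$fits$brownian$loglik - 1e-8)
  }
})

test_that("lambda is recovered from data simulated at its extremes", {
  tree <- gen_tree(50, seed = 11)
  traits <- gen_traits(tree, seed = 12)
  trait <- setNames(traits$ML, traits$species)
  x <- log10(trait)
  for (lam_true in c(0, 1)) {
    cfg <- sim_config(n_species = 50, n_genes = 40, frac_associated = 0,
                      evo_model = "lambda",
                      evo_params = list(sigma2 = 0.2, lambda = lam_true),
                      replicate_noise_sd = 0,
                      seed = 20 + round(10 * lam_true))
    m <- as.matrix(gen_expression(tree, trait, cfg)$matrix)
    colnames(m) <- sub("_r1$", "", colnames(m))
    lam_hat <- vapply(seq_len(nrow(m)), function(i) {
      fit_trait_models(m[i, ], x, tree)$fits$lambda$param
    }, numeric(1))
    expect_lt(abs(median(lam_hat) - lam_true), 0.2)
  }
})

test_that("true-model slope p-values are uniform under the null", {
  tree <- gen_tree(15, seed = 31)
  traits <- gen_traits(tree, seed = 32)
  trait <- setNames(traits$ML, traits$species)
  x <- log10(trait)
  cfg <- sim_config(n_species = 15, n_genes = 400, frac_associated = 0,
                    evo_model = "brownian", evo_params = list(sigma2 = 0.1),
                    replicate_noise_sd = 0, seed = 33)
  m <- as.matrix(gen_expression(tree, trait, cfg)$matrix)
  colnames(m) <- sub("_r1$", "", colnames(m))
  p <- vapply(seq_len(nrow(m)), function(i) {
    fit_trait_models(m[i, ], x, tree)$fits$brownian$p[2]
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("AIC selection penalizes the extra covariance parameter", {
  fx <- ms_fixture(12, seed = 41)
  set.seed(42)
  y <- setNames(rnorm(12), names(fx$x))
  raw <- fit_trait_models(y, fx$x, fx$tree)
  aic <- fit_trait_models(y, fx$x, fx$tree, aic = TRUE)
  ll <- vapply(raw$fits, `[[`, numeric(1), "loglik")
  k <- c(null = 3, brownian = 3, lambda = 4, ou = 4)
  expect_equal(aic$best, names(which.min(2 * k - 2 * ll)))
})

test_that("species alignment requirements are enforced", {
  fx <- ms_fixture(5, seed = 51)
  y <- setNames(rnorm(3), names(fx$x)[1:3])
  expect_error(fit_trait_models(y, fx$x, fx$tree), ">= 4 species")
  expect_error(fit_trait_models(unname(rnorm(5)), fx$x, fx$tree), "named")
})
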