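# Synthetic-data generators.  These emulate the statistical structure of a
# cross-species fibroblast study -- a mammal phylogeny, life-history traits
# with allometric scaling, expression/metabolite matrices with
# phylogenetically correlated residuals, raw count matrices for the
# normalization stage, and dose-response survival tables -- so every
# downstream stage can be exercised and scored against known truth.

#' Simulation configuration for expression generators
#'
#' @param n_species,n_genes Positive integers.
#' @param frac_associated Fraction of features truly associated with the
#'   trait, in `[0, 1]`; `frac_associated * n_genes` is rounded to a count.
#' @param slope_mean,slope_sd Mean and sd of the true slopes (effect of
#'   log10 trait on feature value) for associated features.
#' @param evo_model Residual covariance model: `"null"`, `"brownian"`,
#'   `"lambda"` or `"ou"`.
#' @param evo_params Named list of model parameters: `sigma2 > 0` for all
#'   models, plus `lambda` in `[0, 1]` or `alpha > 0` as required.
#' @param replicate_noise_sd Within-species replicate noise sd (log10 scale).
#' @param seed RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 15L, n_genes = 500L, frac_associated = 0.1,
                       slope_mean = 1, slope_sd = 0, evo_model = "brownian",
                       evo_params = list(sigma2 = 0.1),
                       replicate_noise_sd = 0.05, seed = 1L) {
  n_species <- check_count(n_species, "n_species", 2L)
  n_genes <- check_count(n_genes, "n_genes")
  if (frac_associated < 0 || frac_associated > 1) {
    stop("`frac_associated` must be in [0, 1]", call. = FALSE)
  }
  evo_model <- match.arg(evo_model, c("null", "brownian", "lambda", "ou"))
  check_evo_params(evo_model, evo_params)
  if (replicate_noise_sd < 0) stop("`replicate_noise_sd` must be >= 0", call. = FALSE)
  structure(list(n_species = n_species, n_genes = n_genes,
                 frac_associated = frac_associated, slope_mean = slope_mean,
                 slope_sd = slope_sd, evo_model = evo_model,
                 evo_params = evo_params, replicate_noise_sd = replicate_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

check_evo_params <- function(model, params) {
  if (!is.list(params)) stop("`evo_params` must be a list", call. = FALSE)
  sigma2 <- params$sigma2
  if (is.null(sigma2) || sigma2 <= 0) {
    stop("`evo_params$sigma2` must be > 0", call. = FALSE)
  }
  if (model == "lambda") {
    lam <- params$lambda
    if (is.null(lam) || lam < 0 || lam > 1) {
      stop("lambda model requires `evo_params$lambda` in [0, 1]", call. = FALSE)
    }
  }
  if (model == "ou") {
    alpha <- params$alpha
    if (is.null(alpha) || alpha <= 0) {
      stop("OU model requires `evo_params$alpha` > 0", call. = FALSE)
    }
  }
  invisible(params)
}

# Residual covariance for a simulation model, from the BM shared-path matrix.
sim_residual_cov <- function(Vbm, D, model, params) {
  switch(model,
    null = params$sigma2 * diag(nrow(Vbm)),
    brownian = params$sigma2 * Vbm,
    lambda = params$sigma2 * lambda_cov_from_parts(Vbm, params$lambda),
    ou = ou_cov_from_parts(Vbm, D, params$alpha, params$sigma2)
  )
}

#' Generate a random ultrametric phylogeny
#'
#' Pure-birth (Yule) tree with the stated number of tips, rescaled to unit
#' root-to-tip depth and relabelled `sp01`, `sp02`, ...  Unit depth makes
#' lambda and alpha comparable across simulations.
#'
#' @param n_tips Number of tips (`>= 2`).
#' @param seed RNG seed.
#' @return Rooted, ultrametric, bifurcating [ape::phylo] tree.
#' @export
gen_tree <- function(n_tips, seed = 1L) {
  n_tips <- check_count(n_tips, "n_tips", 2L)
  with_seed(seed, {
    tree <- if (n_tips == 2L) {
      ape::read.tree(text = "(sp01:1,sp02:1);")
    } else {
      ape::rphylo(n_tips, birth = 1, death = 0)
    }
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth
    tree$tip.label <- sprintf("sp%02d", seq_len(n_tips))
    tree
  })
}

#' Generate life-history traits on a phylogeny
#'
#' Adult weight (AW, grams) is drawn log-uniformly over 10 g to 20 kg, the
#' body-mass range of the small mammals the screen targets.  Maximum
#' lifespan (ML, years) and female time to maturity (FTM, days) follow the
#' allometric expectations `4.88 * AW^0.153` and `78.1 * AW^0.217`
#' multiplied by `exp(eps)` where `eps` is a Brownian deviate on the tree,
#' so longevity residuals carry phylogenetic signal.  The two deviates are
#' correlated (`trait_cor`) because ML and FTM track each other in real
#' life-history tables.
#'
#' @param tree Rooted ultrametric tree from [gen_tree()].
#' @param seed RNG seed.
#' @param bm_sd Standard deviation of the Brownian deviate at unit depth
#'   (natural-log scale).
#' @param trait_cor Correlation between the ML and FTM deviates.
#' @return Data frame with columns `species`, `AW`, `ML`, `FTM`, `MLres`,
#'   `FTMres`.
#' @export
gen_traits <- function(tree, seed = 1L, bm_sd = 0.5, trait_cor = 0.85) {
  check_phylo(tree, rooted = TRUE)
  n <- length(tree$tip.label)
  if (n < 2) stop("tree must have >= 2 tips", call. = FALSE)
  V <- ape::vcv(tree)
  U <- chol(V + diag(1e-12, n))
  with_seed(seed, {
    AW <- 10^runif(n, log10(10), log10(20000))
    z1 <- crossprod(U, rnorm(n))[, 1]
    z2 <- crossprod(U, rnorm(n))[, 1]
    eps_ml <- bm_sd * z1
    eps_ftm <- bm_sd * (trait_cor * z1 + sqrt(1 - trait_cor^2) * z2)
    species <- rownames(V)
    ML <- 4.88 * AW^0.153 * exp(eps_ml)
    FTM <- 78.1 * AW^0.217 * exp(eps_ftm)
    data.frame(species = species, AW = AW, ML = ML, FTM = FTM,
               MLres = compute_mlres(ML, AW),
               FTMres = compute_ftmres(FTM, AW),
               row.names = NULL)
  })
}

#' Generate an expression matrix with planted trait associations
#'
#' For a fraction of features, values follow
#' `y = a + b * log10(trait) + eta` with `eta` multivariate normal under the
#' configured trait-evolution model; the remaining features have slope zero.
#' Optional within-species replicates add i.i.d. normal noise on the log10
#' scale.  The returned truth table records every feature's true slope, so
#' downstream recall and false-positive rates can be scored.
#'
#' @param tree Tree whose tips are the species.
#' @param trait Named positive vector of trait values per tip.
#' @param config A [sim_config()].
#' @param n_replicates Samples per species.
#' @return List with `matrix` (an [omics_matrix], samples named
#'   `<species>_r<k>`) and `truth` (data frame `feature`, `b`).
#' @export
gen_expression <- function(tree, trait, config, n_replicates = 1L) {
  check_phylo(tree, rooted = TRUE)
  stopifnot(inherits(config, "sim_config"))
  n_replicates <- check_count(n_replicates, "n_replicates")
  species <- tree$tip.label
  if (is.null(names(trait)) || !all(species %in% names(trait))) {
    stop("`trait` must be named and cover every tip", call. = FALSE)
  }
  trait <- trait[species]
  if (any(trait <= 0)) stop("trait values must be positive", call. = FALSE)
  n <- length(species)
  Vbm <- ape::vcv(tree)
  D <- stats::cophenetic(tree)[species, species]
  V <- sim_residual_cov(Vbm, D, config$evo_model, config$evo_params)
  U <- chol(V + diag(1e-12 * mean(diag(V)), n))
  g <- config$n_genes
  n_assoc <- round(config$frac_associated * g)
  with_seed(config$seed, {
    b <- numeric(g)
    if (n_assoc > 0) {
      b[seq_len(n_assoc)] <- rnorm(n_assoc, config$slope_mean, config$slope_sd)
    }
    a <- rnorm(g)
    x <- log10(trait)
    eta <- crossprod(U, matrix(rnorm(n * g), n, g))  # n x g, cols iid MVN(0, V)
    y <- matrix(a, n, g, byrow = TRUE) + outer(x, b) + eta
    rownames(y) <- species
    feats <- sprintf("g%05d", seq_len(g))
    vals <- matrix(NA_real_, g, n * n_replicates)
    samp <- character(n * n_replicates)
    spmap <- character(n * n_replicates)
    k <- 0
    for (i in seq_len(n)) {
      for (r in seq_len(n_replicates)) {
        k <- k + 1
        noise <- if (config$replicate_noise_sd > 0) {
          rnorm(g, 0, config$replicate_noise_sd)
        } else 0
        vals[, k] <- y[i, ] + noise
        samp[k] <- sprintf("%s_r%d", species[i], r)
        spmap[k] <- species[i]
      }
    }
    dimnames(vals) <- list(feats, samp)
    list(matrix = omics_matrix(vals, species = setNames(spmap, samp),
                               provenance = "simulated"),
         truth = data.frame(feature = feats, b = b))
  })
}

#' Generate a raw count matrix
#'
#' Negative-binomial counts with gene-specific relative abundances and
#' sample library sizes, optionally planting pathological genes that the
#' count filters must remove: a gene exceeding 5% of a sample's total and
#' genes with fewer than 10 counts in four or more samples.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param lib_sizes Positive expected library sizes, length `n_samples`.
#' @param seed RNG seed.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @param abund_sd Log-scale sd of the gene relative abundances.
#' @param planted_high,planted_low Numbers of planted pathological genes
#'   (included in `n_genes`).
#' @return List with `counts` (integer matrix) and `planted` (IDs per rule).
#' @export
gen_counts <- function(n_genes, n_samples, lib_sizes, seed = 1L,
                       dispersion = 0.05, abund_sd = 1,
                       planted_high = 0L, planted_low = 0L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_samples <- check_count(n_samples, "n_samples", 2L)
  if (length(lib_sizes) != n_samples || any(lib_sizes <= 0)) {
    stop("`lib_sizes` must be positive with length n_samples", call. = FALSE)
  }
  planted_high <- check_count(planted_high, "planted_high", 0L)
  planted_low <- check_count(planted_low, "planted_low", 0L)
  n_base <- n_genes - planted_high - planted_low
  if (n_base < 1) stop("planted genes exceed n_genes", call. = FALSE)
  with_seed(seed, {
    rel <- rlnorm(n_base, 0, abund_sd)
    rel <- rel / sum(rel)
    mu <- outer(rel, lib_sizes)
    counts <- matrix(rnbinom(n_base * n_samples, mu = mu, size = 1 / dispersion),
                     n_base, n_samples)
    ids <- sprintf("gene%05d", seq_len(n_base))
    high_ids <- low_ids <- character(0)
    if (planted_low > 0) {
      low <- matrix(pmin(rpois(planted_low * n_samples, 2), 9L),
                    planted_low, n_samples)
      low_ids <- sprintf("low%03d", seq_len(planted_low))
      counts <- rbind(counts, low)
      ids <- c(ids, low_ids)
    }
    if (planted_high > 0) {
      # dominate sample 1: ~10% of its (pre-plant) total, modest elsewhere
      tot1 <- sum(counts[, 1])
      high <- matrix(rpois(planted_high * n_samples,
                           mean(lib_sizes) / n_base), planted_high, n_samples)
      high[, 1] <- round(0.10 * tot1 / planted_high)
      high_ids <- sprintf("high%03d", seq_len(planted_high))
      counts <- rbind(counts, high)
      ids <- c(ids, high_ids)
    }
    rownames(counts) <- ids
    colnames(counts) <- sprintf("s%02d", seq_len(n_samples))
    storage.mode(counts) <- "integer"
    list(counts = counts, planted = list(high = high_ids, low = low_ids))
  })
}

#' Generate a raw metabolite intensity table
#'
#' Log-normal intensities split across three acquisition modes, with a
#' per-sample multiplicative batch factor that is exactly recoverable
#' through each mode's internal-standard row, missing cells injected
#' completely at random, and optional planted metabolites with >= 10%
#' missingness that the normalization filter must drop.
#'
#' @param n_metabolites,n_samples Table dimensions.
#' @param modes Three acquisition-mode labels.
#' @param missing_rate Fraction of cells set missing at random.
#' @param seed RNG seed.
#' @param n_planted_missing Metabolites planted with >= 10% missing cells.
#' @param batch_sd Log-scale sd of the per-sample batch factor.
#' @return List with `intensities` (metabolites x samples, `NA` = missing),
#'   `intensities_nobatch` (same draws without the batch factor),
#'   `mode_map` (named character), `standards` (modes x samples matrix),
#'   `batch` (per-sample factors) and `planted_missing` (IDs).
#' @export
gen_metabolites <- function(n_metabolites, n_samples,
                            modes = c("HILIC-pos", "HILIC-neg", "C8-pos"),
                            missing_rate = 0.02, seed = 1L,
                            n_planted_missing = 0L, batch_sd = 0.3) {
  n_metabolites <- check_count(n_metabolites, "n_metabolites")
  n_samples <- check_count(n_samples, "n_samples", 2L)
  if (length(modes) != 3L) stop("`modes` must have 3 labels", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must be in [0, 1)", call. = FALSE)
  }
  n_planted_missing <- check_count(n_planted_missing, "n_planted_missing", 0L)
  with_seed(seed, {
    ids <- sprintf("met%04d", seq_len(n_metabolites))
    mode_map <- setNames(rep(modes, length.out = n_metabolites), ids)
    batch <- exp(rnorm(n_samples, 0, batch_sd))
    base <- exp(rnorm(n_metabolites, log(1e4), 1))
    noise <- matrix(exp(rnorm(n_metabolites * n_samples, 0, 0.2)),
                    n_metabolites, n_samples)
    nobatch <- base * noise
    vals <- sweep(nobatch, 2, batch, "*")
    samples <- sprintf("s%02d", seq_len(n_samples))
    dimnames(vals) <- dimnames(nobatch) <- list(ids, samples)
    miss <- matrix(runif(n_metabolites * n_samples) < missing_rate,
                   n_metabolites, n_samples)
    planted <- character(0)
    if (n_planted_missing > 0) {
      planted <- sample(ids, n_planted_missing)
      k <- max(ceiling(0.10 * n_samples), 1L)
      for (p in planted) miss[p == ids, sample.int(n_samples, k)] <- TRUE
    }
    vals[miss] <- NA_real_
    nobatch[miss] <- NA_real_
    standards <- outer(rep(1e5, 3), batch)
    dimnames(standards) <- list(modes, samples)
    list(intensities = vals, intensities_nobatch = nobatch,
         mode_map = mode_map, standards = standards, batch = batch,
         planted_missing = planted)
  })
}

#' Generate a dose-response survival table
#'
#' Survival counts are binomial with success probability
#' `pnorm(slope * (ld50 - dose))`, the probit model that [probit_ld50()]
#' estimates; at `dose = ld50` the expected survival fraction is 0.5.
#'
#' @param ld50 True median lethal dose (`> 0`).
#' @param slope Probit slope (nonzero; positive means survival falls with dose).
#' @param doses Positive dose levels.
#' @param n_per_dose Cells (trials) per dose.
#' @param seed RNG seed.
#' @return Data frame with columns `dose`, `n_survived`, `n_total`.
#' @export
gen_dose_response <- function(ld50, slope, doses, n_per_dose, seed = 1L) {
  check_positive_scalar(ld50, "ld50")
  if (!is.numeric(slope) || slope == 0) stop("`slope` must be nonzero", call. = FALSE)
  if (any(doses <= 0)) stop("`doses` must be positive", call. = FALSE)
  n_per_dose <- check_count(n_per_dose, "n_per_dose")
  with_seed(seed, {
    p <- pnorm(slope * (ld50 - doses))
    data.frame(dose = doses,
               n_survived = rbinom(length(doses), n_per_dose, p),
               n_total = rep(n_per_dose, length(doses)))
  })
}
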