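# The two-step robustness screen: for every feature x trait pair, a full
# phylogenetic regression, an outlier-removal refit (p value.robust), a
# leave-one-out sweep of the remaining species (p value.max), and BH false
# discovery rate adjustment of each p-value column within a trait.

# Fit with an exclusion set, re-selecting the evolution model each time.
# Contexts are cached per subset (keyed by the excluded species) so grid
# Cholesky factors are shared across features in a screen.
screen_fit <- function(y, x, species, exclude, ctx_cache, Vbm_full, D_full) {
  keep <- setdiff(species, exclude)
  key <- paste0("excl:", paste(exclude, collapse = ","))
  ctx <- ctx_cache[[key]]
  if (is.null(ctx)) {
    ctx <- ms_context(Vbm_full[keep, keep], D_full[keep, keep])
    ctx_cache[[key]] <- ctx
  }
  yk <- y[keep]; xk <- x[keep]
  ms_fit_models(ctx, yk - mean(yk), xk - mean(xk))
}

#' Outlier-removal step of the two-step verification
#'
#' Refits the trait regression with each single species excluded
#' (re-selecting the evolution model each time) and identifies the species
#' whose exclusion most improves the slope p-value as the potential
#' outlier.  That species is removed unconditionally -- even when no
#' exclusion beats the all-species p-value -- and the minimal leave-one-out
#' p-value is reported as `p_robust`.  Ties are broken by species-label
#' order.
#'
#' @inheritParams fit_trait_models
#' @return List with `outlier_species`, `p_robust`, `fit` (the selected
#'   refit) and `p_loo` (named vector of leave-one-out slope p-values).
#' @export
robust_step <- function(y, x, tree) {
  check_phylo(tree, rooted = TRUE)
  common <- align_species(y, x, tree$tip.label)
  if (length(common) < 5) stop("need >= 5 species", call. = FALSE)
  Vbm <- ape::vcv(tree)[common, common]
  D <- stats::cophenetic(tree)[common, common]
  cache <- new.env(parent = emptyenv())
  res <- robust_step_core(y[common], x[common], common, cache, Vbm, D)
  res
}

robust_step_core <- function(y, x, species, ctx_cache, Vbm_full, D_full) {
  p_loo <- setNames(numeric(length(species)), species)
  fits <- vector("list", length(species))
  for (i in seq_along(species)) {
    sel <- screen_fit(y, x, species, species[i], ctx_cache, Vbm_full, D_full)
    p_loo[i] <- sel$best_fit$p[2]
    fits[[i]] <- sel
  }
  i_out <- which.min(p_loo)  # first minimum = species-label order tie-break
  list(outlier_species = species[i_out], p_robust = unname(p_loo[i_out]),
       fit = fits[[i_out]], p_loo = p_loo)
}

#' Leave-one-out step of the two-step verification
#'
#' With the outlier already removed, refits the regression dropping each
#' remaining species in turn and reports the largest (least significant)
#' slope p-value, `p_max`.  A small `p_max` certifies that the association
#' does not hinge on any single species.
#'
#' @inheritParams fit_trait_models
#' @param outlier_species Species removed by [robust_step()].
#' @return List with `p_max` and `p_loo` (named vector over exclusions).
#' @export
max_step <- function(y, x, tree, outlier_species) {
  check_phylo(tree, rooted = TRUE)
  common <- align_species(y, x, tree$tip.label)
  if (!outlier_species %in% common) {
    stop("`outlier_species` not among the shared species", call. = FALSE)
  }
  if (length(common) < 6) stop("need >= 6 species so >= 4 remain per refit",
                               call. = FALSE)
  Vbm <- ape::vcv(tree)[common, common]
  D <- stats::cophenetic(tree)[common, common]
  cache <- new.env(parent = emptyenv())
  max_step_core(y[common], x[common], common, outlier_species, cache, Vbm, D)
}

max_step_core <- function(y, x, species, outlier, ctx_cache, Vbm_full, D_full) {
  rest <- setdiff(species, outlier)
  p_loo <- setNames(numeric(length(rest)), rest)
  for (i in seq_along(rest)) {
    sel <- screen_fit(y, x, species, c(outlier, rest[i]), ctx_cache,
                      Vbm_full, D_full)
    p_loo[i] <- sel$best_fit$p[2]
  }
  list(p_max = max(p_loo), p_loo = p_loo)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement, as in
#' `p.adjust(method = "BH")`, with input validation.
#'
#' @param p Vector of p-values in `[0, 1]` (`NA` allowed and propagated).
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Screen every feature against every trait with the two-step procedure
#'
#' For each feature and trait: a full-species phylogenetic regression with
#' model selection (`coef.all`, `p.value.all`), the outlier-removal step
#' (`p.value.robust`), and the leave-one-out sweep (`p.value.max`), with BH
#' q-values computed per trait across features for each p-value column.
#' Feature values are taken as already log-scaled; traits are
#' log10-transformed internally.  Per-feature fit failures are logged and
#' reported as `NA` records rather than aborting the screen.
#'
#' @param x Species-level [omics_matrix] (replicates are averaged first if a
#'   species map with replicates is present) or matrix with species columns.
#' @param traits Data frame with a `species` column and the trait columns.
#' @param tree Rooted [ape::phylo] tree.
#' @param trait_cols Trait columns to screen against.
#' @return Data frame with columns `feature`, `trait`, `coef.all`,
#'   `p.value.all`, `q.value.all`, `outlier`, `p.value.robust`,
#'   `q.value.robust`, `p.value.max`, `q.value.max`, `best.model`.
#' @export
screen_features <- function(x, traits, tree,
                            trait_cols = c("AW", "ML", "FTM", "MLres", "FTMres")) {
  check_phylo(tree, rooted = TRUE)
  om <- as_omics(x)
  if (!is.null(om$species) &&
      !identical(colnames(as.matrix(om)), unname(om$species))) {
    om <- average_replicates(om)
  }
  m <- as.matrix(om)
  missing_cols <- setdiff(trait_cols, names(traits))
  if (length(missing_cols)) {
    stop("trait table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  common <- sort(Reduce(intersect,
                        list(colnames(m), traits$species, tree$tip.label)))
  if (length(common) < 6) stop("need >= 6 species shared by matrix, traits and tree",
                               call. = FALSE)
  Vbm <- ape::vcv(tree)[common, common]
  D <- stats::cophenetic(tree)[common, common]
  features <- sort(rownames(m))
  rows <- vector("list", length(features) * length(trait_cols))
  k <- 0
  for (tr in trait_cols) {
    tvals <- setNames(traits[[tr]], traits$species)[common]
    if (any(tvals <= 0)) stop("trait values must be positive for log10", call. = FALSE)
    xv <- log10(tvals)
    ctx_cache <- new.env(parent = emptyenv())
    for (f in features) {
      k <- k + 1
      yv <- m[f, common]
      rec <- tryCatch({
        full <- screen_fit(yv, xv, common, character(0), ctx_cache, Vbm, D)
        rb <- robust_step_core(yv, xv, common, ctx_cache, Vbm, D)
        mx <- max_step_core(yv, xv, common, rb$outlier_species, ctx_cache, Vbm, D)
        data.frame(feature = f, trait = tr,
                   coef.all = unname(full$best_fit$beta[2]),
                   p.value.all = unname(full$best_fit$p[2]),
                   outlier = rb$outlier_species,
                   p.value.robust = rb$p_robust,
                   p.value.max = mx$p_max,
                   best.model = full$best,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        message(sprintf("screen: feature '%s', trait '%s' failed: %s",
                        f, tr, conditionMessage(e)))
        data.frame(feature = f, trait = tr, coef.all = NA_real_,
                   p.value.all = NA_real_, outlier = NA_character_,
                   p.value.robust = NA_real_, p.value.max = NA_real_,
                   best.model = NA_character_, stringsAsFactors = FALSE)
      })
      rows[[k]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  out$q.value.all <- NA_real_
  out$q.value.robust <- NA_real_
  out$q.value.max <- NA_real_
  for (tr in trait_cols) {
    sel <- out$trait == tr
    out$q.value.all[sel] <- bh_adjust(out$p.value.all[sel])
    out$q.value.robust[sel] <- bh_adjust(out$p.value.robust[sel])
    out$q.value.max[sel] <- bh_adjust(out$p.value.max[sel])
  }
  out[, c("feature", "trait", "coef.all", "p.value.all", "q.value.all",
          "outlier", "p.value.robust", "q.value.robust", "p.value.max",
          "q.value.max", "best.model")]
}

#' Call multi-trait top hits from screen records
#'
#' A feature is a top hit when it passes `p.value.robust < p_robust_cut` and
#' `p.value.max < p_max_cut` in at least `min_traits` longevity traits.
#' Adult weight (`AW`) is a body-mass control, not a longevity trait, and
#' never counts toward support.
#'
#' @param records Screen output from [screen_features()].
#' @param p_robust_cut,p_max_cut Significance cuts for the two steps.
#' @param min_traits Minimum number of supporting longevity traits.
#' @return Data frame with `feature`, `n_traits`, `traits`
#'   (comma-separated supporting traits) and `direction` (comma-separated
#'   slope signs, aligned with `traits`).
#' @export
call_top_hits <- function(records, p_robust_cut = 0.01, p_max_cut = 0.05,
                          min_traits = 2) {
  need <- c("feature", "trait", "coef.all", "p.value.robust", "p.value.max")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  longevity <- setdiff(unique(records$trait), "AW")
  if (!length(longevity)) stop("no longevity-trait records present", call. = FALSE)
  rec <- records[records$trait %in% longevity, , drop = FALSE]
  pass <- !is.na(rec$p.value.robust) & !is.na(rec$p.value.max) &
    rec$p.value.robust < p_robust_cut & rec$p.value.max < p_max_cut
  rec <- rec[pass, , drop = FALSE]
  if (!nrow(rec)) {
    return(data.frame(feature = character(0), n_traits = integer(0),
                      traits = character(0), direction = character(0)))
  }
  hits <- lapply(split(rec, rec$feature), function(d) {
    d <- d[order(d$trait), , drop = FALSE]
    data.frame(feature = d$feature[1], n_traits = nrow(d),
               traits = paste(d$trait, collapse = ","),
               direction = paste(ifelse(d$coef.all >= 0, "+", "-"),
                                 collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  out <- out[out$n_traits >= min_traits, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$feature), , drop = FALSE]
}
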