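# Auxiliary analyses: group-specific slope F-test with permutation
# significance (bird vs primate amino-acid levels), and probit LD50/ED50
# estimation for dose-response stress assays.

# Closed-form F for the group-slope model.  Full model: per-group intercept
# and per-group slope; reduced: per-group intercepts only.  With per-group
# centered responses, RSS_full_g = TSS_g (1 - r_g^2), so
# F = (sum_g TSS_g r_g^2 / 2) / (sum_g TSS_g (1 - r_g^2) / (n - 4)).
# Used by the permutation loop, and cross-checked against lm in tests.
group_f_stat <- function(yc_list, met_list) {
  rss_full <- 0; rss_red <- 0; n <- 0
  for (g in seq_along(yc_list)) {
    yc <- yc_list[[g]]
    mc <- met_list[[g]] - mean(met_list[[g]])
    tss <- sum(yc^2)
    sxx <- sum(mc^2)
    num <- if (sxx > 0) sum(yc * mc)^2 / sxx else 0
    rss_full <- rss_full + (tss - num)
    rss_red <- rss_red + tss
    n <- n + length(yc)
  }
  ((rss_red - rss_full) / 2) / (rss_full / (n - 4))
}

#' F-test for group-specific metabolite slopes on log lifespan
#'
#' Regresses `log(lifespan)` on a metabolite level allowing both intercept
#' and slope to differ between two groups (e.g. bird vs primate), and
#' compares against the group-intercepts-only model:
#' `F = ((RSS_reduced - RSS_full)/2) / (RSS_full/(n - 4))`.  The slope is
#' thus tested jointly across groups without assuming it is shared.
#'
#' @param lifespan Positive per-species lifespans.
#' @param metabolite Per-species metabolite levels.
#' @param group Two-level factor/character (`>= 3` species per group).
#' @return List with `F`, `slopes` (per group), `fit_full`, `fit_reduced`,
#'   and `overflow` (`TRUE` when the full model fits exactly and F is
#'   unbounded).
#' @export
group_slope_ftest <- function(lifespan, metabolite, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("`group` must have exactly 2 levels", call. = FALSE)
  if (any(table(group) < 3)) stop("need >= 3 species per group", call. = FALSE)
  if (any(lifespan <= 0)) stop("lifespans must be positive", call. = FALSE)
  y <- log(lifespan)
  full <- lm(y ~ group + group:metabolite)
  red <- lm(y ~ group)
  rss_f <- sum(residuals(full)^2)
  rss_r <- sum(residuals(red)^2)
  n <- length(y)
  overflow <- rss_f < .Machine$double.eps * rss_r
  Fstat <- if (overflow) Inf else ((rss_r - rss_f) / 2) / (rss_f / (n - 4))
  cf <- coef(full)
  slopes <- cf[grepl(":metabolite", names(cf))]
  names(slopes) <- levels(group)
  list(F = Fstat, slopes = slopes, fit_full = full, fit_reduced = red,
       overflow = overflow)
}

#' Permutation p-value for the group-slope F-test
#'
#' Builds an empirical null by permuting the metabolite values within each
#' group independently (preserving the group/lifespan structure) and
#' reports `p = (1 + #{F_b >= F_obs}) / (B + 1)`.
#'
#' @inheritParams group_slope_ftest
#' @param B Number of permutations.
#' @param seed RNG seed.
#' @return List with `p_perm`, `F_obs`, `B`, `seed`.
#' @export
permutation_pvalue <- function(lifespan, metabolite, group, B = 10000, seed = 1L) {
  B <- check_count(B, "B")
  obs <- group_slope_ftest(lifespan, metabolite, group)
  group <- as.factor(group)
  y <- log(lifespan)
  idx <- split(seq_along(y), group)
  yc_list <- lapply(idx, function(i) y[i] - mean(y[i]))
  met_list <- lapply(idx, function(i) metabolite[i])
  F_obs <- group_f_stat(yc_list, met_list)
  exceed <- with_seed(seed, {
    count <- 0L
    for (b in seq_len(B)) {
      perm <- lapply(met_list, sample)
      if (group_f_stat(yc_list, perm) >= F_obs) count <- count + 1L
    }
    count
  })
  list(p_perm = (1 + exceed) / (B + 1), F_obs = obs$F, B = B, seed = seed)
}

#' Probit LD50 / ED50 estimation from dose-response counts
#'
#' Binomial maximum-likelihood probit regression of survival on dose (or
#' log10 dose), `P(survive) = pnorm(a + b * dose)`; the median lethal dose
#' is `LD50 = -a/b`, with a delta-method standard error.  Fitted survival
#' at the LD50 is 0.5 by construction.
#'
#' @param doses Positive dose levels (`>= 3` distinct values).
#' @param survived,total Survival counts and trials per dose.
#' @param log_dose Fit on `log10(dose)` (e.g. for glucose withdrawal); the
#'   returned LD50 is back-transformed to the dose scale.
#' @return List of class `probit_fit` with `intercept`, `slope`, `ld50`,
#'   `se` (on the dose scale), `fit` (the underlying `glm`).
#' @export
probit_ld50 <- function(doses, survived, total, log_dose = FALSE) {
  if (length(unique(doses)) < 3) stop("need >= 3 distinct doses", call. = FALSE)
  if (any(doses <= 0)) stop("doses must be positive", call. = FALSE)
  if (any(survived < 0) || any(survived > total)) {
    stop("need 0 <= survived <= total", call. = FALSE)
  }
  if (all(survived == total) || all(survived == 0) ||
      length(unique(survived / total)) == 1) {
    stop("non-identifiable: all outcomes identical", call. = FALSE)
  }
  xd <- if (log_dose) log10(doses) else doses
  fit <- suppressWarnings(
    glm(cbind(survived, total - survived) ~ xd, family = binomial(link = "probit"))
  )
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  if (!fit$converged || abs(b) < 1e-12 || abs(b) > 1e6) {
    stop("non-identifiable: probit fit did not converge (separation?)",
         call. = FALSE)
  }
  xp <- -a / b
  Vc <- vcov(fit)
  grad <- c(-1 / b, a / b^2)
  se_xp <- sqrt(drop(t(grad) %*% Vc %*% grad))
  if (log_dose) {
    ld50 <- 10^xp
    se <- log(10) * ld50 * se_xp
  } else {
    ld50 <- xp
    se <- se_xp
  }
  structure(list(intercept = a, slope = b, ld50 = ld50, se = se,
                 log_dose = log_dose, fit = fit),
            class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("<probit_fit> LD50 = %.4g (SE %.3g)%s\n", x$ld50, x$se,
              if (x$log_dose) " [log10-dose fit]" else ""))
  invisible(x)
}
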