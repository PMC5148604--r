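# Allometric longevity residuals: longevity traits scale with body mass as
# c * AW^k, and the residual trait / (c * AW^k) expresses how much longer
# (or shorter) a species lives than its mass predicts.

#' Allometric scaling model
#'
#' @param c Positive scale constant.
#' @param k Exponent.
#' @return An `allometric_model` list.
#' @export
allometric_model <- function(c, k) {
  check_positive_scalar(c, "c")
  if (!is.numeric(k) || length(k) != 1L || is.na(k)) {
    stop("`k` must be a number", call. = FALSE)
  }
  structure(list(c = c, k = k), class = "allometric_model")
}

#' Body-mass-adjusted trait residual
#'
#' `compute_residual` returns `trait / (c * AW^k)`.  The wrappers fix the
#' constants for maximum lifespan, `MLres = ML / (4.88 * AW^0.153)` with ML
#' in years, and female time to maturity,
#' `FTMres = FTM / (78.1 * AW^0.217)` with FTM in days; AW is adult weight
#' in grams in both.
#'
#' @param trait Positive trait values.
#' @param AW Adult weight in grams.
#' @param model An [allometric_model()].
#' @return Positive dimensionless residuals.
#' @export
compute_residual <- function(trait, AW, model) {
  stopifnot(inherits(model, "allometric_model"))
  if (any(trait <= 0) || any(AW <= 0)) {
    stop("trait and AW must be positive", call. = FALSE)
  }
  trait / (model$c * AW^model$k)
}

#' @rdname compute_residual
#' @param ML Maximum lifespan in years.
#' @export
compute_mlres <- function(ML, AW) {
  compute_residual(ML, AW, allometric_model(4.88, 0.153))
}

#' @rdname compute_residual
#' @param FTM Female time to maturity in days.
#' @export
compute_ftmres <- function(FTM, AW) {
  compute_residual(FTM, AW, allometric_model(78.1, 0.217))
}

#' Fit an allometric power law by log-log regression
#'
#' Ordinary least squares of `log10(trait)` on `log10(AW)`; the intercept is
#' back-transformed to the scale constant `c = 10^intercept` and the slope
#' is the exponent `k`.
#'
#' @param AW Adult weights (grams), length `>= 3`.
#' @param trait Positive trait values.
#' @return An [allometric_model()] with attribute `"fit"` holding the `lm`.
#' @export
fit_allometry <- function(AW, trait) {
  if (length(AW) < 3 || length(trait) != length(AW)) {
    stop("need >= 3 paired observations", call. = FALSE)
  }
  if (any(AW <= 0) || any(trait <= 0)) {
    stop("AW and trait must be positive", call. = FALSE)
  }
  fit <- lm(log10(trait) ~ log10(AW))
  model <- allometric_model(10^unname(coef(fit)[1]), unname(coef(fit)[2]))
  attr(model, "fit") <- fit
  model
}

#' Read an AnAge-style species trait table
#'
#' Expects columns `species`, `AW_g`, `ML_yr`, `FTM_d` (adult weight in
#' grams, maximum lifespan in years, female time to maturity in days) and
#' appends the allometric residual columns.  Values far outside the ranges
#' plausible for those units trigger a warning, since unit mix-ups are the
#' most likely user error.  When a tree is supplied, species absent from its
#' tips are reported and analysis proceeds on the intersection.
#'
#' @param path CSV file path.
#' @param tree Optional [ape::phylo] tree to intersect with.
#' @return Data frame with columns `species`, `AW`, `ML`, `FTM`, `MLres`,
#'   `FTMres`.
#' @export
read_trait_csv <- function(path, tree = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "AW_g", "ML_yr", "FTM_d")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("trait table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(species = tab$species, AW = tab$AW_g, ML = tab$ML_yr,
                    FTM = tab$FTM_d, stringsAsFactors = FALSE)
  if (any(out$AW <= 0) || any(out$ML <= 0) || any(out$FTM <= 0)) {
    stop("trait values must be positive", call. = FALSE)
  }
  if (any(out$AW < 1 | out$AW > 1e8)) {
    warning("adult weights outside 1 g - 100 t; check that AW_g is in grams")
  }
  if (any(out$ML < 0.1 | out$ML > 250)) {
    warning("maximum lifespans outside 0.1 - 250 years; check that ML_yr is in years")
  }
  if (any(out$FTM < 5 | out$FTM > 2e4)) {
    warning("female time to maturity outside 5 - 20000 days; check that FTM_d is in days")
  }
  out$MLres <- compute_mlres(out$ML, out$AW)
  out$FTMres <- compute_ftmres(out$FTM, out$AW)
  if (!is.null(tree)) {
    absent <- setdiff(out$species, tree$tip.label)
    if (length(absent)) {
      message("species not in tree (dropped): ", paste(absent, collapse = ", "))
      out <- out[out$species %in% tree$tip.label, , drop = FALSE]
    }
  }
  out
}
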