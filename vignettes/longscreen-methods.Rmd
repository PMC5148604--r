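---
title: "Methods: phylogenetic screening of omics features against longevity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic screening of omics features against longevity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The regression model

Each feature (a gene's normalized expression or a metabolite's normalized
intensity, on the log10 scale) is regressed on a longevity trait, also on
the log10 scale, across species:

$$ y = \beta_0 + \beta_1 x + \varepsilon, \qquad
   \varepsilon \sim N(0,\ \sigma^2 V), $$

where $V$ is built from a rooted phylogeny with branch lengths. Both $y$
and $x$ are centered internally, so $\beta_0$ absorbs nothing of interest;
the screen's statistic is the slope $\beta_1$ and its two-sided t-test
with $n-2$ degrees of freedom, using the unbiased residual variance
$r^\top V^{-1} r/(n-2)$ for the standard error. $\sigma^2$ is profiled
analytically, so $V$ matters only up to scale. The maximized log-likelihood
is $-\tfrac n2(\log 2\pi + \log\hat\sigma^2_{ML} + 1) - \tfrac12\log|V|$
with $\hat\sigma^2_{ML} = r^\top V^{-1} r/n$.

Four covariance structures are fitted per feature-trait pair:

* **null** — $V = I$: residuals independent across species. We interpret
  "null" as the identity (ordinary least squares) rather than a
  zero-correlation Brownian variant; on the unit-depth ultrametric trees
  used throughout, the two coincide anyway, and the alternative is
  available as `lambda_covariance(tree, 0)`.
* **Brownian motion** — $V_{ij} = t_{ij}$, the root-to-MRCA shared path
  length; $V_{ii}$ is the root-to-tip depth.
* **Pagel's lambda** — off-diagonal Brownian entries multiplied by
  $\lambda \in [0,1]$, interpolating independence and full Brownian
  structure.
* **Ornstein–Uhlenbeck** — the non-stationary (Hansen) form
  $V_{ij} = \tfrac{\sigma^2}{2\alpha} e^{-\alpha d_{ij}}
  (1 - e^{-2\alpha t_{ij}})$ with the root at the optimum and zero root
  variance. We chose this form over the stationary one because it reduces
  to Brownian motion as $\alpha \to 0$, keeping the four models nested for
  likelihood comparison.

The best model is the one with the highest maximized likelihood, with no
parameter-count penalty — this mirrors the selection rule the screen is
built around; an AIC option (`aic = TRUE`) is provided but off by default.
Because the lambda and OU families each nest the simpler models, raw-ML
selection effectively grants every feature up to one free covariance
parameter, which makes the selected-model p-value mildly anti-conservative
(see *Limitations*).

## Numerical scheme

With $S = \mathrm{diag}(\sqrt{T_i})$ and $R = S^{-1} V_{BM} S^{-1}$ the
Brownian correlation matrix, the lambda family is
$V(\lambda) = S(\lambda R + (1-\lambda) I)S$. A single symmetric
eigendecomposition of $R$ per species subset therefore turns every lambda
evaluation — and the null and Brownian endpoints — into $O(n)$ weighted
least squares on rotated coordinates; this is an exact reparameterization
(verified against explicit-covariance fits to $10^{-14}$), not an
approximation. OU covariances are not simultaneously diagonalizable in
$\alpha$, so they go through Cholesky factors memoised per grid point.

Profile optimization uses a coarse grid followed by Brent refinement
inside the bracketing interval: $\lambda$ on a 21-point grid over
$[0,1]$, tolerance $10^{-6}$; $\alpha$ on a 25-point log-spaced grid over
$[10^{-4}, 50]$ divided by mean tree depth, tolerance $10^{-4}$ on
$\log\alpha$ (parameter precision far below statistical noise, chosen to
keep large screens fast). Profile likelihoods can be multimodal, which is
why the grid precedes the local search. Ties in model selection resolve
to the simpler model (evaluation order null, Brownian, lambda, OU);
eigenvalues are floored at $10^{-12}$ and a residual sum of squares of
exactly zero yields the minimum representable p-value rather than zero.

# The two-step verification

Associations across 10–20 species are fragile: one species can carry an
apparent trend. The screen therefore reports, per feature and trait:

1. **p value.all** — the slope p-value using all species, under the
   selected model.
2. **p value.robust** — every single-species exclusion is refitted (with
   the evolution model re-selected each time); the exclusion that most
   improves the slope p-value marks the *potential outlier*, which is
   removed unconditionally, and the refit p-value is reported. We remove
   unconditionally — even when no exclusion improves on the all-species
   fit — because conditioning removal on improvement would make the
   statistic's definition data-dependent in a way that is hard to reason
   about; ties in the argmin resolve by species-label order.
3. **p value.max** — with the outlier removed, each remaining species is
   excluded in turn and the *largest* refit p-value is reported: a small
   value certifies the association does not hinge on any single species.

Re-selecting the model inside every refit (rather than freezing the
all-species choice) is the conservative reading of a per-pair "best-fit
covariance"; exclusion refits use submatrices of the full-tree shared-path
and patristic matrices, which exactly preserves the covariance structure
among retained species without re-estimating branch lengths.

Benjamini–Hochberg q-values are computed per trait across features for
each of the three p-value columns. Top hits require
`p.value.robust < 0.01` and `p.value.max < 0.05`; multi-trait hits
additionally require support in at least two longevity traits (ML, FTM,
MLres, FTMres — adult weight is a body-mass control and never counts).
The screen needs at least six shared species so that four remain in every
second-step refit.

# Upstream processing

* **Count filtering.** Features holding more than 5% of any single
  sample's total (the rule is applied per sample, the stricter reading of
  an ambiguous phrasing) or having fewer than 10 counts in four or more
  samples are removed in a single pass against the current totals.
* **TMM scale factors.** Reference sample: 75th-percentile count fraction
  closest to the mean of those. Per sample, log2 ratios of proportions
  (M) and average log2 proportions (A) over genes nonzero in both are
  rank-trimmed 30% (M) and 5% (A) from each tail — the method's standard
  defaults — and combined by inverse-delta-method-variance weights;
  factors are rescaled to unit product. The implementation is our own
  because the exact reference choice, trimming and rescaling conventions
  are part of the contract; it agrees with `edgeR::calcNormFactors` to
  $10^{-6}$ and with an independently coded brute-force oracle to
  $10^{-10}$ in the tests.
* **log10 + quantile normalization.** Counts become CPM with effective
  library sizes (total × factor), with an optional +0.5 pseudo-offset for
  zeros, then log10; quantile normalization maps every column onto the
  mean sorted profile, ties receiving the mean of the reference quantiles
  they span. Masked (missing) cells are excluded from the quantile pools
  and stay masked — with complete data the procedure reduces exactly to
  mean-of-sorted-columns (and matches `limma::normalizeQuantiles`).
* **Metabolites.** Per acquisition mode (three modes), intensities are
  divided by the sample's internal standard and then by the sample's
  within-mode total — both purely multiplicative, so batch factors cancel
  exactly; metabolites with ≥10% missing values are dropped before
  log10 + quantile normalization.
* **Phylograms.** Neighbor joining (Studier–Keppler criterion, ties by
  smallest index pair; negative branch estimates clamped to zero with the
  deficit moved to the sibling so pair distances are preserved) on
  1 − Pearson distances between samples; bootstrap resamples features
  (the tree's taxa are the samples), and support is the fraction of
  replicates containing each bipartition.

Allometric residuals use `trait/(c·AW^k)` with the fixed constants
(4.88, 0.153) for maximum lifespan in years and (78.1, 0.217) for female
time to maturity in days, AW in grams; `fit_allometry()` re-estimates
such constants by log10–log10 least squares. Unit mix-ups being the most
likely user error, the CSV reader warns on values outside plausible
ranges for those units.

# Auxiliary analyses

The bird/primate amino-acid analysis fits
$\log(\mathrm{ML}) \sim$ group intercepts + group-specific metabolite
slopes against the group-intercepts-only reduction,
$F = \frac{(RSS_{red} - RSS_{full})/2}{RSS_{full}/(n-4)}$, and assesses
significance by permutation: metabolite values are shuffled within each
group independently (preserving the group/lifespan structure — the
scheme is our choice where the procedure was underspecified), with
$p = (1 + \#\{F_b \ge F_{obs}\})/(B+1)$ and $B = 10{,}000$ by default.
Natural log is used for lifespan; the base only rescales coefficients,
never $F$.

Dose-response resistance data are fitted by binomial maximum-likelihood
probit regression of survival on dose, LD50 $= -a/b$ with a delta-method
standard error. Linear dose is the default (stress agents); a log10-dose
flag covers glucose-withdrawal-style designs, back-transforming the LD50
to the dose scale. Complete separation and all-identical outcomes are
rejected as non-identifiable.

Enrichment uses the upper-tail hypergeometric probability $P(X \ge k)$
for annotation sets intersected with the universe and size-filtered to
[5, 99] members, with the sample odds ratio
$k(N-K-n+k)/((n-k)(K-k))$ and expected count $nK/N$; two-set overlap uses
Fisher's exact two-sided p (sum of tables at most as probable) with the
sample odds ratio. External pathway services are out of scope; users
supply GMT files.

# What the generators emulate

The synthetic-data module produces: unit-depth pure-birth trees (unit
depth makes $\lambda$ and $\alpha$ comparable across simulations); adult
weights log-uniform over 10 g–20 kg with lifespan and maturity following
the allometric expectations times a Brownian deviate on the tree
(sd 0.5 at unit depth, the two traits' deviates correlated at 0.85 —
values chosen once to give realistic residual spreads and the strong
ML–FTM association seen in real life-history tables); expression matrices
with planted slopes against log10 trait and residuals drawn from any of
the four covariance models, plus optional i.i.d. within-species replicate
noise on the log10 scale (default sd 0.05; real replicate variation is
not i.i.d., see below); negative-binomial count matrices with plantable
filter violations; log-normal metabolite tables with three modes,
internal-standard rows that encode the per-sample batch factor exactly,
and missing cells; and binomial dose-response tables under the same
probit model the estimator assumes. Truth tables record every planted
slope so recall and false-positive rates can be scored without reading
generator internals. All generators are bit-reproducible given a seed
(Mersenne-Twister, inversion normals, pinned explicitly).

What they deliberately do not emulate: read-level sequencing artifacts,
ortholog-calling errors, mass-spectrometry peak extraction,
non-multiplicative batch effects, and structured (non-i.i.d.) replicate
variation. Passing tests on these data therefore certify the statistical
machinery, not robustness to upstream artifacts in real datasets.

# Calibration findings and limitations

Simulation sizes used by the test suite and the acceptance script —
2,000 null features on 15-tip trees for calibration, 500 features at 50
tips for parameter recovery, 500 null metabolites at $B = 1000$ for the
permutation test, 200 simulated assays for LD50 — were chosen to make
Monte-Carlo error small relative to the effects examined while keeping a
full run on one CPU in minutes.

Three findings from those calibrations are worth knowing before applying
the screen:

* **Under the true model the machinery is exact.** Slope p-values under
  the generating covariance model are uniform (Kolmogorov–Smirnov), the
  type-I rate sits at the nominal level, estimates match naive
  explicit-inverse oracles to $10^{-8}$, and planted slopes are recovered
  essentially unbiasedly.
* **Model selection is anti-conservative, more so on some trees.**
  Selecting the covariance by raw maximum likelihood and then quoting the
  selected model's p-value inflates the type-I rate from the nominal 5%
  to roughly 4–8% depending on the tree realization; trees with
  near-zero-length cherries are the worst case. The min-over-exclusions
  *p value.robust* inflates further by construction (its null rate at the
  0.01 cut ranges from ~2% to ~8% across trees), and the *p value.max*
  condition only partly restores stringency. Interpret the dual
  threshold as a robustness filter, not as a calibrated significance
  level, and rely on the BH q-values (computed from the realized p-value
  distribution) for error-rate statements.
* **Measurement noise breaks the Brownian model where branches are
  short.** Adding even small i.i.d. within-species noise on top of
  phylogenetic residuals inflates significance sharply when sister
  species are separated by tiny branch lengths, because GLS whitening
  amplifies exactly those contrasts. With two replicates and noise sd
  0.05 the demo screen's null false-positive rate at the dual threshold
  is about 8% while recall of planted effects stays at 100%. A
  measurement-error (within-species variance) model is a known omission;
  replicate averaging reduces but does not remove the effect.

Other limitations: no REML (variance estimates are ML/unbiased-hybrid as
described), no multivariate-response models, no effect-size shrinkage, no
permutation-based FDR for the screen, and profile-ML $\hat\lambda$
carries tree-dependent finite-sample bias at interior values of
$\lambda$ (median bias up to ~0.1 at 50 tips in our calibrations).
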