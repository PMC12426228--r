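---
title: "Methods: multidimensional social exposome modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multidimensional social exposome modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msexposome)
```

This vignette documents the statistical model, parameter conventions,
numerical choices and known limitations of the package. It states no
empirical result that the test suite does not itself compute.

## The construct and the scoring model

The multidimensional social exposome (MSE) summarizes lifetime social
adversity over ten dimensions: education, food insecurity, financial status,
assets, access to healthcare, childhood labor, subjective socioeconomic
status, childhood experiences, traumatic events, and relationships.
Questionnaire items (mixed formats: binary, Likert, counts, continuous) map
each to exactly one dimension.

**Direction convention.** After scaling, *higher values mean less
adversity*. Items whose raw value increases with adversity carry polarity
`adversity_high` and are flipped during min–max scaling. The opposite coding
circulates in parts of the literature; we adopt the convention under which
the structural path toward cognition is positive, and expose it as the
`higher_is_less_adverse` attribute rather than hard-wiring an
interpretation. Functional-ability and neuropsychiatric instruments, whose
raw scores increase with impairment, are inverted
(`invert_outcome`, an involution) so all outcomes read "higher = better".

**Scaling and averaging.** Each item is min–max scaled to [0, 1] over its
observed values — making composites invariant to affine recodings of native
scales — and items are averaged within dimension. Weights default to equal;
a per-item weight vector (nonnegative, normalized within dimension) is
accepted because "weighted averages" may legitimately differ by instrument
revision. Constant items carry no information and are dropped with a warning
instead of failing a whole pipeline; items flagged as dementia-confounded
(e.g. smartphone use, current employment or salary) are excluded through
`item_meta(excluded = TRUE)`.

**Imputation.** Missing items (up to ~20% in the motivating application) are
imputed before modelling by chained equations with predictive mean matching:
visit items in ascending missingness, regress observed values on the other
(currently completed) items by ridge-stabilized least squares (ridge 1e-6 on
standardized predictors, purely for collinearity protection), and replace
each missing cell by the observed value of one of `k_donors = 5` donors with
the closest predictions, over `n_iterations = 10` passes. These defaults are
conventional chained-equations practice; the matching is type-0
(deterministic predictions, stochastic donor draw), so imputed values never
leave an item's observed support and a fixed seed gives identical output.
For very wide questionnaires, `predictors = "dimension_means"` reduces each
regression to the nine other dimension means.

## The structural equation model

Ten composites $x_1,\dots,x_{10}$ are indicators of one latent factor
$\eta$; three outcomes are regressed on it:

$$x_j = \lambda_j \eta + \varepsilon_j, \qquad
  y_k = \beta_k \eta + \zeta_k .$$

Identification fixes the loading of *access to healthcare* at 1 (the
conventional fixed-indicator choice for this instrument); the latent
variance $\psi$ is free. The implied covariance is built in RAM form
$\Sigma = M S_0 M^\top$ with $M = [ (I-A)^{-1} ]_{\text{obs},\cdot}$, which
also accommodates sensitivity models where exogenous covariates (age, sex,
disease severity, onset, subtype) predict both $\eta$ and every outcome with
a saturated covariate block, and selected residual covariances freed under
guidance of the top modification index.

**Estimation.** Maximum Wishart likelihood: minimize
$F(\theta)=\log|\Sigma(\theta)|+\mathrm{tr}(S\Sigma^{-1})-\log|S|-p$ with
analytic derivatives $\partial F = \mathrm{tr}[(\Sigma^{-1}-\Sigma^{-1}S\Sigma^{-1})\,
\partial\Sigma]$, by `nlminb` (relative tolerance 1e-12, 10⁴ iteration cap)
from principal-axis starting values, followed by a Newton polish on the
expected information until the gradient ∞-norm is below 1e-5 (the
convergence criterion; fits above it are flagged, and bootstrap replicates
so flagged are excluded and counted). Covariances use the $n-1$ denominator
and $\chi^2=(n-1)F$ (the classical normal-theory convention); the same
$n-1$ enters RMSEA. The baseline model is independence (free variances,
zero covariances).

**Fit indices.** CFI $=1-\max(\chi^2_m-df_m,0)/\max(\chi^2_b-df_b,
\chi^2_m-df_m,0)$; TLI from the $\chi^2/df$ ratios (undefined, with a flag,
when $\chi^2_b \le df_b$); RMSEA $=\sqrt{\max(\chi^2_m-df_m,0)/(df_m(n-1))}$;
SRMR as the root mean square of standardized residual covariances over all
$p(p+1)/2$ unique elements, diagonal included. These closed forms are tested
exactly.

**Standardization and uncertainty.** The standardized solution scales by
model-implied standard deviations ($\lambda^\*_j=\lambda_j\,
\mathrm{sd}(\eta)/\mathrm{sd}(x_j)$). Standard errors come from the inverse
expected information, $\mathrm{cov}(\hat\theta) = \tfrac{2}{n-1}H^{-1}$ with
$H_{ab}=\mathrm{tr}(\Sigma^{-1}\Delta_a\Sigma^{-1}\Delta_b)$; standardized
SEs use the simple delta scaling by the same factor as the point estimate,
ignoring the sampling variability of the standard deviations themselves.
One visible consequence: the fixed indicator's standardized loading is
reported with a zero-width interval. Percentile bootstrap intervals
(`bootstrap_sem`) are the recommended uncertainty summary for paths.

**Heywood cases.** Negative residual variances are admissible for the
optimizer and *flagged*, never silently clipped; `bound_variances = TRUE`
imposes nonnegativity when a bounded solution is explicitly wanted.

**Parameter count.** The default model has q = 26 free parameters (9 free
loadings, 3 paths, 13 residual variances, 1 latent variance), df = 91 − 26
= 65. Published analyses of this design sometimes quote a much smaller q
from counting only substantive coefficients; the engine reports its true
count.

**Modification indices** are score tests: with the gradient $g$ and expected
information $H$ on the parameter set augmented by the candidate,
$\mathrm{MI}=\tfrac{n-1}{2}\,g^\top H^{-1} g$, approximating the χ² drop
from freeing the candidate (verified against realized drops in tests).

**Factor scores.** Regression scores $E[\eta\,|\,z]=\mathrm{Cov}(\eta,z)
\Sigma^{-1}(z-\bar z)$ under the fitted Gaussian model (valid with
covariates too); Bartlett scores for covariate-free models. For a one-factor
model the two are affine transforms of each other, so their correlation is
essentially 1.

## Cumulative vs. individual predictors

The comparison pairs, per bootstrap replicate on the *same* resampled
subjects, (i) the SEM standardized path of the latent toward an outcome with
(ii) the in-sample R² of a Lasso of that outcome on the ten dimensions.
These are different effect-size scales; the package reproduces that pairing
deliberately because it is the published design, and the vignette flags the
commensurability caveat rather than resolving it.

Lasso: objective $(1/2n)\lVert y - b_0 - Xb\rVert^2+\lambda\lVert b\rVert_1$
on standardized predictors, solved by covariance-form cyclic coordinate
descent to a 1e-12 coordinate tolerance (KKT residuals ~1e-10, certified by
`lasso_kkt_residual`). $\lambda$ is chosen by 10-fold CV over a 100-point
log grid spanning four decades below $\lambda_{\max}=\max_j |x_j^\top
(y-\bar y)|/n$. Outcomes and predictors are min–max scaled to [0, 1] first,
matching the scoring convention (this is what makes MAE values of ~0.1
interpretable). Within the bootstrap the full-sample CV-selected $\lambda$
is reused per replicate — re-running CV 400 times adds noise and an order of
magnitude of runtime without changing the comparison; `reselect_lambda =
TRUE` restores per-replicate selection. Metrics are in-sample (R², Cohen's
f² = R²/(1−R²), MnSqErr, MAE), flagged as such.

Meta-regression: each arm's draws are pooled with a common per-replicate
variance equal to the arm's empirical bootstrap variance, making the common
effect the arithmetic mean with SE $\sqrt{v/B}$, and the model-type
moderator tested by the 1-df Wald statistic
$Q_M=(\bar e_1-\bar e_2)^2/(v_1/B_1+v_2/B_2)$. The weighting choice is
isolated behind `weighting = "equal"` because the published analysis does
not state its weights; with constant within-arm variances the two pooled
estimates coincide (tested to 1e-10). Fixed-effect only; random-effects
pooling is out of scope.

## Connectivity and quality control

Edge-wise OLS regresses each Fisher-z edge on the MSE score with age, sex
and scanner as covariates of no interest, vectorized over edges through one
shared design decomposition. FDR control follows the per-ROI convention:
Benjamini–Hochberg within each ROI's row of $p-1$ p-values, then
union-symmetrization of the row decisions (a global-BH alternative sits
behind `method = "global"`). Degree centrality binarizes the mask — each
significant edge, positive or negative, adds 1 to both endpoints — with an
optional sign split. Calibration tests measure the row-family FDR on the
pre-symmetrization decisions (`symmetrize = FALSE`), the quantity the
step-up procedure actually controls.

Scrubbing flags frames with framewise displacement > 0.2 mm or
global-signal |z| > 5. Exactly 70% artifact-free frames is *retained*: the
exclusion rule is "less than 70%", and the boundary case is kept. The
alternative published phrasing of the scrubbing criterion ("temporal
derivative variance across space > 5%") is noted but the z-score formulation
is the one implemented. Temporal SNR is computed per non-overlapping
20-frame segment as mean/SD, with zero-variance segments returned as NA with
a flag rather than an arbitrary value.

## The synthetic world

The generators state one world and the tests live in it; none of its
parameters were tuned against test outcomes.

* Group sizes default to HC 1175 / AD 781 / FTLD 255 and demographics to the
  published group means/SDs for age and sex ratios.
* Dimension loadings default to the five published whole-sample loadings
  (0.732, 0.702, 0.694, 0.649, 0.506) and, for the five dimensions whose
  loadings are not printed, to values (0.45, 0.45, 0.40, 0.17, 0.12) fixed
  once, consistent with the printed significance ordering (traumatic events
  and relationships weakest). Structural paths default to 0.261 / 0.079 /
  0.105.
* Items are emitted on heterogeneous native scales (continuous, Likert 0–4,
  binary, counts) through monotone maps of $\lambda_d\eta+$noise, with
  alternating polarity, to exercise scaling; item noise SD defaults to 0.6.
* Outcomes are generated on the raw instrument scale per group (published
  group means/SDs) and truncated to instrument bounds, which reproduces the
  healthy-control floor on functional ability (a documented phenomenon of
  these instruments) rather than injecting it by fiat.
* Latent group means (0, −0.2, −0.2) are a modeling choice: adversity is
  plausibly slightly higher in patient groups, and nothing downstream
  depends on it because all modelling is within-group or adjusts for group.
* Missingness is MCAR or MAR-on-age (logistic in age, intercept calibrated
  to the target rate); connectome edges are Gaussian noise plus specified
  linear exposure/covariate effects; motion traces have sub-threshold
  baselines with exact spikes.
* One integer seed fans out deterministically into per-stage substreams, so
  e.g. regenerating items does not perturb the missingness mask.

What a green test does **not** establish: realism of item marginals (the
instrument's per-item distributions are not public), cross-country
heterogeneity, non-linear exposure effects, or spatial structure in
connectomes beyond single edges. The generators emulate the *statistical
skeleton* the methods assume — a single latent with linear effects — so
pipeline correctness, not biological fidelity, is what the tests certify.

## Numerical and design decisions, collected

* Covariance denominator $n-1$ everywhere; χ² = (n−1)F; RMSEA uses n−1.
* Fixed indicator: access to healthcare; χ² is invariant to this choice
  (tested to 1e-4).
* Optimizer tolerances: `nlminb` rel.tol 1e-12; Newton polish to gradient
  ∞-norm < 1e-5; restart from jittered starts if the first solve stalls.
* Lasso coordinate tolerance 1e-12; KKT certified < 1e-6 at acceptance.
* PMM: k = 5 donors, 10 iterations, ascending-missingness visit order,
  type-0 matching.
* Ties in donor matching break by donor order; the donor among the k
  nearest is drawn uniformly.
* Constant items: dropped with warning (scoring); constant features within
  a group: left unscaled with warning (harmonization rescale).
* BH row correction with union symmetrization; global variant behind a
  flag; FDR monotone in q (tested).
* Degree counts both signs by default, split available.
* The 70% retention boundary is inclusive.

## Known limitations

* No mean structure: models are covariance-only; factor scores center at
  sample means.
* No FIML for missing data (impute first), no ordinal/WLSMV estimation, no
  multi-group SEM with equality constraints, no random-effects
  meta-analysis.
* Standardized SEs ignore variance-of-variance terms; use the bootstrap for
  honest path intervals.
* The global-β vs. Lasso-R² comparison inherits the scale-mismatch caveat
  of its published design.
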