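---
title: "Methods: comparative seed longevity under controlled ageing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative seed longevity under controlled ageing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedspan)
```

This vignette is the package's own account of its models, the parameters
that matter, what the synthetic generator does and does not emulate, and
the design choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The viability model and p50

Controlled ageing stores a seed lot warm and moist (the assay the package
targets uses 45 °C and 60 % eRH) and withdraws samples on a schedule for
germination testing. The survival model is the classical viability
equation: seed deaths are normally distributed in time, so viability in
normal equivalent deviates (NED) declines linearly,

$$v(p) = K_i - p/\sigma ,$$

with $K_i$ the initial viability (NED) and $\sigma$ (days per NED) the
standard deviation of death times. The germinating fraction at withdrawal
time $p$ is $\Phi(K_i - p/\sigma)$.

**Fitting.** `fit_probit()` maximizes the binomial likelihood with this
success probability — exactly probit regression of germinated/tested on
time (intercept $K_i$, slope $-1/\sigma$), solved by IRLS. We chose
binomial ML over the older transform-then-regress route because 0 % and
100 % withdrawals map to infinite NEDs; the NED regression with the
$(r+0.5)/(n+1)$ correction is still available as `fit_probit_ned()` for
cross-checking, clearly flagged secondary. The test suite holds the
optimizer to an exhaustive grid search over $(K_i, \sigma)$ (step 0.01 ×
0.5, refined once 10× finer) within 0.005 log-likelihood units.

**p50 definition.** p50 is the time at which viability reaches 50 % *of
its initial fitted value*:

$$p_{50} = \sigma\,\bigl(K_i - \Phi^{-1}(\Phi(K_i)/2)\bigr),$$

which stays defined when initial viability is below 100 %. Note the
direction of the difference from the absolute definition
$p_{50}^{abs} = K_i\sigma$: half of a sub-100 % start is a level *below*
absolute 50 %, so $p_{50} \ge p_{50}^{abs}$, converging from above as
$K_i \to \infty$. (An early draft of the package contract asserted the
opposite inequality; the closed form and its own worked examples settle
the direction, and the tests assert it.)

**Standard errors** are delta-method through the analytic gradient of
$p_{50}(K_i, \sigma)$ on the GLM's observed-information covariance. A
1000-replicate Monte Carlo in the tests confirms the reported SE tracks
the empirical spread within 20 %.

**Degenerate data.** No decline information (flat curves), complete
separation, or fewer than three informative withdrawals yield
`degenerate = TRUE` with an unreliable SE rather than an error — mirroring
real studies, where hard-seeded species can return enormous SEs. Curves
whose p50 lies beyond the last withdrawal are extrapolated and flagged
`censored = TRUE`.

**The logistic alternative.** `fit_logistic()` fits
$G(t) = (100-\alpha)/(1+e^{\beta(t-c)})$ by the same binomial likelihood.
The curve is implemented in its *declining* orientation (exponent
$+\beta(t-c)$, $\beta > 0$): a survival curve must fall, and the
rising-sign variant sometimes printed for this family of models appears
typographical. Its p50 is the midpoint $c$ by construction. `compare_fits()`
selects by AIC with ties to probit, the convention of the analysis this
package reimplements (probit won for every species there).

## 2. Trees, dating and covariance

Without a resolved dated phylogeny, `build_taxonomy_tree()` makes the
standard stand-in: a rooted tree with a polytomy of orders at the root,
families within orders, genus nodes for congeners, species as tips.
`bladj_adjust()` dates it: named nodes take ages from a table; every other
node is placed by even interpolation between its nearest dated ancestor
and nearest dated descendant (fewest intervening edges; age ties broken
towards the older candidate to avoid inversions), processed root-to-tip so
that placements are mutually consistent. The result is ultrametric with
depth equal to the root age, which the tests check to 1e-9.

The packaged age table is deliberately named
`node_ages_synthetic.csv`: it is a constructed stand-in with plausible
crown-age magnitudes for the 13 orders and 18 families of the fixture, not
a published calibration (which cannot be redistributed). Analyses on this
tree are therefore *qualitatively* comparable to published results —
signs, significance, boundary behaviour — not numerically identical, and
the acceptance suite only holds fixed-tree statistics to that standard.
Users with a real calibration substitute their own CSV.

`phylo_covariance()` returns the matrix of shared root-to-MRCA path
lengths (single-child nodes collapsed first; zero-length terminal branches
perturbed by 1e-6 Myr with a warning to keep V invertible — relevant for
same-age congeners in polytomous genus nodes). `lambda_transform()`
multiplies off-diagonals by λ. Polytomies need no special handling in this
formulation, which is why all downstream statistics work on V rather than
on contrasts.

## 3. Signal statistics

**Pagel's λ** is ML over $[0,1]$ of the multivariate normal likelihood
with mean $\mu\mathbf{1}$ and covariance $\sigma^2 V(\lambda)$; $\mu$
(GLS mean) and $\sigma^2$ (ML variance $e'V^{-1}e/n$) are profiled
analytically and λ found by bounded scalar search (tolerance 1e-6).
Boundary optima are reported exactly at 0 or 1 — published tables print
exactly those values, and the LRT p-values against λ = 0 and λ = 1 use
$\chi^2_1$. Calibration (in the acceptance tests): Brownian traits on a
200-tip tree give mean $\hat\lambda \ge 0.9$; shuffled traits give median
$\hat\lambda < 0.1$.

**Blomberg's K** follows the original construction:
$K = (\mathrm{MSE}_0/\mathrm{MSE}) / E[\mathrm{MSE}_0/\mathrm{MSE}]_{BM}$
with $\mathrm{MSE}_0$ the tip deviation from the phylogenetically weighted
mean $\hat a = (\mathbf{1}'V^{-1}y)/(\mathbf{1}'V^{-1}\mathbf{1})$,
$\mathrm{MSE}$ the GLS residual mean square, and the Brownian expectation
$[\mathrm{tr}(V) - n/\mathbf{1}'V^{-1}\mathbf{1}]/(n-1)$. Significance
shuffles tip values and counts shuffles with MSE at most the observed —
the randomization is on MSE, not on K itself, again following the original
test. K is affine-invariant in the trait (tested exactly).

**Fritz–Purvis' D** for binary traits estimates nodal values by daughter
averaging (post-order means, polytomy-safe) and sums absolute changes
along every branch to get $d_{obs}$, then scales it between the mean $d$
of prevalence-preserving tip shuffles (D = 1) and of Brownian liabilities
thresholded by rank to the observed prevalence (D = 0):

$$D = \frac{d_{obs} - \bar d_{BM}}{\bar d_{rand} - \bar d_{BM}}.$$

The rank threshold matches prevalence exactly — the standard construction
where the method's description leaves the rule open. One-sided p-values
follow the usual orientation: `p_vs_star` = fraction of shuffles with
$d \le d_{obs}$, `p_vs_brownian` = fraction of Brownian simulations with
$d \ge d_{obs}$. All permutation p-values are bit-reproducible under a
fixed seed, and the seeded sections restore the caller's RNG stream. On
the packaged fixture, endosperm presence and physical dormancy come out
strongly conserved (D < 0, p vs star < 0.01), matching the published
signs.

## 4. Candidate models, AICc and averaging

The analysis matrix holds log₁₀ p50 (all continuous traits are
log₁₀-transformed toward normality; the ANOVAs below run on this scale,
while group means are reported in raw days) and six predictors: seed shape
variance $V_S$ (population variance, divisor $n=3$, of the three seed
dimensions scaled by the longest — 0 for spheres, at most 2/9), seed mass,
seed-coat thickness, and indicators for endosperm absence, physical and
physiological dormancy. Rows missing a required predictor are dropped per
model and recorded on the fit.

`fit_candidate_set()` fits the fixed ten-model set (full model, six
single-trait models, coat+PY, shape+mass, null) by ML — never REML, so
log-likelihoods are comparable across fixed-effect structures — as GLS or
as PGLS with per-model ML λ. AICc is
$-2\ell + 2K + 2K(K+1)/(n-K-1)$ with $K$ = coefficients + residual
variance (+1 when λ is estimated). This one consistent counting rule is
kept even though the published table this mirrors appears not to count λ
in its phylogenetic block; with it, our phylogenetic K values are one
higher than those printed, which shifts AICc by a constant within the
block and leaves rankings and weights essentially unchanged. Coefficient
SEs use the unbiased residual variance $RSS/(n-p)$, the convention of
standard GLS software, while the likelihood itself is ML.

`model_average()` is *full* averaging: every coefficient is averaged over
all models with 0 where absent (the published coefficient table reports
every term although most candidates lack it, which identifies the
full-average convention), with unconditional SE
$\sqrt{\sum_i w_i (se_i^2 + (b_i - \bar b)^2)}$ and two-sided normal
p-values on $z = |\hat\beta|/SE$. Conditional averaging is not offered; a
user can filter the fit list and renormalize weights if they want it.

## 5. The synthetic generator: what it emulates

`gen_study()` emulates the stated study world, and its defaults are fixed
rather than tunable knobs:

| Parameter | Default | Why |
|---|---|---|
| schedule | 0–210 d, step 15 | the emulated experiment ended at day 210 |
| n per withdrawal | 50 | the assay's sample size |
| $K_i$ | 2.054 NED | ≈98 % initial viability ("nearly 100 %" lots) |
| species | 39; 25 non-endospermic, 7 PY, 12 PD | fixture composition |
| effects on log₁₀ p50 | +0.33 / +0.47 / −0.33 | published averaged-coefficient magnitudes |
| intercept | 1.05 | published averaged intercept |
| residual tip SD | 0.24 | back-solved from the published full-model logLik (0.60 at n = 35) |
| residual λ | 0.5 | open choice: between the full-model residual λ = 0 and the marginal p50 λ ≈ 0.74; an intermediate value keeps both GLS and PGLS stages honestly challenged |
| tree | taxonomy-shaped, root 160 Myr | same construction as the analysis stand-in |

Physical dormancy is drawn only among non-endospermic species and
excludes physiological dormancy, mirroring the fixture's structure.
σ is solved from each species' p50 in closed form (`sigma_for_p50()`;
the relation is linear in σ, so the bisection one might reach for is
unnecessary). Continuous traits are generated with no effect on p50,
matching the published result that they explain nothing.

What the generator does **not** emulate: seed-lot heterogeneity beyond a
single normal death distribution, dormancy-release kinetics, germination
speed, measurement error in the trait values, or topology uncertainty
below the genus level. A green calibration test therefore establishes
that the estimators recover their own generating model at study scale —
not that any biological conclusion is right.

## 6. Numerical choices and degenerate inputs

- λ searches use `optimize()` on $[0,1]$ with tolerance 1e-6, comparing
  the interior optimum against both endpoints so boundary estimates are
  exact.
- Cholesky factorization backs all GLS algebra; a non-PD covariance is a
  structured error, not an NaN.
- Ties in p50 ranking break alphabetically (with a message); ties in
  model comparison go to probit.
- Non-positive values into `log10_trait()` and non-positive seed
  dimensions are errors, never silent NaN; missing trait values are NA
  and are dropped per model with the retained n reported.
- If the longest seed dimension is not passed as "length", dimensions are
  reordered with a warning (the shape statistic presumes the longest axis
  is the reference).
- All simulation-based p-values take an explicit seed (default 1) and
  leave the global RNG stream untouched.

## 7. Runtime scaling in the tests

The acceptance suite runs the spec-scale experiments (200 time-course
recoveries, 100–200 signal-calibration replicates, 200 full-pipeline sign
recoveries) in about 90 s total on one CPU. One deliberate scale-down:
each D-calibration replicate uses 100 reference simulations instead of
the interactive default 1000; the replicate count itself is not reduced.

## 8. Known limitations

- The taxonomy tree resolves nothing below genus; between-family ages are
  synthetic stand-ins. λ, K and D values on this tree are comparable in
  sign and rough magnitude, not digit-for-digit, with analyses on a
  calibrated megatree.
- p50 standard errors from Table-shaped fixtures are not propagated into
  the regressions (the analyses this package mirrors did not either).
- The logistic model's SE for c comes from the numerical Hessian at the
  optimum and can be fragile on near-separated data; the probit route is
  the primary estimator.
- `fit_probit` extrapolates censored p50s far beyond the observation
  window when asked; the `censored` flag should gate any downstream use.
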