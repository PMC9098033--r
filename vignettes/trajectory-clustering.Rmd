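---
title: "Clustering longitudinal trajectories with simultaneous variable selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering longitudinal trajectories with simultaneous variable selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmmclust)
```

## The model

`lmmclust` addresses a recurring problem in longitudinal epidemiology:
a cohort is measured repeatedly over a few waves, the population plainly
contains subgroups with different outcome trajectories, and each subgroup
may have its *own* set of relevant predictors. Two-step workflows --- first
cluster the trajectories, then select variables within or across clusters
--- rest on incompatible assumptions (the clustering step assumes a
mixture, the selection step a homogeneous population) and discard subjects
with incomplete follow-up. The one-step alternative implemented here fits a
finite mixture of LASSO-penalized random-intercept linear mixed models, so
clustering and per-cluster variable selection happen in the same
likelihood.

Subject $i$ contributes an outcome vector $y_i$ of length $n_i$ (one entry
per observed wave) with fixed-effects design $X_i$ (intercept, wave index,
and covariates) and a random-intercept design $Z_i = \mathbf{1}$. Within
cluster $g$,

$$y_i = X_i \beta_g + Z_i b_{ig} + \epsilon_{ig}, \qquad
  b_{ig} \sim N(0, \sigma_g^2 D_g), \qquad
  \epsilon_{ig} \sim N(0, \sigma_g^2 I),$$

so marginally $y_i \sim N(X_i\beta_g,\; \sigma_g^2 (Z_i D_g Z_i^\top + I))$.
With a scalar random intercept, $D_g = d_g \ge 0$ is the random-intercept
variance *relative* to the residual variance. The observed-data likelihood
is the mixture $\sum_g \pi_g\,\phi(y_i \mid X_i\beta_g, \Sigma_g)$ over the
$G$ components, and each component is interpreted as a cluster.

Sparsity in $\beta_g$ comes from an $\ell_1$ penalty: each component's
M-step maximizes

$$\sum_i w_{ig} \,\log\phi\!\left(y_i \mid X_i\beta_g, \sigma_g^2(Z_iD_gZ_i^\top+I)\right)
  \;-\; \lambda_1 \sum_{j \in \text{penalized}} |\beta_{gj}|,$$

where $w_{ig}$ is the posterior probability (responsibility) that subject
$i$ belongs to cluster $g$. The intercept is never penalized; every other
fixed effect, including the wave indicator, is penalized by default (it
must be *selectable*, not guaranteed). The penalty is applied per cluster
without scaling by cluster size; `lmmclust_control(scale_by_size = TRUE)`
offers size-scaled penalties for sensitivity analysis, and
`lambda2` adds an optional ridge penalty on $d_g$ (off by default, matching
the single-random-intercept application).

## The alternating EM algorithm

`lmmclust()` alternates:

1. **E-step** --- responsibilities
   $w_{ig} = \pi_g \phi_g(y_i) / \sum_l \pi_l \phi_l(y_i)$ computed in log
   space with log-sum-exp (a component with $\pi_g = 0$ simply gets zero
   responsibility), then $\pi_g = n^{-1}\sum_i w_{ig}$.
2. **M-step** --- for each component, blockwise ascent:
   (a) coordinate descent with soft-thresholding on $\beta_g$ under the
   responsibility-weighted whitened least-squares objective (full sweeps
   alternate with sweeps over the active set, as in `glmnet`); (b) the
   variance pair $(d_g, \sigma_g^2)$ by an *exact profile* step ---
   $\hat\sigma_g^2(d)$ has a closed form given $d$, leaving a smooth 1-D
   profile maximized by `optimize()` on $[0, 10^3]$, with an ascent guard
   that keeps the previous value if it scores better. (A generic bounded
   2-D search would also work; profiling is exact in one coordinate and
   cheaper.)

Both steps are generalized-EM moves, so the penalized observed-data
objective never decreases; the iteration stops when it decreases
numerically or improves by less than `tol` (relative, default $10^{-6}$),
or at `max_iter` (default 500), and the best-objective iterate is
returned. The inner coordinate descent uses tolerance `cd_tol`
($10^{-8}$ on the largest coefficient change); the sweep and block caps
(`cd_max_pass`, `block_max`) bound per-iteration work --- EM only needs
ascent, not an exact inner maximum.

Closed forms specific to the random intercept are used throughout:
$(dJ + I)^{-1} = I - \tfrac{d}{1+n_i d}J$ and
$\det(dJ+I) = 1 + n_i d$, which make every E- and M-step pass $O(N p)$.
The generic `subject_loglik()` (Cholesky on an explicit covariance) is
retained for arbitrary $Z_i$, $D_g$ and serves as the reference in tests.

**Initialization** (the literature rarely states one): the default start is
k-means with $G$ centers on per-subject features (outcome mean, OLS slope
over wave; slope 0 for single-record subjects), converted to hard
responsibilities, plus `n_starts - 1` random hard assignments; the run with
the best final penalized objective wins. A component whose effective size
$\sum_i w_{ig}$ falls below $\max(2,\ 0.005\,n)$ (variance parameters are
unidentifiable below two effective subjects) triggers a restart with a
fresh random assignment, up to `max_restarts`; if every attempt collapses,
the best attempt is returned with a warning.

**Ties** in the hard assignment go to the lowest cluster index, so labels
are deterministic.

## Standardization and reported scales

`standardize_covariates()` z-scores every covariate (including the wave
indicator, unless exempted) over all pooled rows. The outcome is *not*
standardized: reported intercepts are then in outcome units at the
first-wave baseline, which is how such coefficient tables are read in
practice. `selection_table()` and `coef(fit, scale = "original")`
back-transform slopes by $1/s_j$ and shift the intercept by
$\sum_j \hat\beta_j \bar x_j / s_j$, so results are reported on the
original covariate scale regardless of the fitting scale.

## Choosing the number of clusters and the penalty

`lmmclust_search()` implements the staged recipe: for each candidate $G$,
fit the penalized mixture down a log-spaced penalty path from the data-
derived path endpoint $\lambda_{\max}$ to $0.01\,\lambda_{\max}$, plus the
unpenalized fit, warm-starting each fit from the previous one; then pick
the $(G, \lambda_1)$ pair minimizing

$$\mathrm{BIC} = -2\,\ell + \mathrm{df}\,\log N,$$

with $\ell$ the unpenalized mixture log-likelihood at the fitted
parameters, $\mathrm{df}$ = (nonzero fixed-effect coefficients over all
clusters) + $2G$ variance parameters + $(G-1)$ mixing probabilities
(the standard LASSO df estimate), and $N$ the total record count
(`count = "subjects"` switches to the subject count for sensitivity). Ties
break toward smaller $G$, then larger $\lambda_1$. Individual fit failures
are recorded and skipped.

$\lambda_{\max}$ is computed operationally: the EM is run with the
penalized coordinates pinned at zero, and the largest KKT score
$|x_j^\top A_i r| / \sigma^2$ seen at *any* coordinate sweep along the
whole path is returned. Because a fit at any $\lambda_1$ at or above this
value reproduces the pinned trajectory exactly (every soft-threshold
evaluates to zero along the way, not merely at convergence), the endpoint
guarantee is exact rather than asymptotic. It is a path-wise supremum, so
it can exceed the familiar single-pass bound evaluated at the null fit.

The stopping rule is applied to the *penalized* objective --- that is the
quantity the alternation maximizes; applying it to the unpenalized
log-likelihood would let penalty bookkeeping masquerade as fit improvement.

`refit_clusters()` provides the customary follow-up: within each cluster of
the hard partition, an unpenalized ML refit on the selected covariates
with Wald $z$ statistics from the inverse fixed-effects information
(variance parameters held at their ML estimates). These are descriptive:
no multiple-testing correction is applied, and no post-selection
adjustment is attempted --- valid post-selection inference for mixture
models is an open problem.

## The synthetic cohort generator

`taag_spec()` encodes the package's reference generative truth, emulating a
three-wave cohort of adolescent girls' daily moderate-to-vigorous physical
activity (MVPA, minutes/day) measured at ages 14, 17 and 23:

* 568 subjects; monotone dropout with per-wave retention
  $(1, 565/568, 428/565)$, so the expected record mix is 428 / 137 / 3
  subjects with 3 / 2 / 1 records;
* three latent clusters with mixing $(0.423, 0.509, 0.068)$: a flat
  "maintainer" cluster (intercept 14.01, wave slope $-1.10$), a declining
  "decreaser" cluster (32.36, $-16.16$), and a small rising "increaser"
  cluster (1.74, $+29.11$);
* 31 candidate covariates at the individual, social and neighborhood
  levels, of which 2 / 6 / 4 (beyond intercept and wave) have nonzero
  cluster-specific effects --- e.g. friend support 0.15 and number of
  nearby parks 0.39 in the maintainer cluster; self-management 0.81,
  self-efficacy 0.37, outcome-expectancy beliefs $-0.42$ and $-0.019$,
  social support $-1.75$, family support $-0.27$ in the decreaser cluster;
  self-management 0.34, neighborhood traffic $-3.62$, distance to the
  nearest park 2.36 and school 5.37 in the increaser cluster;
* residual SDs $(6, 9, 10)$ and relative random-intercept variance
  $d = 0.5$. These variance components are *calibrations, not estimates*
  --- the source application never reports them --- chosen once so that
  simulated per-wave within-cluster SDs fall in the 6--21 minutes/day range
  reported for such cohorts.

Covariates are drawn i.i.d. standard normal, redrawn at each wave --- the
scale covariates have after z-scoring. `cohort_spec()` accepts per-covariate
generators with cluster-specific means and SDs (used below) and Bernoulli
dummies. What the generator does *not* emulate: the real covariates'
marginal distributions and cross-correlations, within-subject covariate
autocorrelation, accelerometer measurement error, and informative dropout.
Passing tests on these cohorts therefore demonstrates correctness of the
algorithm under the model's own assumptions, not performance on real data.

`inflate_separation()` produces the recovery benchmark used by the
acceptance checks: wave slopes $(-1.10, -30, +30)$ and residual SDs capped
at 8, everything else unchanged. Under these conditions the Bayes-optimal
classifier that knows the true parameters attains an adjusted Rand index
of roughly 0.91--0.98 against the true labels at $n = 568$ (maintainers
and decreasers still overlap at moderate random intercepts), which is the
natural ceiling for any fitted classifier.

A deliberately adversarial scenario probes a documented blind spot of
within-cluster selection: a covariate given a large between-cluster mean
difference but near-zero within-cluster variance (e.g. maternal education
acting as a cluster marker). Its within-cluster score has variance
proportional to its within-cluster variability, so it is absorbed by the
cluster intercepts and is not selected at any reasonable penalty --- the
intended behavior for a method whose selections are conditional on
cluster.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
spec <- inflate_separation(taag_spec())
cohort <- simulate_cohort(spec, seed = 1)
dat <- standardize_covariates(cohort$data)

search <- lmmclust_search(dat, G = 2:4,
                          control = lmmclust_control(n_starts = 1, seed = 1))
search$best
adjusted_rand_index(search$best$labels, cohort$truth$cluster)
selection_table(search$best)
plot(search$best)

refit_clusters(dat, search$best$labels,
               selected = lapply(seq_len(search$best$G), function(g) {
                 B <- coef(search$best, scale = "standardized")
                 setdiff(names(which(B[, g] != 0)), "(Intercept)")
               }))
```

## Numerical choices and degenerate inputs

* Residual variance is floored at $10^{-8}$; $d$ is searched on
  $[0, 10^3]$.
* A coordinate whose curvature $x_j^\top A x_j$ is numerically zero under
  the current weights is skipped (its coefficient stays put) rather than
  divided by.
* Zero-variance covariate columns are rejected at standardization with the
  column named; constant columns are rejected at assembly.
* Duplicate (subject, wave) rows and undeclared non-numeric covariates are
  errors; rows with missing modelled values are dropped with a count.
* Waves are recoded to consecutive integers from 0 so the intercept is the
  first-wave baseline.
* `G` larger than the subject count is an error; a single-record subject
  contributes a slope feature of 0 to the k-means initialization.

## Problem sizes in the test suite

The suite exercises the full pipeline at desk scale, chosen so the whole
run stays comfortably within a typical CI budget: oracle-equivalence fits
at $n = 100$ (five seeds, compared to a generic-optimizer ML fit at
relative tolerance $10^{-4}$), ascent checks over thirty fits at
$n = 150$, and a ten-seed recovery study at the full $n = 568$ with the
BIC search over $G \in \{2,3,4\}$ and an eight-point penalty path. The
generator's covariance law is verified component-wise at $n = 10{,}000$
subjects per component.

## Known limitations

* Only scalar random intercepts are exercised ($q = 1$); the covariance
  algebra in `marginal_covariance()`/`subject_loglik()` accepts general
  $Z_i, D_g$ but the fast fitting path does not.
* No BLUP prediction of individual random intercepts, and no standard
  errors for penalized estimates (refit-based Wald statistics are
  descriptive).
* BIC evaluated at shrunken estimates tends to prefer smaller penalties
  than support recovery would want: the $\ell_1$ bias on large (e.g. wave)
  coefficients costs likelihood at large $\lambda_1$, which BIC trades
  against the df of spurious small coefficients. Cluster-number selection
  is robust to this; exact support recovery of sub-noise effects
  (|effect| below ~1.5 standard errors) is not achievable at these sample
  sizes by any selector.
* Label switching across EM runs is resolved only by `align_labels()`
  (exhaustive over permutations, so practical for $G \le 8$).
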