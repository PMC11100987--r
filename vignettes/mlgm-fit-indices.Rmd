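---
title: "Level-specific fit indices for multilevel latent growth models under unbalanced designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Level-specific fit indices for multilevel latent growth models under unbalanced designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlgmsim)
```

## The model

`mlgmsim` studies how conventional SEM fit indices behave when a
multilevel latent growth model (MLGM) is estimated on clustered
longitudinal data whose clusters have *unequal* sizes. The data model is a
two-level latent growth curve: individual $i$ in cluster $g$ is observed at
$T = 5$ waves, and

$$
y_{gi} = \underbrace{\Lambda \eta_{B,g} + \varepsilon_{B,g}}_{\text{cluster component } b_g}
       + \underbrace{\Lambda \eta_{W,gi} + \varepsilon_{W,gi}}_{\text{individual component}},
$$

with $\Lambda$ the $T \times 3$ polynomial basis over time codes
$0,\dots,4$ (intercept, linear, quadratic),
$\eta_{B,g} \sim N(\alpha_B, \Phi_B)$,
$\eta_{W,gi} \sim N(0, \Phi_W)$, and diagonal residual covariances
$\Theta_B$, $\Theta_W$. All observed means are carried at the cluster
level. The implied moments are $\mu = \Lambda\alpha_B$,
$\Sigma_W = \Lambda\Phi_W\Lambda' + \Theta_W$ and
$\Sigma_B = \Lambda\Phi_B\Lambda' + \Theta_B$.

The default population values (shipped in
`inst/extdata/population_model.yaml`, an LSAY-style mathematics-achievement
parameterization) give implied intraclass correlations between 0.13 and
0.28 across waves:

```{r}
spec <- default_mlgm_spec()
round(icc_profile(implied_moments(spec)), 3)
```

Time codes default to $0,1,2,3,4$: the source material fixes five waves
with a quadratic trajectory but no explicit codes, and integer coding is
the convention of the simulation lineage this design follows. Both the
codes and the polynomial degree are configurable through
`build_growth_basis()`.

## Unbalanced design and sufficient statistics

Each design cell has `NG` clusters, exactly half of size $s$ and half of
size $3s$, which fixes the coefficient of variation of cluster sizes at
0.5 — a moderate imbalance. With unequal sizes the classical scaled
between-cluster covariance $S^*_B$ is no longer a sufficient statistic, so
the estimator never consumes it; instead `sufficient_stats()` compresses a
dataset losslessly into the pooled within-cluster scatter plus, per
distinct cluster size $n$, the count, mean and scatter of that size class's
cluster means. The exact log-likelihood of any mean-and-covariance
structure $(\mu, \Sigma_W, \Sigma_B)$ is then

$$
\ell = -\tfrac12 \sum_g \left[ n_g p \log 2\pi + p \log n_g
  + (n_g - 1)\log|\Sigma_W| + \mathrm{tr}(\Sigma_W^{-1} S_g)
  + \log|V_{n_g}| + (\bar y_g - \mu)' V_{n_g}^{-1} (\bar y_g - \mu) \right],
$$

with $V_n = \Sigma_B + \Sigma_W / n$, computable in a number of matrix
operations proportional to the number of *distinct* sizes (two, here) —
not the number of clusters. `mlgm_loglik()` is verified against
`mlgm_loglik_bruteforce()`, which builds each cluster's
$I_n \otimes \Sigma_W + J_n \otimes \Sigma_B$ covariance explicitly.

## Model templates and degrees of freedom

Level-specific and target-specific fit indices come from *partially
saturated* comparisons: the nuisance side of the model is freed completely
so that any misfit is attributable to the target side.

| template | within cov | between cov | means | params | df |
|---|---|---|---|---|---|
| H1 | saturated | saturated | saturated | 35 | 0 |
| PS_B (= TS_COV) | saturated | growth structure | saturated | 31 | 4 |
| PS_W | growth structure | saturated | saturated | 31 | 4 |
| TS_MEAN | saturated | saturated | $\mu = \Lambda\alpha$ | 33 | 2 |
| BASE_B / BASE_W | diagonal at target level | saturated elsewhere | saturated | 25 | 10 |
| BASE_MEAN | saturated | saturated | equal means | 31 | 4 |

Two design choices deserve comment, because the source material leaves
them open:

* **Structured blocks free all six elements of $\Phi$**, including
  covariances the population model sets to zero. This is the only counting
  that yields the documented 4 degrees of freedom for both partially
  saturated models, and it keeps those models correctly specified — their
  chi-square means should then sit near 4, which the study confirms.
  `model_template(phi_offdiag_free = FALSE)` switches to diagonal-$\Phi$
  templates (7 df) for investigators probing alternative conventions.
* **PS_B carries a saturated mean vector.** Structured means would give
  6 df, not 4; mean-structure misfit is tested separately by TS_MEAN.
* **Baselines are never defined in the source material.** The package uses
  the standard independence convention per level (target-level covariance
  diagonal, everything else saturated) and an equal-means baseline for the
  mean structure. These are config choices, not facts about the indices.

Under the literal construction, the target-specific covariance model
TS_COV — "saturate the within level and the between-level mean structure" —
is *identical* to PS_B, and the catalog fits it once and stores it under
both names. The published descriptive tables this package shadows report
very different, $N$-growing chi-squares for their TS models, which cannot
be reconstructed from the literal text; the growing-with-$N$ direction is
checked qualitatively, but no TS magnitude is treated as a reference value.

## Estimation

Every template is estimated by full-information ML on the sufficient
statistics, with analytic gradients, using PORT quasi-Newton iterations
(`nlminb`).

**Parameters are unconstrained.** Covariance blocks are parameterized by
their unique elements and residual variances as free reals; the likelihood
is evaluated only where $\Sigma_W$ and every $V_n$ are positive definite,
and returns $-\infty$ outside that region so line searches back off.
Within the feasible region nothing stops a between-level residual variance
from going negative or $\hat\Phi_B$ from going indefinite, exactly as in
conventional SEM ML software. This matters: with 200 clusters the
unconstrained optimum of the structured between block frequently lies
outside the PD cone, and a positive-definite-by-construction
parameterization (log-Cholesky) was found to truncate those solutions,
inflating the between-level chi-square mean from ≈4 to ≈7 and breaking its
$\chi^2_4$ calibration. The log-Cholesky surface also produced spurious
stationary points that trapped BFGS. The package therefore reports
PD-admissibility as a separate `admissible` flag on each fit rather than
forcing it; in the largest design cell most replications contain at least
one mildly inadmissible component (typically $\hat\Phi_B$'s tiny quadratic
variance, population value 0.02, crossing zero), which is sampling noise,
not estimation failure.

**Starting values** are moment estimates: $S_{PW}$ for $\Sigma_W$, the
PSD-projected $(S^*_B - S_{PW})/\bar n$ for $\Sigma_B$, the grand mean for
$\mu$; structured blocks project these through the pseudoinverse of
$\Lambda$ with residual variances floored at $10^{-4}$. Structured
templates are additionally started from a diagonal-$\Phi$ projection and
the better optimum kept — a cheap guard against multimodality.

**Convergence** requires the gradient sup-norm below
$10^{-6}\max(1, |\ell|)$ — a relative criterion in the spirit of the
$10^{-6}$ convergence tolerance conventional SEM software uses. On
non-convergence the optimizer restarts from its current point (fresh
Hessian approximation), then once from jittered starts (`fit_control()`
exposes tolerance, the 500-iteration cap, and restart count). Replications
with any non-converged fit are flagged and excluded from summaries; across
the full default grid none occur.

## Fit indices

From the deviance $\chi^2 = 2(\ell_{H1} - \ell_{H0})$ (floored at 0):

* RMSEA $= \sqrt{\max(\chi^2 - df, 0)/(df \cdot N)}$ with $N$ the **total
  individual count for every index**, between-targeted ones included. With
  $N_{cluster}$ instead, the between-level RMSEA at the largest cell would
  sit near 0.07 rather than the documented 0.003; the total-$N$ convention
  is the one the reference software uses.
* CFI $= 1 - \max(\chi^2-df,0)/\max(\chi^2_b-df_b, \chi^2-df, 0)$, in
  $[0,1]$.
* TLI $= ((\chi^2_b/df_b) - (\chi^2/df))/((\chi^2_b/df_b) - 1)$, stored
  unclamped — values above 1 are common and informative here.
* SRMR: root mean square of correlation-metric residuals between the
  saturated covariance estimate at a level and the hypothesized model's
  implied covariance at that level. Mean residuals are excluded by default
  (the level-specific models keep means saturated, so they are identically
  zero); `srmr_mean_residuals = TRUE` appends standardized mean residuals
  for mean-structure diagnostics. If a Heywood-type saturated solution
  leaves a non-positive between variance, the SRMR standardization is
  undefined; the replication is then flagged rather than failed. P-values
  are computed but never summarized.

A note on between-level SRMR magnitudes: the saturated between-covariance
estimate carries sampling noise of order $1/\sqrt{G}$, not $1/\sqrt{N}$,
so for a correctly specified between structure on $G = 200$ clusters the
standardized between residuals in the four constrained directions put the
expected SRMR$_B$ in the few-hundredths range (roughly
$\sqrt{\chi^2/G}$-scale) — an order of magnitude above SRMR$_W$ at the
same design, whose residuals shrink at the $1/\sqrt{N}$ rate. Published
two-level simulation tables are not consistent with each other on this
quantity; some report between-SRMR values that shrink at the total-$N$
rate, which no residual statistic of the between covariance estimate can
do. This package reports the standard construction and leaves it at that.

## The Monte Carlo study

`run_study()` crosses NG ∈ {50, 100, 200} with group sizes 5/15, 10/30,
25/75 (total $N$ from 500 to 10,000). All randomness descends from one
root seed: replication $r$ of condition $c$ uses a counter-based child
seed, so any single replication can be replayed in isolation
(`replay_replication()`) and conditions are independently reproducible.
Cluster-size assignment is deterministic (first half small); order is
irrelevant because clusters are exchangeable.

Summaries are means and sample SDs (divisor $n-1$) per cell over converged
replications. Sensitivity is a two-factor fixed-effects ANOVA per index —
the design is a 3×3 two-factor grid, and with equal cell counts the
sequential and Type III decompositions coincide — reported as
$\eta^2 = SS_{factor}/SS_{total}$ with the moderate-effect threshold
0.0588. A factor is *practically* influential only if the index also
varies: indices whose pooled SD falls below 0.005 (a configurable reading
of "standard deviation close to 0") are exempt.

Problem sizes used by the package's own reproduction: the bundled analysis
scripts run 100 replications per cell, and the acceptance checks run 200
(the full design used 1,000). At 200 replications the Monte Carlo standard
error of a $\chi^2_4$ mean is about 0.2, which sets the tolerances used in
the acceptance tests. The chi-square calibration check
(Kolmogorov–Smirnov against $\chi^2_4$) uses 500 replications of the
within-level comparison in the largest cell.

One consequence of using the plain ML deviance worth knowing before
comparing against published tables: with 200 clusters the level-specific
chi-square means sit near their degrees of freedom in *every* group-size
condition — the statistic is calibrated by the number of clusters, and
enlarging clusters at fixed $G$ changes it only marginally. Published
tables built on robust-scaled statistics can show a much stronger
group-size gradient on the same design. The RMSEA and SRMR families, by
contrast, respond clearly to both design factors here, and the
target-specific chi-squares under the literal construction do **not** grow
with total sample size (TS_COV is the PS_B model; TS_MEAN is correctly
specified at 2 df).

## What the generator does and does not emulate

The generator reproduces the study conditions exactly: multivariate-normal
latent effects and residuals, quadratic growth at both levels, two cluster
sizes per cell with the large size triple the small. It does **not**
emulate non-normal outcomes, missing data, more than two size classes,
misspecified population structures, or informative cluster sizes. Passing
results therefore say nothing about robustness to any of those; they say
that under exactly these textbook conditions the level-specific indices
are calibrated and the target-specific ones are not.

## Known limitations

* Plain ML throughout: no robust (sandwich/scaled) corrections, no
  standard errors — the study's outcomes never use them, and under
  normality the point estimates and deviances coincide with the robust
  estimator's.
* The mean-structure population values are taken from the printed matrices
  as authoritative even where the surrounding prose disagrees with them
  (standardized-scale wording vs. $\alpha_B = (49.96, 4.32, -0.13)$; the
  "zero off-diagonal" wording vs. the printed intercept–slope covariances;
  the stated 0.15–0.19 ICC range vs. the implied 0.13–0.28).
* Degenerate designs with very few clusters (roughly $G \le T$) leave the
  saturated between model unbounded and are rejected by validation rather
  than estimated.
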