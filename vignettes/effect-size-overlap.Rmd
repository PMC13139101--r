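---
title: "Comparing mean-based effect sizes with distributional overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing mean-based effect sizes with distributional overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovlsim)
```

## The four indices

Given two samples $y_1$ (group 1) and $y_2$ (group 2), `ovlsim` computes
four summaries of the group contrast:

* **Cohen's d** — the standardised mean difference
  $d = (\bar y_1 - \bar y_2)/s_p$ with
  $s_p^2 = \{(n_1-1)s_1^2 + (n_2-1)s_2^2\}/(n_1+n_2-2)$. The sign
  convention throughout is group 1 minus group 2.
* **CLES** — the common language effect size, i.e. the probability that a
  random draw from one group exceeds a random draw from the other. Two
  estimators are provided: the ordered-pair count
  $N_1/(N_1+N_0)$ (ties excluded from both counts, with no half-credit)
  and the normal-theory transform $\Phi(|d|/\sqrt 2)$.
* **Parametric overlap** $\eta_p = 2\Phi(-|d|/2)$ — the shared area of two
  equal-variance normal densities separated by $d$ pooled SDs.
* **Nonparametric overlap** $\eta = \int \min\{f_1, f_2\}$ — the shared
  area under the two *kernel-estimated* densities, which responds to any
  distributional difference (location, scale, skewness, tails), not only
  to the means.

The first three are deterministic functions of the same location contrast
and correlate almost perfectly; $\eta$ measures something genuinely
different. The point of the package is to quantify how differently they
*perform* as estimators when normality and variance homogeneity fail.

`overlap_es()` is the user-facing fit for real data. It accepts either two
vectors or a `response ~ group` formula, and returns an object with
`print`, `summary`, `coef`, `confint`, and `plot` methods; the plot shades
the estimated shared area under the two densities.

## Confidence intervals

* For $d$, the 95% interval inverts the noncentral-t distribution of the
  two-sample t statistic $t_{\mathrm{obs}} = d\sqrt{n_1 n_2/(n_1+n_2)}$:
  the bounds are the noncentrality parameters whose upper/lower tail
  probability at $t_{\mathrm{obs}}$ equals 0.025, rescaled to the d scale.
  The inversion is a bracketed root search on the tail probability
  (absolute tolerance $10^{-8}$); the bracket is seeded at
  $t_{\mathrm{obs}} \pm 4\sqrt{1 + t_{\mathrm{obs}}^2/(2\,\mathrm{df})}$, a
  normal-approximation width that remains reliable for the extreme
  statistics that arise at $n = 1000$, $d = 2$, and expands geometrically
  if needed.
* CLES and $\eta_p$ intervals are obtained by evaluating their transforms
  at the endpoints of the $d$ interval and ordering the two values. Both
  transforms fold through $|d|$, so they are not monotone on an interval
  that straddles zero: the folded endpoints then both sit on the same side
  of the transform's extremum, and the literal endpoint rule cannot reach
  $\eta_p = 1$ (nor CLES below the larger folded endpoint). We implement
  the literal rule as the default because it is the plainest reading of
  endpoint transformation, and it reproduces the characteristic coverage
  collapse of the transformed intervals in null cells. Setting
  `widen_etap_at_zero = TRUE` (or `widen_at_zero` in
  `ci_transform_monotone()`) additionally includes the transform's value
  at $d = 0$ whenever the interval contains zero, which restores the
  attainable bound.
* The $\eta$ interval is a percentile bootstrap: each group is resampled
  independently with replacement, the overlap recomputed, and the 2.5th
  and 97.5th percentiles taken (type-7 quantiles, i.e. linear
  interpolation, so results are bit-reproducible given seeds). The default
  is 1000 resamples; tests use 100–200, which is enough for interval
  *machinery* checks though not for publication-grade coverage. A
  degenerate resample (zero spread) is redrawn, capped at 100 attempts.

## Kernel settings

$\eta$ uses Gaussian kernels with Silverman's rule-of-thumb bandwidth
$0.9\min(s,\ \mathrm{IQR}/1.34)\,n^{-1/5}$ (`stats::bw.nrd0`), both
densities evaluated on one shared 1024-point grid spanning the pooled data
range extended by 3 bandwidths, each density renormalised to unit mass on
that grid, and the pointwise minimum integrated by the trapezoidal rule.
All of this is configurable through `kde_config()` (kernel, bandwidth rule,
grid size, grid extension). Renormalisation matters: without it, grid
truncation alone would bias the overlap of identical samples below 1 by
the clipped tail mass. A sample with zero spread raises a degenerate-sample
error rather than silently inheriting the bandwidth rule's fallback width.

## The generator and the study design

The synthetic populations are skew-normal, $SN(\xi, \omega, \alpha)$, with
density $f(y) = \tfrac{2}{\omega}\phi(z)\Phi(\alpha z)$, $z = (y -
\xi)/\omega$. Its mean and SD are $\mu = \xi + \omega\gamma\sqrt{2/\pi}$
and $\sigma = \omega\sqrt{1 - 2\gamma^2/\pi}$ with $\gamma =
\alpha/\sqrt{1+\alpha^2}$; `sn_params_from_moments()` inverts these so a
cell can be specified directly by its *target* mean and SD. Sampling uses
the exact stochastic representation $Z = \gamma|U| +
\sqrt{1-\gamma^2}\,V$ with $U, V$ independent standard normals — exact,
rejection-free, and O(n).

A study condition fixes group 1 at $N(0,1)$ and moment-matches group 2 to
mean $\delta \in \{0, 2\}$, SD $\sigma \in \{1, 5\}$, slant $\alpha \in
\{0, 10\}$ — eight scenarios spanning a mean shift, a 5:1 variance ratio,
and strong right skew (population skewness $\approx 0.95$ at $\alpha =
10$) — at per-group sizes $n \in \{10, 50, 100, 300, 500, 1000\}$, i.e. 48
conditions, with 2000 replicate pairs per condition by default. These
defaults *are* the study conditions; desk-scale runs reduce `n_reps`, not
the grid.

What the generator does **not** emulate: heavy tails beyond the
skew-normal's (its tails are normal-like), multimodality, discreteness or
floor effects, dependence between groups, and unequal group sizes. Passing
tests therefore certify behaviour under controlled skewness and variance
heterogeneity, not under every non-normal shape seen in real data.

### Seeding

Each replicate's seed is a 31-bit hash of (master seed, $\delta$, $\sigma$,
$\alpha$, $n$, replicate index). Two consequences the tests rely on:
reruns are bit-identical, and a condition rerun in isolation — or a grid
run in any order — reproduces exactly the same replicates. The bootstrap
seed is derived from the replicate seed, so a single interval can be
reproduced without rerunning the grid.

## Estimands

Performance is judged per index against its own population target:

* $\theta_d = -\delta/\sqrt{(1+\sigma^2)/2}$, the population counterpart
  of the pooled-SD standardiser at equal $n$ (moment matching guarantees
  the group-2 mean and SD for every $\alpha$, so $\theta_d$ does not
  depend on the slant).
* $\theta_{\mathrm{CLES}}$: by default the folded true probability of
  superiority $\max(p, 1-p)$, $p = P(Y_2 > Y_1) = \int \Phi(y) f_2(y)\,
  \mathrm dy$ by quadrature. Because the recorded estimator is the folded
  transform $\Phi(|\hat d|/\sqrt2)$, an alternative rule
  (`theta_cles_rule = "transform_of_theta_d"`) judges it against
  $\Phi(|\theta_d|/\sqrt2)$ instead. Under normal equal-variance cells the
  two coincide; under skewness or heteroscedasticity they do not, and the
  gap between them is precisely the model-misspecification bias that makes
  CLES unreliable there. Both rules are exposed because neither is
  canonical; the default targets the quantity CLES claims to estimate.
* $\theta_\eta = \int \min\{f_1, f_2\}$ by adaptive quadrature (relative
  tolerance $10^{-10}$, integration range $\pm 10$ target SDs beyond the
  means, which covers all but $<10^{-9}$ of either mass). **Both** overlap
  indices are judged against this one target: $\eta_p$ claims to estimate
  the shared area, and judging it against the true shared area is the only
  reading under which its behaviour is informative — unbiased where
  normal-equal-variance theory holds ($\sigma = 1$), and strongly biased
  where it does not ($\sigma = 5$, where $2\Phi(-|\theta_d|/2)$ can exceed
  twice the true overlap). Judging $\eta_p$ against its own plug-in limit
  would instead certify it as always unbiased and erase the comparison.

Closed forms anchor the quadrature in tests: overlap $2\Phi(-\delta/2)$
for equal-variance normal cells, the crossing-point construction for
zero-mean unequal-variance normal cells, and $\Phi(\delta/\sqrt{1 +
\sigma^2})$ for the normal-cell probability of superiority.

## Performance metrics

Per condition and index, over $B$ replicates with estimates
$\hat\theta_b$:

* **RMB** $= \tfrac1B\sum_b (\hat\theta_b - \theta)/\theta$, with
  $\pm 0.10$ as the conventional acceptability band. When $\theta = 0$
  exactly (only $\theta_d$ in the $\delta = 0$ cells), $\epsilon = 10^{-6}$
  replaces the denominator; the resulting values are astronomically scaled
  by construction, so the summary also reports the raw mean bias
  ($\tfrac1B\sum\hat\theta_b - \theta$) alongside — the literal
  $\epsilon$-rule column is faithful, the raw column is interpretable.
* **NRMSE** $= \mathrm{RMSE}/(\max_b \hat\theta_b - \min_b \hat\theta_b)$;
  a degenerate zero range yields 0 if the RMSE is also 0 and `NA`
  otherwise.
* **Coverage** — the fraction of replicates whose interval contains
  $\theta$, closed endpoints.

Cross-index agreement is summarised by Pearson correlations over
replicate-level estimates pooled across all conditions (condition means
would wash out the within-cell disagreement that distinguishes $\eta$).
Because $d$ is signed while the other three fold through $|d|$, the
correlation matrix is reported both on the raw columns and as magnitudes
after folding $d$; the magnitude form is the comparable one.

## Problem sizes and numerical tolerances used in validation

The package's own test suite runs the full 48-condition grid at 200
replicates per condition for correlation and bias checks, 2000 replicates
for the single-cell coverage calibration of the noncentral-t interval, 500
replicate pairs for the null CLES value, and $10^5$-point samples for
KDE-consistency checks. At 200 replicates a per-cell RMB carries
Monte-Carlo error up to $\approx 0.06$ SE in the hardest cells
($\sigma = 5$, $n = 10$, where $|\theta_d| \approx 0.55$), so
reduced-replicate checks of the $\pm 0.10$ band allow each cell its own
2-SE sampling margin; the full-scale band itself is a 2000-replicate
statement. Monte-Carlo assertions elsewhere use absolute bands of 2–4
standard errors under fixed seeds.

## Known limitations

* The KDE overlap is biased upward by smoothing for well-separated,
  moderately sized samples, and structurally below 1 for identical
  populations (two finite samples never overlap exactly); the bounded
  estimator also makes percentile-bootstrap coverage fragile when the true
  overlap is at or near 1.
* `pt(..., ncp)` is accurate to about $10^{-6}$ in the extreme tails, so
  the interval inversion is limited by that, not by the root-finder
  tolerance.
* Only two-group, equal-$n$ designs are generated; the estimators
  themselves accept unequal $n$.
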