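# ovlsim

Effect-size indices and distributional overlap under non-normality.

Standardised mean differences dominate how two-group effects are reported,
but the three most common indices — Cohen's *d*, the common language effect
size (CLES), and the parametric overlap coefficient — all encode the same
location contrast and inherit the same normality and equal-variance
assumptions. When distributions are skewed or heteroscedastic (reaction
times, symptom scales, anything with a floor and a heavy right tail), a
mean-based summary can misstate how much two groups actually differ.
`ovlsim` is for methodologists and applied researchers who want to (a)
compute all four indices, including the distribution-sensitive
nonparametric overlap, with proper confidence intervals on real data, and
(b) stress-test the indices themselves under controlled violations via a
deterministic Monte-Carlo engine.

## The indices

For samples $y_1$ (group 1, size $n_1$) and $y_2$ (group 2, size $n_2$):

* Cohen's $d = (\bar y_1 - \bar y_2)/s_p$, with
  $s_p^2 = \{(n_1-1)s_1^2+(n_2-1)s_2^2\}/(n_1+n_2-2)$;
* CLES $= N_1/(N_1+N_0)$ over all ordered pairs (ties dropped), or the
  normal-theory form $\Phi(|d|/\sqrt2)$;
* parametric overlap $\eta_p = 2\Phi(-|d|/2)$;
* nonparametric overlap $\eta = \int \min\{\hat f_1, \hat f_2\}$, the
  shared area under the two kernel density estimates.

95% intervals: noncentral-t inversion for $d$; endpoint transformation of
$d$'s interval for CLES and $\eta_p$; independent-groups percentile
bootstrap for $\eta$.

The simulation engine draws group 1 from $N(0,1)$ and group 2 from a
skew-normal moment-matched to a target mean difference $\delta$, SD
$\sigma$, and slant $\alpha$, then scores every index per replicate
against its own population target (relative mean bias, normalised RMSE,
interval coverage) over a factorial grid — by default
$\delta \in \{0,2\} \times \sigma \in \{1,5\} \times \alpha \in \{0,10\}
\times n \in \{10,...,1000\}$, 48 conditions at 2000 replicates each.

## Worked example

Two simulated reaction-time-like groups: patients are slower on average,
more variable, and more right-skewed than controls.

```r
library(ovlsim)
set.seed(42)
rt_ctrl <- 0.45 + sn_sample(40, sn_params_from_moments(0, 0.08, 4))
rt_pat  <- 0.55 + sn_sample(40, sn_params_from_moments(0, 0.15, 8))
fit <- overlap_es(rt_ctrl, rt_pat, n_boot = 1000, seed = 1)
summary(fit)
#> Two-group effect sizes (n1 = 40, n2 = 40, CLES: from_d)
#> 95% confidence intervals
#>       estimate   lower   upper
#> d      -0.4642 -0.9070 -0.0185
#> cles    0.6286  0.5052  0.7393
#> eta_p   0.8165  0.6502  0.9926
#> eta     0.7384  0.5738  0.8341
```

The mean shift is moderate (`d` about −0.46; negative because group 1 minus
group 2 with patients slower) and would be read as "63% of random
patient–control pairs have the patient slower". But the two overlap
coefficients disagree: the *d*-derived `eta_p` (0.82) assumes
equal-variance normals, while the kernel estimate `eta` (0.74) sees the
extra variance and skew of the patient group — the distributions share
less area than the mean-based transform implies. `plot(fit)` draws both
densities and shades the shared area.

Running the full study:

```r
cfg <- run_config(n_reps = 2000, master_seed = 1)   # the complete design
res <- run_grid(cfg)                                # replicate-level table
summarize_conditions(res)                           # RMB / NRMSE / coverage
correlation_matrix(res)                             # pooled index agreement
```

or from a shell, `Rscript inst/scripts/run_study.R run --reps 200 --seed 1
--no-intervals --out results/` (also `summarize`, `truths`, and a
`--grid-preset smoke` for a quick pass). Configurations can be read from
JSON or YAML with `read_run_config()`.

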