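---
title: "Adaptive reference ranges: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive reference ranges: models, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptref)
```

## Why adapt a reference range

A static reference range answers "is this value unusual *for the
population*?". In longitudinal monitoring the more useful question is "is
this value unusual *for this person*?". The two diverge exactly when the
between-subject variance (BSV, `tau^2`) is large relative to a person's own
within-subject variance (WSV, `sigma_i^2`): a person who normally sits at
the bottom of the population range can double their level and still be
"normal" by the static criterion. `adaptref` models both variance
components, lets the WSV differ per subject, and updates each person's range
as their history grows.

## The hierarchical model and its assumptions

All methods in the package share one data model: within subject `i` the
measurements are exchangeable draws `y_ij ~ N(mu_i, sigma_i^2)`, and the
subject means are themselves draws `mu_i ~ N(mu, tau^2)`. The assumptions
that matter in practice:

* **Normality within subject.** Skewed biomarkers should be log-transformed
  first (the CLI `--log` flag does this on read and exponentiates the limits
  on write). The `stratification_ratio()` helper implements the Harris–Boyd
  rule of thumb — stratify (e.g. by sex) when the ratio of group BSVs
  exceeds 1.5 — for deciding whether one population model is enough.
* **Exchangeability within subject.** Only the order of observations is
  used, never their spacing; timestamps are reduced to rank order at
  validation. Trends, circadian structure or serial correlation are outside
  the model: a drifting subject will eventually be flagged, but the model
  will not anticipate the drift.
* **Subjects are independent** and a subject's variance is constant over
  their series.

## Prior and tuning parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `nu` | prior SD of the grand mean (assay units) | 1000 | effectively flat on any reasonable biomarker scale; lower it only if values are huge |
| `alpha1, beta1` | IG shape/scale for each WSV | 0.01 | vague; keeps the conditional proper even for subjects with one observation |
| `alpha2, beta2` | IG shape/scale for the BSV | 0.01 | vague |
| `alpha_level` | two-sided band miscoverage | 0.05 | the conventional 95% range |
| `n_iter / burn_in / thin` | Gibbs run length | 4000 / 1000 / 1 | desk-scale accuracy; the acceptance runs use 1500/500 and match the longer runs to well within Monte-Carlo error |
| `p, confidence` | tolerance-interval content and confidence | 0.95 / 0.95 | the standard clinical convention |
| `tol, max_iter` | EM convergence | 1e-8 relative log-likelihood, 500 | the marginal likelihood is cheap (closed form per subject), so a tight tolerance costs little |
| `batch_size` | SEMA warm-up | `20 * I` rows | streaming from a cold start is unstable on short histories; a batch EM pass on the head of the stream fixes the scale before O(1) updates take over |

## Estimation

**Gibbs sampler.** Every full conditional is conjugate: normal for `mu` and
each `mu_i`, inverse gamma for `tau^2` and each `sigma_i^2`. The sweep
updates `mu -> tau^2 -> {sigma_i^2} -> {mu_i}` and touches the data only
through `(n_i, sum_j y_ij, sum_j y_ij^2)`, so an iteration is O(I)
regardless of series lengths; the loop is compiled, and the identical
conditionals exist as plain R functions (`sample_mu()` etc.) against which
the compiled path is tested. Initial values are method-of-moments (grand
mean, subject means, variance of subject means, subject sample variances
with the pooled WSV substituted where `n_i < 2`).

**Batch EM.** The same model without priors is the heterogeneous-variance
random-intercept model; EM treats the `mu_i` as missing. The E step is pure
shrinkage: `rho_i = tau^2/(tau^2 + sigma_i^2/n_i)`,
`mu_i = rho_i*ybar_i + (1-rho_i)*mu`, posterior variance
`nu_i = tau^2*(1-rho_i)`. The M step needs only three complete-data
sufficient statistics (`T1 = sum mu_i`, `T2 = sum(nu_i + mu_i^2)`,
`T3_i = sum_j[(y_ij-mu_i)^2 + nu_i]`): `mu = T1/I`, `tau^2 = T2/I - mu^2`,
`sigma_i^2 = T3_i/n_i`. Convergence is declared on the relative change of
the observed-data log-likelihood, which has a closed form per subject
through the within/between decomposition of `tau^2 J + sigma_i^2 I` and is
non-decreasing along the iterations (tested on random fixtures, and against
a brute-force optimiser of the marginal likelihood).

**Streaming approximation (SEMA).** When one observation arrives for
subject `i`, only that subject's running summaries and CDSS contribution are
recomputed with the *current* parameter estimates and swapped into the
totals (`T(t) = T(t-1) - T_i(t-1) + T_i(t)`); the M step then reruns from
the totals. Other subjects' contributions stay frozen, which makes the
update O(1) but the sufficient statistics only approximate — contributions
computed under old parameter values linger until that subject is seen
again. The approximation error vanishes as data accumulate; the package
asserts 5% agreement with batch EM at I = 200, n = 50.

## From fit to reference range

The Bayesian band is the central `1 - alpha` interval of the posterior
predictive sample (`y* ~ N(mu_i, sigma_i^2)` per retained draw; empirical
quantiles with linear interpolation). The EM band is the plug-in normal
interval: centre `(mu/tau^2 + (j-1)*ybar/sigma_i^2)/(1/tau^2 +
(j-1)/sigma_i^2)`, variance `1/(1/tau^2 + (j-1)/sigma_i^2) + sigma_i^2`.
Both need at least two prior observations to say anything about a personal
variance, so indices `j <= 2` fall back to the static tolerance interval
built from the other subjects — this keeps the three methods comparable at
early indices.

Abnormality is scored by the two-sided predictive tail probability
(empirical for the Bayesian method, exact normal for EM, population-normal
for static); thresholding the score at `alpha` is identical to falling
outside the `1 - alpha` band, and the scores are what the ROC analysis
ranks.

## What the simulation study emulates — and what it does not

`simulate_population()` generates exactly the world the model assumes:
normal subject means, normal observations, subject variances either fixed or
drawn from an inverse gamma whose mean and variance are set by
`r2 = E(WSV)/BSV` and `r1 = Var(WSV)/BSV`. The inverse-gamma choice is an
implementation decision (the generating law for the WSVs is not dictated by
the ratios alone); it is conjugate-consistent with the model's prior, and
its occasionally heavy tail is itself informative — it is why the *static*
normal fit slightly over-flags under strong heterogeneity (the marginal
population distribution becomes a heavy-tailed scale mixture).

The evaluation is leave-one-subject-out with case alteration: each subject
is independently a case with probability 0.5 (the assignment probability is
a design choice; only the ROC, not the AUC, depends on it), and a case's
final observation is shifted by exactly `3*sigma_i` away from its true mean
(downward if below it, upward otherwise). Because the evaluated points could
bias the fits, every subject's final observation is excluded from model
fitting; one joint fit per replicate then serves all subjects'
predictive scores, which is information-equivalent to per-subject refits up
to the other subjects' single held-out points and is what makes the full
grid affordable. The static cohort for a subject always excludes that
subject entirely. Streams are fed in round-robin order (everyone's first
visit, then everyone's second, ...), the realistic arrival pattern for a
cohort monitored in parallel.

A green simulation therefore establishes that the estimators and bands do
what the theory says *under the model*. It does not establish robustness to
trends, serial correlation, non-normality, or informative measurement
timing — none of which the generator produces.

## Numerical choices and degenerate inputs

* Variances are floored at 1e-10 when an M-step update would make them
  non-positive (warned); subjects with fewer than two observations keep the
  pooled WSV until they have two.
* Empirical predictive quantiles use the default linear interpolation;
  predictive tail scores are floored at `1/(m+1)` for `m` draws so a value
  beyond every draw still gets a positive score.
* Duplicate `(subject, index)` pairs, non-finite values and empty tables are
  rejected at validation; a constant sample is a hard error for the
  tolerance interval rather than a zero-width band.
* Seeds: every stochastic entry point takes an explicit seed; scenario
  replicates draw per-replicate seeds once, and each method consumes its own
  seeded RNG stream so results are invariant to the order in which methods
  are evaluated.

## Design choices that were genuinely open

* **Individual z-score scaling.** The individual-history statistic is
  implemented with the `sqrt(1 + 1/(n+1))` factor exactly as printed in its
  source, although the conventional prediction-interval factor is
  `sqrt(1 + 1/n)`; a `conventional_factor` flag switches. The tests derive
  the exact null size under the literal factor in closed form rather than
  pretending it is nominal.
* **Universal-WSV estimator** for the population-informed z-score: the
  standard unbiased pooled within-subject variance over subjects with at
  least two observations.
* **Tolerance factor.** Howe's approximation; isolated in
  `tolerance_factor()` so an exact method could be swapped in. Accurate to
  three decimals for n over 30.
* **Static cohort construction.** All observations of the other subjects are
  pooled (an option fits one mean per subject instead; in the simulation the
  two give indistinguishable detection performance, differing grand-average
  AUC by under 0.01).
* **Config files** are JSON (YAML accepted when the yaml package is
  installed).

## Known limitations

* The EM plug-in band ignores the sampling error of the parameter estimates,
  so with very short histories it over-flags (measured: about 0.16 at
  `alpha = 0.05` with three prior observations under strong heterogeneity,
  decaying to nominal by 50). The fully Bayesian band, which integrates
  over parameter uncertainty, stays near 0.05 throughout; prefer it when
  series are short and miscoverage matters.
* The grand-average AUCs of the benchmark grid depend on how the variance
  ratios are weighted; the package's grid spans r2 from 0.1 to 2 and
  measures about 0.82 for the static method — harder worlds (small r2)
  pull the static method down the most, and a grid weighted toward large r2
  would flatter it.
* No covariates, no trends, no multivariate biomarkers; one variance per
  subject for the whole series.
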