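# adaptref — adaptive reference ranges for longitudinal biomarker monitoring

`adaptref` builds **individualised, adaptive reference ranges** for
biomarkers that are measured repeatedly over time — blood chemistry in
athlete monitoring, continuous glucose readings, any setting where the same
person is tested again and again. Conventional ("static") reference ranges
are derived from a healthy population and applied identically to every
observation of every person; when a person's own within-subject variability
is small compared with the population's between-subject spread, a clinically
meaningful change can sit comfortably inside the static range and go
unnoticed. The package implements ranges that tighten around each individual
as their history accumulates, and a simulation framework that quantifies how
much detection performance this buys.

## The model

Observations are modelled hierarchically with **subject-specific
within-subject variances**:

```
y_ij | mu_i, sigma_i^2  ~  N(mu_i, sigma_i^2)      j = 1..n_i,  i = 1..I
mu_i | mu, tau^2        ~  N(mu, tau^2)
mu ~ N(0, nu^2),   sigma_i^2 ~ IG(a1, b1),   tau^2 ~ IG(a2, b2)
```

`tau^2` is the between-subject variance (BSV), `sigma_i^2` each subject's
own within-subject variance (WSV). Three routes to a reference range are
provided:

* **Static** (`tolerance_interval`, `static_band_for_subject`): a two-sided
  normal tolerance interval `mean ± k·sd` covering proportion `p` of the
  population with confidence `1 − α` (Howe's `k` factor), fitted on all
  *other* subjects and constant across a subject's series. A Harris–Boyd
  check (`stratification_ratio`, stratify when the group BSV ratio exceeds
  1.5) is included.
* **Fully Bayesian** (`gibbs_fit`, `dynamic_band_bayes`): all four full
  conditionals are conjugate, so the joint posterior is sampled by a Gibbs
  sweep `mu → tau² → {sigma_i²} → {mu_i}` (compiled inner loop, O(I) per
  iteration via per-subject sufficient statistics). The band for a subject's
  next observation is the central `1 − α` interval of its posterior
  predictive sample; the first two indices fall back to the static range
  because a personal variance needs at least two points.
* **Streaming EM / empirical Bayes** (`em_fit`, `sema_fit`, `sema_update`,
  `dynamic_band_em`): maximum-likelihood estimation of
  `(mu, tau², {sigma_i²})` by EM over the random-intercept model, with an
  O(1)-per-observation streaming approximation (SEMA) that keeps only
  `(n_i, ȳ_i, ȳ²_i)` and three complete-data sufficient statistics per
  subject — the whole state is a few vectors of length I, independent of the
  number of observations, and serialises to JSON for resumable streams. The
  band is the plug-in normal predictive interval with shrinkage weight
  `rho_i = tau²/(tau² + sigma_i²/(j−1))`.

Z-score baselines (`zscore_individual` with its exact Student-t reference,
and the population-informed variant with a universal WSV) are included for
comparison.

## Detection performance

`run_scenario`/`run_grid` reproduce a leave-one-subject-out evaluation:
simulate a population, randomly make each subject a case or control, shift a
case's final observation by `3·sigma_i` away from its true mean, score that
observation with each method's two-sided predictive tail probability, and
measure the ROC AUC. On the default grid (`benchmark_grid()`: I ∈
{5,10,20,100}, n_i ∈ {5,10,20,50,100}, WSV/BSV ratios r2 ∈ {0.1,…,2}, WSV
heterogeneity r1 ∈ {0,…,1}) this package measures grand-average AUCs of
about **0.99 (Bayesian) > 0.99 (streaming EM) > 0.82 (static)**, with the
gap to the static method widest when within-subject variability is small
relative to between-subject spread, and all methods converging as r2 grows.

## Worked example

```r
library(adaptref)

# a cohort of 25 subjects, 8 visits each; subject means spread with
# tau2 = 4 around 14, personal variances averaging a quarter of that
sim <- simulate_population(I = 25, n_per_subject = 8, mu = 14, tau2 = 4,
                           sigma2_spec = list(r1 = 0.2, r2 = 0.25), seed = 2)
tab <- sim$table

fit <- em_fit(tab)
fit
#> EM state: 25 subjects, mu = 14.24, tau2 = 2.539, mean sigma2 = 2.678
#>   iterations: 9, converged: TRUE

em_band_for_subject(tab, "S001", alpha = 0.05)
#>   subject index value lower upper atypical method
#> 1    S001     1  13.2  8.88  19.3    FALSE     em
#> 2    S001     2  13.3  8.88  19.3    FALSE     em
#> 3    S001     3  12.9 13.05  13.4     TRUE     em
#> 4    S001     4  12.4 12.68  13.6     TRUE     em
#> 5    S001     5  12.9 12.13  13.8    FALSE     em
#> 6    S001     6  15.7 12.25  13.7     TRUE     em
#> 7    S001     7  14.5 11.06  15.9    FALSE     em
#> 8    S001     8  14.1 11.25  16.0    FALSE     em

static_band_for_subject(tab, "S001")  # limits 8.88 – 19.28 at every index
```

Indices 1–2 carry the static fallback (8.88, 19.3). From index 3 the band is
personal: it hugs S001's own level and flags the jump to 15.7 at index 6 —
a value the static range considers unremarkable. (The very narrow band at
index 3 is the plug-in interval after only two observations; the fully
Bayesian band from `dynamic_band_bayes`, which carries parameter
uncertainty, is wider there and is the calibrated choice for short
histories: at index 6 it gives (12.0, 14.0) and also flags 15.7.)

The same fit can run on a live stream:

```r
state <- sema_fit(tab)                      # batch warm-up, then O(1) updates
state <- sema_update(state, "S001", 15.1)   # new observation arrives
dynamic_band_em(state, "S001")              # band for the next visit
```

## Command line

```sh
adaptref static   --input data.csv --subject A --p 0.95 --confidence 0.95 --out band.csv
adaptref zscore   --input data.csv --subject A --method individual --out scores.csv
adaptref bayes    --input data.csv --subject A --alpha 0.05 --iters 4000 --burnin 1000 --seed 7 --out band.csv
adaptref em       --input data.csv --subject A --alpha 0.05 --out band.csv
adaptref stream   --input stream.csv --state state.json --out alerts.csv
adaptref simulate --grid grid.json --methods static,bayes,em --replicates 200 --seed 11 --out results.csv
```

The launcher lives at `inst/cli/adaptref` (or call
`adaptref::adaptref_main()` with the same arguments). Input CSVs have the
header `subject,index,value`; `--log` analyses on the natural-log scale and
writes back exponentiated limits. Exit codes: 0 ok, 1 usage, 2 data,
3 numerical.

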