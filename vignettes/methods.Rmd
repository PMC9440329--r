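---
title: "Exhaustive out-of-sample weather-feature selection for district yield regressions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive out-of-sample weather-feature selection for district yield regressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropsieve)
```

## The model

cropsieve predicts annual crop yields per *district* (a spatial subunit
with its own yield series and monthly weather) with multiple linear
regressions of the form

$$y(t) = \alpha + \beta_0\, t + \sum_{i=1}^{d} \beta_i\, w_{i,t} +
\varepsilon, \qquad d \in \{0,\dots,4\},$$

where $y(t)$ is the yield (dt ha$^{-1}$) in harvest year $t$, $\beta_0 t$
a linear technology trend, and the $w_{i,t}$ are *weather features*: a
single weather variable (e.g. mean temperature `tas`, precipitation `pr`,
sunshine duration `sund`) aggregated (mean or sum) over a contiguous
window of 2–6 calendar months inside the 12-month season ending at a
crop-specific *cut-off month* (June for winter wheat, August for silage
maize, in the motivating application).  A feature is named by its variable
and zero-padded start/end months: `tas0506` is the May–June temperature
mean; `pr1202` the December–February precipitation sum, where months after
the cut-off are drawn from the calendar year before harvest.  With a
12-month season there are $\sum_{L=2}^{6}(13-L) = 45$ windows per
variable, hence 135 features for three variables and
$\binom{135}{4} = 13{,}232{,}835$ candidate four-feature regressions per
district and target year.

The scientific point of the package is **how the four features are
chosen**: not by expert preselection, but by an exhaustive search
disciplined to be strictly out-of-sample — every statistic used to select
features, combinations, or district models for a *target year* is computed
with that year's yields censored from all fits.  The pipeline runs in five
stages per target year:

1. **Screening** (`prospect()`).  For every district, all admissible
   $d$-feature subsets are fitted in-sample (target year censored) and the
   top $k$ (default 23) by $R^2$ retained.  Feature occurrences are
   tallied across districts; under the null that retained regressions draw
   features uniformly, each feature's count is Binomial$(n, p)$ with
   $n = \text{districts} \times k$ and $p = d/135$.  Features whose count
   strictly exceeds the smallest $c$ with $P(X \le c) \ge 0.999$ survive.
   At the reference scale ($n = 7498$, $p = 4/135$) this gives
   $E(x) = 222.163$, $\sqrt{np(1-p)} = 14.683$, cutoff 269.
2. **Evaluation** (`build_eval_table()`).  All subsets of the $q$ screened
   features of sizes $0..4$ (including the trend-only model, and excluding
   pairs of overlapping same-variable windows) are scored per district by
   the Pearson correlation between observed yields and leave-one-out
   predictions.
3. **Selection** (`select_combos()`).  "Global heroes" (highest mean $r$
   across districts) are pooled with "local heroes of subsets"
   (combinations ranked by their best $\lceil f \cdot n \rceil$ districts,
   $f = 1.0, 0.9, \dots, 0.1$), and every district takes its best pool
   member.  Choosing each district's global argmax instead
   (`local_heroes_only()`) is available but overfits single noisy series.
4. **Prediction** (`predict_district()`).  The selected combination is
   refitted per district — without the target year's yield for hindcasts,
   with all observed years for true forecasts — and evaluated at the
   target year's feature values.
5. **Aggregation** (`aggregate_districts()`).  District predictions are
   averaged with crop growing areas as weights (renormalised over
   districts that actually have predictions), regionally and for the whole
   domain; independent district errors partially cancel, so the aggregate
   is more accurate than typical districts.

## Why the search must be exhaustive and out-of-sample

In-sample fit at this search scale is meaningless: with millions of
candidate regressions the best in-sample $R^2$ is driven by selection
optimism (on our synthetic panels, in-sample $R^2$ near 0.9 coexists with
out-of-sample skill near 0.1, mirroring the experience that motivated the
design).  The selection of regressors carries roughly as much information
as the coefficients; re-using the target year anywhere in the selection
chain silently inflates validation scores.  The package therefore treats
out-of-sample purity as a testable invariant: perturbing $y(t)$ in every
district changes *nothing* in the target-year-$t$ screening counts,
evaluation table, selection, or hindcast (this is asserted bitwise in the
acceptance suite).

One subtlety is the evaluation-stage correlation.  A plain leave-one-out
loop over all observed years produces one estimate per year (22 with 22
yield years) but lets $y(t)$ enter the Pearson $r$ as an observation.  The
default `strict = TRUE` additionally censors the target year's pair from
$r$, making the whole table invariant to $y(t)$; `strict = FALSE`
reproduces the plain behaviour for comparability.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cutoff_month` | 6 | last weather month before harvest (8 for late crops) |
| `window_min`, `window_max` | 2, 6 | feature window length bounds (months) |
| `d_max` | 4 | max weather features per regression |
| `k` | 23 | regressions retained per district in screening |
| `confidence` | 0.999 | binomial screening confidence |
| `min_years` | 17 | minimum observed yields per district |
| `min_pairs` | 8 | minimum LOO pairs for a valid $r$ cell |
| `n_global`, `fractions` | 5, 1.0…0.1 | selection pool composition |
| `min_coverage` | 0.5 | districts with valid $r$ required for pool eligibility |
| `strict` | TRUE | censor the target year from the evaluation $r$ |
| `non_overlap` | TRUE | forbid overlapping same-variable windows in one model |

Defaults follow the motivating application where it states them
(`k = 23`, `min_years = 17`, confidence 99.9%, $d \le 4$, cut-off months).
Where the original recipe is not public — the exact merge rule of the
selection pool — the implementation is a documented interpretation: the
top 5 global combinations plus the top combination per fraction, both
knobs configurable; on real data the original reports 9–19 applied
combinations per year, and these defaults land in that range on synthetic
panels.  Ranking ties (rare with continuous data) break towards the
lexicographically smaller feature-name combination, deterministically.

## Numerical choices

The exhaustive search is compiled (Rcpp).  For each district the Gram
matrix of $[1, t - \bar t, W]$ is accumulated once; each candidate subset
solves its $\le 6 \times 6$ normal equations by a dense Cholesky
factorisation read out of the big Gram matrix ($\approx 80$ ns per subset,
so the full $2.5\times10^6$-subset search over 60 districts takes seconds,
and 326 districts x 135 features remains tractable on one CPU).  The trend
column is centred to keep calendar-year Grams well conditioned.  A
candidate whose Cholesky pivot falls below $10^{-10}$ (relative) is
*degenerate* — rank-deficient after censoring — and is excluded from
rankings rather than scored.  The R-level `fit_regression()` uses QR and
serves as the independent cross-check: unit tests require the compiled
route to agree with explicit normal-equations and `lm()` oracles to
$10^{-8}$.

LOO fits are genuine refits via rank-one downdates of the subset Gram
($G - z_j z_j^\top$), which is algebraically exact; cells with fewer than
`min_pairs` valid pairs, zero variance, or degenerate fits are missing
(`NA`), never zero.  Missing monthly weather makes the affected feature
value missing for that district-year — silent imputation would bias the
regressions.  Missing yield years are simply dropped (pairwise deletion in
$r$).

Validation $R^2_\mathrm{val}$ is explained variance $1 - SSE/SST$ about
the observed mean (it can be negative); the squared Pearson correlation is
reported alongside, since printed headline numbers elsewhere could follow
either convention.  Hindcast uncertainty bands are
$\pm 1.96\,\mathrm{sd}(e)$ of the regional prediction errors; the true
forecast interval is wider and centred on the mean error, implemented as
$t_{0.975,\,n-1}\,\mathrm{sd}(e)\sqrt{1 + 1/n}$ — the reference only says
"slightly wider", so the $t$/$\sqrt{1+1/n}$ inflation is this package's
concrete reading (a plain-normal variant is a one-line change in
`uncertainty_interval()`).

Sunshine duration's aggregation operator is nowhere stated in the source
material; monthly *sums* of hours are used as the physically additive
convention (means would preserve within-length rankings but not across
window lengths).  Operators are configurable per variable.

## The synthetic world

`simulate_dataset()` generates the panel every end-to-end test runs on:
60 districts, 25 harvest years, two variables (`tas` mean, `pr` sum) —
sized so the full pipeline runs in minutes on one CPU.  Monthly weather is
seasonal climatology plus a shared regional anomaly plus district noise;
the shared fraction sets the inter-district correlation (default 0.7,
mimicking spatially coherent mid-latitude weather fields).  Yields follow
the regression model itself: district-specific intercept
($\mathcal N(75, 8^2)$ dt/ha) and trend ($\mathcal N(0.5, 0.15^2)$ dt/ha
per year), a planted 3-feature signal (`tas0506` $-2.5$, `pr0306` $+0.04$,
`tas1011` $+1.2$ — warm late springs hurt a winter cereal, spring rain
helps, mild late autumns help), and Gaussian noise whose district-level sd
equals the district's weather-signal sd (a 50% noise variance share).

What a green test does and does not establish: the generator honours
exactly the structure the analysis assumes — linear trend, additive window
effects, Gaussian noise, complete weather.  Recovery and purity results on
it validate the *machinery* (search, screening arithmetic, censoring,
selection, aggregation), not the meteorological realism: real data add
nonstationary trends, fat-tailed extremes blind to monthly aggregation,
heteroscedastic and spatially structured noise, and missing records.
Planted-feature recovery is counted as a window-overlap match ($\ge$ 50%
of the planted window's months, same variable) because adjacent windows
are nearly collinear and exact window identity is not statistically
identifiable.

Determinism: all randomness is R's default Mersenne-Twister; the
weather, district-parameter, yield-noise, and area draws use distinct
fixed offsets of the one `seed` argument, so a dataset is reproducible
from its seed alone, across platforms.

## Known limitations

- The linear base trend is per district and unpenalised; stagnating yield
  trends are mis-extrapolated.
- Monthly aggregation cannot represent short extremes (heat days, storm
  rainfall).
- The selection pool recipe is an interpretation where the original is
  unpublished; `n_global` and `fractions` exist precisely because of that.
- The evaluation stage's computational cost grows as
  $\sum_{s \le 4}\binom{q}{s}$ per district; screened sets much larger
  than $q \approx 40$ get slow on one CPU.
- Weather completeness is assumed within a district's usable years for
  the compiled fast path (rows with any missing screened feature are
  dropped district-wide for that combination set).

## A worked example

```{r example, eval = FALSE}
ds <- simulate_dataset(seed = 1)                    # 60 districts x 25 years
fm <- build_feature_matrix(ds$panel, ds$cutoff_month)

scr <- prospect(fm, ds$yields, target_year = 2010)  # stage 1
scr$q                                               # features surviving the screen
et  <- build_eval_table(fm, ds$yields, scr$selected, 2010)  # stage 2
sel <- select_combos(et)                            # stage 3
yr  <- run_year(fm, ds$yields, 2010)                # stages 1-4 in one call

recovery_report(scr$selected, ds$truth)$recall      # planted-feature recall
```

The same flow, file-based: `write_synthetic_dataset("data/")` writes the
ASCII tables and a control file; `run_all("data/control.txt")` executes
all stages for every target year and persists each intermediate table so
any stage can be re-run from files.
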