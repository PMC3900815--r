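---
title: "Forecasting mortality-age curves: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting mortality-age curves: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvecast)
```

## The model

`curvecast` treats the annual sequence of age-specific mortality rates as a
functional time series. Writing $x_1 < \dots < x_A$ for the age-group
midpoints (the midpoint of the group $(l, u)$ is $(l+u)/2$, so "45--49"
sits at 47), the observed log rate in year $t$ is an underlying smooth
function of age observed with error,
$$ y_t(x_i) = f_t(x_i) + \sigma_t(x_i)\,\varepsilon_{t,i}, $$
and the smooth curves follow a functional principal components model
$$ f_t(x) = \mu(x) + \sum_{k=1}^{K} \beta_{t,k}\,\phi_k(x) + e_t(x), $$
with orthonormal basis functions $\phi_k$, uncorrelated score series
$\beta_{\cdot,k}$, and a model residual $e_t(x)$ with variance curve
$v(x)$. Each score series is forecast independently with a damped-trend
exponential smoothing state-space model, and curve forecasts are rebuilt
from the forecast scores. The key assumptions are that (i) log mortality is
smooth in age, (ii) the age-patterns of variation are stable enough over
time to be captured by a few fixed basis functions, and (iii) the score
dynamics are adequately described by a local level-plus-damped-trend
process. Structural breaks (screening programmes, treatment changes,
cohort effects) violate (ii)--(iii) and are outside the model.

Zero observed rates are treated as missing rather than offset-adjusted: the
log is undefined there, and any pseudo-rate constant would distort the curve
tail. The smoother interpolates across missing cells. Rates are
log-transformed on the per-100,000 scale; the scale choice only shifts
$\mu(x)$.

## Smoothing

Each year is smoothed with a penalized cubic B-spline (knots at the age
midpoints, three boundary knots each side, second-difference coefficient
penalty), fit by penalized weighted least squares. The penalty null space
contains linear functions, so lines are reproduced exactly at any penalty
and the infinite-penalty limit is the weighted least-squares line. Weights
default to uniform because the package takes precomputed rates without
denominators; a weight matrix argument accepts inverse-variance weights when
death counts are available.

The penalty is chosen per year by generalized cross-validation over
$\lambda \in 10^{-4}, \dots, 10^{4}$ (25 logarithmic steps), with ties
broken toward the larger (smoother) $\lambda$. Curves are evaluated on a
uniform grid (default step 1 year of age) spanning the midpoint range; the
same grid carries all downstream quadrature. The observational variance
$\sigma^2(x)$ is pooled across years — per-age mean squared residuals,
inflated by the average residual-degrees-of-freedom ratio, then regressed on
age with the same smoother and floored at zero — because per-year estimates
from 8 residuals are too unstable.

## Functional principal components

The decomposition is computed from the singular value decomposition of the
centered, quadrature-weighted curve matrix (numerically preferable to
forming the covariance). All inner products use trapezoidal weights on the
shared grid. Scores are quadrature inner products
$\langle f_t - \mu, \phi_k\rangle$; variance-explained proportions are
eigenvalue shares; the residual variance curve $v(x)$ is the pointwise
variance (denominator $T$) of the reconstruction residuals. Each basis
function is signed so that its quadrature integral is positive (first
nonzero element positive in the degenerate case), which makes refits
bit-reproducible.

## Score forecasting

The damped-trend model in innovations form is
$$ y_t = \ell_{t-1} + \phi_d b_{t-1} + \varepsilon_t,\qquad
   \ell_t = \ell_{t-1} + \phi_d b_{t-1} + \alpha\varepsilon_t,\qquad
   b_t = \phi_d b_{t-1} + \beta\varepsilon_t. $$
Parameters and initial states are estimated jointly by bounded quasi-Newton
maximization of the Gaussian innovations likelihood from five fixed starting
points; ties are broken toward the smallest $\alpha$. Bounds:
$\alpha \in [10^{-4}, 0.9999]$, $\beta \in [10^{-4}, \alpha]$ (enforced by
optimizing the ratio $\beta/\alpha$), and $\phi_d \in [0.8, 0.98]$ by
default — the classical damping range; damping below 0.8 makes the trend
die implausibly fast for annual demographic series, and $\phi_d$ near 1 is
indistinguishable from an undamped trend on 50 observations. The bounds are
overridable, and `fix_phi = 1` gives the undamped linear-trend special
case. Series shorter than 8 observations fix $\phi_d = 0.9$ and estimate
only the rest; constant series return a degenerate flat model. Forecast
means and variances use the closed forms
$$ \hat y_{T+h} = \ell_T + (\phi_d + \dots + \phi_d^h) b_T, \qquad
   v_h = \sigma^2\Big(1 + \sum_{j=1}^{h-1} c_j^2\Big),\quad
   c_j = \alpha + \beta(\phi_d + \dots + \phi_d^j), $$
verified in the tests against 200,000-path Monte Carlo simulation of the
recursions. Intervals are Gaussian; no bootstrap option in this version.

## Curve forecasts and intervals

The pointwise log-scale forecast variance is the sum of three stored
components: propagated score-forecast variance
$\sum_k \phi_k(x)^2 \mathrm{Var}(\hat\beta_{T+h,k})$, the model-residual
variance $v(x)$, and the observational variance $\sigma^2(x)$; the latter
two are held constant over the horizon. Rate-scale intervals exponentiate
the log-scale Gaussian bounds (quantile mapping), and the rate-scale point
forecast is $\exp(\text{mean log})$ — the median of the implied lognormal,
not its mean.

Whether the observational term belongs in the interval depends on the
interval's target. The package exposes both toggles and pairs them
consistently in its calibration experiment: intervals for the *future smooth
curve* (the default target, and what a mortality forecast is usually read
as) include score and model-residual variance but not observational noise;
intervals for a *future noisy observation* include all three.

## Basis-order selection

The integrated squared forecast error between a forecast and a realized
smooth curve is the trapezoidal integral of the squared difference over age,
divided by the age-range length, so a constant offset $\delta$ scores
$\delta^2$ (units: squared log-rate). Order selection holds out the last $H$
years (single split, default $H = 10$), fits the full pipeline on the
training window for each candidate $K$, and averages the ISFE over horizons
$1..H$ scored against the held-out years' smooth curves. Held-out truth is
the holdout year smoothed with the same settings — the quantity the model
claims to forecast. The component-1 scores are identical across candidate
$K$ (nested SVD), so MISE differences isolate the higher components.

Selection minimizes MISE with ties toward smaller $K$. An *adequate-fit*
rule is available (`adequacy_tol`): the smallest $K$ whose MISE is within a
stated fraction (typically 5%) of the minimum. The strict minimum is the
default, but the adequate-fit rule is the recommended instrument — and the
one used in the package's recovery experiments — because extra components
beyond the truth change holdout MISE only at noise level, making the strict
argmin an unstable coin flip among near-ties while the 5% rule consistently
returns the parsimonious order.

## The synthetic generator

`simulate_surface()` draws surfaces from exactly the model above, with every
latent quantity stored: damped-trend score paths (extended past the observed
window so future truth exists), white-coefficient residual components
spanning $v(x)$, and observational noise, each from an independently seeded
stream so one source can be toggled without perturbing the others.

The default configuration imitates the shape of a female breast-cancer
mortality surface: 8 five-year age groups 45--84 (midpoints 47--82), $T =
52$ annual observations, a concave increasing mean log-rate curve rising
from about 55 to about 220 deaths per 100,000 across the age range, one
dominant component peaked at ages 60--70 whose score follows a damped-trend
process ($\alpha = 0.3$, $\beta = 0.05$, $\phi_d = 0.9$, $b_0 = 0.25$,
$\sigma = 0.12$ — a persistent rise that levels off, with innovations that
can turn it downward), two small residual components (coefficient sd 0.05),
and observational noise sd 0.04 on the log scale.

What the generator does *not* emulate: death-count (Poisson) noise whose
variance depends on population size, ICD coding-revision jumps, cohort
effects travelling diagonally through the age-period plane, and
cross-component score correlation. Passing calibration tests on these
surfaces therefore demonstrates internal consistency of the method under
its own assumptions, not robustness to the ways real registry data violate
them.

A note on realized versus nominal structure: score processes with
persistent dynamics produce sample paths that are correlated across
components in any finite window, so the empirical eigenstructure of a
generated surface is a rotation of the generating basis.
`implied_var_explained()` therefore reports the eigenvalue shares of an
exact decomposition of the realized noiseless truth curves — the correct
oracle for what the pipeline's FPCA should recover.

## Experiment sizes and numerical choices

The calibration experiment uses 500 replicate surfaces of the default
scenario, forecast to horizon 20 at the 80% level, with coverage of the true
future smooth curve recorded at horizons 1, 10 and 20 on the full age grid
and summarized as the average over ages and horizons. The experiment also
reports coverage per horizon; in these runs short horizons come out
conservative (the estimated $v(x)$ absorbs some smoothing noise) and long
horizons anti-conservative (maximum-likelihood score forecasts ignore
parameter uncertainty), deviations that partially offset in the average —
a known behaviour of plug-in prediction intervals.

Order-selection recovery uses 20 seeds per scenario: a rank-1 scenario at
the default $T = 52$, and rank-2/rank-3 scenarios with longer records
($T = 150$--$200$, holdout 5) whose secondary components are persistent
level processes with well-separated eigenvalue shares (roughly 5x and 3x).
The longer record is a property of the scenario, not a tuning trick: a
persistent component's out-of-sample payoff grows with the displacement it
accumulates over the record, and with only ~40 training years that payoff
is a single noisy chi-square draw that no selection rule can read reliably.

Numerical guards worth knowing about: GCV denominators are floored to avoid
division by zero at effective degrees of freedom near $n$; residual-variance
estimates floor the degrees-of-freedom correction; coverage comparisons use
a $10^{-8}$ relative floating-point guard so zero-width degenerate intervals
count numerically identical targets as covered; the FPCA of an exactly
constant curve set returns zero scores and zero variance-explained rather
than failing.

## Limitations

Prediction intervals are plug-in: parameter and model-selection uncertainty
in the smoother, the decomposition and the score models is not propagated,
which is the main driver of the long-horizon undercoverage noted above.
Score models are univariate; any residual cross-score dependence is ignored.
The holdout MISE uses a single split by default (an expanding-window variant
would be more stable but multiplies cost). Intervals are pointwise, not
simultaneous over age. The model is not designed for populations with strong
cohort effects or imminent structural change.
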