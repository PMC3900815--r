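Package: curvecast
Title: Functional Data Analysis Forecasting of Age-Specific Mortality Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models annual age-specific mortality rates as a functional time
    series: each year's log mortality-age profile is smoothed with a
    penalized spline, the smooth curves are decomposed by functional
    principal components into a mean curve, orthonormal age-basis functions
    and uncorrelated score series, each score series is forecast with a
    damped-trend exponential smoothing state-space model fitted by maximum
    likelihood, and the forecasts are recombined into future mortality-age
    curves with pointwise prediction intervals built from score-forecast,
    model-residual and observational variance components. Includes
    out-of-sample integrated squared forecast error for basis-order
    selection, and a synthetic-surface generator with stored ground truth
    for calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    splines,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
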