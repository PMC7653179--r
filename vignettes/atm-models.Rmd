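---
title: "Age trajectories of child mortality: models, theory, and the synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age trajectories of child mortality: models, theory, and the synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atmort)
```

## The estimand and its estimator

The object of study is the age trajectory of mortality (ATM): the force of
mortality μ(x) through childhood, estimated per age category [A, B) as

    mu = D / (L * (B - A))

deaths divided by person-years, where L is the living population passing
through the age window and B − A its width in years. One year is the time
unit everywhere (1 day = 1/365 year; leap years ignored), so rates are per
person-year; the conventional per-100,000 scale is presentation only.
Demographic drift of L inside a window is ignored: through childhood the
living counts change by orders of magnitude less than the death counts.

Zero deaths in a category make the log-scale rate undefined. The package
follows the registry practice of pooling before dividing (the Halley
method): deaths and living counts are summed per age category over all
selected countries and calendar years, and only then turned into rates
(`halley_aggregate()`). Aggregation is exact, associative and commutative,
so pooling three country blocks equals pooling all records at once. A
trajectory with a remaining zero-death category is flagged incomplete;
log-scale fits refuse it by default (`strict` mode) and can instead drop the
undefined points on explicit request (`drop_undefined = TRUE`). This keeps
the default behaviour identical to the rule that such a trajectory "is not
constructed", while allowing exploratory use.

The representative age of a category is always the arithmetic midpoint of
its endpoints, including the wide [28 d, 365 d) and [5, 10) bins. This is a
deliberate, consequential choice discussed under *Discretization geometry*
below.

## The log-log model family

All model fitting happens on the log-log scale by unweighted ordinary least
squares with natural logarithms. The family, from general to nested:

* **Quadratic**: ln μ = c + γ ln x + δ (ln x)². Only used to test
  linearity: the t-test of δ = 0 and the equivalent F-test against the
  linear submodel are both reported (`test_linearity_quadratic()`).
* **Linear (two parameters)**: ln μ = c + γ ln x. The slope γ gets a
  t-based 95% confidence interval on n − 2 degrees of freedom, and fixed
  values of interest — 0 (age independence), −1 (inverse proportion), −2
  (the uniform-risk regime) — are tested by two-sided t-tests
  (`test_fixed_slope()`).
* **Inverse proportion (one parameter)**: μ(x) = μ₁/x. Its scale has the
  closed form ln μ₁ = mean(ln μᵢ + ln xᵢ) — the least-squares minimizer,
  with the same residual degrees of freedom (n − 1) as an arithmetic mean —
  and its fit quality is R²_b = 1 − SS_resid/SS_total measured against the
  fixed slope −1 line (`fit_inverse_proportion()`).
* **Nested F-test**: whether the two-parameter line improves on the
  one-parameter inverse proportion,
  F = (RSS₁ − RSS₂)/(RSS₂/(n − 2)) ~ F(1, n − 2).

Residual diagnostics are deliberately two, labelled in the output, because
the appropriate check differs by model: for the one-parameter fit, the
slope of residuals on ln x (an age trend the fixed slope failed to absorb);
for the two-parameter fit, whose residuals are orthogonal to ln x by
construction, the quadratic term as a U-shape proxy.

Degenerate inputs follow one convention: a model that fits exactly cannot
reject its own adequacy, so zero-RSS reference fits give p = 1, and a
perfect linear fit makes the fixed-slope t-test an error rather than a
0/0. All tests default to α = 0.05, configurable. No multiple-testing
correction is applied; raw p-values are reported for the reader to adjust
if desired.

Unweighted (rather than death-count-weighted) least squares is itself a
design decision: the trajectories of interest span six orders of magnitude
in age and three in rate, the log transform already stabilizes the relative
sampling error, and plain least-squares coefficients of determination are
the standard summary in this literature.

## The theory of congenital individual risks

The explanatory layer assumes a heterogeneous born population: each
individual carries a fixed congenital risk r (per person-year) and the
subpopulation at level r survives exponentially, S(r, x) = e^(−r·x). The
majority of the population has negligible risk, so the observed rate — the
death intensity relative to the (nearly constant) initial population — is

    mu(x) = integral f(r) * r * exp(-r * x) dr

over the risk density f (`hazard_from_density()`). Identifying μ(x) with
this death intensity over a constant denominator, rather than the exact
mixture hazard, is the reading under which the closed forms below hold; the
two differ by the survivor fraction, which stays within a couple of percent
of 1 whenever the impaired mass is small (the regime the theory assumes).

Three density shapes generate the three empirically relevant regimes:

* f ∝ 1/r ("the more severe, the rarer") gives μ(x) = c/x — the inverse
  proportion, log-log slope −1;
* f flat on (0, r_max] (no selection against severity) gives
  μ(x) = c·(1 − e^(−r_max·x)(1 + r_max·x))/x², which approaches c/x² —
  slope −2 — once r_max·x ≫ 1;
* f ∝ 1/r truncated at r_max gives the **bending** trajectory
  μ(x) = (μ₁/x)(1 − e^(−r_max·x)): approximately the constant μ₁·r_max
  while r_max·x < 1 (strict inequality is the convention in
  `constant_approx_region()`), and μ₁/x for large r_max·x.

`fit_bending()` estimates (μ₁, r_max) by least squares, on the log scale by
default for consistency with every other comparison in the family (the
natural-scale option is retained because either reading is defensible;
at zero noise both recover the same optimum). Numerical choices: the
optimization runs in (ln μ₁, ln r_max); μ₁ is initialized from the
closed-form one-parameter estimator applied to the last three points (where
the curve is essentially μ₁/x) and r_max from the first-bin rate divided by
that μ₁ (the flat-regime identity rate ≈ μ₁·r_max); five log-spaced r_max
starts guard against local minima; L-BFGS-B bounds r_max to [10⁻⁴, 10⁴] per
year (century-scale to sub-hour risks), with a Nelder-Mead polish. On data
that are already log-log linear with slope −1 the two parameters are not
jointly identifiable — the curve straightens as r_max grows — so the fit
runs to the upper bound and is flagged `straight_line_regime` instead of
pretending convergence.

## Historical models

Four published shapes for the post-birth mortality decline are fitted on
the log scale for comparability (`fit_historical()`); their exact original
parameterizations vary across sources, so the package uses the canonical
published forms and documents the mapping:

* `EXP`: μ(x) = a·e^(−b·x), the exponential (Gompertz-type) decline; linear
  in (x, ln μ), fitted by OLS.
* `BP`: the biometric model writes cumulative infant deaths as linear in
  log³(1 + age); differentiating gives the hazard
  μ(x) = 3b·ln²(1 + x/s)/(x + s). The level constant of the cumulative form
  vanishes under differentiation, so the time scale s (canonically one day)
  is kept free to preserve the two-parameter count. The scale is profiled
  out analytically and s found by a 200-point log-grid search refined with
  `optimize()`.
* `HP`: the childhood term A^((x+B)^C) of the Heligman-Pollard law (the
  senescent terms are irrelevant below age 10). ln A is profiled out
  (linear in the weights (x+B)^C) and (ln B, ln C) optimized by Nelder-Mead
  from a 3×3 multi-start grid.
* `WEIBULL`: the Weibull hazard is a power law a·x^(shape−1), identical to
  the two-parameter log-log line except that its exponent must exceed −1
  (shape > 0). When the unconstrained slope violates the bound the fit pins
  the slope at −1 — where the scale estimator coincides with the
  inverse-proportion closed form — flags `constraint_active` and warns.

`compare_models()` ranks everything with one adjusted R² rule,

    adj R2 = 1 - (RSS / (n - k)) / (SS_total / (n - 1)),

with k the number of fitted parameters. Under this rule the one-parameter
model's adjusted value reduces to its plain R²_b (one parameter, like a
mean, uses one degree of freedom) and the two-parameter line reproduces
`summary.lm`'s adjusted R². Negative values are possible and meaningful: the
model fits worse than a constant.

## The synthetic cohorts

`simulate_cohort()` draws risks per individual (inverse-CDF sampling:
log-uniform for the reciprocal family), exponential death times at each
risk (r = 0 individuals are immortal within the window), and tabulates
deaths per bin with the living denominator equal to the survivors entering
the bin. One RNG stream per (population, year) cell is derived from the
master seed and the cell identity, so subsetting populations or years never
changes the remaining cells, and identical specifications are bit-for-bit
reproducible. `expected_counts()` is the noise-free oracle: expected deaths
in [A, B) are N·∫f(r)(e^(−rA) − e^(−rB))dr (closed forms for the point-mass
and uniform families, adaptive log-scale quadrature at relative tolerance
10⁻¹⁰ for the reciprocal family), rounded half-even to stay a valid count
table; at the default cohort size of 10⁷ rounding shifts fitted slopes by
well under 0.1%.

The preset scenarios (registered in `inst/extdata/presets.yaml`) fix the
study conditions:

* Impaired fraction `p_impaired = 0.02` for the interval families. The
  theory only requires "a small minority"; 2% is of the order of the
  registered prevalence of serious congenital anomaly and keeps the living
  denominators within 2% of the cohort size, which is what the
  constant-denominator reading of μ(x) assumes. Slope recoveries are
  insensitive to this value (checked over 0.005–0.1).
* `inverse_proportion`: reciprocal risks on (10⁻⁴, 10³] per year, N = 10⁷.
  r_min = 10⁻⁴ makes depletion of the mildest risks negligible by age 10;
  r_max = 10³ corresponds to a mean survival of about nine hours for the
  severest lethal anomalies and places the flat-to-decline transition of
  the induced curve at the first representative age (see below), so the
  nine-bin trajectory is consistent with the slope −1 line (the recovered
  slope on expected counts is −0.993).
* `perinatal_uniform`: uniform risks on (0, 50] per year — no selection
  against severity, worst risks acting within days — so the slope −2
  asymptote (r_max·x ≫ 1) is fully reached on [1, 10); recovered slope
  −2.007.
* `bending`: reciprocal risks capped at r_max = 1.5 per year; the bend sits
  at about eight months, inside the observation window, which is what makes
  both parameters identifiable (recovered within about 2% on expected
  counts at N = 10⁷).
* `neoplasm_flat`: a 0.8% susceptible subpopulation at a constant risk of
  0.005 per year — age-independent mortality on [1, 10) with negligible
  depletion (r·x ≤ 0.05), the situation where the total deaths over the
  window bound the susceptible pool from below
  (`subpopulation_lower_limit()`).
* `homogeneous`: a point mass, for calibration tests (every bin estimates
  the same constant hazard).

**What the generator emulates:** the WHO age grid with its four sub-year
categories, multi-country multi-year replication with independent streams,
heterogeneous congenital risk with exponential within-level survival, and
cause labels mapping to distinct risk families. **What it does not:**
cause-of-death misclassification, external causes, migration, seasonality,
secular trends in the birth cohorts, within-lifetime changes of an
individual's risk, and any dependence between the living denominators and
the deaths other than cohort depletion. Tests that pass on these cohorts
therefore validate the estimators and the pipeline mechanics, not the
epidemiological claims about real registries.

## Discretization geometry of the WHO grid

The midpoint convention interacts with the grid's wide logarithmic bins in
a way that matters for parameter recovery, and the package makes no attempt
to hide it. For a hazard exactly proportional to 1/x, the binned rate over
[A, B) is the *logarithmic-mean* value c·ln(B/A)/(B − A), not the midpoint
value c/((A+B)/2); on [28 d, 365 d), where B/A = 13, the binned rate sits
a factor 1.5 (0.40 on the log scale) above the midpoint line. Meanwhile a
finite r_max suppresses the rate below the line wherever r_max·x ≲ 1. The
two effects act on opposite ends of the nine-bin childhood window:

* with r_max near 10³ per year the suppression at the first representative
  age (0.5/365 year) roughly offsets the wide-bin elevation and the fitted
  nine-bin slope is −1 to within 0.01 — the `inverse_proportion` preset's
  regime;
* pushing r_max to infinity (the pure 1/x limit) leaves only the wide-bin
  elevation and steepens the fitted slope to about −1.15;
* pulling r_max down to 10² per year moves the bend (age 1/r_max ≈ 3.7
  days) inside the infant bins and flattens the fitted slope to about
  −0.82. Likewise, a uniform density with r_max = 2 per year reaches its
  x⁻² asymptote only partially on [1, 10), fitting near −1.83 rather than
  −2, whereas r_max ≥ 10 per year fits −2 within 0.01.

The acceptance script (`scripts/acceptance.R`) computes the slopes at
exactly these generator settings; the numbers it reports are the honest
binned-midpoint values described here. Real count tables are not bound by
this geometry: a registry whose wide-bin midpoint rates do sit on the −1
line implies an infant hazard that deviates from an exact power law inside
the first year. A synthetic cohort that *is* an exact power law cannot
reproduce both the binning rule and the midpoint line simultaneously. The
vignette states this openly because it is
the main caveat when translating parameter-recovery results from the
simulator to registry data.

## Problem sizes and runtime

Expected-count analyses use N = 10⁷ and cost only a few quadratures, so the
end-to-end pipeline runs in seconds. Stochastic calibration tests use
cohorts of 10⁵–10⁶ with 50–200 replicates, and the Monte-Carlo size checks
of the F-test and the linearity test use 1,000–2,000 replicates of the
nine-point fit; the full test suite completes in about a minute on one CPU.

## Known limitations

* The package deliberately stops at the analysis layer of count tables; it
  does not parse any registry's raw dump format (the canonical CSV schema
  is the interface), build abridged life tables, or smooth trajectories.
* The bending fit's parameters are unidentifiable on straight-line data by
  construction; consumers must check `straight_line_regime` before
  interpreting r_max.
* Fixed-slope and F-tests assume homoskedastic Gaussian log-scale errors;
  Poisson sampling noise in small-count bins is heteroskedastic, and no
  autocorrelation-robust inference is provided.
* The susceptible-subpopulation bound is exactly what it claims: a lower
  limit, informative only when mortality in the window is genuinely
  age-independent.
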