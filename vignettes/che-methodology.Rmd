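---
title: "Catastrophic health expenditure: methodology and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Catastrophic health expenditure: methodology and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(checap)
```

## The problem

Out-of-pocket (OOP) health spending — consultations, hospitalization,
medicines, diagnostic tests and the transport needed to reach care — can
consume so much of a household's resources that it crowds out basic
consumption.  A household is said to incur **catastrophic health
expenditure (CHE)** when its OOP health spending reaches a set fraction
of its *capacity to pay*.  `checap` implements the capacity-to-pay
methodology used throughout the health-financing literature, oriented to
household surveys of families caring for a psychiatric outpatient, where
CHE incidence is known to be high and the determinants (income,
household size, hospitalization and medicine costs, patient sex and
employment) are of direct policy interest.

## The statistic

For household $h$, with annual total expenditure $THE_h$, annual food
expenditure $food_h$ and annual OOP health spending $OOP_h$:

1. **Equivalized size.** $eq_h = size_h^{\beta}$ with $\beta \in (0,1]$.
   The default $\beta = 0.56$ is the conventional cross-country
   estimate of household economies of scale; $\beta = 1$ recovers the
   per-capita scale.
2. **Food-share poverty line.** Let $w_h = food_h / THE_h$.  Households
   whose food share lies in the 45th–55th percentile window of the
   sample distribution are taken as the reference group — neither so
   poor that food crowds out everything else, nor so rich that food is
   a token share — and the line is the mean of their per-equivalent-adult
   food spending, $pl = \operatorname{mean}_{h \in W}(food_h / eq_h)$.
3. **Subsistence expenditure.** $SE_h = pl \cdot eq_h$.
4. **Capacity to pay.** $PC_h = THE_h - SE_h$.  For households spending
   less than the sample's subsistence standard this is negative; the
   poverty line is then substituted by the household's own food
   spending, $PC_h = THE_h - food_h$, which is non-negative whenever
   food is contained in total expenditure (ingestion rejects rows where
   it is not).
5. **CHE flag.** $CHE_h = \mathbf{1}\{OOP_h / PC_h \ge z\}$, with the
   default threshold $z = 0.30$ and a **closed** boundary: a household
   sitting exactly at 30% is flagged.  Sensitivity analysis repeats the
   flag at $z \in \{0.10, 0.20, 0.30, 0.40\}$ from a single
   decomposition pass; incidence is non-increasing in $z$ by
   construction.
6. **Incidence.** $E = 100 \cdot \#\{CHE_h = 1\} / n$, reported with a
   Wilson score 95% interval — chosen over the Wald interval for its
   behavior near 0% and 100%, and because the underlying surveys are
   small (hundreds of households).

The whole chain is scale-invariant: multiplying every money field by a
common positive constant moves $pl$, $SE_h$, $PC_h$ and $OOP_h$
together and leaves every flag unchanged.  This is the key invariant
the test suite checks, alongside exact equivalence with an
independently coded brute-force implementation on small random
datasets.

### Numerical and edge-case choices

* **Percentile definition.** The reference window uses the empirical
  nearest-rank percentile (`quantile(type = 1)`) with inclusive bounds.
  Interpolating definitions give platform- and version-stable results
  too, but nearest-rank makes the window membership a pure rank
  statement, reproducible by hand.
* **Zero total expenditure** makes the food share undefined: such
  households are excluded from the reference window with a warning.
* **Zero capacity to pay** with positive OOP is flagged catastrophic at
  every threshold (any spending against no capacity), with a warning;
  zero OOP against zero capacity is not flagged.
* **Weights.** The window mean is unweighted unless a `weights` column
  is present; surveys of this kind are typically simple random samples,
  and the weighted estimator reduces to the unweighted one under unit
  weights.
* **Period and currency are metadata**, not column names.  `annualize()`
  multiplies money columns by exactly 12 and refuses to run twice;
  `che_decompose()` refuses monthly input.  This makes the classic
  double-annualization error a state error instead of a silent
  12-fold bias.

## The determinants stage

The CHE flag at a chosen threshold (default 30%) is regressed on
household covariates two ways:

* **Logistic regression** (`fit_logit()`, maximum likelihood via IRLS)
  with Wald standard errors, McFadden pseudo-$R^2$ and the
  likelihood-ratio $\chi^2$ against the intercept-only model.
* **Linear probability model** (`fit_lpm()`, OLS) with HC1
  heteroskedasticity-robust standard errors — an LPM is
  heteroskedastic by construction, so classical OLS standard errors
  would be wrong by design.

Money covariates enter per 1000 MXN so a coefficient reads as the
probability change per 1000 pesos.  For comparability,
`marginal_effects()` converts the logit to **average marginal effects**
(AME): for a continuous covariate the sample mean of
$\hat\beta_j \, p_i (1 - p_i)$, for a binary covariate the contrast of
mean predicted probabilities between the all-1 and all-0
counterfactuals.  AMEs are the dominant modern convention;
effects-at-means are available behind `type = "mem"`.  AME standard
errors are delta-method, propagating the coefficient covariance through
a numerical Jacobian.  The test suite checks every AME against a
central finite difference of the mean predicted probability.

The LPM reading of slopes as probability changes is defensible when
prevalence is mid-range (roughly 20–80%); `compare_models()` makes the
check explicit by aligning AMEs with OLS slopes and reporting sign
agreement and absolute differences.

**Stepwise entry–removal** (`stepwise_select()`) is the classic
bidirectional search on Wald p-values: add the best candidate below
`p_enter` (default 0.05), drop the worst included term above `p_remove`
(default 0.10), repeat; deterministic given column order (ties resolve
to the earlier column), with an audit log of every step and an abort on
revisiting a model state.  `p_enter = p_remove = 1` returns the full
model and `p_enter \to 0` the empty one, which the tests exercise.
Stepwise selection inherits all its usual inferential caveats
(post-selection p-values are optimistic); it is provided because it is
the field's reporting convention, not as a recommendation.

**Instability is surfaced, never masked.**  At low thresholds CHE
prevalence can approach 100% and the response becomes nearly
deterministic in the OOP covariates; the logistic fit then separates or
fails to converge.  `fit_logit()` reports this through `converged` /
`instability` and a warning naming suspect covariates.  The detection
rule is deliberately two-sided: the IRLS boundary warning ("fitted
probabilities numerically 0 or 1") alone is *not* treated as
separation, because a heavy-tailed income covariate routinely pushes a
few fitted values to machine 0/1 in perfectly healthy fits
(max $|\hat\beta| \approx 3$, max SE $\approx 0.2$); separation is
declared only when coefficients or standard errors have actually
diverged (max $|\hat\beta| > 10$ or max SE $> 5$) or IRLS did not
converge (observed max SE in the degenerate regime: thousands).

## The synthetic survey generator

The surveys this methodology is applied to are rarely depositable, so
validation runs end-to-end on `simulate_households()`, which emulates
the statistical structure the analysis assumes, with known ground
truth:

* **Income** is lognormal.  The default (`meanlog = 8.667`,
  `sdlog = 0.592`) gives a mean of about 6930 MXN/month — US$338 at the
  20.48 MXN/USD default rate — and the coefficient of variation implied
  by a standard deviation of US$219, the income scale typical of
  uninsured psychiatric-outpatient households in Mexico City.
* **Consumption** is a uniform 75–95% of income; the **food share of
  consumption** follows an Engel-type curve, declining in log income
  (baseline 0.42 at median income, slope 0.08 per log-income unit,
  Gaussian noise 0.08, clamped to [0.05, 0.90]).
* **OOP components** follow two-part (hurdle) models: logistic
  occurrence and lognormal positive amounts, matching the empirical
  pattern of OOP spending — mass at zero for hospitalization and
  diagnostics, right-skewed positive amounts.  Covariate loadings give
  the generator its configured effect directions: male patients and
  severity proxies (schizophrenia diagnosis, missed work days) raise
  occurrence and/or amounts of hospitalization and medicines; an
  employed patient and an anxiety diagnosis lower them; household size
  raises medicine amounts mildly.  Occurrence probabilities and amount
  dispersions are free parameters of the generator — the motivating
  literature reports no dispersions — and are documented as such.
* **Total expenditure** is assembled as consumption plus OOP, so food
  never exceeds total and every generated dataset passes ingestion
  validation with zero rejects (a tested invariant).
* **Reproducibility.** A master seed expands into named substreams
  (covariates, consumption rate, Engel noise, occurrence and amount per
  component), so adding a component does not perturb earlier draws, and
  all draws are coupled through explicit uniforms/normals.

### Calibration and ground truth

`calibrate_to_incidence()` bisects on the single `oop_scale` knob —
which multiplies every positive OOP amount and moves each household's
OOP/PC ratio, hence incidence, monotonically — until the simulated
incidence at n = 20000 (fixed evaluation seed, so the objective is
deterministic and monotone) is within tolerance of the target.  The
bundled study-scale scenario targets 34.8%, the incidence scale at
which this methodology is typically exercised.

`ground_truth()` defines the generator's implied average marginal
effects by Monte-Carlo counterfactual: flip (binary) or shift by one
design unit (continuous) a covariate for every simulated household,
re-simulate everything downstream with common random numbers, and
difference the CHE probabilities.  The poverty line is held at its
base-sample value across arms so the contrast isolates the
household-level effect rather than movement of the reference line
(at validation sizes, n = 100 000+, the line is stable anyway).  A
closed form is unavailable because CHE is a nonlinear functional of
the whole expenditure vector through a sample-dependent poverty line.

## What the validation does and does not show

The end-to-end validation suite runs at these problem sizes:
200 random datasets of up to 50 households for exact oracle
equivalence; 8 generated datasets for threshold monotonicity; 5 money
rescalings for scale invariance; 50 replications of n = 5000 for
parameter recovery against ground truth computed at n = 200 000; 200
replications of n = 5000 for stepwise operating characteristics;
calibration at n = 20 000.

Two scoping choices deserve emphasis:

* **Recovery is asserted for the configured effects** — household size,
  patient sex, patient employment, missed work days — whose paths into
  CHE run through the configured OOP loadings (household size also has
  a mechanical path through subsistence expenditure).  The **income**
  effect is emergent: income enters CHE through the hyperbolic
  $1/PC_h$ channel, so $P(CHE \mid income)$ is strongly convex and
  neither a logistic AME nor, especially, an LPM slope is a consistent
  estimator of its average derivative — the linear projection
  understates the derivative by more than its (tiny) standard error at
  any sample size.  The suite therefore asserts the income effect's
  direction and its AME-vs-LPM agreement, not coverage.  This is the
  same reason the applied literature reads LPM coefficients only as
  approximations justified by mid-range prevalence.
* **Synthetic data validates the machinery, not the world.**  The
  generator reproduces the skeleton real surveys share — skewed income,
  Engel-type food shares, hurdle-type OOP spending with mass at zero —
  but not interviewer effects, recall error, correlated covariate
  structure beyond the configured loadings, sampling weights, or
  within-household clustering.  Passing tests show the estimators
  recover what this structure implies; they cannot show that any real
  survey satisfies the structure.

## Known limitations

* No survey-weighted estimation, multilevel models or causal machinery
  (matching, instruments): out of scope by design.
* No poverty head-count, impoverishment-due-to-OOP or inequality
  indices; the pipeline stops at CHE incidence and determinants.
* Stepwise inference is reported as-is, with the audit log as the
  honesty device.
* The exchange rate is configuration (default 20.48 MXN/USD); the
  pipeline never hard-codes derived dollar figures.
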