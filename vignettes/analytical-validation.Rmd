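---
title: "Methods: analytical validation statistics for a multiplex biomarker panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analytical validation statistics for a multiplex biomarker panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoval)
```

## Scope

`immunoval` implements the statistical machinery of an analytical validation
for a multiplexed sandwich immunoassay measuring three plasma biomarkers of
kidney-function decline — KIM-1, sTNFR-1 and sTNFR-2 — on multi-spot
electrochemiluminescence plates. Each plate carries a 7-point calibration
series, a blank, four quality-control samples and the diluted specimens; the
validation studies the package supports are calibration and
back-calculation, detection limits, linearity, precision variance
components, multiplex cross-reactivity, interference recovery, and the
reproducibility of a composite risk score computed from the biomarker
triplet. The risk algorithm itself is deliberately out of scope: it enters
only as a pluggable deterministic function plus a monotone
probability-to-score table.

## Calibration model

The signal–concentration relationship is the four-parameter logistic

$$y = a + \frac{d - a}{1 + (c_{50}/x)^b},$$

with lower asymptote $a$ (counts), upper asymptote $d$ (counts), inflection
$c_{50}$ (pg/mL) and slope $b > 0$, monotone increasing in $x$. The
platform's vendor software is not prescriptive about the regression model,
so the package adopts the de-facto standard for this readout: 4PL with
$1/y^2$ weighting (noise on light counts is roughly proportional to the
signal). Weighting is configurable (`none`, `1/y`, `1/y^2`) so users can
match their instrument; a 5PL variant is intentionally not offered.

Fitting is weighted nonlinear least squares via Levenberg–Marquardt with
multi-start initialisation: $a$ from the blank (or minimum) signal, $d$ from
5% above the maximum, $c_{50}$ from a grid around the geometric
mid-concentration, and slopes $b \in \{0.6, 1, 1.4, 2\}$; the best weighted
residual wins. The blank is *not* a curve point — $x = 0$ has no finite
logarithm on the sigmoid — but it anchors the lower-asymptote start and is
retained for the quantification-limit blank-ratio rule. Back-calculation
uses the analytic inverse; signals at or beyond the fitted asymptotes return
an absent concentration flagged `below_curve`/`above_curve`, never zero,
forcing downstream code to treat censoring explicitly. Detection-limit
arithmetic operates in-well (dilution factor 1); dilution correction applies
only when reporting specimen concentrations.

A practical caveat the test suite documents: back-calculation is
ill-conditioned near the asymptotes. With single calibrator wells and 5%
signal noise the fitted upper asymptote is uncertain enough that per-level
calibrator recovery cannot be guaranteed inside 80–120%; with duplicate
standards at 2% signal noise and the top standard kept near 87% of the upper
asymptote it can. This is the same phenomenon that motivates capping the
upper limit of quantification at 70% of the top-calibrator signal.

## Detection limits

The classical approach is used throughout. The limit of blank is
$\mathrm{LoB} = \bar x_B + c_p s_B$ with the percentile multiplier corrected
for finite degrees of freedom, $c_p = 1.645/(1 - 1/(4f))$, $f = n_B - K$
for $K$ pooled assays; a nonparametric alternative (interpolated 95th
percentile rank) is selectable. The limit of detection adds the pooled
within-sample SD of low-level samples: $\mathrm{LoD} = \mathrm{LoB} + c_p
s_L$ with $f$ equal to total low-level results minus the number of samples.
Blank "concentrations" are back-calculated diluent results and may be
negative; the parametric route tolerates that, which is why it is the
default.

The quantification limits come from a four-part criteria scan over
user-supplied candidate levels: a level passes the lower scan when its
worst intra-plate replicate CV is below 10%, its mean recovery lies in
80–120%, and its mean signal is at least 3× the blank signal; it passes
the upper scan when CV and recovery pass and its mean signal is at most
70% of the top-calibrator signal. The reported LLoQ is the larger of the
LoD and the lowest passing level (the "LoD-restricted" case occurs when
every tested level passes); the ULoQ is the highest passing level. The
evidence table — every criterion for every level — is part of the result,
and the ordering invariant $0 \le \mathrm{LoB} \le \mathrm{LoD} \le
\mathrm{LLoQ} < \mathrm{ULoQ}$ is asserted whenever limits are assembled.
Two readings were genuinely open and are fixed here: *intra-plate* CV means
the worst plate governs (the conservative reading of a pass/fail
criterion), and when limits are computed per reagent lot the reported limit
is the maximum across lots.

## Linearity

Linearity uses the mixing design: a high pool (concentration above the
upper limit) mixed into a low pool at fractions 0, 0.025, 0.05, 0.10, 0.20,
…, 0.90, 1.0, giving expected values $f \cdot \mathrm{high} + (1 - f)
\cdot \mathrm{low}$. Measured replicate concentrations (five per level in
the reference design) are regressed on expected values by weighted least
squares *with an intercept*, each level weighted by its inverse replicate
variance; a level with zero variance falls back to $1/\mathrm{expected}^2$,
which keeps relative errors comparable across the concentration range.
The per-level deviation is $100(\bar y_\ell - \hat y_\ell)/\hat y_\ell$
against the fitted line. Levels violating the allowable deviation δ are
trimmed from the extremes — when both extremes fail, the worse one goes
first — and the line is re-fitted after every trim (a one-pass variant is
available by flag for comparisons). The retained interval must be a
contiguous run of at least four levels; an interior failure invalidates the
interval rather than splitting it. δ defaults to 15%, a required config
value chosen comfortably above deviations a passing assay exhibits; the
deviation statistic is exactly zero for any affine response, so the default
matters only near genuine nonlinearity.

## Precision variance components

Two designs are supported. The repeatability design (20 days × 2 runs/day ×
2 replicates/run per sample) is balanced and nested, so the ANOVA method of
moments applies in closed form:
$\hat\sigma^2_{rep} = MS_{within}$,
$\hat\sigma^2_{run} = (MS_{run(day)} - MS_{within})/n_{rep}$,
$\hat\sigma^2_{day} = (MS_{day} - MS_{run(day)})/(n_{run} n_{rep})$,
with negative estimates truncated to zero and logged. Layouts missing cells
fall back to REML with a warning.

The within-laboratory design adds two operators and two reagent lots (5
replicates × 2 runs × 10 days = 100 records per sample, days split evenly
across lots, one run per operator per day). That rotation is not a clean
nesting, so the model is fitted by REML with random effects for lot,
operator (crossed), day nested in lot, and run nested in day; the residual
is the repeatability component. Two consequences of the layout are worth
stating plainly. First, each run is performed by exactly one operator, so
the operator factor is a fixed two-group partition of the runs and the
operator and run variances are only jointly identifiable; simulation
recovery checks therefore evaluate the sums operator+run and lot+day
against truth. Second, a calibration-cycle effect would be confounded with
run in this design and is not modelled separately. CVs are always computed
against the per-sample grand mean (the designs print one mean per sample),
the sample SD uses the $n-1$ denominator, and reported CVs are rounded
half-away-from-zero to one decimal; summaries exclude (but still display)
samples whose grand mean falls outside the analytical measuring interval.

## Specificity, interference

Non-specific binding is the blank-normalised nonspecific signal as a
percentage of the blank-normalised specific signal,
$100(\mathrm{ns} - \mathrm{blank})/(\mathrm{s} - \mathrm{blank})$, floored
at zero; blank subtraction is the minimal reading of "normalised" that
makes the ratio a percentage of specific binding. Singleplex/multiplex
concordance pairs specimens measured under single-analyte and blended
detection antibodies and reports per-specimen percentage differences of
the means plus per-format inter-assay CVs across days. Interference
recovery evaluates spiked or mixed samples against the 80–120% band; for
1:1 plasma mixes the expectation halves each contributor's baseline
(dilutional mixing), and grossly elevated results — the signature of a
TNF-α-inhibitor fusion protein interfering with the sTNFR-2 assay — are
flagged as failed recoveries rather than suppressed.

## Risk-score reproducibility

Each patient sample contributes replicate biomarker triplets (duplicate
measurements, 2 runs/day, 5 days → 20 replicates). A caller-supplied
deterministic score function maps a triplet to a probability; a monotone
lookup table maps probabilities onto the scaled score grid 5, 10, …, 100;
categories follow the cutoffs low ≤ 45, intermediate 50–85, high > 85
(scores 46–49 are unreachable on the grid, so the bands partition it).
Reproducibility is summarised as per-sample %CV of the probabilities and
their arithmetic mean; concordance compares each replicate's category with
the sample's consensus category, defined as the category of the *mean
scaled score* — under which ties cannot occur — and pools matches over all
replicates.

The probability-to-score scaling of any validated clinical algorithm is
proprietary and not derivable from published category summaries, so the
default table is an explicit construction: probability bands below 0.15,
0.15–0.25, and above 0.25 are subdivided evenly onto the low, intermediate
and high score ranges. These cutpoints are bracketed by published
per-category probability summaries (a low-risk sample near 0.14, the lowest
intermediate near 0.16, the lowest high near 0.30) and are documented as
inferred defaults, not authoritative values; the default score function —
a logistic in the log biomarkers — is likewise a simulation stand-in and
makes no claim about any clinical algorithm.

## The synthetic-data generator

All verification inputs come from `sim_truth()` and the `simulate_*`
functions. The noise model is hierarchical and multiplicative: every design
factor level (lot, operator, day, run) draws a mean-one lognormal factor
with log-SD $\sqrt{\log(1 + (\mathrm{CV}/100)^2)}$, replicate noise
multiplies on top, and signals additionally receive a small additive
Gaussian floor (SD 0.5 counts by default) so blanks are never noiseless.
Multiplicative noise matches the observation that immunoassay SDs scale
roughly with concentration; an additive blank floor supplies the near-zero
behaviour the limit-of-blank machinery needs. Crosstalk is a 3×3 matrix of
fractional signal bleed (entries at most 0.05) added spot-wise from the
other analytes' specific signals.

Default magnitudes are anchored to the validated panel: 4PL curves with
blank-level signals of 120–150 counts and upper asymptotes of 2.5–8 × 10⁵,
7-point 4-fold calibrator series topping at 10 000 / 50 000 / 150 000
pg/mL, sample panels at the published per-sample concentration anchors
(e.g. KIM-1 24–3633 pg/mL), and CV components lot 3%, operator 2%, day 6%,
run 2%, replicate 3% — chosen once so that the implied repeatability CV
(~3%) and within-laboratory CV (~8%) fall inside the reported 2–8% and
6.3–13.1% ranges. Factor effects are drawn per plate (or per factor level
within a study), respecting the real confounding: one run per operator per
day, lots rotated between operators.

What the generator does *not* emulate: plasma matrix chemistry, hook
effects, drug pharmacokinetics, plate-position bias, or correlated noise
between analytes sharing a well. Passing tests therefore demonstrate that
the estimators recover the truth of this noise model at the study's design
sizes — not that any particular real assay meets its specifications.

## Numerical choices and degenerate inputs

* Sample SD uses $n-1$ everywhere; reported CVs and recoveries round
  half-away-from-zero to 1 d.p.; internal computation is full precision.
* 4PL fits refuse fewer than 5 distinct positive levels, signals that
  decrease by more than 20% (configurable) between adjacent level means,
  and non-convergence from every start (the error carries the best
  residual).
* Variance components are truncated at zero with the truncation recorded;
  REML boundary fits are reported as zeros, not errors.
* CV is undefined at zero mean and with fewer than two values; both are
  classed errors, as are unpaired specimens, missing 1:1-mix partners,
  out-of-order detection limits, and off-grid scaled scores.
* Plate files are delimited text with a mandatory header; numerics are
  written at full precision (`%.17g`) so a write/read cycle is bit-exact,
  and unparseable rows are rejected with row numbers.

## Verification problem sizes

The shipped tests run the estimators at the study's own design sizes
(20×2×2 and 10×2×5 with 7–8 samples; 10 samples × 20 replicates for risk
scores; 13-level mixing series with 5 replicates) and verify stochastic
properties over 100–500 simulation seeds for the variance-component,
detection-limit and linearity behaviour, 20–50 seeds for the slower
plate-level pipelines. The acceptance script reworks every printed summary
row it ships and regenerates the behavioural statistics from fresh
simulations under a caller-supplied seed.

## Known limitations

* Each plate is calibrated independently; there is no cross-plate
  calibration transfer.
* The LoB/LoD/LoQ machinery reproduces the *procedure*, not any published
  numeric limits, which depend on raw measurements that are not public.
* No confidence intervals on variance components, no outlier rejection, no
  probit-based detection limit, and no polynomial-significance linearity
  variant.
* The multifactor design cannot separate operator from run variance, nor
  calibration cycle from run (above); both totals are still correct.
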