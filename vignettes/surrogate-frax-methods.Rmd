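---
title: "Methods: surrogate fracture-probability models in surfrax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surrogate fracture-probability models in surfrax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfrax)
```

## The problem

FRAX-style calculators turn a patient's age, sex, clinical risk factors
(CRFs) and femoral-neck BMD into a 10-year probability of hip fracture or of
any major osteoporotic fracture (MOF: hip, clinical spine, distal forearm,
proximal humerus), discounted for the competing risk of death. Calibrating
such a model needs two national inputs: fracture incidence and mortality.
Where no usable fracture registry exists, accepted practice is a *surrogate*
model — fracture incidence borrowed from an epidemiologically similar donor
country, combined with the index country's own mortality. `surfrax`
implements the machinery for building surrogate models, quantifying their
divergence from the donor's authentic model over exhaustive clinical
scenarios, and projecting the national fracture burden.

## The probability engine

### Construction

The engine is the classical double-decrement life-table computation with
annual discretization. Hazards are piecewise constant within each year of
age (tables are published in age bands; within a band the hazard is flat, no
interpolation — standard abridged-life-table practice, and it keeps the
engine checkable against closed forms). For a profile aged $a_0$ of sex $s$,
with $a = a_0 + t$, $t = 0, \dots, 9$:

$$h_f(a) = i(a, s)\,\mathrm{RR}(\text{profile}), \qquad h_d(a) = m(a, s),$$

where $i$ is the outcome's incidence per person-year and $m$ the annual
death hazard. With $S(0) = 1$ and $H = h_f + h_d$:

$$P_{10} = \sum_{t=0}^{9} S(t)\,\frac{h_f}{H}\left(1 - e^{-H}\right),
\qquad S(t+1) = S(t)\,e^{-H}.$$

Fracture and death compete as exits from one state; the first event wins. A
year with $H = 0$ contributes nothing and leaves $S$ unchanged. The
symmetric death term plus 10-year survival completes the identity
$\sum P_f + \sum P_d + S(10) = 1$, which the test suite asserts to
$10^{-12}$.

### Risk adjustment

CRF effects are mutually multiplicative and age-independent:
$\mathrm{RR} = \prod_{j \in \text{present}} \mathrm{RR}_j \times
\mathrm{GR}^{-T}$, with GR the gradient of risk per SD of femoral-neck
T-score. Three deliberate choices:

* **T-score anchor.** The multiplier is 1 at $T = 0$ and GR is applied per
  SD below zero (symmetric credit above). Anchoring at zero avoids
  importing an external young-adult reference population; the scenario grid
  starts at $T = 0$, so the anchor is also the grid's origin.
* **BMI is recorded but inert.** The scenario protocol fixes BMI at
  26 kg/m²; no BMI–risk function is part of the model, so a no-op is the
  honest implementation and is testable as such.
* **Mortality is never adjusted.** Relative risks act on the fracture
  hazard only; mortality is a country-level input. Post-fracture excess
  mortality is out of scope.

The six CRFs toggled by the grid are prior fragility fracture, parental hip
fracture, current smoking, glucocorticoid use, rheumatoid arthritis and
alcohol ≥ 3 units/day — the standard dichotomous set minus secondary
osteoporosis, which carries no independent weight once BMD is entered.

The CRF relative risks and gradients of risk are configuration inputs (they
come from cohort meta-analyses that publish no reusable table). The
packaged defaults (e.g. prior fracture 2.0/1.8 for hip/MOF, GR 2.4 for hip
and 1.6 for MOF) are literature-scale values chosen once for the synthetic
scenario; they are not estimates of any calibrated engine's coefficients.

### A structural caveat

Because the hip gradient of risk exceeds the MOF gradient (as the
literature reports), the *adjusted* hip hazard can exceed the adjusted MOF
hazard at very negative T-scores wherever the MOF:hip ratio is close to 1
(old age). In that regime the computed hip probability can exceed the MOF
probability, although MOF includes hip by definition. This is a known
consequence of applying per-outcome multipliers to an imputed aggregate
hazard rather than modelling fracture sites separately; site-separated
modelling is out of scope. The ordering invariant
$P_{\text{hip}} \le P_{\text{MOF}}$ is therefore guaranteed — and tested —
only where the adjusted MOF hazard dominates, which includes every
unadjusted (no-CRF, no-BMD) profile.

## Tables and units

Incidence is stored as events per 100,000 person-years (registry
convention), mortality per person-year; conversion happens only inside
`hazard_at()`. Age bands are half-open integer intervals $[lo, hi)$, per
sex contiguous and covering at least $[50, 90)$. An open-ended final band
extends to a hard model ceiling of age 100 with constant hazard — a bounded,
documented integration horizon; ages ≥ 100 raise a range error rather than
extrapolate. MOF incidence is hip incidence times the age/sex MOF:hip
ratio table (the Malmö-pattern assumption); band edges must match exactly,
and no proration across mismatched bands is attempted, because silent
re-banding is a classic source of irreproducible burden estimates.

## The comparison protocol

The scenario grid crosses all $2^6$ CRF combinations with eight T-scores (0
to −3.5 SD in 0.5 SD steps) at ages 50, 60, 70, 80 and both sexes — 512
combinations per age/sex cell. This is an array of all possible
combinations, not a population simulation; it weights rare and common
profiles equally, which is exactly what one wants when asking "could any
clinical scenario be materially misclassified?".

* **Percentile differences.** Within a cell, profiles are ranked by the
  reference (authentic) model's probability; the percentile value uses
  linear interpolation between closest ranks (an even-count median is the
  mean of the central pair — the same convention as type-7 quantiles, pinned
  so tests can be exact). The surrogate's value *for the same profiles* is
  interpolated with the same rank weights, and the relative difference uses
  the reference value as denominator.
* **Tolerance intervals.** Comparison tables in this field typically quote
  95% tolerance intervals without defining their construction. `surfrax`
  uses a deterministic order-statistic method: the surrogate values of profiles
  ranked within ±10 of the reference percentile feed a distribution-free
  interval — the narrowest symmetric pair of order statistics
  $(x_{(i)}, x_{(n+1-i)})$ whose coverage law
  $\mathrm{Beta}(n+1-2i,\, 2i)$ puts at least the requested confidence on
  the requested coverage. Samples too small for any pair to qualify return
  $(\min, \max)$ with an `under_covered` flag. With the default ±10-rank
  window the flag is always set; the interval is then simply the range of
  surrogate values near the percentile. This is a documented stand-in, not
  an attempt to reproduce any published interval numerically.
* **Piecewise regression.** Surrogate (%) is regressed on reference (%)
  over the hinge basis $\{1, x, \max(0, x - 40)\}$ — continuous at the 40%
  knot, where treatment-relevant probabilities saturate. The reported $r$
  is the Pearson correlation between the two models' probabilities. When no
  point lies above the knot (common for hip panels) the hinge coefficient
  is fixed at 0, `slope_above` is reported as 0 and the fit is flagged
  degenerate rather than erroring.

## Burden projection

Expected counts are cross-sectional: for each projection year,
$\text{count}(s) = \sum_{\text{bands}, lo \ge 50} \text{rate}/10^5 \times
\text{persons}$, with incidence held fixed — the "stable incidence"
assumption that isolates demographic change. Bands whose lower edge is
below the age cut-off are excluded entirely. Counts stay real-valued
internally (rounding before chaining compounds error); reports round counts
to whole fractures and percent increases half-up to integer percent, the
convention that reproduces conventional published tables from their own
unrounded counts.

## The synthetic scenario

No registry tables ship with the package; the synthetic module generates
every input with known parametric structure, so each pipeline stage has an
exact oracle.

* **Incidence and mortality** follow a Gompertz law
  $\alpha e^{\beta(a - 50)}$ evaluated at band midpoints (an open-ended
  band's midpoint uses the age-100 ceiling). Defaults: hip incidence
  $\alpha = 20$ per 100,000 PY at 50 and $\beta = 0.09$ for women,
  $\alpha = 15$, $\beta = 0.075$ for men — a moderate-risk country;
  mortality $\beta = 0.095$ for both sexes with $\alpha = 0.002$ (women)
  and $0.004$ (men) per person-year, realistic mid-mortality levels (the
  male disadvantage and the roughly 10%-per-year rise are the robust
  features of adult mortality schedules). The surrogate target's mortality
  is 10% higher at every age — surrogate construction presumes broadly
  similar mortality, and a modest level shift exercises the competing-risk
  machinery without caricature.
* **MOF:hip ratios** decline log-linearly from 7.0 at age 50 to 1.3 at age
  90 (forearm fractures dominate early, hip late), floored at 1.
* **Population pyramids** decline 18% per 5-year band, grow 2%/year across
  projection years, with a seeded lognormal jitter (sd 0.05) per cell that
  is identical across years — realistic roughness that leaves the
  year-on-year growth exactly geometric, so the projection's closed-form
  checks remain exact.
* **The Monte Carlo oracle** simulates each year as one exponential draw on
  the total hazard plus a Bernoulli cause split $h_f/H$ — the *same*
  decomposition the engine integrates, so engine-vs-oracle tests are sharp
  at 3 binomial standard errors rather than approximate. Individuals are
  exchangeable, so the cohort advances by binomial draws per year;
  randomness sits behind one explicit seed and never touches the global
  RNG stream.

What the synthetic data does *not* emulate: secular trends in incidence,
cohort effects in mortality, urban/rural registry under-capture,
correlation between CRF prevalence and age, or any real country's absolute
rates. Passing tests therefore demonstrate the *machinery* — competing-risk
integration, exact pairing of scenarios, rounding conventions — not the
calibration of any national model, which would require the proprietary
cohort coefficients and registry tables that are explicitly out of scope.

## Problem sizes and numerical tolerances

The test suite evaluates full 4,096-profile grids where the property needs
them (self-comparison, cardinality) and 1–2-age grids elsewhere; the
engine–oracle sweep uses 20 random hazard/profile configurations at
n = 100,000, and the acceptance script mirrors the same sizes. Closed-form
engine checks are asserted to $10^{-12}$ relative; piecewise-regression
recovery on noiseless data to $10^{-10}$; conservation to $10^{-12}$.
Percentile and rounding conventions are pinned exactly as described above
so that worked examples are reproducible to the digit.

## Known limitations

* Hip/MOF probability ordering can invert at extreme BMD deficits (see the
  structural caveat above).
* The tolerance-interval construction is a documented stand-in; published
  tables built with an undisclosed method will not match numerically.
* No post-fracture excess mortality, no secular incidence trends, no
  site-separated fracture modelling, no population-weighted scenario
  simulation.
* The engine is not, and does not attempt to be, numerically equivalent to
  any proprietary calculator; its purpose is the surrogate-construction and
  comparison methodology.
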