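---
title: "Analyzing larval zebrafish light-dark transition screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing larval zebrafish light-dark transition screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(zfscreen)
library(dplyr)
```

## The assay and its two analyses

The light-dark transition test records the swimming of individual larval
zebrafish (typically 6 days post-fertilization, one larva per well of a
96-well plate) through a dark acclimation period, a long illuminated phase,
and an abrupt return to darkness. Healthy larvae swim little in the light
and burst into activity at the dark transition (the startle), which then
habituates toward a dark plateau. Developmental exposure to a neuroactive
chemical can blunt or exaggerate any part of this profile. The per-larva
raw datum is the distance moved in consecutive 2-min bins, with a 0.02 cm
minimum-movement filter applied before binning so tracking jitter never
accumulates; by default the protocol is 20 min dark acclimation, 40 min
light, 40 min dark, giving 10/20/20 bins.

`zfscreen` implements the two parallel analyses such screens use:

1. a **traditional repeated-measures ANOVA** on the mean distance moved per
   phase, with concentration as the between-subject factor, phase
   (light/dark) as the within-subject factor, and a Fisher's LSD post hoc
   gated on the omnibus test; and
2. a **13-endpoint concentration-response analysis**: each larva's profile
   is reduced to 13 endpoints, standardized against vehicle controls via an
   optimized Box-Cox transformation, and each endpoint's
   concentration-response is fit with a ten-model suite to yield a
   continuous hitcall in [0, 1] and, when active, a benchmark concentration
   (BMC) with bootstrap confidence bounds.

The first is conservative (one test, multiplicity-corrected post hocs); the
second is sensitive (13 uncorrected endpoints, potency estimated from the
whole curve). The package deliberately preserves that asymmetry: no
cross-endpoint multiplicity correction is applied in the 13-endpoint arm.

## The thirteen endpoints

With light bins $l_1,\dots,l_m$ and dark bins $d_1,\dots,d_n$ (acclimation
bins are excluded from every endpoint):

| endpoint | definition | captures |
|---|---|---|
| `avgSL`, `avgSD`, `avgST` | $\bar l$, $\bar d$, mean of both | overall activity |
| `hbt1L`, `hbt1D` | $(l_m - l_1)/(m-1)$, same for dark | within-phase trend |
| `hbt2L`, `hbt2D` | $\frac{l_m - l_2}{m-2} - \frac{l_{m-1} - l_1}{m-2}$ | trend curvature |
| `RoAL`, `RoAD` | $\max / (\min + 1)$ | activity range |
| `strtlA` | $d_1 - l_m$ | startle jump |
| `strtlAavg` | $d_1 - \bar l$ | startle vs light baseline |
| `strtlF` | $d_1 / \max(l_m, 0.02)$ | startle magnitude ratio |
| `AUC_r` | trapezoid AUC(dark) / max(AUC(light), 0.02) | dark:light balance |

Numerical conventions, chosen once and used everywhere:

* **Slopes are per bin index** (cm per bin), not per minute. Since every
  endpoint is subsequently Box-Cox transformed and standardized, a uniform
  rescaling of a slope endpoint is absorbed by the normalization and has no
  effect on hitcalls or BMCs.
* **`strtlF` and `AUC_r` denominators are floored at 0.02 cm**, the
  tracking noise floor: a last-light-bin distance below the filter
  threshold is not a measurable denominator. The `+1` guard in the `RoA`
  endpoints is part of their definition and is kept as is (it also breaks
  scale-invariance of `RoA`, which is expected).
* **AUC is trapezoidal over bin index.** It reduces to the bin sum up to
  end corrections and treats the profile as a sampled curve.
* **Bins are half-open** `[start, start + width)`; a sample falling exactly
  on a boundary belongs to the later bin.

```{r endpoints-example}
prof <- tibble::tibble(
  larva_id = "a", conc_uM = 0,
  bin_start_min = seq(0, 14, by = 2),
  phase = rep(c("light", "dark"), each = 4),
  distance_cm = c(1, 2, 3, 4, 8, 6, 4, 2)
)
compute_endpoints(prof) |> dplyr::select(avgSL:AUC_r) |> as.data.frame()
```

## Vehicle-referenced normalization

Raw endpoint distributions are strongly right-skewed (activity data are
non-negative with heavy upper tails), so each endpoint is transformed with
an optimized Box-Cox power transformation fit on a designated pool of
vehicle-control larvae — ideally a large frozen historical pool (this
package's simulated analogue uses 641 controls, and
`simulate_vehicle_reference()` reproduces that design). The transform is

$$g(x) = \frac{(x + s)^\lambda - 1}{\lambda} \quad (\lambda \ne 0), \qquad
  g(x) = \log(x + s) \quad (\lambda = 0),$$

with $\lambda$ maximizing the profile log-likelihood over a grid
$[-3, 3]$ in steps of 0.01 (likelihood ties broken toward $\lambda = 1$,
i.e. no transformation) and the shift $s = \max(0, 10^{-6} - \min x)$
accommodating endpoints that can be zero or negative (startle differences,
habituation slopes).

Two details are package design choices rather than assay constants:

* **Responses are scaled by the control SD** after centering, not merely
  centered. A single cutoff definition (in control-SD units) then works
  identically across all 13 endpoints, which the hitcall requires. The
  cutoff multiplier (default 1 control SD) and the benchmark response
  multiplier (default 1.349 control SDs, the conventional continuous
  benchmark response corresponding to a ~10% tail shift under normality)
  are both configurable because they are laboratory policy, not constants
  of nature.
* **Treated values below the transform's domain** ($x + s \le 0$, possible
  when a treatment pushes an endpoint below every control value) are
  floored at the positivity floor and flagged in the output rather than
  dropped.

## The concentration-response suite, hitcall, and BMC

Each endpoint's standardized responses are fit with ten models: constant,
linear and quadratic in $\log_{10}$ concentration, power, Hill, gain-loss
(a Hill rise times a Hill loss), and four exponential forms (saturating
and non-saturating, unit and free exponent). Residuals are Student-t with
4 degrees of freedom — a robust likelihood that tolerates the occasional
wild larva without outlier removal. The vehicle group is mapped to a
pseudo-concentration half a log10 step below the lowest tested level so
every model is evaluated on a finite log-concentration axis; all models
pass through zero response at zero dose. Positive parameters (potencies,
exponents) are optimized on the log scale, which enforces their bounds;
fits that fail to converge are dropped with a message and never abort the
endpoint.

The **winning model** is the lowest-AIC fit (AIC $= 2k - 2\ell$, $k$
counting the residual scale), with the standard parsimony refinement that
models within 4 AIC units of the minimum have comparable support and the
simplest of them is selected. On null data this prevents a spuriously
wiggly model from edging out the constant; on real signal the AIC gaps are
tens to hundreds of units and the refinement never changes the winner.

The **continuous hitcall** is the product of three weights in [0, 1]:

* $w_1$: one minus the Akaike weight of the constant model among all fits
  — the evidence that any concentration-response shape beats flat;
* $w_2$: the probability that the treated group with the largest absolute
  median response truly exceeds the cutoff. The median's sampling SE under
  the fitted t(4) error model is $\sigma / (2 f(0) \sqrt{n})$ with
  $f(0) = 0.375$ the standardized t(4) density at zero;
* $w_3$: the probability that the winning model's top (maximal absolute
  predicted response over the tested range) exceeds the cutoff, using a
  delta-method SE from the numeric Hessian of the negative log-likelihood
  (falling back to $\sigma/\sqrt{N}$ when the Hessian is singular). When
  the constant model wins, $w_3 = 0$.

An endpoint is **active** when the hitcall is at or above 0.9. The **BMC**
is the smallest concentration in the tested range where the winning
curve's absolute response equals the benchmark response (grid bracket plus
log-scale bisection); when the curve never reaches the BMR the BMC is
reported absent with the reason. BMDL/BMDU are the 5th/95th percentiles of
the BMC over nonparametric bootstrap refits of the winning model,
resampling responses within concentration groups; `bmc()` defaults to
1000 refits for final reporting, while `screen_chemical()` uses 200 for
routine screening (the bounds stabilize well before that for the designs
here, and the full 13-endpoint screen stays interactive).

## The traditional analysis

`rm_anova()` computes the mixed-design decomposition explicitly: subject
(per-larva) means carry the between-subject stratum (concentration effect,
tested against subjects-within-groups), and within-subject phase
differences carry the within stratum (phase and interaction, tested
against the phase-by-subject residual). With only two within-subject
levels, sphericity holds trivially and no correction is applied — this is
a property of the design, not an option. The test suite verifies the
decomposition against `stats::aov`'s Error-stratum output.

`fishers_lsd()` is gated: it refuses to run unless the omnibus
concentration effect or the concentration-by-phase interaction reaches
p ≤ 0.05. Comparisons are unadjusted pooled-variance t-tests of each
treatment against vehicle on each larva's total average activity (the mean
over both phases), using the between-subject error mean square and its
degrees of freedom. Totals — rather than per-phase comparisons — are the
declared convention.

## Developmental toxicity, QC, and dosing arithmetic

Each well's raw observations (alive, hatched, malformation set, observer
severity call) collapse to one of five exclusive statuses with precedence
**dead > not hatched > severely abnormal > abnormal > normal**. Non-hatching
outranks malformation calls because morphology cannot be fully scored
inside the chorion; the severe/mild split comes from the observer's
severity field, not from malformation counts. A plate fails QC when
strictly more than 15% of its vehicle controls deviate from normal in any
way — "abnormal" in the QC rule is read as any departure from normal,
including dead and unhatched controls. Only live, hatched, fully normal
larvae (an uninflated swim bladder counts as a malformation) enter the
behavior analysis.

`build_series()` and `rinse_residual()` carry the dosing arithmetic: an
8-point semi-log series from a 25 mM stock with the standard 250× plate
dilution spans 100 µM down to 0.0316 µM final (displayed to 2 significant
figures; the conventional printed range rounds the bottom to 0.03), and
five 50% rinses leave $100 \times 0.5^5 = 3.125\%$ (≈3%) of the original
concentration.

## The synthetic plate generator

Because raw screen data live outside this package, every stage is
exercised against a generative model with known ground truth,
`sim_config()` / `simulate_plate()`:

* **Design**: 96 wells, five semi-log concentrations (default the 1-100 µM
  series) at n = 16 plus 16 vehicle wells, randomized layout.
* **Baseline profile**: light mean 3 cm/bin with a mild within-phase
  trend; dark plateau 8 cm/bin plus a 6 cm/bin startle amplitude decaying
  at 0.15 per bin; acclimation 6 cm/bin. These place the light:dark
  contrast, the startle overshoot, and its habituation in the ranges
  control larvae show in this assay.
* **Noise**: each larva carries a log-normal frailty (SD 0.3 on the log
  scale, mean 1) multiplying its whole profile, and bin distances are
  Gamma (shape 5) around the frailty-scaled mean — non-negative,
  right-skewed marginals with realistic between-larva correlation, which
  is exactly what the Box-Cox step exists to handle.
* **Effects** are Hill factors $1 - E_{max} c^h / (c^h + AC_{50}^h)$
  applied multiplicatively to drivers (whole light level, whole dark
  level, startle amplitude, habituation rate), so one injected mechanism
  moves several endpoints coherently — as real neuroactive chemicals do.
  The standard active scenario used throughout the tests suppresses the
  dark level with $E_{max} = 0.6$, $AC_{50} = 3$ µM, $h = 2$.
* **Developmental toxicity** is drawn per well from logistic
  dose-response curves per status, applied in precedence order; excluded
  larvae produce no locomotor profile.
* `true_bmc()` forward-evaluates the noiseless effect model through the
  endpoint formulas and the frozen reference and solves for the
  concentration where the standardized shift equals the BMR — the oracle
  for recovery tests.

What the generator does **not** emulate: within-phase autocorrelation
beyond the mean curve, plate-edge and well-position effects, time-of-day
drift, or tracker artifacts. Passing recovery tests therefore demonstrates
that the estimation machinery is correct and calibrated under a realistic
noise family, not that any particular laboratory's effect sizes will be
detected.

## Problem sizes and calibration checks

The validation suite runs, among others: endpoint-formula agreement with
an independent transcription on 1000 random profiles (tolerance 1e-12);
Box-Cox λ recovery within ±0.15 at n = 641 for λ ∈ {−1, 0, 0.5, 1};
analytic Hill BMC inversion within 1%; BMC recovery within ±0.3 log10
(median over 100 seeded plates of the standard active scenario); a null
false-positive check over 200 seeded vehicle-only plates (per-endpoint
active rate ≤ 10%, and ≥ 90% of plates with zero active endpoints); ANOVA
Type-I rate within [0.03, 0.07] over 500 null simulations; and end-to-end
active detection (avgSD and avgST flagged) in ≥ 90% of 20 seeded active
plates. These sizes are the package's standing validation design and are
shared by `scripts/acceptance.R`.

## A complete run

```{r full-run, eval = FALSE}
cfg <- sim_config(
  effects = list(list(driver = "dark_level", emax = 0.6, ac50 = 3, hill = 2)),
  chemical = "dark_suppressor"
)
ref <- simulate_vehicle_reference(cfg, n_controls = 641, seed = 7)
plate <- simulate_plate(cfg, seed = 21)
run <- run_screen(plate, config = pipeline_config(n_boot = 200, seed = 42),
                  reference = ref)
run$results |> dplyr::filter(active)
autoplot(run$screen)                 # 13-endpoint heatmap
autoplot(run$screen$fits$avgSD)      # BMC diagnostic for one endpoint
```

## Known limitations

* The hitcall weight formulas ($w_2$, $w_3$) are principled
  operationalizations of the three-factor definition; other
  implementations in this family make different (equally defensible)
  choices, so hitcalls should be compared across pipelines only
  qualitatively.
* The BMC bootstrap resamples larvae within concentration groups and
  refits only the winning model; model-selection uncertainty is not
  propagated into the confidence bounds.
* `rm_anova()` expects every larva to contribute both phases and at least
  three larvae per group; heavily unbalanced or incomplete designs should
  go to a mixed-effects model instead.
* The Box-Cox reference assumes the control pool is exchangeable with the
  treated plates' controls; a drifting baseline between historical and
  current controls will shift every standardized response.
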