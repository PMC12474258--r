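# zfscreen

Analysis of larval zebrafish **light–dark transition** behavioral screens,
for developmental neurotoxicology labs running 96-well locomotor assays.

In this assay each 6-dpf larva swims through a dark acclimation period, a
40-min light phase, and an abrupt 40-min dark phase while a tracker records
the distance moved in 2-min bins. Healthy larvae are quiet in the light and
show a startle burst at the dark transition that habituates toward a
plateau; developmental exposure to a neuroactive chemical can distort any
part of that profile. `zfscreen` implements both analyses such screens use
in parallel:

1. **Traditional analysis** — repeated-measures ANOVA of mean distance
   moved with concentration (between subjects) and phase (light/dark,
   within subjects), followed by a Fisher's LSD post hoc on total average
   activity, gated on the omnibus test (p ≤ 0.05).
2. **13-endpoint concentration–response analysis** — each larva's profile
   is reduced to 13 endpoints (phase average speeds `avgSL`/`avgSD`/`avgST`,
   habituation slopes `hbt1L/D` and `hbt2L/D`, max:min ratios `RoAL/D`,
   startle endpoints `strtlA`, `strtlAavg`, `strtlF`, and the dark:light
   AUC ratio `AUC_r`), standardized against a vehicle-control pool via an
   optimized Box–Cox transformation
   (λ maximizing the profile likelihood on a grid over [−3, 3]), then fit
   per endpoint with a ten-model concentration–response suite (constant,
   log-linear, log-quadratic, power, Hill, gain–loss, four exponentials)
   under a robust Student-t(4) likelihood. Each endpoint gets a
   **continuous hitcall** in [0, 1] — the product of three weights
   (non-constant model support by AIC; a group median beyond the cutoff;
   the winning model's top beyond the cutoff) — and, when active
   (hitcall ≥ 0.9), a **benchmark concentration** (BMC): the lowest
   concentration where the fitted |response| reaches the benchmark
   response (default 1.349 control SDs), with bootstrap BMDL/BMDU bounds.

The package also provides developmental-toxicity status classification
(dead / not hatched / severely abnormal / abnormal / normal), plate-level
QC (>15% abnormal controls fails the plate), behavior-inclusion filtering,
semi-log dosing-series arithmetic, and a seeded synthetic plate generator
with known ground truth (`sim_config()`, `simulate_plate()`, `true_bmc()`)
so the whole pipeline runs and validates with no external data.

## Worked example

Simulate a chemical that suppresses dark-phase activity (Emax 0.6,
AC50 3 µM), screen it against a frozen 641-larva vehicle reference, and run
both analyses:

```r
library(zfscreen)

cfg <- sim_config(
  effects = list(list(driver = "dark_level", emax = 0.6, ac50 = 3, hill = 2)),
  chemical = "dark_suppressor"
)
ref   <- simulate_vehicle_reference(cfg, n_controls = 641, seed = 7)
plate <- simulate_plate(cfg, seed = 21)
run   <- run_screen(plate, config = pipeline_config(n_boot = 200, seed = 42),
                    reference = ref)

dplyr::select(dplyr::filter(run$results, active),
              endpoint, winner, hitcall, bmc, bmdl, bmdu)
#> # A tibble: 6 × 6
#>   endpoint  winner hitcall   bmc  bmdl  bmdu
#>   <chr>     <chr>    <dbl> <dbl> <dbl> <dbl>
#> 1 avgSD     exp4     1      4.35  3.64  5.43
#> 2 avgST     exp4     1.000  6.43  4.91  9.24
#> 3 RoAD      poly1    0.996 72.6  33.4  94.2
#> 4 strtlA    poly1    0.996 32.3  19.7  58.1
#> 5 strtlAavg poly1    1.000 20.1  13.8  31.8
#> 6 AUC_r     hill     1      2.29  1.88  2.69
```

Six of the 13 endpoints respond: the dark-phase suppression shows up
directly in the dark average speed (`avgSD`, BMC ≈ 4 µM, near the injected
AC50 of 3 µM), drags the total average (`avgST`) with it, and propagates
into the startle difference endpoints, the dark max:min ratio, and the
dark:light AUC ratio — one injected
mechanism, several coherent endpoint hits, which is exactly how real
neuroactive chemicals read out in this assay. The hitcall is the 0-to-1
activity confidence; `bmc` is the estimated potency in µM with its 90%
bootstrap interval (`bmdl`, `bmdu`).

The traditional arm of the same run:

```r
run$anova[, c("term", "df", "statistic", "p.value")]
#> # A tibble: 5 × 4
#>   term                    df statistic  p.value
#>   <chr>                <dbl>     <dbl>    <dbl>
#> 1 conc                     5      21.1 7.04e-14
#> 2 subjects(conc)          90      NA   NA
#> 3 phase                    1     756.  1.45e-45
#> 4 conc:phase               5      68.9 2.90e-29
#> 5 phase:subjects(conc)    90      NA   NA
```

Both the concentration effect and the concentration-by-phase interaction
are significant, so the gated Fisher's LSD (`run$lsd`) compares each
concentration with vehicle on total average activity.

Diagnostic graphics: `plot_locomotor_profile(plate$bins)` (the classic
per-bin line plot), `autoplot(run$screen)` (13-endpoint hitcall heatmap),
and `autoplot(run$screen$fits$avgSD)` (response points, group means,
cutoff band, BMR line, fitted curve, and BMC with its confidence band).

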