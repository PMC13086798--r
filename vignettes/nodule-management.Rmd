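---
title: "Methods: the Modified I-ELCAP Croatia nodule-management model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Modified I-ELCAP Croatia nodule-management model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldctscreen)
```

## The protocol

Croatia's national lung-cancer-screening program manages pulmonary nodules
found on low-dose CT (LDCT) with a modified I-ELCAP decision table. Each
scan is classified into one of three categories:

* **NEGATIVE** — routine screening continues (next scan in 12 or 24
  months).
* **SEMI-POSITIVE** (indeterminate) — an earlier-than-annual LDCT is
  scheduled (1, 3, 6, or 12 months), but no referral is made.
* **POSITIVE** — the participant is referred to a specialized nodule
  clinic and leaves the screening algorithm.

The rules differ by *screening context*: the **baseline** (first) scan,
scheduled **annual/biennial repeat** scans, and short-interval **interim
follow-up** scans triggered by an earlier indeterminate finding.
`ldctscreen` implements each context as a separate column of the decision
table (`classify_baseline()`, `classify_repeat()`, `classify_followup()`,
or `classify_scan()` with a `round_type`), and every decision carries a
stable rule code (`BL.*`, `RPT.*`, `FU.*`) naming the table cell that
fired, so a classification can always be audited back to the protocol
text.

## Thresholds and units

All size thresholds are available, with documentation, from
`protocol_thresholds()`:

```{r thresholds}
unlist(protocol_thresholds())
```

* Diameters are in millimetres; an average diameter is defined as the
  mean of the long and short axes (`average_diameter()`).
* Volumes are in cubic millimetres. The diameter equivalents assume a
  sphere: `sphere_volume(d) = pi * d^3 / 6`, so 3.0 mm ≈ 20 mm³,
  6.5 mm ≈ 150 mm³, 15.5 mm ≈ 2000 mm³.
* **Volume governs when both measurements are present.** Volumetry is
  the protocol's preferred measurement; the diameter criterion is a
  fallback for nodules without a volumetric segmentation.
* Size cut-offs are **closed below** (a 6.5 mm nodule is "6.5 mm or
  larger"). The one exception, printed that way in the protocol, is the
  follow-up referral for large nodules: *larger than* 15 mm (2000 mm³),
  a strict inequality on a 15 mm — not 15.5 mm — cut-off, carried in the
  separate `followup_large_mm` / `followup_large_mm3` fields.
* For **part-solid** nodules, the size that drives management is the
  size of the *solid component*, not of the whole nodule
  (`solid_comp_diameter_mm` / `solid_comp_volume_mm3`), except in the
  follow-up large-nodule referral, which reads the whole-nodule size as
  printed.

## Growth and volume doubling time

Growth is modelled as exponential. The volume doubling time of a nodule
observed at volumes $V_1$ and $V_2$ a time $\Delta t$ days apart is

$$ \mathrm{VDT} = \frac{\Delta t \cdot \ln 2}{\ln(V_2 / V_1)} . $$

`compute_vdt()` implements this identity and `grow_nodule()` its inverse
($V_2 = V_1 \cdot 2^{\Delta t / \mathrm{VDT}}$); the test suite checks the
round trip to a tolerance of 1e-9. A nodule that has not grown has no
finite doubling time: `compute_vdt()` returns `NA` there, and the
accompanying `growth_class` column (`STABLE` / `SHRINKING`) distinguishes
"assessed, not growing" from "assessment missing", which is an error on
scans that require one.

`assess_growth()` compares two observations of the same nodule and
assigns one of `NEW`, `GROWING`, `SLOWLY_GROWING`, `STABLE`, `SHRINKING`,
`RESOLVED`. A relative volume increase below
`growth_config()$min_relative_volume_increase` (default 0.30) is treated
as `STABLE`: volumetric measurement error easily produces apparent
changes of this size, so small increases are deliberately *not* called
growth. `SLOWLY_GROWING` is reserved for non-solid nodules whose increase
clears the threshold but whose VDT still exceeds 600 days, which the
protocol returns to annual screening rather than escalating.

On interim follow-up scans the VDT drives management directly:
VDT < 400 days is positive (referral), 400–599 days earns a 6-month
recall (or referral if the nodule is larger than 15 mm / 2000 mm³), and
VDT ≥ 600 days returns the participant to annual screening. A stable
nodule at follow-up is handled as the slow limit of that last band.

## Multi-nodule aggregation

Rules are applied per nodule; a scan's classification is the aggregate:

* category = the **maximum severity** over nodules;
* interval = the **minimum** (soonest) recommended interval;
* any referral dominates everything else;
* the `trace` list-column records every `(nodule_id, rule_code)` hit,
  and `driving_nodule_id` names the nodule that set the final result.

The "consider antibiotics" advisory attached to new 6.5 mm+ solid
nodules on repeat scans (rule `RPT.b4`) is carried as a flag; it never
changes the category or interval.

## Eligibility and quality control

`assess_eligibility()` applies the program's inclusion rules — age 50–75
years (closed bounds), at least 30 pack-years, current smoker or former
smoker who quit within the last 15 years — and six exclusion criteria
supplied as flags. Failed criteria are reported per participant as
machine-readable codes, not just a boolean.

`qc_check_scanner()` validates a scanner protocol against the program's
minimum technical requirements (120–140 kVp, 20–60 mAs, collimation
≤ 1 mm, rotation ≤ 0.5 s, CTDIvol ≤ 3.0 mGy, mean effective dose
≤ 1.5 mSv, ≥ 128 slices of ≤ 1 mm), returning one check per row.
`qc_check_scan_dose()` applies the per-scan 1.5 mSv limit (closed:
exactly 1.5 mSv passes), and `cumulative_dose()` / `dose_summary()`
track accumulated participant dose across rounds.

## The microsimulator

`generate_cohort()` + `run_program()` exercise the whole protocol on a
synthetic cohort: baseline scan, rule-driven recalls, annual/biennial
routing (a negative repeat moves the participant to a 24-month cycle),
interim follow-ups, and referral as an absorbing state.

The generator's defaults (`simulation_config()`) are **fabricated study
conditions chosen for testability, not calibrated to any real cohort**:
30% of participants carry at least one nodule, nodule diameters are
log-normal (median 4 mm), 5% of nodules are "malignant" with log-normal
VDT around 250 days, benign nodules occasionally grow slowly or resolve,
and per-scan effective dose is drawn near 0.9 mSv. They were set once,
from plausibility, and are not tuned to reproduce published program
outcomes; real positivity and detection rates depend on population
characteristics this synthetic model does not capture.

Volumetry error is multiplicative log-normal with **mean exactly 1**:
for a coefficient of variation $c$,
$\sigma^2 = \ln(1 + c^2)$ and $\mu = -\sigma^2/2$, so measured volumes
are unbiased and always positive. With `volume_measurement_cv = 0` the
pipeline is exact, which is how the test suite verifies that the
simulator's observation path recovers every sampled VDT to 1e-9.

Runs are seed-deterministic: the same `simulation_config(seed = )`
produces byte-identical cohorts and program results. The test suite
checks this at 10,000 participants over a 5-year horizon — a size chosen
so that full-program runs stay under a couple of minutes on one CPU
while still giving stable round-level statistics.

## Limitations

* The decision table is implemented as printed; clinical judgement,
  incidental findings other than the structured-report fields, and
  diagnostic work-up after referral are out of scope.
* No images are processed: inputs are nodule *measurements*
  (diameters, volumes, attenuation class), so segmentation error beyond
  the simple CV model is not represented.
* The synthetic natural-history model is intentionally minimal (one
  growth law, independent nodules, no death or attrition); it validates
  the engine's plumbing, not epidemiological predictions.
* The 15 mm follow-up referral cut-off and the closed/open bound
  conventions follow the protocol text literally; other screening
  programs (e.g. Lung-RADS) draw these lines differently.
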