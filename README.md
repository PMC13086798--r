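# ldctscreen

A deterministic, auditable implementation of the **Modified I-ELCAP
Croatia** rules for managing pulmonary nodules found on low-dose CT
(LDCT) lung-cancer-screening scans.

Croatia's national screening program classifies every LDCT scan as
**negative** (routine screening continues), **semi-positive**
(indeterminate: an earlier repeat LDCT at 1, 3, 6, or 12 months), or
**positive** (referral to a specialized nodule clinic), using a decision
table with separate columns for the baseline scan, scheduled
annual/biennial repeat scans, and short-interval interim follow-up scans.
Management is driven by nodule attenuation class (solid, part-solid,
non-solid, endobronchial, calcified), by size — volume in mm³ preferred,
average diameter in mm as fallback, and the *solid component* for
part-solid nodules — and, on follow-up scans, by the volume doubling
time (VDT): VDT < 400 days is positive, 400–599 days earns a 6-month
recall, ≥ 600 days returns the participant to annual screening.

The package provides:

* **Rule engine** — `classify_baseline()`, `classify_repeat()`,
  `classify_followup()`, `classify_scan()`, `classify_scans()`. Every
  result carries the decision-table rule code that fired and a
  per-nodule trace for audit.
* **Volumetry and growth** — `sphere_volume()`, `equivalent_diameter()`,
  `average_diameter()`, `compute_vdt()`, `grow_nodule()`,
  `assess_growth()`.
* **Eligibility** — `assess_eligibility()`, `screen_roster()`: age
  50–75, ≥ 30 pack-years, current smoker or quit within 15 years, plus
  exclusion flags, with machine-readable failure codes.
* **Scanner QC and dose tracking** — `qc_check_scanner()`,
  `qc_check_scan_dose()` (≤ 1.5 mSv per scan), `cumulative_dose()`,
  `dose_summary()`.
* **Microsimulator** — `simulation_config()`, `generate_cohort()`,
  `run_program()`: a seed-deterministic synthetic cohort run through the
  full multi-round protocol, with `tidy()`, `glance()`, and `autoplot()`
  methods on the results.
* **IO / CLI** — CSV/JSON readers and writers for nodule tables,
  rosters, scanner profiles, dose records, and structured reports; YAML
  threshold overrides; an `ldct_cli()` entry point and
  `inst/cli/ldctscreen.R` script.

No images are processed: inputs are nodule *measurements*, not DICOM.

## Worked example

A baseline scan with two findings — an 8.2 mm solid nodule with a
210 mm³ volumetric measurement, and an 11 mm ground-glass (non-solid)
nodule:

```r
library(ldctscreen)

nodules <- tibble::tibble(
  nodule_id       = c("L1", "L2"),
  type            = c("SOLID", "NON_SOLID"),
  avg_diameter_mm = c(8.2, 11.0),
  volume_mm3      = c(210, NA)
)
classify_baseline(nodules)
#> # A tibble: 1 × 7
#>   category      action      interval_months consider_antibiotics rule_code
#>   <chr>         <chr>                 <int> <lgl>                <chr>
#> 1 SEMI_POSITIVE REPEAT_LDCT               3 FALSE                BL.b3
#> # ℹ 2 more variables: driving_nodule_id <chr>, trace <list>
```

The solid nodule's volume (210 mm³ ≥ 150 mm³) drives a 3-month interim
LDCT under rule `BL.b3`. At that follow-up scan the nodule has grown to
320 mm³:

```r
assess_growth(
  prior   = tibble::tibble(nodule_id = "L1", type = "SOLID", volume_mm3 = 210),
  current = tibble::tibble(nodule_id = "L1", type = "SOLID", volume_mm3 = 320),
  delta_days = 92
)
#> # A tibble: 1 × 6
#>   nodule_id prior_volume_mm3 current_volume_mm3 delta_days vdt_days growth_class
#>   <chr>                <dbl>              <dbl>      <dbl>    <dbl> <chr>
#> 1 L1                     210                320         92     151. GROWING

classify_followup(tibble::tibble(
  nodule_id = "L1", type = "SOLID", avg_diameter_mm = 9.0,
  volume_mm3 = 320, growth_class = "GROWING", vdt_days = 151.4
))
#> # A tibble: 1 × 7
#>   category action              interval_months consider_antibiotics rule_code
#>   <chr>    <chr>                         <int> <lgl>                <chr>
#> 1 POSITIVE REFER_NODULE_CLINIC              NA FALSE                FU.c1
```

A VDT of 151 days is well under the 400-day positivity cut-off: the
participant is referred to the nodule clinic (`FU.c1`).

Running a synthetic 500-participant cohort through five years of the
program:

```r
cfg <- simulation_config(n_participants = 500, seed = 7, horizon_years = 5)
res <- run_program(generate_cohort(cfg))
summarize_results(res)
#> # A tibble: 6 × 6
#>   round_index n_scans n_negative n_semi_positive n_positive positivity
#>         <int>   <int>      <int>           <int>      <int>      <dbl>
#> 1           1     500        359             140          1    0.002
#> 2           2     499        458              38          3    0.00601
#> 3           3     496        465              27          4    0.00806
#> 4           4     492        465              23          4    0.00813
#> 5           5      17         10               6          1    0.0588
#> 6           6       4          0               2          2    0.5
```

(The simulator's population defaults are fabricated study conditions for
exercising the protocol, not a calibrated epidemiological model; see the
methods vignette `vignettes/nodule-management.Rmd`.)

## Running the tests

```r
testthat::test_dir("tests/testthat", package = "ldctscreen",
                   load_package = "installed")
```

The suite includes unit tests per module, property-based suites
(monotonicity of severity in nodule size and VDT, VDT round-trip
identities, IO round-trips, CLI byte-stability), and an equivalence
check of the rule engine against an independently written brute-force
decision table over a dense grid of single-nodule scenarios.

## Limitations

The decision table is implemented as printed; diagnostic work-up after
referral, incidental findings beyond the structured-report fields, and
image processing are out of scope. See the methods vignette for the
growth-model conventions, boundary conventions (closed size cut-offs;
the strict > 15 mm / 2000 mm³ follow-up referral), and simulator
assumptions.
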