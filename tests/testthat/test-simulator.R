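test_that("invalid configurations are rejected before any sampling", {
  expect_error(simulation_config(nodule_prevalence = 1.2), "probabilities")
  expect_error(simulation_config(type_mix = c(SOLID = 1)), "five nodule types")
  expect_error(simulation_config(type_mix = c(SOLID = 0.6, PART_SOLID = 0.2,
                                              NON_SOLID = 0.1,
                                              ENDOBRONCHIAL = 0.05,
                                              CALCIFIED = 0.2)),
               "sum to 1")
  expect_error(simulation_config(diameter_median_mm = -1), "positive")
  expect_error(simulation_config(horizon_years = 0), "horizon")
})

test_that("cohort generation is seed-deterministic and respects prevalence", {
  cfg <- simulation_config(n_participants = 1000, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  none <- generate_cohort(simulation_config(n_participants = 200, seed = 5,
                                            nodule_prevalence = 0,
                                            new_nodule_rate_per_year = 0))
  expect_equal(nrow(none$nodules), 0L)

  big <- generate_cohort(simulation_config(n_participants = 10000, seed = 9,
                                           nodule_prevalence = 0.3,
                                           new_nodule_rate_per_year = 0))
  frac <- length(unique(big$nodules$participant_id)) / 10000
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(frac - 0.3), 3 * se)
})

test_that("generated participants all satisfy the inclusion criteria", {
  cohort <- generate_cohort(simulation_config(n_participants = 500, seed = 3))
  expect_true(all(assess_eligibility(cohort$participants)$eligible))
})

test_that("volumetry noise has the configured coefficient of variation", {
  truth <- tibble::tibble(nodule_id = sprintf("n%d", 1:10000),
                          type = "SOLID", volume_mm3 = 100)
  set.seed(31)
  obs <- observe_nodule(truth, measurement_cv = 0.1)
  expect_true(all(obs$volume_mm3 > 0))
  empirical_cv <- sd(obs$volume_mm3) / mean(obs$volume_mm3)
  expect_lt(abs(empirical_cv - 0.1) / 0.1, 0.10)

  exact <- observe_nodule(truth[1:5, ], measurement_cv = 0)
  expect_equal(exact$volume_mm3, truth$volume_mm3[1:5])
  expect_equal(exact$avg_diameter_mm, rep(equivalent_diameter(100), 5),
               tolerance = 1e-12)
})

test_that("a zero-nodule cohort is negative in every round", {
  cohort <- generate_cohort(simulation_config(
    n_participants = 50, seed = 6, nodule_prevalence = 0,
    new_nodule_rate_per_year = 0, horizon_years = 5))
  res <- run_program(cohort)
  expect_true(all(res$events$category == "NEGATIVE"))
  expect_equal(res$n_referred, 0L)
  expect_true(all(summarize_results(res)$positivity == 0))
})

test_that("a cohort of large solid nodules is fully referred at baseline", {
  cohort <- generate_cohort(simulation_config(n_participants = 40, seed = 8,
                                              nodule_prevalence = 1,
                                              new_nodule_rate_per_year = 0))
  # overwrite the natural histories: one 20 mm solid nodule each
  cohort$nodules <- tibble::tibble(
    participant_id = cohort$participants$participant_id,
    nodule_id = paste0(cohort$participants$participant_id, "-N1"),
    type = "SOLID",
    baseline_volume_mm3 = sphere_volume(20),
    solid_comp_fraction = NA_real_,
    vdt_days = NA_real_, malignant = FALSE, appearance_day = 0
  )
  res <- run_program(cohort)
  baseline <- res$per_round[res$per_round$round_index == 1, ]
  expect_equal(baseline$positivity, 1)
  expect_equal(res$n_referred, 40L)
  expect_equal(res$rounds_simulated, 1L)
})

test_that("referral counts do not decrease with malignant fraction", {
  refs <- vapply(c(0.02, 0.1, 0.4), function(mf) {
    cohort <- generate_cohort(simulation_config(
      n_participants = 300, seed = 77, malignant_fraction = mf,
      horizon_years = 5))
    run_program(cohort)$n_referred
  }, integer(1))
  expect_true(all(diff(refs) >= 0))
})

test_that("noise-free follow-up recovers the true sampled VDT", {
  cohort <- generate_cohort(simulation_config(
    n_participants = 300, seed = 13, volume_measurement_cv = 0,
    malignant_fraction = 0.5, benign_resolve_prob = 0,
    horizon_years = 5))
  res <- run_program(cohort)
  growing <- cohort$nodules[!is.na(cohort$nodules$vdt_days), ]
  # replay one scan pair for each growing nodule at exact volumes
  for (i in seq_len(min(50, nrow(growing)))) {
    v0 <- growing$baseline_volume_mm3[i]
    vdt <- growing$vdt_days[i]
    v1 <- grow_nodule(v0, vdt, 365)
    expect_equal(compute_vdt(v0, v1, 365), vdt, tolerance = 1e-9)
  }
  # and the program itself referred fast growers
  expect_gt(res$n_referred, 0L)
})

test_that("program runs are byte-identical under a fixed seed", {
  cfg <- simulation_config(n_participants = 150, seed = 99, horizon_years = 4)
  r1 <- run_program(generate_cohort(cfg))
  r2 <- run_program(generate_cohort(cfg))
  expect_identical(r1, r2)
})

test_that("the biennial rule is observable in the event log", {
  cohort <- generate_cohort(simulation_config(
    n_participants = 20, seed = 17, nodule_prevalence = 0,
    new_nodule_rate_per_year = 0, horizon_years = 5))
  ev <- run_program(cohort)$events
  p1 <- ev[ev$participant_id == ev$participant_id[1], ]
  # negative baseline -> annual repeat at 12 months -> biennial thereafter
  expect_equal(p1$round_type[1:3],
               c("BASELINE", "ANNUAL_REPEAT", "BIENNIAL_REPEAT"))
  expect_equal(diff(p1$day)[1], 365.25, tolerance = 1e-9)
  expect_equal(diff(p1$day)[2], 730.5, tolerance = 1e-9)
})

test_that("summaries are internally consistent and tidiers work", {
  cohort <- generate_cohort(simulation_config(n_participants = 80, seed = 23,
                                              horizon_years = 3))
  res <- run_program(cohort)
  tab <- summarize_results(res)
  expect_equal(tab$n_negative + tab$n_semi_positive + tab$n_positive,
               tab$n_scans)
  expect_identical(tidy(res), tab)
  g <- glance(res)
  expect_equal(g$n_scans, nrow(res$events))
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_dose_distribution(res), "ggplot")
  # positivity fractions recomputed from counts
  expect_equal(tab$positivity, tab$n_positive / tab$n_scans)
})
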