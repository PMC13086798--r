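test_that("baseline column: every printed cell is reproduced", {
  # a1: no non-calcified nodules
  empty <- classify_baseline(no_nodules())
  expect_equal(empty$category, "NEGATIVE")
  expect_equal(empty$interval_months, 12L)
  expect_equal(empty$rule_code, "BL.a1")

  calc_only <- classify_baseline(nod("CALCIFIED", d = 4))
  expect_equal(calc_only$category, "NEGATIVE")
  expect_equal(calc_only$interval_months, 12L)

  # b1: only non-solid, any size
  b1 <- classify_baseline(nod("NON_SOLID", d = 22))
  expect_equal(b1[, c("category", "interval_months", "rule_code")],
               tibble::tibble(category = "SEMI_POSITIVE",
                              interval_months = 12L, rule_code = "BL.b1"))

  # b2: largest solid below 6.5 mm / 150 mm^3
  b2 <- classify_baseline(nod("SOLID", d = 5))
  expect_equal(b2$rule_code, "BL.b2")
  expect_equal(b2$interval_months, 12L)

  # b3: solid in [6.5, 15.5) mm
  b3 <- classify_baseline(nod("SOLID", d = 10))
  expect_equal(b3$category, "SEMI_POSITIVE")
  expect_equal(b3$interval_months, 3L)
  expect_equal(b3$rule_code, "BL.b3")

  # b3 via part-solid solid component
  ps <- classify_baseline(nod("PART_SOLID", d = 12, comp_d = 7))
  expect_equal(ps$interval_months, 3L)
  expect_equal(ps$category, "SEMI_POSITIVE")

  # b4: endobronchial of any size
  b4 <- classify_baseline(nod("ENDOBRONCHIAL", d = 5))
  expect_equal(b4$category, "SEMI_POSITIVE")
  expect_equal(b4$interval_months, 1L)
  expect_equal(b4$rule_code, "BL.b4")

  # c1: solid at or above 15.5 mm
  c1 <- classify_baseline(nod("SOLID", d = 16))
  expect_equal(c1$category, "POSITIVE")
  expect_equal(c1$action, "REFER_NODULE_CLINIC")
  expect_true(is.na(c1$interval_months))
  expect_equal(c1$rule_code, "BL.c1")
})

test_that("volume governs when it disagrees with the diameter", {
  # diameter says b3 (>= 6.5), volume says b2 (< 150): volume wins
  v_wins <- classify_baseline(nod("SOLID", d = 7, v = 100))
  expect_equal(v_wins$rule_code, "BL.b2")
  # volume at the positive cut-off wins over a small diameter
  v_pos <- classify_baseline(nod("SOLID", d = 10, v = 2000))
  expect_equal(v_pos$category, "POSITIVE")
})

test_that("threshold boundaries are closed below, exactly as printed", {
  expect_equal(classify_baseline(nod("SOLID", d = 6.5))$rule_code, "BL.b3")
  expect_equal(classify_baseline(nod("SOLID", v = 150))$rule_code, "BL.b3")
  expect_equal(classify_baseline(nod("SOLID", d = 15.5))$category, "POSITIVE")
  expect_equal(classify_baseline(nod("SOLID", v = 2000))$category, "POSITIVE")
  expect_equal(classify_repeat(nod("SOLID", d = 3, is_new = TRUE))$interval_months, 6L)
  expect_equal(classify_repeat(nod("SOLID", v = 20, is_new = TRUE))$interval_months, 6L)
})

test_that("annual/biennial column: every printed cell is reproduced", {
  # a1: nothing new, nothing growing
  stable <- classify_repeat(dplyr::bind_rows(
    nod("SOLID", d = 5, growth = "STABLE", id = "n1"),
    nod("NON_SOLID", d = 8, growth = "STABLE", id = "n2")
  ))
  expect_equal(stable$category, "NEGATIVE")
  expect_equal(stable$interval_months, 24L)
  expect_equal(stable$rule_code, "RPT.a1")

  # b1: new or slowly growing non-solid
  b1 <- classify_repeat(nod("NON_SOLID", d = 9, is_new = TRUE))
  expect_equal(b1$interval_months, 12L)
  expect_equal(b1$rule_code, "RPT.b1")
  b1s <- classify_repeat(nod("NON_SOLID", d = 9, growth = "SLOWLY_GROWING",
                             vdt = 900))
  expect_equal(b1s$rule_code, "RPT.b1")

  # b2: new/growing solid below 3 mm
  b2 <- classify_repeat(nod("SOLID", d = 2, is_new = TRUE))
  expect_equal(b2$category, "SEMI_POSITIVE")
  expect_equal(b2$interval_months, 12L)
  expect_equal(b2$rule_code, "RPT.b2")

  # b3: new/growing solid in [3, 6.5) mm
  b3 <- classify_repeat(nod("SOLID", d = 4, is_new = TRUE))
  expect_equal(b3$interval_months, 6L)
  expect_equal(b3$rule_code, "RPT.b3")
  grown <- classify_repeat(nod("SOLID", d = 4, growth = "GROWING", vdt = 300))
  expect_equal(grown$rule_code, "RPT.b3")

  # b4: new/growing solid at/above 6.5 mm, antibiotics advised
  b4 <- classify_repeat(nod("SOLID", d = 8, is_new = TRUE))
  expect_equal(b4$category, "SEMI_POSITIVE")
  expect_equal(b4$interval_months, 1L)
  expect_true(b4$consider_antibiotics)
  expect_equal(b4$rule_code, "RPT.b4")

  # b5: new endobronchial
  b5 <- classify_repeat(nod("ENDOBRONCHIAL", d = 4, is_new = TRUE))
  expect_equal(b5$interval_months, 1L)
  expect_equal(b5$rule_code, "RPT.b5")

  # c1: non-solid doubled within a year with an emergent solid component
  c1 <- classify_repeat(nod("PART_SOLID", d = 9, comp_d = 3,
                            growth = "GROWING", vdt = 300,
                            prior_type = "NON_SOLID"))
  expect_equal(c1$category, "POSITIVE")
  expect_equal(c1$rule_code, "RPT.c1")
  # plain doubling without a solid component is NOT positive
  no_comp <- classify_repeat(nod("NON_SOLID", d = 9, growth = "GROWING",
                                 vdt = 300))
  expect_equal(no_comp$category, "SEMI_POSITIVE")
  expect_equal(no_comp$rule_code, "RPT.b1")

  # c2: persistent endobronchial
  c2 <- classify_repeat(nod("ENDOBRONCHIAL", d = 4, growth = "STABLE"))
  expect_equal(c2$category, "POSITIVE")
  expect_equal(c2$rule_code, "RPT.c2")
})

test_that("stable nodules cannot raise severity on repeat scans", {
  big_stable <- classify_repeat(nod("SOLID", d = 20, growth = "STABLE"))
  expect_equal(big_stable$category, "NEGATIVE")
  expect_equal(big_stable$interval_months, 24L)
  shrink <- classify_repeat(nod("SOLID", d = 12, growth = "SHRINKING"))
  expect_equal(shrink$category, "NEGATIVE")
})

test_that("repeat scans demand growth assessments for pre-existing nodules", {
  expect_error(classify_repeat(nod("SOLID", d = 5)), "growth assessment")
})

test_that("follow-up column: every printed cell is reproduced", {
  # a1: nodule resolved
  a1 <- classify_followup(nod("SOLID", is_resolved = TRUE))
  expect_equal(a1$category, "NEGATIVE")
  expect_equal(a1$interval_months, 24L)
  expect_equal(a1$rule_code, "FU.a1")

  # b1: VDT >= 600 d, back to annual screening
  b1 <- classify_followup(nod("SOLID", d = 10, vdt = 700))
  expect_equal(b1$category, "SEMI_POSITIVE")
  expect_equal(b1$interval_months, 12L)
  expect_equal(b1$rule_code, "FU.b1")
  expect_equal(classify_followup(nod("SOLID", d = 10, vdt = 600))$rule_code,
               "FU.b1")  # 600 itself is in the slow band

  # not growing at all is the slow limit of the b1 band
  stable <- classify_followup(nod("SOLID", d = 10, growth = "STABLE"))
  expect_equal(stable$rule_code, "FU.b1")

  # b2: VDT in [400, 600)
  b2 <- classify_followup(nod("SOLID", d = 10, vdt = 500))
  expect_equal(b2$interval_months, 6L)
  expect_equal(b2$rule_code, "FU.b2")
  expect_equal(classify_followup(nod("SOLID", d = 10, vdt = 400))$rule_code,
               "FU.b2")

  # c1: VDT < 400 d
  c1 <- classify_followup(nod("SOLID", d = 10, vdt = 350))
  expect_equal(c1$category, "POSITIVE")
  expect_equal(c1$rule_code, "FU.c1")
  expect_equal(classify_followup(nod("SOLID", d = 10, vdt = 399.9))$category,
               "POSITIVE")

  # c2: persistent endobronchial
  c2 <- classify_followup(nod("ENDOBRONCHIAL", d = 4, growth = "STABLE"))
  expect_equal(c2$category, "POSITIVE")
  expect_equal(c2$rule_code, "FU.c2")

  # c3: intermediate VDT but larger than 15 mm (2000 mm^3)
  c3 <- classify_followup(nod("SOLID", d = 16, vdt = 500))
  expect_equal(c3$category, "POSITIVE")
  expect_equal(c3$rule_code, "FU.c3")
  # 15 mm itself is not "larger than 15 mm"
  expect_equal(classify_followup(nod("SOLID", d = 15, vdt = 500))$rule_code,
               "FU.b2")
  expect_equal(classify_followup(nod("SOLID", v = 2001, vdt = 500))$rule_code,
               "FU.c3")
})

test_that("follow-up requires a VDT for unresolved non-endobronchial nodules", {
  expect_error(classify_followup(nod("SOLID", d = 10)), "VDT missing")
})

test_that("multi-nodule scans take the worst category and the shortest interval", {
  multi <- classify_baseline(dplyr::bind_rows(
    nod("SOLID", d = 5, id = "small"),
    nod("SOLID", d = 10, id = "mid"),
    nod("NON_SOLID", d = 20, id = "ggo")
  ))
  expect_equal(multi$category, "SEMI_POSITIVE")
  expect_equal(multi$interval_months, 3L)
  expect_equal(multi$driving_nodule_id, "mid")
  expect_equal(nrow(multi$trace[[1]]), 3L)

  dominated <- classify_baseline(dplyr::bind_rows(
    nod("SOLID", d = 10, id = "mid"),
    nod("SOLID", d = 20, id = "big")
  ))
  expect_equal(dominated$category, "POSITIVE")
  expect_equal(dominated$driving_nodule_id, "big")
  expect_true(is.na(dominated$interval_months))

  # resolved nodule plus an active one on follow-up: the recall wins
  fu <- classify_followup(dplyr::bind_rows(
    nod("SOLID", is_resolved = TRUE, id = "gone"),
    nod("SOLID", d = 8, vdt = 500, id = "active")
  ))
  expect_equal(fu$interval_months, 6L)
  expect_equal(fu$driving_nodule_id, "active")
})

test_that("adding a calcified nodule never changes a classification", {
  set.seed(21)
  for (i in 1:40) {
    sc <- random_scenario()
    base <- do.call(engine_classify, sc)
    nods <- nod(sc$type, d = sc$d, comp_d = sc$comp_d, is_new = sc$is_new,
                growth = sc$growth, vdt = sc$vdt, id = "n1")
    with_calc <- classify_scan(
      dplyr::bind_rows(nods, nod("CALCIFIED", d = 6, id = "calc",
                                 growth = NA_character_)),
      round_type = sc$round, thresholds = protocol_thresholds()
    )
    expect_equal(with_calc$category, base$category)
    expect_equal(if (is.na(with_calc$interval_months)) NA
                 else with_calc$interval_months, base$interval)
  }
})

test_that("classification invariants hold across random scenarios", {
  set.seed(22)
  for (i in 1:200) {
    sc <- random_scenario()
    r <- do.call(engine_classify, sc)
    expect_true(r$category %in% c("NEGATIVE", "SEMI_POSITIVE", "POSITIVE"))
    if (r$category == "POSITIVE") {
      expect_true(is.na(r$interval))
    } else {
      expect_true(r$interval %in% c(1L, 3L, 6L, 12L, 24L))
    }
  }
})

test_that("classify_scan validates inputs", {
  expect_error(classify_scan(nod("SOLD", d = 5), "BASELINE"), "unknown nodule type")
  expect_error(classify_scan(nod("SOLID", d = 5), "QUARTERLY"), "round_type")
  expect_error(classify_baseline(nod("SOLID")), "no size")
  expect_error(classify_baseline(nod("SOLID", d = 5, is_new = TRUE,
                                     is_resolved = TRUE)), "both new and resolved")
  expect_error(classify_baseline(nod("SOLID", d = 5, comp_d = 3)),
               "PART_SOLID")
})

test_that("classify_scans batches a long table by scan", {
  nods <- dplyr::bind_rows(
    dplyr::mutate(nod("SOLID", d = 10), participant_id = "p1", scan_id = "s1",
                  round_type = "BASELINE"),
    dplyr::mutate(nod("CALCIFIED", d = 3, id = "n2"), participant_id = "p1",
                  scan_id = "s1", round_type = "BASELINE"),
    dplyr::mutate(nod("SOLID", d = 4, is_new = TRUE), participant_id = "p2",
                  scan_id = "s2", round_type = "ANNUAL_REPEAT")
  )
  out <- classify_scans(nods)
  expect_equal(nrow(out), 2L)
  expect_equal(out$rule_code[out$scan_id == "s1"], "BL.b3")
  expect_equal(out$rule_code[out$scan_id == "s2"], "RPT.b3")
})

test_that("next_round_type implements the biennial rule and recall routing", {
  neg_baseline <- classify_baseline(no_nodules())
  expect_equal(next_round_type(neg_baseline), "ANNUAL_REPEAT")

  neg_repeat <- classify_repeat(nod("SOLID", d = 5, growth = "STABLE"))
  expect_equal(next_round_type(neg_repeat), "BIENNIAL_REPEAT")

  recall <- classify_baseline(nod("SOLID", d = 10))
  expect_equal(next_round_type(recall), "INTERIM_FOLLOWUP")

  pos <- classify_baseline(nod("SOLID", d = 20))
  expect_true(is.na(next_round_type(pos)))
})
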