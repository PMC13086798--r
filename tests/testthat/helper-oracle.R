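# Independent brute-force oracle for single-nodule scans: a literal
# top-to-bottom reading of the printed decision table, written as plain
# scalar if-chains with no code shared with the engine. Returns the expected
# category, interval and rule code for one nodule observed on one scan.

oracle_classify <- function(round, type, d = NA, v = NA,
                            comp_d = NA, comp_v = NA,
                            is_new = FALSE, is_resolved = FALSE,
                            growth = NA, vdt = NA, prior_type = NA) {
  res <- function(category, interval, rule) {
    list(category = category,
         interval = if (is.na(interval)) NA else as.integer(interval),
         rule = rule)
  }
  # closed-below size test on the governing measurement (volume wins)
  at_least <- function(dd, vv, cut_mm, cut_mm3) {
    if (!is.na(vv)) vv >= cut_mm3 else dd >= cut_mm
  }

  if (round == "BASELINE") {
    if (type == "CALCIFIED") return(res("NEGATIVE", 12, "BL.a1"))
    if (type == "NON_SOLID") return(res("SEMI_POSITIVE", 12, "BL.b1"))
    if (type == "ENDOBRONCHIAL") return(res("SEMI_POSITIVE", 1, "BL.b4"))
    sd <- if (type == "PART_SOLID") comp_d else d
    sv <- if (type == "PART_SOLID") comp_v else v
    if (at_least(sd, sv, 15.5, 2000)) return(res("POSITIVE", NA, "BL.c1"))
    if (at_least(sd, sv, 6.5, 150)) return(res("SEMI_POSITIVE", 3, "BL.b3"))
    return(res("SEMI_POSITIVE", 12, "BL.b2"))
  }

  if (round %in% c("ANNUAL_REPEAT", "BIENNIAL_REPEAT")) {
    if (type == "CALCIFIED") return(res("NEGATIVE", 24, "RPT.a1"))
    if (type == "ENDOBRONCHIAL") {
      if (is_new) return(res("SEMI_POSITIVE", 1, "RPT.b5"))
      return(res("POSITIVE", NA, "RPT.c2"))
    }
    if (type == "PART_SOLID" && !is.na(prior_type) &&
        prior_type == "NON_SOLID" && !is.na(vdt) && vdt <= 365) {
      return(res("POSITIVE", NA, "RPT.c1"))
    }
    if (type == "NON_SOLID") {
      if (is_new || (!is.na(growth) &&
                       growth %in% c("GROWING", "SLOWLY_GROWING"))) {
        return(res("SEMI_POSITIVE", 12, "RPT.b1"))
      }
      return(res("NEGATIVE", 24, "RPT.a1"))
    }
    # SOLID or PART_SOLID
    if (!is_new && !(!is.na(growth) && growth == "GROWING")) {
      return(res("NEGATIVE", 24, "RPT.a1"))
    }
    sd <- if (type == "PART_SOLID") comp_d else d
    sv <- if (type == "PART_SOLID") comp_v else v
    if (at_least(sd, sv, 6.5, 150)) return(res("SEMI_POSITIVE", 1, "RPT.b4"))
    if (at_least(sd, sv, 3, 20)) return(res("SEMI_POSITIVE", 6, "RPT.b3"))
    return(res("SEMI_POSITIVE", 12, "RPT.b2"))
  }

  # interim follow-up
  if (is_resolved) return(res("NEGATIVE", 24, "FU.a1"))
  if (type == "CALCIFIED") return(res("NEGATIVE", 24, "FU.a1"))
  if (type == "ENDOBRONCHIAL") return(res("POSITIVE", NA, "FU.c2"))
  if (is.na(vdt)) return(res("SEMI_POSITIVE", 12, "FU.b1"))  # not growing
  if (vdt < 400) return(res("POSITIVE", NA, "FU.c1"))
  if (vdt < 600) {
    big <- if (!is.na(v)) v > 2000 else d > 15
    if (big) return(res("POSITIVE", NA, "FU.c3"))
    return(res("SEMI_POSITIVE", 6, "FU.b2"))
  }
  res("SEMI_POSITIVE", 12, "FU.b1")
}

# Run the engine on the same single-nodule scenario and return the same
# shape for comparison.
engine_classify <- function(round, type, d = NA, v = NA,
                            comp_d = NA, comp_v = NA,
                            is_new = FALSE, is_resolved = FALSE,
                            growth = NA, vdt = NA, prior_type = NA,
                            thresholds = protocol_thresholds()) {
  cls <- classify_scan(
    nod(type, d = d, v = v, comp_d = comp_d, comp_v = comp_v,
        is_new = is_new, is_resolved = is_resolved,
        growth = growth, vdt = vdt, prior_type = prior_type),
    round_type = round, thresholds = thresholds
  )
  list(category = cls$category,
       interval = if (is.na(cls$interval_months)) NA else cls$interval_months,
       rule = cls$rule_code)
}

severity_rank <- function(category) {
  match(category, c("NEGATIVE", "SEMI_POSITIVE", "POSITIVE"))
}

# A random but protocol-valid single-nodule scenario, for the property
# suites. Returns the argument list understood by oracle/engine_classify.
random_scenario <- function() {
  round <- sample(c("BASELINE", "ANNUAL_REPEAT", "INTERIM_FOLLOWUP"), 1)
  type <- if (round == "INTERIM_FOLLOWUP") {
    sample(c("SOLID", "PART_SOLID", "NON_SOLID"), 1)
  } else {
    sample(c("SOLID", "PART_SOLID", "NON_SOLID", "ENDOBRONCHIAL"), 1)
  }
  d <- round(stats::runif(1, 0.5, 30), 1)
  comp_d <- if (type == "PART_SOLID") round(stats::runif(1, 0.2, d), 1) else NA
  is_new <- round == "ANNUAL_REPEAT" && stats::runif(1) < 0.5
  growth <- if (round == "ANNUAL_REPEAT" && !is_new) {
    sample(c("GROWING", "SLOWLY_GROWING", "STABLE", "SHRINKING"), 1)
  } else {
    NA
  }
  vdt <- if (round == "INTERIM_FOLLOWUP") round(stats::runif(1, 100, 900)) else NA
  list(round = round, type = type, d = d, comp_d = comp_d,
       is_new = is_new, growth = growth, vdt = vdt)
}

# Lean single-nodule classification through the engine's internal entry
# point, for the large grid and property sweeps (the public wrapper is
# exercised against it on a random subsample).
fast_classify <- function(round, type, d = NA, v = NA,
                          comp_d = NA, comp_v = NA,
                          is_new = FALSE, is_resolved = FALSE,
                          growth = NA, vdt = NA, prior_type = NA,
                          thr = protocol_thresholds()) {
  df <- structure(
    list(nodule_id = "n1", type = type,
         avg_diameter_mm = as.numeric(d), volume_mm3 = as.numeric(v),
         solid_comp_diameter_mm = as.numeric(comp_d),
         solid_comp_volume_mm3 = as.numeric(comp_v),
         is_new = is_new, is_resolved = is_resolved,
         growth_class = as.character(growth), vdt_days = as.numeric(vdt),
         prior_type = as.character(prior_type)),
    class = "data.frame", row.names = c(NA_integer_, -1L)
  )
  r <- ldctscreen:::.classify_impl(df, round, thr, complete = FALSE)
  list(category = r$category,
       interval = if (is.na(r$interval_months)) NA else r$interval_months,
       rule = r$rule_code)
}
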