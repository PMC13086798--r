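#' @importFrom rlang .data
NULL

.CATEGORIES <- c("NEGATIVE", "SEMI_POSITIVE", "POSITIVE")
.ROUND_TYPES <- c("BASELINE", "ANNUAL_REPEAT", "BIENNIAL_REPEAT",
                  "INTERIM_FOLLOWUP")

# Ensure every observation column the engine consults exists, with typed NA
# defaults, so the rule code can be written against a fixed schema.
.complete_obs <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  defaults <- list(
    nodule_id = NA_character_, type = NA_character_,
    avg_diameter_mm = NA_real_, volume_mm3 = NA_real_,
    solid_comp_diameter_mm = NA_real_, solid_comp_volume_mm3 = NA_real_,
    is_new = FALSE, is_resolved = FALSE,
    growth_class = NA_character_, vdt_days = NA_real_,
    prior_type = NA_character_
  )
  for (col in names(defaults)) {
    if (is.null(df[[col]])) df[[col]] <- rep(defaults[[col]], nrow(df))
  }
  if (is.null(df$nodule_id) || all(is.na(df$nodule_id))) {
    df$nodule_id <- if (nrow(df)) paste0("nodule_", seq_len(nrow(df))) else character()
  }
  df$is_new[is.na(df$is_new)] <- FALSE
  df$is_resolved[is.na(df$is_resolved)] <- FALSE
  df
}

.validate_obs <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  bad <- !df$type %in% nodule_types
  if (any(bad)) {
    stop(sprintf("unknown nodule type %s (row %d)",
                 dQuote(df$type[bad][1]), which(bad)[1]), call. = FALSE)
  }
  for (col in c("avg_diameter_mm", "volume_mm3",
                "solid_comp_diameter_mm", "solid_comp_volume_mm3")) {
    if (any(df[[col]] < 0, na.rm = TRUE)) {
      stop(sprintf("%s must be non-negative", col), call. = FALSE)
    }
  }
  if (any(df$is_new & df$is_resolved)) {
    stop("a nodule cannot be both new and resolved on the same scan",
         call. = FALSE)
  }
  has_comp <- !is.na(df$solid_comp_diameter_mm) | !is.na(df$solid_comp_volume_mm3)
  if (any(has_comp & df$type != "PART_SOLID")) {
    stop("solid-component measurements are only valid for PART_SOLID nodules",
         call. = FALSE)
  }
  no_size <- is.na(df$avg_diameter_mm) & is.na(df$volume_mm3) & !df$is_resolved
  if (any(no_size)) {
    stop(sprintf("observation with no size measurement (nodule %s)",
                 df$nodule_id[no_size][1]), call. = FALSE)
  }
  invisible(df)
}

# Closed-below threshold test on the governing size: the measured volume when
# present, otherwise the diameter. NA when neither size is available.
.size_ge <- function(d, v, cut_mm, cut_mm3) {
  ifelse(!is.na(v), v >= cut_mm3, ifelse(!is.na(d), d >= cut_mm, NA))
}

# Strictly-above test (the follow-up "larger than" cell).
.size_gt <- function(d, v, cut_mm, cut_mm3) {
  ifelse(!is.na(v), v > cut_mm3, ifelse(!is.na(d), d > cut_mm, NA))
}

# The size that drives solid-rule bands: the nodule itself for SOLID, the
# solid component for PART_SOLID.
.solid_size <- function(df) {
  ps <- df$type == "PART_SOLID"
  list(
    d = ifelse(ps, df$solid_comp_diameter_mm, df$avg_diameter_mm),
    v = ifelse(ps, df$solid_comp_volume_mm3, df$volume_mm3)
  )
}

.stop_no_size <- function(id) {
  stop(sprintf("cannot apply size rule: nodule %s has no usable size measurement",
               id), call. = FALSE)
}

# Per-nodule rule evaluation for a baseline scan. Returns parallel vectors
# rule/severity/interval/antibiotics (rule NA = nodule triggers nothing).
.rules_baseline <- function(df, thr) {
  n <- nrow(df)
  rule <- rep(NA_character_, n); sev <- integer(n)
  int <- rep(NA_integer_, n); abx <- logical(n)

  solidish <- df$type %in% c("SOLID", "PART_SOLID")
  if (any(solidish)) {
    sz <- .solid_size(df)
    ge_semi <- .size_ge(sz$d, sz$v, thr$semi_solid_mm, thr$semi_solid_mm3)
    ge_pos <- .size_ge(sz$d, sz$v, thr$positive_solid_mm, thr$positive_solid_mm3)
    if (any(solidish & is.na(ge_semi))) {
      .stop_no_size(df$nodule_id[solidish & is.na(ge_semi)][1])
    }
    i <- solidish & ge_pos
    rule[i] <- "BL.c1"; sev[i] <- 2L
    i <- solidish & !ge_pos & ge_semi
    rule[i] <- "BL.b3"; sev[i] <- 1L; int[i] <- thr$baseline_recall
    i <- solidish & !ge_semi
    rule[i] <- "BL.b2"; sev[i] <- 1L; int[i] <- thr$annual
  }
  i <- df$type == "NON_SOLID"
  rule[i] <- "BL.b1"; sev[i] <- 1L; int[i] <- thr$annual
  i <- df$type == "ENDOBRONCHIAL"
  rule[i] <- "BL.b4"; sev[i] <- 1L; int[i] <- thr$immediate_recall

  list(rule = rule, sev = sev, int = int, abx = abx)
}

# Per-nodule rules for a regular annual/biennial repeat scan. Only NEW or
# GROWING findings (plus slowly growing non-solid and persistent
# endobronchial nodules) contribute; stable disease is a negative scan.
.rules_repeat <- function(df, thr) {
  n <- nrow(df)
  rule <- rep(NA_character_, n); sev <- integer(n)
  int <- rep(NA_integer_, n); abx <- logical(n)

  needs_growth <- !df$is_new & !df$is_resolved & df$type != "CALCIFIED"
  miss <- needs_growth & is.na(df$growth_class)
  if (any(miss)) {
    stop(sprintf("growth assessment missing for pre-existing nodule %s",
                 df$nodule_id[miss][1]), call. = FALSE)
  }

  endo <- df$type == "ENDOBRONCHIAL" & !df$is_resolved
  i <- endo & df$is_new
  rule[i] <- "RPT.b5"; sev[i] <- 1L; int[i] <- thr$immediate_recall
  i <- endo & !df$is_new          # persistent endobronchial after 1 month
  rule[i] <- "RPT.c2"; sev[i] <- 2L

  # Non-solid nodule that doubled within a year with an emergent solid
  # component: observed now as PART_SOLID where it was NON_SOLID before.
  emergent <- df$type == "PART_SOLID" &
    !is.na(df$prior_type) & df$prior_type == "NON_SOLID" &
    !is.na(df$vdt_days) & df$vdt_days <= 365
  rule[emergent] <- "RPT.c1"; sev[emergent] <- 2L

  grown <- !is.na(df$growth_class) & df$growth_class == "GROWING"
  ns_active <- df$type == "NON_SOLID" & !df$is_resolved &
    (df$is_new | grown |
       (!is.na(df$growth_class) & df$growth_class == "SLOWLY_GROWING"))
  rule[ns_active] <- "RPT.b1"; sev[ns_active] <- 1L; int[ns_active] <- thr$annual

  solidish <- df$type %in% c("SOLID", "PART_SOLID") & !df$is_resolved &
    !emergent & (df$is_new | grown)
  if (any(solidish)) {
    sz <- .solid_size(df)
    ge_small <- .size_ge(sz$d, sz$v, thr$small_solid_mm, thr$small_solid_mm3)
    ge_semi <- .size_ge(sz$d, sz$v, thr$semi_solid_mm, thr$semi_solid_mm3)
    if (any(solidish & is.na(ge_small))) {
      .stop_no_size(df$nodule_id[solidish & is.na(ge_small)][1])
    }
    i <- solidish & ge_semi
    rule[i] <- "RPT.b4"; sev[i] <- 1L; int[i] <- thr$immediate_recall
    abx[i] <- TRUE
    i <- solidish & !ge_semi & ge_small
    rule[i] <- "RPT.b3"; sev[i] <- 1L; int[i] <- thr$short_recall
    i <- solidish & !ge_small
    rule[i] <- "RPT.b2"; sev[i] <- 1L; int[i] <- thr$annual
  }

  list(rule = rule, sev = sev, int = int, abx = abx)
}

# Per-nodule rules for an interim follow-up scan: management is driven by the
# volume doubling time measured since the triggering scan.
.rules_followup <- function(df, thr) {
  n <- nrow(df)
  rule <- rep(NA_character_, n); sev <- integer(n)
  int <- rep(NA_integer_, n); abx <- logical(n)

  i <- df$is_resolved
  rule[i] <- "FU.a1"; int[i] <- thr$biennial     # severity stays NEGATIVE

  live <- !df$is_resolved & df$type != "CALCIFIED"
  endo <- live & df$type == "ENDOBRONCHIAL"
  rule[endo] <- "FU.c2"; sev[endo] <- 2L

  assessed <- live & !endo
  # A stable or shrinking nodule has no finite VDT: that is the slow limit of
  # the VDT >= 600 d band. An absent assessment altogether is an error.
  not_growing <- assessed & is.na(df$vdt_days) &
    !is.na(df$growth_class) & df$growth_class %in% c("STABLE", "SHRINKING")
  miss <- assessed & is.na(df$vdt_days) & !not_growing
  if (any(miss)) {
    stop(sprintf("VDT missing for unresolved nodule %s on follow-up scan",
                 df$nodule_id[miss][1]), call. = FALSE)
  }

  fast <- assessed & !is.na(df$vdt_days) & df$vdt_days < thr$vdt_positive_days
  rule[fast] <- "FU.c1"; sev[fast] <- 2L

  mid <- assessed & !is.na(df$vdt_days) &
    df$vdt_days >= thr$vdt_positive_days & df$vdt_days < thr$vdt_semi_upper_days
  if (any(mid)) {
    large <- .size_gt(df$avg_diameter_mm, df$volume_mm3,
                      thr$followup_large_mm, thr$followup_large_mm3)
    if (any(mid & is.na(large))) .stop_no_size(df$nodule_id[mid & is.na(large)][1])
    i <- mid & large
    rule[i] <- "FU.c3"; sev[i] <- 2L
    i <- mid & !large
    rule[i] <- "FU.b2"; sev[i] <- 1L; int[i] <- thr$short_recall
  }

  slow <- (assessed & !is.na(df$vdt_days) &
             df$vdt_days >= thr$vdt_semi_upper_days) | not_growing
  rule[slow] <- "FU.b1"; sev[slow] <- 1L; int[slow] <- thr$annual

  list(rule = rule, sev = sev, int = int, abx = abx)
}

# Aggregate per-nodule rule hits into one scan-level classification.
# Category = worst severity; among repeat recommendations the shortest
# interval wins; referral dominates everything.
.aggregate <- function(df, hits, default_rule, default_interval) {
  fired <- which(!is.na(hits$rule))
  if (length(fired) == 0) {
    return(list(category = "NEGATIVE", action = "REPEAT_LDCT",
                interval_months = as.integer(default_interval),
                consider_antibiotics = FALSE, rule_code = default_rule,
                driving_nodule_id = NA_character_,
                trace = data.frame(nodule_id = character(),
                                   rule_code = character(),
                                   stringsAsFactors = FALSE)))
  }
  trace <- data.frame(nodule_id = df$nodule_id[fired],
                      rule_code = hits$rule[fired],
                      stringsAsFactors = FALSE)
  sev <- hits$sev[fired]; int <- hits$int[fired]
  max_sev <- max(sev)
  abx <- any(hits$abx[fired])
  if (max_sev == 2L) {
    drv <- fired[which(sev == 2L)[1]]
    return(list(category = "POSITIVE", action = "REFER_NODULE_CLINIC",
                interval_months = NA_integer_, consider_antibiotics = abx,
                rule_code = hits$rule[drv],
                driving_nodule_id = df$nodule_id[drv], trace = trace))
  }
  best <- fired[order(int, -sev)[1]]
  list(category = .CATEGORIES[max_sev + 1L], action = "REPEAT_LDCT",
       interval_months = as.integer(min(int, na.rm = TRUE)),
       consider_antibiotics = abx, rule_code = hits$rule[best],
       driving_nodule_id = df$nodule_id[best], trace = trace)
}

# Fast internal entry point working on plain data frames; the exported
# classify_* wrappers add validation and tibble packaging. `complete` skips
# schema completion when the caller already supplies every column.
.classify_impl <- function(nodules, round_type, thr, complete = TRUE) {
  df <- if (complete) .complete_obs(nodules) else nodules
  res <- switch(
    round_type,
    BASELINE = .aggregate(df, .rules_baseline(df, thr), "BL.a1", thr$annual),
    ANNUAL_REPEAT = ,
    BIENNIAL_REPEAT = .aggregate(df, .rules_repeat(df, thr), "RPT.a1",
                                 thr$biennial),
    INTERIM_FOLLOWUP = .aggregate(df, .rules_followup(df, thr), "FU.a1",
                                  thr$biennial),
    stop(sprintf("unknown round_type %s", dQuote(round_type)), call. = FALSE)
  )
  res
}

.classification_tibble <- function(res) {
  tibble::tibble(
    category = res$category,
    action = res$action,
    interval_months = res$interval_months,
    consider_antibiotics = res$consider_antibiotics,
    rule_code = res$rule_code,
    driving_nodule_id = res$driving_nodule_id,
    trace = list(tibble::as_tibble(res$trace))
  )
}

#' Classify a baseline screening scan
#'
#' Applies the baseline column of the nodule-management decision table to the
#' nodules seen on a participant's first LDCT. A scan with no non-calcified
#' nodules is negative (first annual screen in 12 months); non-calcified
#' findings are graded by attenuation class and by the size of the solid
#' nodule (or of the solid component of a part-solid nodule), with volume
#' taking precedence over diameter when both were measured. A solid finding
#' at or above the positive cut-off is referred to the nodule clinic.
#'
#' @param nodules Data frame with one row per nodule: `nodule_id`, `type`
#'   (one of [nodule_types]), `avg_diameter_mm`, `volume_mm3`, and for
#'   part-solid nodules `solid_comp_diameter_mm` / `solid_comp_volume_mm3`.
#'   Zero rows = no nodules.
#' @param thresholds A [protocol_thresholds()].
#' @return One-row tibble: `category`, `action`, `interval_months` (`NA` on
#'   referral), `consider_antibiotics`, `rule_code`, `driving_nodule_id`, and
#'   a `trace` list-column with one `(nodule_id, rule_code)` row per rule
#'   that fired.
#' @examples
#' classify_baseline(tibble::tibble(
#'   nodule_id = "n1", type = "SOLID", avg_diameter_mm = 10
#' ))
#' @export
classify_baseline <- function(nodules, thresholds = protocol_thresholds()) {
  classify_scan(nodules, round_type = "BASELINE", thresholds = thresholds)
}

#' Classify a regular annual or biennial repeat scan
#'
#' Applies the annual/biennial column of the decision table. Only new or
#' growing nodules can raise the category; a scan where nothing is new and
#' nothing grew is negative, with the next repeat in 24 months (the biennial
#' rule). Pre-existing non-calcified nodules must carry a growth assessment
#' (`growth_class`, and `vdt_days` where growing) from [assess_growth()].
#'
#' @param nodules As in [classify_baseline()], plus `is_new`, `is_resolved`,
#'   `growth_class`, `vdt_days`, and optionally `prior_type` (the attenuation
#'   class on the prior scan, used to spot a solid component emerging in a
#'   formerly non-solid nodule).
#' @inheritParams classify_baseline
#' @inherit classify_baseline return
#' @examples
#' classify_repeat(tibble::tibble(
#'   nodule_id = "n1", type = "SOLID", avg_diameter_mm = 4, is_new = TRUE
#' ))
#' @export
classify_repeat <- function(nodules, thresholds = protocol_thresholds()) {
  classify_scan(nodules, round_type = "ANNUAL_REPEAT", thresholds = thresholds)
}

#' Classify an interim follow-up scan
#'
#' Applies the follow-up column of the decision table, where management is
#' driven by the volume doubling time measured against the triggering scan:
#' VDT below 400 days is positive; VDT in \[400, 600) days earns a 6-month
#' recall unless the nodule is larger than 15 mm (2000 mm^3), which is
#' positive; VDT of 600 days or more (including nodules that did not grow)
#' returns the participant to the annual schedule; a resolved nodule is
#' negative with the next screen in 24 months. A persistent endobronchial
#' nodule is positive.
#'
#' @param nodules As in [classify_repeat()]; unresolved non-endobronchial
#'   nodules must carry `vdt_days` (or a STABLE/SHRINKING `growth_class`).
#' @inheritParams classify_baseline
#' @inherit classify_baseline return
#' @examples
#' classify_followup(tibble::tibble(
#'   nodule_id = "n1", type = "SOLID", avg_diameter_mm = 10, vdt_days = 500
#' ))
#' @export
classify_followup <- function(nodules, thresholds = protocol_thresholds()) {
  classify_scan(nodules, round_type = "INTERIM_FOLLOWUP",
                thresholds = thresholds)
}

#' Classify a scan of any round type
#'
#' Dispatches to the baseline, repeat or follow-up rules according to
#' `round_type`. Annual and biennial repeats share one rule set.
#'
#' @inheritParams classify_baseline
#' @param round_type One of `"BASELINE"`, `"ANNUAL_REPEAT"`,
#'   `"BIENNIAL_REPEAT"`, `"INTERIM_FOLLOWUP"`.
#' @inherit classify_baseline return
#' @examples
#' classify_scan(tibble::tibble(nodule_id = character(), type = character()),
#'               round_type = "BASELINE")
#' @export
classify_scan <- function(nodules, round_type,
                          thresholds = protocol_thresholds()) {
  stopifnot(inherits(thresholds, "protocol_thresholds"))
  if (!is.character(round_type) || length(round_type) != 1 ||
      !round_type %in% .ROUND_TYPES) {
    stop(sprintf("round_type must be one of %s",
                 paste(.ROUND_TYPES, collapse = ", ")), call. = FALSE)
  }
  df <- .complete_obs(nodules)
  .validate_obs(df)
  .classification_tibble(.classify_impl(df, round_type, thresholds,
                                        complete = FALSE))
}

#' Classify a batch of scans
#'
#' Splits a long nodule table (one row per nodule per scan) by scan and
#' classifies each scan with [classify_scan()].
#'
#' @param nodules Data frame with `participant_id`, `scan_id`, `round_type`
#'   plus the per-nodule columns of [classify_scan()]. All rows of one scan
#'   must share one `round_type`.
#' @inheritParams classify_baseline
#' @return A tibble with one row per scan: `participant_id`, `scan_id`,
#'   `round_type` and the [classify_scan()] columns.
#' @examples
#' nods <- tibble::tibble(
#'   participant_id = c("p1", "p1", "p2"),
#'   scan_id = c("s1", "s1", "s2"),
#'   round_type = "BASELINE",
#'   nodule_id = c("a", "b", "c"),
#'   type = c("SOLID", "CALCIFIED", "NON_SOLID"),
#'   avg_diameter_mm = c(7, 4, 12)
#' )
#' classify_scans(nods)
#' @export
classify_scans <- function(nodules, thresholds = protocol_thresholds()) {
  req <- c("participant_id", "scan_id", "round_type")
  miss <- setdiff(req, names(nodules))
  if (length(miss)) {
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  nodules |>
    dplyr::group_by(.data$participant_id, .data$scan_id) |>
    dplyr::group_modify(function(grp, key) {
      rt <- unique(grp$round_type)
      if (length(rt) != 1) {
        stop(sprintf("scan %s mixes round types", key$scan_id), call. = FALSE)
      }
      cls <- classify_scan(dplyr::select(grp, -"round_type"), rt, thresholds)
      dplyr::bind_cols(tibble::tibble(round_type = rt), cls)
    }) |>
    dplyr::ungroup()
}

#' Next scheduled round after a classification
#'
#' Negative results with a 24-month recall move the participant to biennial
#' screening; 12-month results schedule the next annual repeat; short recalls
#' (1, 3 or 6 months) schedule an interim follow-up; a referral ends
#' scheduled screening (`NA`).
#'
#' @param classification A classification tibble from [classify_scan()] (any
#'   number of rows).
#' @return Character vector of round types, `NA` where screening ends.
#' @examples
#' cls <- classify_baseline(tibble::tibble(nodule_id = character(),
#'                                         type = character()))
#' next_round_type(cls)  # "ANNUAL_REPEAT"
#' @export
next_round_type <- function(classification) {
  action <- classification$action
  int <- classification$interval_months
  out <- rep(NA_character_, length(action))
  rpt <- action == "REPEAT_LDCT"
  out[rpt & int >= 24] <- "BIENNIAL_REPEAT"
  out[rpt & int == 12] <- "ANNUAL_REPEAT"
  out[rpt & int < 12] <- "INTERIM_FOLLOWUP"
  out
}
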