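.NODULE_COLS <- c("participant_id", "scan_id", "nodule_id", "type",
                  "avg_diameter_mm", "volume_mm3", "solid_comp_diameter_mm",
                  "solid_comp_volume_mm3", "is_new", "is_resolved",
                  "location")

#' Read a nodule observation table
#'
#' Reads the interchange format for nodule observations: one row per nodule
#' per scan, CSV (header mandatory, UTF-8, empty string = missing) or JSON
#' (array of objects with the same fields). Every malformed row is reported
#' with its row number and offending field; duplicate `(scan_id, nodule_id)`
#' pairs and unknown nodule types are hard errors.
#'
#' @param path File to read.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @return Tibble with columns `participant_id`, `scan_id`, `nodule_id`,
#'   `type`, `avg_diameter_mm`, `volume_mm3`, `solid_comp_diameter_mm`,
#'   `solid_comp_volume_mm3`, `is_new`, `is_resolved`, `location`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' readr::write_csv(tibble::tibble(
#'   participant_id = "p1", scan_id = "s1", nodule_id = "n1",
#'   type = "SOLID", avg_diameter_mm = 7, volume_mm3 = NA,
#'   solid_comp_diameter_mm = NA, solid_comp_volume_mm3 = NA,
#'   is_new = FALSE, is_resolved = FALSE, location = "RUL"
#' ), f)
#' read_nodule_table(f)
#' @export
read_nodule_table <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    df <- tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    df <- suppressWarnings(readr::read_csv(
      path, na = c("", "NA"), show_col_types = FALSE,
      col_types = readr::cols(
        participant_id = readr::col_character(),
        scan_id = readr::col_character(),
        nodule_id = readr::col_character(),
        type = readr::col_character(),
        avg_diameter_mm = readr::col_double(),
        volume_mm3 = readr::col_double(),
        solid_comp_diameter_mm = readr::col_double(),
        solid_comp_volume_mm3 = readr::col_double(),
        is_new = readr::col_logical(),
        is_resolved = readr::col_logical(),
        location = readr::col_character()
      )
    ))
    probs <- readr::problems(df)
    if (nrow(probs)) {
      stop(sprintf("malformed value in %s at row %d, column %d (expected %s)",
                   path, probs$row[1], probs$col[1], probs$expected[1]),
           call. = FALSE)
    }
  }
  miss <- setdiff(c("participant_id", "scan_id", "nodule_id", "type"),
                  names(df))
  if (length(miss)) {
    stop(sprintf("nodule table %s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (col in setdiff(.NODULE_COLS, names(df))) {
    df[[col]] <- if (col %in% c("is_new", "is_resolved")) NA else NA_real_
  }
  df$is_new[is.na(df$is_new)] <- FALSE
  df$is_resolved[is.na(df$is_resolved)] <- FALSE

  bad <- which(!df$type %in% nodule_types)
  if (length(bad)) {
    stop(sprintf("row %d: unknown nodule type %s (column 'type')",
                 bad[1], dQuote(df$type[bad[1]])), call. = FALSE)
  }
  dup <- duplicated(df[, c("scan_id", "nodule_id")])
  if (any(dup)) {
    stop(sprintf("row %d: duplicate (scan_id, nodule_id) = (%s, %s)",
                 which(dup)[1], df$scan_id[which(dup)[1]],
                 df$nodule_id[which(dup)[1]]), call. = FALSE)
  }
  df[, .NODULE_COLS]
}

#' Write a nodule observation table
#'
#' Inverse of [read_nodule_table()]; round-trips canonical tables exactly.
#'
#' @param nodules Nodule observation tibble.
#' @param path Destination; `.json` writes the JSON variant, anything else
#'   CSV.
#' @return `path`, invisibly.
#' @export
write_nodule_table <- function(nodules, path) {
  nodules <- tibble::as_tibble(nodules)
  for (col in setdiff(.NODULE_COLS, names(nodules))) {
    nodules[[col]] <- if (col %in% c("is_new", "is_resolved")) FALSE
                      else NA_real_
  }
  nodules <- nodules[, .NODULE_COLS]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(nodules, path, dataframe = "rows", na = "null",
                         auto_unbox = FALSE, digits = NA, pretty = TRUE)
  } else {
    readr::write_csv(nodules, path, na = "")
  }
  invisible(path)
}

#' Read a participant roster
#'
#' CSV with columns `participant_id, age_years, smoking_status, pack_years,
#' years_since_quit, flags` (flags semicolon-separated exclusion codes).
#'
#' @param path File to read.
#' @return Roster tibble suitable for [assess_eligibility()].
#' @export
read_roster <- function(path) {
  df <- readr::read_csv(
    path, na = c("", "NA"), show_col_types = FALSE,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      age_years = readr::col_double(),
      smoking_status = readr::col_character(),
      pack_years = readr::col_double(),
      years_since_quit = readr::col_double(),
      flags = readr::col_character()
    )
  )
  probs <- readr::problems(df)
  if (nrow(probs)) {
    stop(sprintf("malformed value in %s at row %d, column %d",
                 path, probs$row[1], probs$col[1]), call. = FALSE)
  }
  df$flags[is.na(df$flags)] <- ""
  df
}

#' Read a scanner profile from JSON
#'
#' @param path JSON file with the [qc_check_scanner()] fields.
#' @return Named list.
#' @export
read_scanner_profile <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Read dose records
#'
#' CSV `participant_id, scan_id, scan_date, effective_dose_mSv`
#' (ISO-8601 dates).
#'
#' @param path File to read.
#' @return Tibble of dose records.
#' @export
read_dose_records <- function(path) {
  readr::read_csv(
    path, na = c("", "NA"), show_col_types = FALSE,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      scan_id = readr::col_character(),
      scan_date = readr::col_date(),
      effective_dose_mSv = readr::col_double()
    )
  )
}

.GRADES <- c("NONE", "MILD", "MODERATE", "SEVERE")

#' Build a structured radiology report
#'
#' The structured report couples the scan's classification with mandatory
#' per-scan and cumulative effective dose fields and the ancillary findings
#' the program records: emphysema and coronary artery calcification on a
#' four-level visual scale, and the diameters of the aorta and pulmonary
#' artery.
#'
#' @param participant_id,scan_id Identifiers.
#' @param effective_dose_mSv,cumulative_dose_mSv Mandatory dose fields,
#'   mSv, > 0.
#' @param classification One-row tibble from [classify_scan()].
#' @param findings Nodule observation tibble (may be empty).
#' @param emphysema_grade,cac_grade One of `"NONE"`, `"MILD"`, `"MODERATE"`,
#'   `"SEVERE"`.
#' @param aorta_diameter_mm,pulmonary_artery_diameter_mm Vessel diameters,
#'   mm (optional).
#' @param significant_ancillary_flag Whether ancillary findings need
#'   separate work-up.
#' @return A list of class `structured_report`.
#' @examples
#' cls <- classify_baseline(tibble::tibble(nodule_id = character(),
#'                                         type = character()))
#' structured_report("p1", "s1", 0.9, 0.9, cls)
#' @export
structured_report <- function(participant_id, scan_id,
                              effective_dose_mSv, cumulative_dose_mSv,
                              classification,
                              findings = NULL,
                              emphysema_grade = "NONE",
                              cac_grade = "NONE",
                              aorta_diameter_mm = NA_real_,
                              pulmonary_artery_diameter_mm = NA_real_,
                              significant_ancillary_flag = FALSE) {
  if (is.null(effective_dose_mSv) || is.na(effective_dose_mSv) ||
      effective_dose_mSv <= 0) {
    stop("effective_dose_mSv is mandatory and must be positive", call. = FALSE)
  }
  if (is.null(cumulative_dose_mSv) || is.na(cumulative_dose_mSv) ||
      cumulative_dose_mSv < effective_dose_mSv) {
    stop("cumulative_dose_mSv is mandatory and must be >= the per-scan dose",
         call. = FALSE)
  }
  if (!emphysema_grade %in% .GRADES || !cac_grade %in% .GRADES) {
    stop(sprintf("grades must be one of %s", paste(.GRADES, collapse = ", ")),
         call. = FALSE)
  }
  structure(
    list(
      participant_id = participant_id, scan_id = scan_id,
      effective_dose_mSv = effective_dose_mSv,
      cumulative_dose_mSv = cumulative_dose_mSv,
      classification = tibble::as_tibble(classification),
      findings = if (is.null(findings)) {
        tibble::tibble(nodule_id = character(), type = character())
      } else {
        tibble::as_tibble(findings)
      },
      ancillary = list(
        emphysema_grade = emphysema_grade, cac_grade = cac_grade,
        aorta_diameter_mm = aorta_diameter_mm,
        pulmonary_artery_diameter_mm = pulmonary_artery_diameter_mm
      ),
      significant_ancillary_flag = significant_ancillary_flag
    ),
    class = "structured_report"
  )
}

#' Write a structured report to JSON
#'
#' Stable field order; [read_report()] reads the file back to an equal
#' object.
#'
#' @param report A [structured_report()].
#' @param path Destination JSON file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "structured_report"))
  out <- unclass(report)
  out$classification <- as.data.frame(
    dplyr::select(out$classification, -dplyr::any_of("trace")))
  out$trace <- as.data.frame(report$classification$trace[[1]])
  out$findings <- as.data.frame(out$findings)
  jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a structured report from JSON
#'
#' @param path JSON file written by [write_report()].
#' @return A `structured_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cls <- tibble::as_tibble(x$classification)
  cls$interval_months <- if (is.null(cls$interval_months) ||
                               all(is.na(cls$interval_months))) {
    NA_integer_
  } else {
    as.integer(cls$interval_months)
  }
  trace <- x$trace
  cls$trace <- list(if (length(trace) == 0) {
    tibble::tibble(nodule_id = character(), rule_code = character())
  } else {
    tibble::as_tibble(trace)
  })
  structured_report(
    participant_id = x$participant_id, scan_id = x$scan_id,
    effective_dose_mSv = x$effective_dose_mSv,
    cumulative_dose_mSv = x$cumulative_dose_mSv,
    classification = cls,
    findings = tibble::as_tibble(x$findings),
    emphysema_grade = x$ancillary$emphysema_grade,
    cac_grade = x$ancillary$cac_grade,
    aorta_diameter_mm = x$ancillary$aorta_diameter_mm %||% NA_real_,
    pulmonary_artery_diameter_mm =
      x$ancillary$pulmonary_artery_diameter_mm %||% NA_real_,
    significant_ancillary_flag = isTRUE(x$significant_ancillary_flag)
  )
}

#' Read protocol overrides from a YAML config
#'
#' One YAML file can override the nodule-management thresholds, QC limits
#' and eligibility bounds; absent sections keep the printed defaults, so an
#' empty config reproduces the protocol exactly.
#'
#' @param path YAML file with optional top-level sections `thresholds`,
#'   `qc_limits`, `eligibility`, `growth`.
#' @return List with elements `thresholds`, `qc_limits`, `eligibility`,
#'   `growth`.
#' @export
read_protocol_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x)) x <- list()
  list(
    thresholds = do.call(protocol_thresholds,
                         x$thresholds %||% list()),
    qc_limits = do.call(qc_limits, x$qc_limits %||% list()),
    eligibility = do.call(eligibility_criteria, x$eligibility %||% list()),
    growth = do.call(growth_config, x$growth %||% list())
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
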