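#' Check a scanner profile against the minimum technical requirements
#'
#' One verdict per parameter; the scanner passes overall only when every
#' parameter is within its limit. All bounds are closed.
#'
#' @param profile Named list or one-row data frame with
#'   `peak_kilovoltage_kVp`, `tube_current_mAs`, `collimation_mm`,
#'   `rotation_time_s`, `ctdi_vol_mGy`, `avg_effective_dose_mSv`,
#'   `detector_slices`, `slice_thickness_mm`.
#' @param limits A [qc_limits()].
#' @return A list of class `qc_report`: `checks` (tibble `parameter`,
#'   `value`, `limit`, `pass`) and `overall_pass`.
#' @examples
#' prof <- list(peak_kilovoltage_kVp = 120, tube_current_mAs = 40,
#'              collimation_mm = 1, rotation_time_s = 0.5,
#'              ctdi_vol_mGy = 2.5, avg_effective_dose_mSv = 0.9,
#'              detector_slices = 128, slice_thickness_mm = 1)
#' qc_check_scanner(prof)
#' @export
qc_check_scanner <- function(profile, limits = qc_limits()) {
  stopifnot(inherits(limits, "qc_limits"))
  profile <- as.list(profile)
  fields <- c("peak_kilovoltage_kVp", "tube_current_mAs", "collimation_mm",
              "rotation_time_s", "ctdi_vol_mGy", "avg_effective_dose_mSv",
              "detector_slices", "slice_thickness_mm")
  for (f in fields) {
    v <- profile[[f]]
    if (is.null(v) || length(v) != 1 || is.na(v)) {
      stop(sprintf("scanner profile is missing field %s", dQuote(f)),
           call. = FALSE)
    }
    if (!is.numeric(v) || v <= 0) {
      stop(sprintf("scanner profile field %s must be a positive number",
                   dQuote(f)), call. = FALSE)
    }
  }
  checks <- tibble::tibble(
    parameter = c("peak_kilovoltage_kVp", "tube_current_mAs",
                  "collimation_mm", "rotation_time_s", "ctdi_vol_mGy",
                  "avg_effective_dose_mSv", "detector_slices",
                  "slice_thickness_mm"),
    value = c(profile$peak_kilovoltage_kVp, profile$tube_current_mAs,
              profile$collimation_mm, profile$rotation_time_s,
              profile$ctdi_vol_mGy, profile$avg_effective_dose_mSv,
              profile$detector_slices, profile$slice_thickness_mm),
    limit = c(sprintf("[%g, %g] kVp", limits$kvp_min, limits$kvp_max),
              sprintf("[%g, %g] mAs", limits$mas_min, limits$mas_max),
              sprintf("<= %g mm", limits$collimation_max_mm),
              sprintf("<= %g s", limits$rotation_max_s),
              sprintf("<= %g mGy", limits$ctdi_vol_max_mGy),
              sprintf("<= %g mSv", limits$effective_dose_max_mSv),
              sprintf(">= %d slices", limits$detector_slices_min),
              sprintf("<= %g mm", limits$slice_thickness_max_mm)),
    pass = c(
      profile$peak_kilovoltage_kVp >= limits$kvp_min &&
        profile$peak_kilovoltage_kVp <= limits$kvp_max,
      profile$tube_current_mAs >= limits$mas_min &&
        profile$tube_current_mAs <= limits$mas_max,
      profile$collimation_mm <= limits$collimation_max_mm,
      profile$rotation_time_s <= limits$rotation_max_s,
      profile$ctdi_vol_mGy <= limits$ctdi_vol_max_mGy,
      profile$avg_effective_dose_mSv <= limits$effective_dose_max_mSv,
      profile$detector_slices >= limits$detector_slices_min,
      profile$slice_thickness_mm <= limits$slice_thickness_max_mm
    )
  )
  structure(list(checks = checks, overall_pass = all(checks$pass)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Scanner QC: %s\n",
              if (x$overall_pass) "PASS" else "FAIL"))
  print(x$checks, n = Inf)
  invisible(x)
}

#' Per-scan effective dose check
#'
#' A scan passes when its effective dose does not exceed the program limit
#' (closed bound: a dose exactly at the limit passes).
#'
#' @param effective_dose_mSv Effective dose(s) per scan, mSv, > 0.
#'   Vectorised.
#' @param limits A [qc_limits()].
#' @return Logical vector, `TRUE` where the scan passes.
#' @examples
#' qc_check_scan_dose(c(0.89, 1.5, 1.6))  # TRUE TRUE FALSE
#' @export
qc_check_scan_dose <- function(effective_dose_mSv, limits = qc_limits()) {
  stopifnot(inherits(limits, "qc_limits"))
  if (any(!is.finite(effective_dose_mSv) | effective_dose_mSv <= 0)) {
    stop("effective_dose_mSv must be positive", call. = FALSE)
  }
  effective_dose_mSv <= limits$effective_dose_max_mSv
}

#' Cumulative radiation dose per participant
#'
#' Sums the effective doses of a participant's scans; the structured report
#' carries this cumulative dose alongside the per-scan dose.
#'
#' @param records Data frame of dose records: `participant_id`, `scan_id`,
#'   `scan_date`, `effective_dose_mSv`.
#' @param participant_id Single id to total; `NULL` returns the
#'   per-participant table.
#' @return With an id, a single number (0 when the participant has no
#'   records); otherwise a tibble `participant_id`, `cumulative_dose_mSv`,
#'   `n_scans`.
#' @examples
#' recs <- tibble::tibble(participant_id = "p1", scan_id = c("s1", "s2"),
#'                        scan_date = as.Date("2023-01-01") + c(0, 365),
#'                        effective_dose_mSv = c(0.9, 0.8))
#' cumulative_dose(recs, "p1")  # 1.7
#' @export
cumulative_dose <- function(records, participant_id = NULL) {
  records <- tibble::as_tibble(records)
  if (nrow(records) && any(records$effective_dose_mSv <= 0, na.rm = TRUE)) {
    stop("dose records must have positive effective_dose_mSv", call. = FALSE)
  }
  if (!is.null(participant_id)) {
    sel <- records$effective_dose_mSv[records$participant_id == participant_id]
    return(sum(sel))
  }
  records |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(cumulative_dose_mSv = sum(.data$effective_dose_mSv),
                     n_scans = dplyr::n(), .groups = "drop")
}

#' Summarise radiation doses across a screening program
#'
#' @inheritParams cumulative_dose
#' @return A list of class `dose_summary`: `n_scans`, `mean_mSv`, `max_mSv`,
#'   and `per_participant` (the [cumulative_dose()] table).
#' @examples
#' recs <- tibble::tibble(participant_id = c("p1", "p2"),
#'                        scan_id = c("s1", "s2"),
#'                        scan_date = as.Date("2023-01-01"),
#'                        effective_dose_mSv = c(0.8, 1.0))
#' dose_summary(recs)$mean_mSv  # 0.9
#' @export
dose_summary <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    stop("cannot summarise an empty set of dose records", call. = FALSE)
  }
  if (any(records$effective_dose_mSv <= 0, na.rm = TRUE)) {
    stop("dose records must have positive effective_dose_mSv", call. = FALSE)
  }
  structure(
    list(n_scans = nrow(records),
         mean_mSv = mean(records$effective_dose_mSv),
         max_mSv = max(records$effective_dose_mSv),
         per_participant = cumulative_dose(records)),
    class = "dose_summary"
  )
}

#' @export
print.dose_summary <- function(x, ...) {
  cat(sprintf("Doses over %d scans: mean %.3f mSv, max %.3f mSv\n",
              x$n_scans, x$mean_mSv, x$max_mSv))
  invisible(x)
}
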