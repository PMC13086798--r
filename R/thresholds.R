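#' Protocol thresholds for nodule management
#'
#' Every numeric constant of the Modified I-ELCAP Croatia decision table in
#' one place. Diameter (mm) and volume (mm^3) cut-offs are *independent*
#' criteria exactly as the protocol prints them: the 6.5 mm / 150 mm^3 and
#' 15.5 mm / 2000 mm^3 pairs are not exact sphere equivalents of one another
#' and are never recomputed from each other. When a nodule carries both a
#' measured volume and a diameter, the volume criterion governs.
#'
#' @param small_solid_mm,small_solid_mm3 Lower solid-nodule cut-off
#'   (new/growing nodules below this are managed on the annual schedule).
#' @param semi_solid_mm,semi_solid_mm3 Cut-off above which a solid nodule (or
#'   the solid component of a part-solid nodule) triggers short-interval
#'   recall.
#' @param positive_solid_mm,positive_solid_mm3 Cut-off at or above which a
#'   baseline solid finding is positive (referral).
#' @param followup_large_mm,followup_large_mm3 Size above which a nodule in
#'   the intermediate VDT band on follow-up is referred rather than recalled.
#' @param vdt_positive_days Volume doubling time below which a follow-up scan
#'   is positive.
#' @param vdt_semi_upper_days VDT at or above which growth is slow enough to
#'   return to the annual schedule; the intermediate band is
#'   `[vdt_positive_days, vdt_semi_upper_days)`.
#' @param immediate_recall,baseline_recall,short_recall,annual,biennial
#'   Recall intervals, months.
#'
#' @return A list of class `protocol_thresholds`.
#' @examples
#' protocol_thresholds()
#' protocol_thresholds(semi_solid_mm = 6)$semi_solid_mm
#' @export
protocol_thresholds <- function(small_solid_mm = 3.0,
                                small_solid_mm3 = 20.0,
                                semi_solid_mm = 6.5,
                                semi_solid_mm3 = 150.0,
                                positive_solid_mm = 15.5,
                                positive_solid_mm3 = 2000.0,
                                followup_large_mm = 15.0,
                                followup_large_mm3 = 2000.0,
                                vdt_positive_days = 400,
                                vdt_semi_upper_days = 600,
                                immediate_recall = 1L,
                                baseline_recall = 3L,
                                short_recall = 6L,
                                annual = 12L,
                                biennial = 24L) {
  thr <- list(
    small_solid_mm = small_solid_mm,
    small_solid_mm3 = small_solid_mm3,
    semi_solid_mm = semi_solid_mm,
    semi_solid_mm3 = semi_solid_mm3,
    positive_solid_mm = positive_solid_mm,
    positive_solid_mm3 = positive_solid_mm3,
    followup_large_mm = followup_large_mm,
    followup_large_mm3 = followup_large_mm3,
    vdt_positive_days = vdt_positive_days,
    vdt_semi_upper_days = vdt_semi_upper_days,
    immediate_recall = as.integer(immediate_recall),
    baseline_recall = as.integer(baseline_recall),
    short_recall = as.integer(short_recall),
    annual = as.integer(annual),
    biennial = as.integer(biennial)
  )
  num <- unlist(thr)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all protocol thresholds must be finite and positive", call. = FALSE)
  }
  if (!(thr$small_solid_mm < thr$semi_solid_mm &&
        thr$semi_solid_mm < thr$positive_solid_mm)) {
    stop("diameter thresholds must be strictly ordered: small < semi < positive",
         call. = FALSE)
  }
  if (!(thr$small_solid_mm3 < thr$semi_solid_mm3 &&
        thr$semi_solid_mm3 < thr$positive_solid_mm3)) {
    stop("volume thresholds must be strictly ordered: small < semi < positive",
         call. = FALSE)
  }
  if (!(thr$vdt_positive_days < thr$vdt_semi_upper_days)) {
    stop("vdt_positive_days must be below vdt_semi_upper_days", call. = FALSE)
  }
  structure(thr, class = "protocol_thresholds")
}

#' Growth classification settings
#'
#' The protocol itself does not define "growing"; these knobs make the
#' convention explicit. A nodule is called growing when its volume increased
#' by at least `min_relative_volume_increase` between the paired scans;
#' non-solid nodules growing that much but with a VDT above
#' `slow_growth_vdt_days` are classed as slowly growing (they stay on the
#' annual schedule).
#'
#' @param min_relative_volume_increase Fractional volume increase below which
#'   a change is treated as measurement noise (stable). Must be in `[0, 1)`;
#'   0 is the limit case in which any strict increase counts as growth.
#' @param slow_growth_vdt_days VDT (days) separating growing from slowly
#'   growing non-solid nodules.
#' @return A list of class `growth_config`.
#' @examples
#' growth_config()
#' @export
growth_config <- function(min_relative_volume_increase = 0.30,
                          slow_growth_vdt_days = 600) {
  if (!is.numeric(min_relative_volume_increase) ||
      min_relative_volume_increase < 0 || min_relative_volume_increase >= 1) {
    stop("min_relative_volume_increase must be in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(slow_growth_vdt_days) || slow_growth_vdt_days <= 0) {
    stop("slow_growth_vdt_days must be positive", call. = FALSE)
  }
  structure(
    list(min_relative_volume_increase = min_relative_volume_increase,
         slow_growth_vdt_days = slow_growth_vdt_days),
    class = "growth_config"
  )
}

#' Minimum technical requirements for LDCT scanners
#'
#' Default limits reproduce the program's minimum technical requirements
#' table. All bounds are closed, as printed ("=<", ">="); the per-scan
#' effective dose check consequently passes at exactly the limit.
#'
#' @param kvp_min,kvp_max Peak kilovoltage window, kVp.
#' @param mas_min,mas_max Tube current window, mAs.
#' @param collimation_max_mm Maximum collimation, mm.
#' @param rotation_max_s Maximum gantry rotation time, s.
#' @param ctdi_vol_max_mGy Maximum CTDIvol, mGy.
#' @param effective_dose_max_mSv Maximum (average and per-scan) effective
#'   dose, mSv.
#' @param detector_slices_min Minimum number of detector slices.
#' @param slice_thickness_max_mm Maximum image slice thickness, mm.
#' @return A list of class `qc_limits`.
#' @examples
#' qc_limits()
#' @export
qc_limits <- function(kvp_min = 120, kvp_max = 140,
                      mas_min = 20, mas_max = 60,
                      collimation_max_mm = 1,
                      rotation_max_s = 0.5,
                      ctdi_vol_max_mGy = 3.0,
                      effective_dose_max_mSv = 1.5,
                      detector_slices_min = 128L,
                      slice_thickness_max_mm = 1) {
  lim <- list(
    kvp_min = kvp_min, kvp_max = kvp_max,
    mas_min = mas_min, mas_max = mas_max,
    collimation_max_mm = collimation_max_mm,
    rotation_max_s = rotation_max_s,
    ctdi_vol_max_mGy = ctdi_vol_max_mGy,
    effective_dose_max_mSv = effective_dose_max_mSv,
    detector_slices_min = as.integer(detector_slices_min),
    slice_thickness_max_mm = slice_thickness_max_mm
  )
  num <- unlist(lim)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all QC limits must be finite and positive", call. = FALSE)
  }
  if (lim$kvp_min > lim$kvp_max || lim$mas_min > lim$mas_max) {
    stop("QC limit ranges must satisfy min <= max", call. = FALSE)
  }
  structure(lim, class = "qc_limits")
}

#' Eligibility criteria settings
#'
#' Inclusion bounds for the screening program: age window, minimum smoking
#' exposure, and the maximum quit window for former smokers. All bounds are
#' closed (ages 50 and 75, exactly 30 pack-years and a quit exactly 15 years
#' ago all qualify).
#'
#' @param min_age,max_age Age window, years.
#' @param min_pack_years Minimum smoking history, pack-years.
#' @param max_years_since_quit Former smokers must have quit within this many
#'   years.
#' @return A list of class `eligibility_criteria`.
#' @examples
#' eligibility_criteria()
#' @export
eligibility_criteria <- function(min_age = 50L, max_age = 75L,
                                 min_pack_years = 30,
                                 max_years_since_quit = 15) {
  if (min_age > max_age) stop("min_age must not exceed max_age", call. = FALSE)
  if (min_pack_years < 0 || max_years_since_quit < 0) {
    stop("pack-year and quit-window bounds must be non-negative", call. = FALSE)
  }
  structure(
    list(min_age = as.integer(min_age), max_age = as.integer(max_age),
         min_pack_years = min_pack_years,
         max_years_since_quit = max_years_since_quit),
    class = "eligibility_criteria"
  )
}
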