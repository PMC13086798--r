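# Small constructors for nodule observation tibbles used throughout the
# suite.

nod <- function(type, d = NA_real_, v = NA_real_,
                comp_d = NA_real_, comp_v = NA_real_,
                is_new = FALSE, is_resolved = FALSE,
                growth = NA_character_, vdt = NA_real_,
                prior_type = NA_character_, id = "n1") {
  tibble::tibble(
    nodule_id = id, type = type,
    avg_diameter_mm = d, volume_mm3 = v,
    solid_comp_diameter_mm = comp_d, solid_comp_volume_mm3 = comp_v,
    is_new = is_new, is_resolved = is_resolved,
    growth_class = growth, vdt_days = vdt, prior_type = prior_type
  )
}

no_nodules <- function() {
  tibble::tibble(nodule_id = character(), type = character())
}

participant <- function(id = "p1", age = 62, status = "CURRENT",
                        pack_years = 35, quit = NA_real_, flags = "") {
  tibble::tibble(
    participant_id = id, age_years = age, smoking_status = status,
    pack_years = pack_years, years_since_quit = quit, flags = flags
  )
}

good_scanner <- function(...) {
  utils::modifyList(
    list(peak_kilovoltage_kVp = 120, tube_current_mAs = 40,
         collimation_mm = 1.0, rotation_time_s = 0.5,
         ctdi_vol_mGy = 2.5, avg_effective_dose_mSv = 0.9,
         detector_slices = 128, slice_thickness_mm = 1.0),
    list(...)
  )
}
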