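#' Nodule type and growth-class vocabularies
#'
#' The attenuation classes a nodule observation may carry, and the growth
#' classes a paired-scan assessment may assign. Calcified nodules are
#' considered benign and never drive management.
#'
#' @format Character vectors.
#' @name vocab
NULL

#' @rdname vocab
#' @export
nodule_types <- c("SOLID", "PART_SOLID", "NON_SOLID", "ENDOBRONCHIAL",
                  "CALCIFIED")

#' @rdname vocab
#' @export
growth_classes <- c("NEW", "GROWING", "SLOWLY_GROWING", "STABLE",
                    "SHRINKING", "RESOLVED")

#' Volume doubling time of a nodule between two scans
#'
#' Under exponential growth, a nodule whose volume went from `prior` to
#' `current` over `delta_days` has doubling time
#' `VDT = delta_days * log(2) / log(current / prior)`. A nodule that did not
#' grow (`current <= prior`) has no finite doubling time; that is reported as
#' `NA` (the not-growing sentinel), never as infinity.
#'
#' @param prior_volume_mm3 Volume on the earlier scan, mm^3, > 0. Vectorised.
#' @param current_volume_mm3 Volume on the later scan, mm^3.
#' @param delta_days Days between the scans, > 0.
#' @return VDT in days, or `NA` where the nodule did not grow.
#' @examples
#' compute_vdt(100, 200, 365)  # 365: doubled in exactly one year
#' compute_vdt(100, 400, 800)  # 400: two doublings in 800 days
#' compute_vdt(100, 90, 365)   # NA: not growing
#' @export
compute_vdt <- function(prior_volume_mm3, current_volume_mm3, delta_days) {
  if (any(!is.finite(prior_volume_mm3) | prior_volume_mm3 <= 0)) {
    stop("prior_volume_mm3 must be positive", call. = FALSE)
  }
  if (any(!is.finite(delta_days) | delta_days <= 0)) {
    stop("delta_days must be positive", call. = FALSE)
  }
  if (any(!is.finite(current_volume_mm3) | current_volume_mm3 < 0)) {
    stop("current_volume_mm3 must be non-negative", call. = FALSE)
  }
  ratio <- current_volume_mm3 / prior_volume_mm3
  out <- rep(NA_real_, length(ratio))
  grew <- ratio > 1
  out[grew] <- (delta_days * log(2) / log(ratio))[grew]
  out
}

#' Grow a nodule volume forward in time
#'
#' Exponential volume growth consistent with the VDT definition:
#' `V(t + delta) = V(t) * 2^(delta / vdt)`. A not-growing nodule
#' (`vdt_days = NA`) keeps its volume.
#'
#' @param volume_mm3 Starting volume(s), mm^3, > 0.
#' @param vdt_days Volume doubling time, days, or `NA` for a non-growing
#'   nodule.
#' @param delta_days Elapsed time, days, >= 0.
#' @return Volume(s) after `delta_days`.
#' @examples
#' grow_nodule(100, 400, 400)  # 200
#' grow_nodule(100, NA, 999)   # 100
#' @export
grow_nodule <- function(volume_mm3, vdt_days, delta_days) {
  if (any(!is.finite(volume_mm3) | volume_mm3 <= 0)) {
    stop("volume_mm3 must be positive", call. = FALSE)
  }
  if (any(!is.finite(delta_days) | delta_days < 0)) {
    stop("delta_days must be non-negative", call. = FALSE)
  }
  if (any(vdt_days <= 0, na.rm = TRUE)) {
    stop("vdt_days must be positive where given", call. = FALSE)
  }
  factor <- ifelse(is.na(vdt_days), 1, 2^(delta_days / vdt_days))
  volume_mm3 * factor
}

# Resolve the working volume of an observation row: measured volume if
# present, else derived from the average diameter under the sphere model.
.obs_volume <- function(volume_mm3, avg_diameter_mm) {
  ifelse(!is.na(volume_mm3), volume_mm3,
         ifelse(!is.na(avg_diameter_mm), pi * avg_diameter_mm^3 / 6,
                NA_real_))
}

#' Assess nodule growth between two paired observations
#'
#' Compares a nodule's observation on the current scan with the prior scan
#' and assigns a growth class plus a volume doubling time. Volumes are taken
#' as measured, or derived from average diameters under the sphere model when
#' no volume was measured. Relative volume increases below
#' `cfg$min_relative_volume_increase` are treated as within measurement
#' tolerance (STABLE). Non-solid nodules growing past the threshold but with
#' a VDT above `cfg$slow_growth_vdt_days` are SLOWLY_GROWING.
#'
#' @param prior,current Data frames (or one-row tibbles) with at least
#'   `volume_mm3` and `avg_diameter_mm` (either may be `NA`); `current` may
#'   also carry `nodule_id`, `type`, `is_new`, `is_resolved`. `prior = NULL`
#'   marks a nodule first seen on the current scan.
#' @param delta_days Days between the scans, > 0.
#' @param cfg A [growth_config()].
#' @return A one-row tibble: `nodule_id`, `prior_volume_mm3`,
#'   `current_volume_mm3`, `delta_days`, `vdt_days` (`NA` when not growing),
#'   `growth_class`.
#' @examples
#' prior <- tibble::tibble(volume_mm3 = 100, avg_diameter_mm = NA_real_)
#' cur <- tibble::tibble(nodule_id = "n1", type = "SOLID",
#'                       volume_mm3 = 150, avg_diameter_mm = NA_real_,
#'                       is_new = FALSE, is_resolved = FALSE)
#' assess_growth(prior, cur, delta_days = 365)
#' @export
assess_growth <- function(prior, current, delta_days, cfg = growth_config()) {
  stopifnot(inherits(cfg, "growth_config"))
  nodule_id <- if (!is.null(current[["nodule_id"]])) current$nodule_id[1] else NA_character_
  type <- if (!is.null(current[["type"]])) current$type[1] else "SOLID"
  is_resolved <- isTRUE(current[["is_resolved"]][1])
  is_new <- isTRUE(current[["is_new"]][1])

  if (is_resolved) {
    pv <- if (is.null(prior)) NA_real_ else
      .obs_volume(prior$volume_mm3[1], prior$avg_diameter_mm[1])
    return(tibble::tibble(
      nodule_id = nodule_id, prior_volume_mm3 = pv,
      current_volume_mm3 = NA_real_, delta_days = delta_days,
      vdt_days = NA_real_, growth_class = "RESOLVED"
    ))
  }

  cv <- .obs_volume(current$volume_mm3[1], current$avg_diameter_mm[1])
  if (is.null(prior) || is_new) {
    return(tibble::tibble(
      nodule_id = nodule_id, prior_volume_mm3 = NA_real_,
      current_volume_mm3 = cv, delta_days = delta_days,
      vdt_days = NA_real_, growth_class = "NEW"
    ))
  }

  pv <- .obs_volume(prior$volume_mm3[1], prior$avg_diameter_mm[1])
  if (is.na(pv) || is.na(cv)) {
    stop("growth unassessable: no size measurement on one of the paired scans",
         call. = FALSE)
  }
  if (!is.finite(delta_days) || delta_days <= 0) {
    stop("delta_days must be positive", call. = FALSE)
  }

  vdt <- compute_vdt(pv, cv, delta_days)
  rel <- (cv - pv) / pv
  cls <- if (cv > pv && rel >= cfg$min_relative_volume_increase) {
    if (type == "NON_SOLID" && !is.na(vdt) && vdt > cfg$slow_growth_vdt_days) {
      "SLOWLY_GROWING"
    } else {
      "GROWING"
    }
  } else if (cv < pv) {
    "SHRINKING"
  } else {
    "STABLE"
  }

  tibble::tibble(
    nodule_id = nodule_id, prior_volume_mm3 = pv, current_volume_mm3 = cv,
    delta_days = delta_days, vdt_days = vdt, growth_class = cls
  )
}
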