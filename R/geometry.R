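#' Sphere volume of a nodule from its average diameter
#'
#' Nodule volumetry under the spherical model: `V = pi * d^3 / 6`. Used to
#' align diameter-based and volume-based size criteria and to derive volumes
#' when only diameters were measured.
#'
#' @param avg_diameter_mm Average nodule diameter(s), mm. Non-negative.
#' @return Volume(s), mm^3. `NA` in gives `NA` out.
#' @seealso [equivalent_diameter()]
#' @examples
#' sphere_volume(6.5)   # ~143.79 mm^3
#' sphere_volume(15.5)  # ~1949.82 mm^3
#' @export
sphere_volume <- function(avg_diameter_mm) {
  if (!is.numeric(avg_diameter_mm)) {
    stop("avg_diameter_mm must be numeric", call. = FALSE)
  }
  if (any(avg_diameter_mm < 0, na.rm = TRUE)) {
    stop("avg_diameter_mm must be non-negative", call. = FALSE)
  }
  pi * avg_diameter_mm^3 / 6
}

#' Equivalent spherical diameter of a nodule volume
#'
#' Inverse of [sphere_volume()]: the diameter of the sphere with the given
#' volume, `d = (6 V / pi)^(1/3)`.
#'
#' @param volume_mm3 Nodule volume(s), mm^3. Non-negative.
#' @return Diameter(s), mm.
#' @examples
#' equivalent_diameter(150)   # ~6.59 mm
#' equivalent_diameter(sphere_volume(10))  # 10
#' @export
equivalent_diameter <- function(volume_mm3) {
  if (!is.numeric(volume_mm3)) {
    stop("volume_mm3 must be numeric", call. = FALSE)
  }
  if (any(volume_mm3 < 0, na.rm = TRUE)) {
    stop("volume_mm3 must be non-negative", call. = FALSE)
  }
  (6 * volume_mm3 / pi)^(1 / 3)
}

#' Average nodule diameter from long and short axes
#'
#' The mean-of-axes convention: `(long + short) / 2`.
#'
#' @param long_axis_mm,short_axis_mm Axis lengths, mm, with
#'   `long_axis_mm >= short_axis_mm >= 0`. Vectorised.
#' @return Average diameter(s), mm.
#' @examples
#' average_diameter(8, 5)  # 6.5
#' @export
average_diameter <- function(long_axis_mm, short_axis_mm) {
  if (!is.numeric(long_axis_mm) || !is.numeric(short_axis_mm)) {
    stop("axis lengths must be numeric", call. = FALSE)
  }
  if (any(short_axis_mm < 0, na.rm = TRUE)) {
    stop("axis lengths must be non-negative", call. = FALSE)
  }
  if (any(short_axis_mm > long_axis_mm, na.rm = TRUE)) {
    stop("short_axis_mm must not exceed long_axis_mm", call. = FALSE)
  }
  (long_axis_mm + short_axis_mm) / 2
}
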