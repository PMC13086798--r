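#' Exclusion criteria codes
#'
#' The program's six exclusion criteria, supplied as boolean flags by the
#' referring physician (they reflect clinical judgment and are never
#' computed here).
#'
#' @format Character vector of flag codes.
#' @export
exclusion_flags <- c(
  "SYMPTOMS_SUGGESTING_MALIGNANCY",
  "CHEST_CT_WITHIN_12_MONTHS",
  "LUNG_CANCER_TREATED_WITHIN_5_YEARS",
  "CONDITION_PREVENTS_DIAGNOSTICS",
  "CANNOT_CONSENT",
  "CANNOT_LIE_FLAT_HOLD_BREATH_OR_CLAUSTROPHOBIA"
)

.parse_flags <- function(flags) {
  if (is.list(flags)) return(flags)
  if (is.null(flags)) return(list(character()))
  lapply(strsplit(ifelse(is.na(flags), "", flags), ";", fixed = TRUE),
         function(x) trimws(x[nzchar(trimws(x))]))
}

#' Assess screening eligibility of candidate participants
#'
#' A candidate is eligible when aged 50-75 (inclusive), with at least 30
#' pack-years of smoking, currently smoking or having quit within the last
#' 15 years, and carrying none of the six exclusion flags. Every violated
#' criterion is reported, not just the first.
#'
#' @param roster Data frame with one row per candidate: `participant_id`,
#'   `age_years`, `smoking_status` (`CURRENT`/`FORMER`/`NEVER`),
#'   `pack_years`, `years_since_quit` (`NA` unless FORMER), and `flags`
#'   (semicolon-separated exclusion codes, or a list-column of character
#'   vectors; see [exclusion_flags]).
#' @param criteria An [eligibility_criteria()].
#' @return The roster as a tibble with `eligible` (logical) and
#'   `failed_criteria` (list-column of criterion codes) appended.
#' @examples
#' roster <- tibble::tibble(
#'   participant_id = c("p1", "p2"),
#'   age_years = c(62, 49),
#'   smoking_status = "CURRENT",
#'   pack_years = c(35, 40),
#'   years_since_quit = NA_real_,
#'   flags = ""
#' )
#' assess_eligibility(roster)
#' @export
assess_eligibility <- function(roster, criteria = eligibility_criteria()) {
  stopifnot(inherits(criteria, "eligibility_criteria"))
  roster <- tibble::as_tibble(roster)
  status <- roster$smoking_status
  bad_status <- !status %in% c("CURRENT", "FORMER", "NEVER")
  if (any(bad_status)) {
    stop(sprintf("unknown smoking_status %s", dQuote(status[bad_status][1])),
         call. = FALSE)
  }
  if (any(status == "NEVER" & roster$pack_years > 0, na.rm = TRUE)) {
    stop("inconsistent roster: NEVER smoker with positive pack_years",
         call. = FALSE)
  }
  if (any(status == "FORMER" & is.na(roster$years_since_quit))) {
    stop("years_since_quit required for FORMER smokers", call. = FALSE)
  }
  if (any(roster$pack_years < 0, na.rm = TRUE) ||
      any(roster$years_since_quit < 0, na.rm = TRUE)) {
    stop("pack_years and years_since_quit must be non-negative", call. = FALSE)
  }

  flags <- .parse_flags(roster[["flags"]])
  if (length(flags) == 1 && nrow(roster) > 1) flags <- rep(flags, nrow(roster))
  unknown <- setdiff(unique(unlist(flags)), exclusion_flags)
  if (length(unknown)) {
    stop(sprintf("unknown exclusion flag %s", dQuote(unknown[1])),
         call. = FALSE)
  }

  failed <- purrr::pmap(
    list(roster$age_years, status, roster$pack_years,
         roster$years_since_quit, flags),
    function(age, st, py, ysq, fl) {
      f <- character()
      if (age < criteria$min_age) f <- c(f, "AGE_BELOW_MIN")
      if (age > criteria$max_age) f <- c(f, "AGE_ABOVE_MAX")
      if (is.na(py) || py < criteria$min_pack_years) {
        f <- c(f, "INSUFFICIENT_PACK_YEARS")
      }
      if (st == "NEVER") f <- c(f, "NEVER_SMOKER")
      if (st == "FORMER" && ysq > criteria$max_years_since_quit) {
        f <- c(f, "QUIT_TOO_LONG_AGO")
      }
      c(f, fl)
    }
  )

  roster$eligible <- lengths(failed) == 0
  roster$failed_criteria <- failed
  roster
}

#' Summarise eligibility over a roster
#'
#' Evaluates [assess_eligibility()] over a roster and tallies how often each
#' criterion was violated. Counts of eligible and ineligible candidates sum
#' to the roster size; the per-criterion tally counts every violation, so a
#' candidate failing several criteria appears in several rows.
#'
#' @inheritParams assess_eligibility
#' @return A list of class `roster_summary`: `n`, `n_eligible`,
#'   `n_ineligible`, and `criterion_tally` (tibble `criterion`, `n`).
#' @examples
#' roster <- tibble::tibble(
#'   participant_id = "p1", age_years = 49, smoking_status = "CURRENT",
#'   pack_years = 40, years_since_quit = NA_real_, flags = ""
#' )
#' screen_roster(roster)
#' @export
screen_roster <- function(roster, criteria = eligibility_criteria()) {
  roster <- tibble::as_tibble(roster)
  if (nrow(roster) == 0) {
    return(structure(
      list(n = 0L, n_eligible = 0L, n_ineligible = 0L,
           criterion_tally = tibble::tibble(criterion = character(),
                                            n = integer())),
      class = "roster_summary"
    ))
  }
  assessed <- assess_eligibility(roster, criteria)
  tally <- tibble::tibble(criterion = unlist(assessed$failed_criteria)) |>
    dplyr::count(.data$criterion)
  structure(
    list(n = nrow(assessed),
         n_eligible = sum(assessed$eligible),
         n_ineligible = sum(!assessed$eligible),
         criterion_tally = tally),
    class = "roster_summary"
  )
}

#' @export
print.roster_summary <- function(x, ...) {
  cat(sprintf("Screening roster: %d candidates, %d eligible, %d ineligible\n",
              x$n, x$n_eligible, x$n_ineligible))
  if (nrow(x$criterion_tally)) {
    cat("Failed criteria:\n")
    print(x$criterion_tally, n = Inf)
  }
  invisible(x)
}
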