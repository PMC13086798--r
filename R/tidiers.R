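#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a program-results object
#'
#' @param x A [run_program()] result.
#' @param ... Unused.
#' @return Per-round tibble of scan counts and positivity (one row per
#'   round).
#' @export
tidy.program_results <- function(x, ...) {
  summarize_results(x)
}

#' One-row summary of a simulated screening program
#'
#' @param x A [run_program()] result.
#' @param ... Unused.
#' @return One-row tibble: participants, scans, rounds, baseline positivity,
#'   referrals, detected malignancies, mean per-scan dose.
#' @export
glance.program_results <- function(x, ...) {
  baseline <- x$per_round[x$per_round$round_index == 1L, ]
  tibble::tibble(
    n_participants = x$config$n_participants,
    n_scans = nrow(x$events),
    rounds_simulated = x$rounds_simulated,
    baseline_positivity = if (nrow(baseline)) baseline$positivity else NA_real_,
    n_referred = x$n_referred,
    detected_malignant = x$detected_malignant,
    mean_dose_mSv = if (nrow(x$events)) mean(x$events$dose_mSv) else NA_real_
  )
}

#' Tidy a roster summary
#'
#' @param x A [screen_roster()] result.
#' @param ... Unused.
#' @return Tibble of failed-criterion tallies.
#' @export
tidy.roster_summary <- function(x, ...) {
  x$criterion_tally
}

#' Tidy a scanner QC report
#'
#' @param x A [qc_check_scanner()] result.
#' @param ... Unused.
#' @return The per-parameter checks tibble.
#' @export
tidy.qc_report <- function(x, ...) {
  x$checks
}

#' Plot category mix per screening round
#'
#' Stacked bars of scan categories by round, the standard way to look at how
#' positivity and recall load evolve over a simulated program.
#'
#' @param object A [run_program()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.program_results <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_round,
    cols = c("n_negative", "n_semi_positive", "n_positive"),
    names_to = "category", values_to = "n"
  ) |>
    dplyr::mutate(category = factor(
      sub("^n_", "", .data$category),
      levels = c("negative", "semi_positive", "positive"),
      labels = c("Negative", "Semi-positive", "Positive")
    ))
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$round_index), y = .data$n, fill = .data$category
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(Negative = "#4d9221",
                                          `Semi-positive` = "#f1a340",
                                          Positive = "#b2182b")) +
    ggplot2::labs(x = "Screening round", y = "Scans", fill = "Category",
                  title = "Scan classifications by screening round") +
    ggplot2::theme_minimal()
}

#' Plot per-participant cumulative dose
#'
#' @param results A [run_program()] result.
#' @param limits A [qc_limits()]; the per-scan dose limit is drawn for
#'   reference.
#' @return A ggplot object.
#' @export
plot_dose_distribution <- function(results, limits = qc_limits()) {
  ggplot2::ggplot(results$dose_per_participant,
                  ggplot2::aes(x = .data$cumulative_dose_mSv)) +
    ggplot2::geom_histogram(bins = 30, fill = "#2166ac", colour = "white") +
    ggplot2::geom_vline(xintercept = limits$effective_dose_max_mSv,
                        linetype = "dashed") +
    ggplot2::labs(x = "Cumulative effective dose (mSv)", y = "Participants",
                  title = "Cumulative radiation dose across the program") +
    ggplot2::theme_minimal()
}
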