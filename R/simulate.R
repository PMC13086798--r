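#' Configuration of the synthetic screening cohort
#'
#' Defines the synthetic population and nodule natural histories used by the
#' microsimulator. All distribution defaults are fabricated for testability
#' and exercise of the rule engine; they are not estimates of any real
#' screening cohort. Nodule growth is exponential in volume (the model
#' underlying the VDT), measurement noise is multiplicative log-normal on
#' volume, and new nodules appear at a constant per-year hazard.
#'
#' @param n_participants Cohort size.
#' @param seed Integer seed; the whole simulation is deterministic given the
#'   config.
#' @param nodule_prevalence Probability a participant has at least one
#'   nodule at baseline.
#' @param nodules_per_affected_mean Mean nodule count among affected
#'   participants (zero-truncated Poisson).
#' @param type_mix Named probabilities over [nodule_types]; must sum to 1.
#' @param diameter_median_mm,diameter_sdlog Log-normal baseline diameter
#'   distribution (median mm, log-sd).
#' @param malignant_fraction Fraction of non-calcified nodules that are
#'   malignant.
#' @param malignant_vdt_median_days,malignant_vdt_sdlog Log-normal VDT of
#'   malignant nodules (days).
#' @param benign_growth_prob Probability a benign nodule grows at all.
#' @param benign_vdt_min_days Slowest-growing benign nodules still double,
#'   but only with VDT above this floor.
#' @param benign_resolve_prob Per-scan probability a previously seen benign
#'   nodule has resolved.
#' @param endobronchial_resolve_prob Per-scan resolution probability for
#'   benign endobronchial nodules (mostly transient secretions).
#' @param volume_measurement_cv Coefficient of variation of volumetry.
#' @param new_nodule_rate_per_year Per-participant hazard of incident
#'   nodules.
#' @param dose_mean_mSv,dose_sd_mSv Per-scan effective dose distribution
#'   (normal, truncated at 0.1 mSv).
#' @param horizon_years Program horizon.
#' @return A list of class `simulation_config`.
#' @examples
#' simulation_config(n_participants = 100, seed = 1)
#' @export
simulation_config <- function(n_participants = 1000,
                              seed = 1L,
                              nodule_prevalence = 0.30,
                              nodules_per_affected_mean = 1.3,
                              type_mix = c(SOLID = 0.55, PART_SOLID = 0.10,
                                           NON_SOLID = 0.15,
                                           ENDOBRONCHIAL = 0.02,
                                           CALCIFIED = 0.18),
                              diameter_median_mm = 4,
                              diameter_sdlog = 0.5,
                              malignant_fraction = 0.05,
                              malignant_vdt_median_days = 250,
                              malignant_vdt_sdlog = 0.4,
                              benign_growth_prob = 0.05,
                              benign_vdt_min_days = 800,
                              benign_resolve_prob = 0.10,
                              endobronchial_resolve_prob = 0.70,
                              volume_measurement_cv = 0.10,
                              new_nodule_rate_per_year = 0.02,
                              dose_mean_mSv = 0.9,
                              dose_sd_mSv = 0.12,
                              horizon_years = 5) {
  cfg <- list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    nodule_prevalence = nodule_prevalence,
    nodules_per_affected_mean = nodules_per_affected_mean,
    type_mix = type_mix,
    diameter_median_mm = diameter_median_mm, diameter_sdlog = diameter_sdlog,
    malignant_fraction = malignant_fraction,
    malignant_vdt_median_days = malignant_vdt_median_days,
    malignant_vdt_sdlog = malignant_vdt_sdlog,
    benign_growth_prob = benign_growth_prob,
    benign_vdt_min_days = benign_vdt_min_days,
    benign_resolve_prob = benign_resolve_prob,
    endobronchial_resolve_prob = endobronchial_resolve_prob,
    volume_measurement_cv = volume_measurement_cv,
    new_nodule_rate_per_year = new_nodule_rate_per_year,
    dose_mean_mSv = dose_mean_mSv, dose_sd_mSv = dose_sd_mSv,
    horizon_years = as.integer(horizon_years)
  )
  if (cfg$n_participants < 0) stop("n_participants must be >= 0", call. = FALSE)
  probs <- c(cfg$nodule_prevalence, cfg$malignant_fraction,
             cfg$benign_growth_prob, cfg$benign_resolve_prob,
             cfg$endobronchial_resolve_prob, cfg$type_mix)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!setequal(names(cfg$type_mix), nodule_types)) {
    stop("type_mix must name exactly the five nodule types", call. = FALSE)
  }
  if (abs(sum(cfg$type_mix) - 1) > 1e-8) {
    stop("type_mix must sum to 1", call. = FALSE)
  }
  pos <- c(cfg$nodules_per_affected_mean, cfg$diameter_median_mm,
           cfg$diameter_sdlog, cfg$malignant_vdt_median_days,
           cfg$malignant_vdt_sdlog, cfg$benign_vdt_min_days,
           cfg$dose_mean_mSv, cfg$dose_sd_mSv)
  if (any(!is.finite(pos) | pos <= 0)) {
    stop("distribution parameters must be positive", call. = FALSE)
  }
  if (cfg$nodules_per_affected_mean < 1) {
    stop("nodules_per_affected_mean must be >= 1 (count is truncated at 1)",
         call. = FALSE)
  }
  if (cfg$volume_measurement_cv < 0 || cfg$new_nodule_rate_per_year < 0) {
    stop("volume_measurement_cv and new_nodule_rate_per_year must be >= 0",
         call. = FALSE)
  }
  if (cfg$horizon_years < 1) stop("horizon_years must be >= 1", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

# Sample per-nodule natural-history attributes for nodules of given count.
.sample_nodules <- function(n, cfg, participant_id, appearance_days) {
  type <- sample(names(cfg$type_mix), n, replace = TRUE, prob = cfg$type_mix)
  diameter <- stats::rlnorm(n, log(cfg$diameter_median_mm), cfg$diameter_sdlog)
  volume <- sphere_volume(diameter)
  benign_type <- type == "CALCIFIED"
  malignant <- !benign_type &
    stats::runif(n) < cfg$malignant_fraction
  vdt <- rep(NA_real_, n)
  vdt[malignant] <- stats::rlnorm(sum(malignant),
                                  log(cfg$malignant_vdt_median_days),
                                  cfg$malignant_vdt_sdlog)
  benign_growing <- !malignant & !benign_type &
    stats::runif(n) < cfg$benign_growth_prob
  vdt[benign_growing] <- cfg$benign_vdt_min_days *
    (1 + stats::rexp(sum(benign_growing), rate = 2))
  solid_frac <- ifelse(type == "PART_SOLID", stats::runif(n, 0.1, 0.6),
                       NA_real_)
  tibble::tibble(
    participant_id = participant_id,
    nodule_id = character(n),
    type = type,
    baseline_volume_mm3 = volume,
    solid_comp_fraction = solid_frac,
    vdt_days = vdt,
    malignant = malignant,
    appearance_day = appearance_days
  )
}

#' Generate a synthetic screening cohort
#'
#' Samples participants (all satisfying the program's inclusion criteria)
#' and their nodule natural histories: true type, true baseline volume, true
#' VDT (or not growing), malignancy flag and appearance time. Truth fields
#' are never shown to the rule engine; [run_program()] feeds it noisy
#' observations only.
#'
#' @param config A [simulation_config()].
#' @return A list of class `ldct_cohort`: `participants` tibble, `nodules`
#'   tibble, and the `config`.
#' @examples
#' cohort <- generate_cohort(simulation_config(n_participants = 50, seed = 7))
#' nrow(cohort$participants)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_participants
  horizon_days <- cfg$horizon_years * 365.25

  smoking <- sample(c("CURRENT", "FORMER"), n, replace = TRUE,
                    prob = c(0.6, 0.4))
  participants <- tibble::tibble(
    participant_id = sprintf("P%05d", seq_len(n)),
    age_years = if (n) sample(50:75, n, replace = TRUE) else integer(),
    smoking_status = smoking,
    pack_years = round(30 + stats::rexp(n, rate = 1 / 15), 1),
    years_since_quit = ifelse(smoking == "FORMER",
                              round(stats::runif(n, 0, 15), 1), NA_real_),
    flags = rep("", n)
  )

  affected <- stats::runif(n) < cfg$nodule_prevalence
  counts <- integer(n)
  counts[affected] <- 1L +
    stats::rpois(sum(affected), cfg$nodules_per_affected_mean - 1)
  incident <- stats::rpois(n, cfg$new_nodule_rate_per_year * cfg$horizon_years)

  pid <- rep(participants$participant_id, counts + incident)
  appearance <- unlist(purrr::map2(counts, incident, function(k, m) {
    c(rep(0, k), stats::runif(m, 1, horizon_days))
  }), use.names = FALSE)
  if (is.null(appearance)) appearance <- numeric()

  nodules <- .sample_nodules(length(pid), cfg, pid, appearance)
  nodules$nodule_id <- if (nrow(nodules)) {
    paste0(nodules$participant_id, "-N",
           stats::ave(seq_len(nrow(nodules)), nodules$participant_id,
                      FUN = seq_along))
  } else character()

  structure(list(participants = participants, nodules = nodules,
                 config = cfg),
            class = "ldct_cohort")
}

#' @export
print.ldct_cohort <- function(x, ...) {
  cat(sprintf("Synthetic screening cohort: %d participants, %d nodules (seed %d)\n",
              nrow(x$participants), nrow(x$nodules), x$config$seed))
  invisible(x)
}

#' Observe true nodule volumes with volumetry noise
#'
#' Applies multiplicative log-normal measurement noise with the given
#' coefficient of variation to true volumes, and derives every reported
#' diameter from the noisy volume under the sphere model (diameters are
#' never noised independently). The noise is mean-one, so volumetry is
#' unbiased.
#'
#' @param truth Tibble with `nodule_id`, `type`, `volume_mm3` (true volume),
#'   and optionally `solid_comp_fraction` for part-solid nodules.
#' @param measurement_cv Coefficient of variation; 0 observes exactly.
#' @return Observation tibble: `nodule_id`, `type`, `avg_diameter_mm`,
#'   `volume_mm3`, `solid_comp_diameter_mm`, `solid_comp_volume_mm3`.
#' @examples
#' truth <- tibble::tibble(nodule_id = "n1", type = "SOLID", volume_mm3 = 100)
#' observe_nodule(truth, measurement_cv = 0)
#' @export
observe_nodule <- function(truth, measurement_cv) {
  truth <- tibble::as_tibble(truth)
  if (any(truth$volume_mm3 <= 0)) {
    stop("true volumes must be positive", call. = FALSE)
  }
  n <- nrow(truth)
  vol <- truth$volume_mm3
  if (measurement_cv > 0 && n > 0) {
    sdlog <- sqrt(log(1 + measurement_cv^2))
    vol <- vol * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  frac <- if (!is.null(truth[["solid_comp_fraction"]])) {
    truth$solid_comp_fraction
  } else {
    rep(NA_real_, n)
  }
  comp_vol <- ifelse(truth$type == "PART_SOLID" & !is.na(frac),
                     vol * frac, NA_real_)
  tibble::tibble(
    nodule_id = truth$nodule_id,
    type = truth$type,
    avg_diameter_mm = equivalent_diameter(vol),
    volume_mm3 = vol,
    solid_comp_diameter_mm = ifelse(is.na(comp_vol), NA_real_,
                                    equivalent_diameter(comp_vol)),
    solid_comp_volume_mm3 = comp_vol
  )
}

#' Run the multi-round screening program on a synthetic cohort
#'
#' Event-driven microsimulation of the full protocol: each participant is
#' scanned on their schedule, nodules are grown exponentially to the scan
#' date, observed with volumetry noise, growth-assessed against the previous
#' scan, classified, and the next round scheduled from the classification
#' (24-month negatives move to biennial screening; short recalls trigger
#' interim follow-ups; referral ends screening for that participant).
#' Deterministic given the cohort's config.
#'
#' @param cohort An [generate_cohort()] result.
#' @param thresholds A [protocol_thresholds()].
#' @param growth_cfg A [growth_config()].
#' @return A list of class `program_results`: `events` (one row per scan),
#'   `per_round` counts, `interval_histogram`, `dose_per_participant`,
#'   `n_referred`, `detected_malignant`, `rounds_simulated`, `config`.
#' @examples
#' cohort <- generate_cohort(simulation_config(n_participants = 30, seed = 2,
#'                                             horizon_years = 3))
#' res <- run_program(cohort)
#' res$per_round
#' @export
run_program <- function(cohort, thresholds = protocol_thresholds(),
                        growth_cfg = growth_config()) {
  stopifnot(inherits(cohort, "ldct_cohort"))
  cfg <- cohort$config
  set.seed(cfg$seed + 1L)
  horizon_days <- cfg$horizon_years * 365.25
  days_per_month <- 365.25 / 12
  sdlog <- if (cfg$volume_measurement_cv > 0) {
    sqrt(log(1 + cfg$volume_measurement_cv^2))
  } else {
    0
  }

  nod_by_p <- if (nrow(cohort$nodules)) {
    split(cohort$nodules, cohort$nodules$participant_id)
  } else {
    list()
  }

  events <- vector("list", 4L * max(1L, nrow(cohort$participants)))
  k <- 0L
  n_referred <- 0L
  detected_malignant <- 0L

  for (p in cohort$participants$participant_id) {
    nods <- nod_by_p[[p]]
    has_nods <- !is.null(nods) && nrow(nods) > 0
    day <- 0
    round_type <- "BASELINE"
    round_index <- 1L
    prev_vol <- NULL    # named observed volumes on the previous scan
    prev_day <- NA_real_
    resolved <- character()
    resolving_now <- character()

    while (day <= horizon_days) {
      obs <- NULL
      if (has_nods) {
        live <- nods[nods$appearance_day <= day &
                       !nods$nodule_id %in% resolved, , drop = FALSE]
        # An interim follow-up is a targeted re-scan of the indeterminate
        # finding; the decision table has no rule for a nodule first seen
        # there, so incident nodules surface as NEW at the next scheduled
        # screening round instead.
        if (round_type == "INTERIM_FOLLOWUP" && !is.null(prev_vol)) {
          live <- live[live$nodule_id %in% names(prev_vol), , drop = FALSE]
        }
        resolving_now <- character()
        if (nrow(live) && round_type != "BASELINE" && !is.null(prev_vol)) {
          seen_before <- live$nodule_id %in% names(prev_vol)
          can_resolve <- seen_before & !live$malignant
          p_res <- ifelse(live$type == "ENDOBRONCHIAL",
                          cfg$endobronchial_resolve_prob,
                          cfg$benign_resolve_prob)
          res_draw <- stats::runif(nrow(live)) < p_res
          resolving_now <- live$nodule_id[can_resolve & res_draw]
          live <- live[!live$nodule_id %in% resolving_now, , drop = FALSE]
        }
        if (nrow(live)) {
          true_vol <- grow_nodule(live$baseline_volume_mm3, live$vdt_days,
                                  day - live$appearance_day)
          vol <- true_vol
          if (sdlog > 0) {
            vol <- vol * stats::rlnorm(length(vol), -sdlog^2 / 2, sdlog)
          }
          comp_vol <- ifelse(live$type == "PART_SOLID",
                             vol * live$solid_comp_fraction, NA_real_)
          is_new <- if (round_type == "BASELINE" || is.null(prev_vol)) {
            rep(FALSE, nrow(live))
          } else {
            !live$nodule_id %in% names(prev_vol)
          }
          gcls <- rep(NA_character_, nrow(live))
          vdt_obs <- rep(NA_real_, nrow(live))
          if (round_type != "BASELINE" && !is.null(prev_vol)) {
            for (j in seq_len(nrow(live))) {
              if (is_new[j]) next
              ga <- assess_growth(
                prior = data.frame(volume_mm3 = prev_vol[[live$nodule_id[j]]],
                                   avg_diameter_mm = NA_real_),
                current = data.frame(nodule_id = live$nodule_id[j],
                                     type = live$type[j],
                                     volume_mm3 = vol[j],
                                     avg_diameter_mm = NA_real_,
                                     is_new = FALSE, is_resolved = FALSE),
                delta_days = day - prev_day, cfg = growth_cfg
              )
              gcls[j] <- ga$growth_class
              vdt_obs[j] <- ga$vdt_days
            }
          }
          obs <- data.frame(
            nodule_id = live$nodule_id, type = live$type,
            avg_diameter_mm = equivalent_diameter(vol), volume_mm3 = vol,
            solid_comp_diameter_mm = ifelse(is.na(comp_vol), NA_real_,
                                            equivalent_diameter(comp_vol)),
            solid_comp_volume_mm3 = comp_vol,
            is_new = is_new, is_resolved = FALSE,
            growth_class = gcls, vdt_days = vdt_obs,
            prior_type = NA_character_,
            stringsAsFactors = FALSE
          )
        }
        if (length(resolving_now)) {
          res_rows <- data.frame(
            nodule_id = resolving_now,
            type = nods$type[match(resolving_now, nods$nodule_id)],
            avg_diameter_mm = NA_real_, volume_mm3 = NA_real_,
            solid_comp_diameter_mm = NA_real_,
            solid_comp_volume_mm3 = NA_real_,
            is_new = FALSE, is_resolved = TRUE,
            growth_class = "RESOLVED", vdt_days = NA_real_,
            prior_type = NA_character_,
            stringsAsFactors = FALSE
          )
          obs <- if (is.null(obs)) res_rows else rbind(obs, res_rows)
        }
      }
      if (is.null(obs)) {
        obs <- data.frame(nodule_id = character(), type = character(),
                          stringsAsFactors = FALSE)
      }

      cls <- .classify_impl(obs, round_type, thresholds)
      dose <- max(0.1, stats::rnorm(1, cfg$dose_mean_mSv, cfg$dose_sd_mSv))

      k <- k + 1L
      events[[k]] <- list(
        participant_id = p,
        scan_id = sprintf("%s-S%d", p, round_index),
        round_index = round_index, round_type = round_type,
        day = day, category = cls$category, action = cls$action,
        interval_months = cls$interval_months,
        rule_code = cls$rule_code, dose_mSv = dose
      )

      resolved <- c(resolved, resolving_now)
      prev_vol <- if (nrow(obs)) {
        stats::setNames(obs$volume_mm3[!obs$is_resolved],
                        obs$nodule_id[!obs$is_resolved])
      } else {
        stats::setNames(numeric(), character())
      }
      prev_day <- day

      if (cls$action == "REFER_NODULE_CLINIC") {
        n_referred <- n_referred + 1L
        if (has_nods && any(nods$malignant &
                              nods$nodule_id %in% names(prev_vol))) {
          detected_malignant <- detected_malignant + 1L
        }
        break
      }
      nrt <- if (cls$interval_months >= 24) "BIENNIAL_REPEAT"
             else if (cls$interval_months == 12) "ANNUAL_REPEAT"
             else "INTERIM_FOLLOWUP"
      day <- day + cls$interval_months * days_per_month
      round_type <- nrt
      round_index <- round_index + 1L
    }
  }

  events <- dplyr::bind_rows(events[seq_len(k)])
  if (nrow(events) == 0) {
    events <- tibble::tibble(
      participant_id = character(), scan_id = character(),
      round_index = integer(), round_type = character(), day = numeric(),
      category = character(), action = character(),
      interval_months = integer(), rule_code = character(),
      dose_mSv = numeric()
    )
  }

  per_round <- events |>
    dplyr::group_by(.data$round_index) |>
    dplyr::summarise(
      n_scans = dplyr::n(),
      n_negative = sum(.data$category == "NEGATIVE"),
      n_semi_positive = sum(.data$category == "SEMI_POSITIVE"),
      n_positive = sum(.data$category == "POSITIVE"),
      positivity = .data$n_positive / .data$n_scans,
      .groups = "drop"
    )
  interval_histogram <- events |>
    dplyr::filter(!is.na(.data$interval_months)) |>
    dplyr::count(.data$interval_months, name = "n_scans")
  dose_per_participant <- events |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(cumulative_dose_mSv = sum(.data$dose_mSv),
                     n_scans = dplyr::n(), .groups = "drop")

  structure(
    list(events = events, per_round = per_round,
         interval_histogram = interval_histogram,
         dose_per_participant = dose_per_participant,
         n_referred = n_referred, detected_malignant = detected_malignant,
         rounds_simulated = if (nrow(events)) max(events$round_index) else 0L,
         config = cfg),
    class = "program_results"
  )
}

#' Summarise program results
#'
#' Recomputes the per-round category fractions from the raw event counts and
#' asserts internal consistency (category counts per round sum to scans;
#' fractions in \[0, 1\]).
#'
#' @param results A [run_program()] result.
#' @return Tibble with one row per round: scans, counts per category, and
#'   `positivity`.
#' @examples
#' cohort <- generate_cohort(simulation_config(n_participants = 20, seed = 3,
#'                                             horizon_years = 2))
#' summarize_results(run_program(cohort))
#' @export
summarize_results <- function(results) {
  stopifnot(inherits(results, "program_results"))
  tab <- results$per_round
  if (nrow(tab)) {
    stopifnot(all(tab$n_negative + tab$n_semi_positive + tab$n_positive ==
                    tab$n_scans))
    stopifnot(all(tab$positivity >= 0 & tab$positivity <= 1))
  }
  tab
}

#' @export
print.program_results <- function(x, ...) {
  cat(sprintf(
    "Screening program simulation: %d scans over %d rounds, %d referrals (%d with a malignant nodule)\n",
    nrow(x$events), x$rounds_simulated, x$n_referred, x$detected_malignant))
  print(x$per_round, n = Inf)
  invisible(x)
}
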