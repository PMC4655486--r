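# Parameter sensitivity at the projection horizon: paired
# common-random-number ensembles at baseline and perturbed parameter
# values. Pairing the replicate seeds removes most of the Monte-Carlo
# variance of the difference.

.sensitivity_targets <- c("food_availability", "poisoning_mortality",
                          "natural_mortality")

#' Effect of a small parameter perturbation at the projection horizon
#'
#' Runs two projection ensembles from the same hindcast states with
#' identical replicate seeds: one at baseline, one with the target
#' parameter perturbed. The effect is the paired difference in the mean
#' number of adult females (breeding + floaters by default) at the horizon
#' year, with its Monte-Carlo standard error from the per-replicate
#' differences.
#'
#' `"food_availability"` scales the projection rabbit biomass;
#' `"poisoning_mortality"` scales the per-exit poisoning hazard;
#' `"natural_mortality"` scales both natural rates (breeder and
#' non-breeder). In `"relative"` mode the parameter is multiplied by
#' `1 + delta`; in `"absolute"` mode `delta` is added to the rate (and to
#' the residual food fraction).
#'
#' @param params A calibrated `ev_params` object.
#' @param hindcast An `ev_ensemble` from [run_hindcast()] with kept states.
#' @param target_param One of `"food_availability"`,
#'   `"poisoning_mortality"`, `"natural_mortality"`.
#' @param delta Perturbation size (default 0.01, i.e. +1%).
#' @param mode `"relative"` (default) or `"absolute"`.
#' @param n_years Projection horizon in years (default 35).
#' @param seed Root seed shared by the paired ensembles.
#' @param griffon_scenario `"stable"` or `"doubling"`.
#' @param segment Which females to count at the horizon:
#'   `"adult_females"` (breeding + floaters, default) or
#'   `"breeding_females"`.
#' @param baseline Optional precomputed baseline `ev_ensemble` run with the
#'   same `seed`, `hindcast` and settings (reused across the three target
#'   parameters).
#' @return A one-row tibble: `parameter`, `delta`, `mode`, `effect`, `se`,
#'   `baseline_mean`, `perturbed_mean`, `horizon_year`, `segment`,
#'   `n_reps`, `seed`.
#' @export
perturbation_effect <- function(params, hindcast,
                                target_param = .sensitivity_targets,
                                delta = 0.01, mode = c("relative",
                                                       "absolute"),
                                n_years = 35, seed = 1,
                                griffon_scenario = "stable",
                                segment = c("adult_females",
                                            "breeding_females"),
                                baseline = NULL) {
  .require_calibrated(params)
  target_param <- rlang::arg_match(target_param)
  mode <- rlang::arg_match(mode)
  segment <- rlang::arg_match(segment)

  pert <- params
  food_mult <- 1
  if (target_param == "food_availability") {
    food_mult <- if (mode == "relative") 1 + delta else
      (params$rhd_survival_fraction + delta) / params$rhd_survival_fraction
    if (params$rhd_survival_fraction * food_mult < 0 ||
        params$rhd_survival_fraction * food_mult > 1) {
      rlang::abort("perturbed food fraction escapes [0, 1]",
                   class = "neophron_config_error")
    }
  } else if (target_param == "poisoning_mortality") {
    p <- params$p_poison_per_exit
    p_new <- if (mode == "relative") p * (1 + delta) else p + delta
    if (p_new < 0 || p_new > 1) {
      rlang::abort("perturbed poisoning hazard escapes [0, 1]",
                   class = "neophron_config_error")
    }
    pert$p_poison_per_exit <- p_new
  } else {
    scale_or_add <- function(v) if (mode == "relative") v * (1 + delta) else
      v + delta
    m1 <- scale_or_add(params$m_natural_annual)
    m2 <- scale_or_add(params$m_nonbreeder)
    if (m1 < 0 || m1 > 1 || m2 < 0 || m2 > 1) {
      rlang::abort("perturbed natural mortality escapes [0, 1]",
                   class = "neophron_config_error")
    }
    pert$m_natural_annual <- m1
    pert$m_nonbreeder <- m2
  }

  if (is.null(baseline)) {
    baseline <- run_projection(params, hindcast, n_years = n_years,
                               seed = seed,
                               griffon_scenario = griffon_scenario)
  }
  perturbed <- run_projection(pert, hindcast, n_years = n_years,
                              seed = seed,
                              griffon_scenario = griffon_scenario,
                              food_multiplier = food_mult)

  var <- if (segment == "adult_females") "females_adult" else "pairs"
  horizon <- max(baseline$records$year)
  pull_fin <- function(ens) {
    ens$records |>
      dplyr::filter(.data$year == horizon) |>
      dplyr::arrange(.data$replicate) |>
      dplyr::pull(dplyr::all_of(var))
  }
  b <- pull_fin(baseline)
  p <- pull_fin(perturbed)
  d <- p - b
  tibble::tibble(
    parameter = target_param,
    delta = delta,
    mode = mode,
    effect = mean(d),
    se = stats::sd(d) / sqrt(length(d)),
    baseline_mean = mean(b),
    perturbed_mean = mean(p),
    horizon_year = horizon,
    segment = segment,
    n_reps = length(d),
    seed = seed
  )
}

#' Sensitivity table for the three headline parameters
#'
#' Convenience wrapper running [perturbation_effect()] for food
#' availability, poisoning mortality and natural mortality with a shared
#' baseline ensemble.
#'
#' @inheritParams perturbation_effect
#' @return A three-row tibble (one per parameter).
#' @export
sensitivity_analysis <- function(params, hindcast, delta = 0.01,
                                 mode = "relative", n_years = 35, seed = 1,
                                 segment = "adult_females") {
  baseline <- run_projection(params, hindcast, n_years = n_years,
                             seed = seed)
  purrr::map_dfr(.sensitivity_targets, function(tp) {
    perturbation_effect(params, hindcast, target_param = tp, delta = delta,
                        mode = mode, n_years = n_years, seed = seed,
                        segment = segment, baseline = baseline)
  })
}
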