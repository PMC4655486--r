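# Exogenous drivers: monthly rabbit-carcass biomass (pre-crash plateau,
# >90% crash at the RHD year, scenario-controlled recovery) and the griffon
# abundance index (zero before 1990, exponential growth in pairs to 2013,
# then stable or linearly doubling). Only the product
# kappa_interception x griffon_index enters the model, so the absolute scale
# of the index is immaterial (a tested metamorphic invariance).

#' Griffon breeding pairs in a given year
#'
#' Zero before the first established pair; exponential interpolation in pair
#' numbers from 1 pair at `griffon_first_pair_year` to `griffon_pairs_2013`
#' at the hindcast end (the regional growth has been exponential); for
#' projection years either constant at the 2014 level (`"stable"`) or growing
#' linearly to twice that level 35 years after the projection start
#' (`"doubling"`).
#'
#' @param year Integer vector of calendar years.
#' @param params An `ev_params` object.
#' @param griffon_scenario `"stable"` or `"doubling"`.
#' @return Numeric vector of pair counts.
#' @export
griffon_pairs <- function(year, params, griffon_scenario = "stable") {
  griffon_scenario <- rlang::arg_match(griffon_scenario,
                                       c("stable", "doubling"))
  y0 <- params$griffon_first_pair_year
  y1 <- params$hindcast_end
  p1 <- params$griffon_pairs_2013
  proj0 <- params$hindcast_end + 1
  vapply(year, function(y) {
    if (y < y0) return(0)
    if (y <= y1) return(p1^((y - y0) / (y1 - y0)))
    if (griffon_scenario == "stable") return(p1)
    p1 * (1 + (y - proj0) / 35)
  }, numeric(1))
}

#' Griffon abundance index
#'
#' Total griffons linked to the breeding population: pairs x 2 breeders,
#' plus a non-breeding fraction of `griffon_nonbreeder_ratio` birds per
#' breeder. The index is what the carcass-interception probability scales
#' with.
#'
#' @inheritParams griffon_pairs
#' @return Numeric vector.
#' @export
griffon_index <- function(year, params, griffon_scenario = "stable") {
  griffon_pairs(year, params, griffon_scenario) * 2 *
    (1 + params$griffon_nonbreeder_ratio)
}

#' Monthly rabbit-carcass biomass
#'
#' Constant at the calibrated pre-crash level `R0 =
#' rabbit_biomass_monthly_kg` before `rhd_year`; `R0 x
#' rhd_survival_fraction` for the rest of the hindcast (the >90% crash); and
#' `R0 x max(rhd_survival_fraction, food_factor)` in projection years, where
#' `food_factor` in [0, 1] is the scenario-controlled recovery expressed as a
#' fraction of the pre-crash rabbit population.
#'
#' @param year Integer vector of calendar years.
#' @param params A calibrated `ev_params` object (needs
#'   `rabbit_biomass_monthly_kg`).
#' @param food_factor Recovery fraction in [0, 1] applied to projection
#'   years only; `NULL` means no recovery (the residual level persists).
#' @return Numeric vector of kg per month.
#' @export
rabbit_biomass <- function(year, params, food_factor = NULL) {
  r0 <- params$rabbit_biomass_monthly_kg
  if (is.na(r0)) {
    rlang::abort("rabbit_biomass_monthly_kg is uncalibrated",
                 class = "neophron_uncalibrated_error")
  }
  if (!is.null(food_factor)) {
    if (food_factor < 0 || food_factor > 1) {
      rlang::abort("food_factor must lie in [0, 1]",
                   class = "neophron_config_error")
    }
  }
  resid <- params$rhd_survival_fraction
  vapply(year, function(y) {
    if (y < params$rhd_year) return(r0)
    if (y <= params$hindcast_end || is.null(food_factor)) return(r0 * resid)
    r0 * max(resid, food_factor)
  }, numeric(1))
}

#' Build the exogenous driver series
#'
#' One row per simulated month: the rabbit-carcass biomass deposited that
#' month (constant within a calendar year) and the griffon abundance index.
#'
#' @param params A calibrated `ev_params` object.
#' @param years Integer vector of calendar years to cover.
#' @param food_factor Projection-year rabbit recovery fraction (see
#'   [rabbit_biomass()]).
#' @param griffon_scenario `"stable"` or `"doubling"`.
#' @param food_multiplier Multiplier applied to the rabbit biomass of
#'   projection years (used by the sensitivity analysis; default 1).
#' @return A tibble with columns `year`, `month`, `rabbit_kg`,
#'   `griffon_index`, `food_factor`, `griffon_scenario`.
#' @examples
#' \dontrun{
#' drv <- driver_series(calibrated, 1980:2013)
#' }
#' @export
driver_series <- function(params, years, food_factor = NULL,
                          griffon_scenario = "stable",
                          food_multiplier = 1) {
  griffon_scenario <- rlang::arg_match(griffon_scenario,
                                       c("stable", "doubling"))
  rk <- rabbit_biomass(years, params, food_factor)
  proj <- years > params$hindcast_end
  rk[proj] <- rk[proj] * food_multiplier
  gi <- griffon_index(years, params, griffon_scenario)
  tidyr::expand_grid(
    year = years,
    month = seq_len(params$months_in_area)
  ) |>
    dplyr::mutate(
      rabbit_kg = rep(rk, each = params$months_in_area),
      griffon_index = rep(gi, each = params$months_in_area),
      food_factor = if (is.null(food_factor)) NA_real_ else food_factor,
      griffon_scenario = griffon_scenario
    )
}
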