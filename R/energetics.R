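# Per-capita daily food-mass requirements. Base intakes are free constants
# of field-metabolic-rate magnitude for a ~2 kg (Egyptian vulture) and ~8 kg
# (griffon) scavenger; successful breeders eat up to 30% more during the
# chick-rearing months.

#' Daily per-capita food intake
#'
#' @param species `"egyptian"` or `"griffon"`.
#' @param status `"successful_breeder_rearing"` (a territorial bird feeding a
#'   chick during the rearing months) or `"other"` (failed breeders and
#'   non-territorial birds).
#' @param params An `ev_params` object.
#' @return Mass in kg/day.
#' @examples
#' daily_intake("egyptian", "successful_breeder_rearing", ev_params())
#' @export
daily_intake <- function(species, status, params) {
  species <- rlang::arg_match(species, c("egyptian", "griffon"))
  status <- rlang::arg_match(status, c("successful_breeder_rearing", "other"))
  base <- switch(species,
    egyptian = params$ev_daily_intake_kg,
    griffon = params$gv_daily_intake_kg
  )
  if (status == "successful_breeder_rearing") {
    base <- base * (1 + params$chick_rearing_increment)
  }
  base
}

#' Annual food demand of a population
#'
#' Sums [daily_intake()] over individuals and the residence days, applying
#' the chick-rearing increment only during the configured rearing months.
#' Linear in both the counts and the daily intakes.
#'
#' @param counts A data frame with columns `species`, `status`, `n`.
#' @param params An `ev_params` object.
#' @return Total mass in kg per year.
#' @examples
#' annual_population_demand(
#'   tibble::tibble(species = "egyptian", status = "other", n = 1),
#'   ev_params(ev_daily_intake_kg = 0.2)
#' ) # 0.2 * 180 = 36
#' @export
annual_population_demand <- function(counts, params) {
  stopifnot(all(c("species", "status", "n") %in% names(counts)))
  if (any(counts$n < 0)) {
    rlang::abort("counts must be non-negative", class = "neophron_config_error")
  }
  days <- .days_in_area(params)
  rearing_days <- (params$chick_rearing_last_month -
                     params$chick_rearing_first_month + 1) *
    params$days_per_month
  per_head <- purrr::map2_dbl(counts$species, counts$status, function(sp, stt) {
    sp <- rlang::arg_match0(sp, c("egyptian", "griffon"))
    stt <- rlang::arg_match0(stt, c("successful_breeder_rearing", "other"))
    base <- if (sp == "egyptian") params$ev_daily_intake_kg else
      params$gv_daily_intake_kg
    base * days +
      (stt == "successful_breeder_rearing") *
        base * params$chick_rearing_increment * rearing_days
  })
  sum(per_head * counts$n)
}
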