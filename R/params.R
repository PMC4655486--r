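# Model parameters: every vital rate, foraging constant and calibrated
# coefficient, with a provenance flag per field ("paper" = stated in the field
# study, "design" = package design choice, "calibrated" = solved by
# calibrate_params()).

.param_defaults <- function() {
  list(
    # calendar
    start_year              = 1980,
    hindcast_end            = 2013,
    rhd_year                = 1990,
    months_in_area          = 6,
    days_per_month          = 30,
    # initial population & territories (females; one breeder = one pair)
    n_pairs_init            = 50,
    n_nonbreeders_init      = 50,
    nonbreeder_age_min      = 1,
    nonbreeder_age_max      = 5,
    age_first_breeding      = 8,
    territory_cap           = 50,
    # vital-rate targets
    m_breeder_pre           = 0.02,
    m_nonbreeder            = 0.10,
    m_breeder_post_target   = 0.17,
    productivity_pre        = 0.4,
    productivity_post_target = 0.2,
    exit_fraction_pre       = 0.20,
    rabbit_diet_fraction_pre = 0.80,
    rhd_survival_fraction   = 0.10,
    # energetics
    ev_daily_intake_kg      = 0.20,
    gv_daily_intake_kg      = 0.55,
    rabbit_carcass_mass_kg  = 1.0,
    chick_rearing_increment = 0.30,
    chick_rearing_first_month = 3,
    chick_rearing_last_month  = 6,
    # griffon trajectory
    griffon_first_pair_year = 1990,
    griffon_pairs_2013      = 85,
    griffon_nonbreeder_ratio = 1.0,
    griffon_breeding_fraction = 0.25,
    griffon_productivity    = 0.25,
    # competition calibration target (2013 griffon share of consumed carrion)
    gv_share_target         = 0.27,
    # scenario dials
    hazard_multiplier       = 1.0,
    # pre-era poisoning hazard: poisoned baits essentially absent before the
    # crash year
    p_poison_pre            = 0.0,
    # calibrated fields (NA until calibrate_params() has run)
    p_exit_base             = NA_real_,
    rabbit_biomass_monthly_kg = NA_real_,
    m_natural_annual        = NA_real_,
    p_poison_per_exit       = NA_real_,
    repro_intercept         = NA_real_,
    repro_slope             = NA_real_,
    kappa_interception      = NA_real_,
    post_exit_fraction      = NA_real_
  )
}

.param_provenance <- c(
  start_year = "design", hindcast_end = "design", rhd_year = "paper",
  months_in_area = "paper", days_per_month = "paper",
  n_pairs_init = "paper", n_nonbreeders_init = "paper",
  nonbreeder_age_min = "paper", nonbreeder_age_max = "paper",
  age_first_breeding = "paper", territory_cap = "paper",
  m_breeder_pre = "paper", m_nonbreeder = "paper",
  m_breeder_post_target = "paper",
  productivity_pre = "paper", productivity_post_target = "paper",
  exit_fraction_pre = "paper", rabbit_diet_fraction_pre = "paper",
  rhd_survival_fraction = "paper",
  ev_daily_intake_kg = "design", gv_daily_intake_kg = "design",
  rabbit_carcass_mass_kg = "design",
  chick_rearing_increment = "paper",
  chick_rearing_first_month = "design", chick_rearing_last_month = "design",
  griffon_first_pair_year = "paper", griffon_pairs_2013 = "paper",
  griffon_nonbreeder_ratio = "paper", griffon_breeding_fraction = "paper",
  griffon_productivity = "paper", gv_share_target = "paper",
  hazard_multiplier = "design", p_poison_pre = "design",
  p_exit_base = "calibrated", rabbit_biomass_monthly_kg = "calibrated",
  m_natural_annual = "calibrated", p_poison_per_exit = "calibrated",
  repro_intercept = "calibrated", repro_slope = "calibrated",
  kappa_interception = "calibrated", post_exit_fraction = "calibrated"
)

.rate_fields <- c(
  "m_breeder_pre", "m_nonbreeder", "m_breeder_post_target",
  "exit_fraction_pre", "rabbit_diet_fraction_pre", "rhd_survival_fraction",
  "griffon_breeding_fraction", "gv_share_target", "p_poison_pre"
)
.count_fields <- c(
  "n_pairs_init", "n_nonbreeders_init", "territory_cap",
  "age_first_breeding", "months_in_area", "days_per_month",
  "griffon_pairs_2013"
)

#' Model parameter set
#'
#' Construct the full parameter set of the vulture population model. All
#' defaults are the study conditions: a 1980 population of 50 breeding pairs
#' (one simulated female per pair) plus 50 non-breeding females aged 1-5;
#' pre-crash breeder/non-breeder mortality 2%/10% per year and productivity
#' 0.4 fledglings per breeding female; a rabbit-hemorrhagic-disease crash in
#' 1990 leaving 10% of carcass biomass; post-crash breeder mortality rising to
#' 17% per year and productivity falling to 0.2; and a griffon vulture
#' population growing from its first pair in 1990 to 85 pairs in 2013.
#'
#' Fields flagged `"calibrated"` (see [param_provenance()]) are `NA` until
#' [calibrate_params()] resolves them; the simulator refuses to run with an
#' uncalibrated set.
#'
#' @param ... Named overrides of any default field. Unknown names are an
#'   error.
#' @return An object of class `ev_params`: a named list of parameter values.
#' @examples
#' p <- ev_params()
#' p$territory_cap
#' ev_params(rhd_survival_fraction = 0.2)$rhd_survival_fraction
#' @export
ev_params <- function(...) {
  defaults <- .param_defaults()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      rlang::abort("all arguments to ev_params() must be named")
    }
    unknown <- setdiff(names(dots), names(defaults))
    if (length(unknown)) {
      rlang::abort(paste0(
        "unknown parameter field(s): ", paste(unknown, collapse = ", ")
      ), class = "neophron_config_error")
    }
    defaults[names(dots)] <- dots
  }
  p <- structure(defaults, class = "ev_params")
  validate_params(p)
  p
}

#' @rdname ev_params
#' @param params An `ev_params` object.
#' @return `validate_params()` returns `params` invisibly, erroring on an
#'   invalid set.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "ev_params"))
  for (f in .rate_fields) {
    v <- params[[f]]
    if (!is.na(v) && (v < 0 || v > 1)) {
      rlang::abort(paste0(f, " must lie in [0, 1], got ", v),
                   class = "neophron_config_error")
    }
  }
  for (f in .count_fields) {
    v <- params[[f]]
    if (!is.na(v) && (v < 0 || v != round(v))) {
      rlang::abort(paste0(f, " must be a non-negative integer, got ", v),
                   class = "neophron_config_error")
    }
  }
  for (f in c("ev_daily_intake_kg", "gv_daily_intake_kg",
              "rabbit_carcass_mass_kg", "chick_rearing_increment",
              "hazard_multiplier")) {
    v <- params[[f]]
    if (!is.na(v) && v < 0) {
      rlang::abort(paste0(f, " must be non-negative"),
                   class = "neophron_config_error")
    }
  }
  if (params$n_pairs_init > params$territory_cap) {
    rlang::abort("n_pairs_init exceeds territory_cap",
                 class = "neophron_config_error")
  }
  if (params$chick_rearing_first_month > params$chick_rearing_last_month ||
      params$chick_rearing_last_month > params$months_in_area) {
    rlang::abort("chick-rearing window must lie within the residence months",
                 class = "neophron_config_error")
  }
  if (params$hindcast_end <= params$rhd_year) {
    rlang::abort("hindcast_end must come after rhd_year",
                 class = "neophron_config_error")
  }
  invisible(params)
}

#' Provenance of each parameter field
#'
#' @return A tibble with one row per parameter field: its name, current
#'   value, and provenance flag (`paper`, `design`, or `calibrated`).
#' @param params An `ev_params` object.
#' @examples
#' dplyr::count(param_provenance(ev_params()), provenance)
#' @export
param_provenance <- function(params = ev_params()) {
  stopifnot(inherits(params, "ev_params"))
  tibble::tibble(
    field = names(.param_provenance),
    value = unlist(params[names(.param_provenance)], use.names = FALSE),
    provenance = unname(.param_provenance)
  )
}

#' Has a parameter set been calibrated?
#'
#' @param params An `ev_params` object.
#' @return `TRUE` when every calibrated field has been resolved.
#' @export
is_calibrated <- function(params) {
  cal <- names(.param_provenance)[.param_provenance == "calibrated"]
  !any(vapply(params[cal], is.na, logical(1)))
}

.require_calibrated <- function(params) {
  if (!is_calibrated(params)) {
    rlang::abort(
      "parameter set is not calibrated; run calibrate_params() first",
      class = "neophron_uncalibrated_error"
    )
  }
  invisible(params)
}

#' Residence days per simulated year
#' @noRd
.days_in_area <- function(params) params$months_in_area * params$days_per_month

#' @export
print.ev_params <- function(x, ...) {
  cal <- is_calibrated(x)
  cat("<ev_params> vulture population model parameters\n")
  cat("  calibrated:", if (cal) "yes" else "no (run calibrate_params())", "\n")
  tab <- param_provenance(x)
  for (prov in c("paper", "design", "calibrated")) {
    sub <- tab[tab$provenance == prov, ]
    cat("  --", prov, "--\n")
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("  %-26s %s\n", sub$field[i], format(sub$value[i])))
    }
  }
  invisible(x)
}

#' Read and write parameter files
#'
#' Parameters are serialized to a flat declarative YAML file (`key: value`
#' per line). Unknown keys in a file are rejected, so a stale or misspelled
#' configuration fails loudly rather than silently using a default.
#'
#' @param path File path.
#' @param params An `ev_params` object.
#' @return `read_params()` returns an `ev_params` object; `write_params()`
#'   returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yml")
#' write_params(ev_params(), f)
#' read_params(f)$territory_cap
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) rlang::abort("config file must be a flat key: value map",
                                  class = "neophron_config_error")
  raw <- lapply(raw, function(v) {
    if (is.null(v) || (length(v) == 1 && is.na(v))) NA_real_ else v
  })
  do.call(ev_params, raw)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "ev_params"))
  yaml::write_yaml(unclass(params), path, precision = 15)
  invisible(path)
}
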