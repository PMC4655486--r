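# Simulated population state. The simulator tracks FEMALES: one breeder
# equals one occupied territory (a pair). Reported "adults" double the
# breeding females under a 1:1 sex ratio; immature and floater counts are
# female counts. State is a plain list of parallel vectors for speed in the
# daily loop.

.ST_IMMATURE <- 1L
.ST_FLOATER  <- 2L
.ST_BREEDER  <- 3L

.new_state <- function(year, age, status, bred) {
  list(
    year = as.integer(year),
    age = as.integer(age),
    status = as.integer(status),
    bred = as.logical(bred),
    exits_year = integer(length(age)),
    fed_today = rep(TRUE, length(age)),
    consumed_ev = 0, consumed_gv = 0, deposited = 0,
    births = 0L, deaths_nat_breeder = 0L, deaths_nat_nonbreeder = 0L,
    deaths_poison = 0L
  )
}

.remove_birds <- function(state, idx) {
  keep <- setdiff(seq_along(state$age), idx)
  state$age <- state$age[keep]
  state$status <- state$status[keep]
  state$bred <- state$bred[keep]
  state$exits_year <- state$exits_year[keep]
  state$fed_today <- state$fed_today[keep]
  state
}

#' Initialize the simulated population
#'
#' Builds the starting state: `n_pairs_init` breeding females (each holding
#' one territory) and `n_nonbreeders_init` immature females with ages drawn
#' uniformly on `nonbreeder_age_min:nonbreeder_age_max`. Uses the current RNG
#' stream, so a fixed seed reproduces the age multiset exactly.
#'
#' @param params An `ev_params` object.
#' @param year Calendar year of the initial state (default `start_year`).
#' @return A population state (plain list, class `ev_state`).
#' @examples
#' set.seed(1)
#' st <- init_population(ev_params())
#' census(st)
#' @export
init_population <- function(params, year = params$start_year) {
  validate_params(params)
  nb <- params$n_pairs_init
  ni <- params$n_nonbreeders_init
  ages <- c(
    rep(params$age_first_breeding, nb),
    if (ni > 0) {
      sample(seq(params$nonbreeder_age_min, params$nonbreeder_age_max),
             ni, replace = TRUE)
    }
  )
  status <- c(rep(.ST_BREEDER, nb), rep(.ST_IMMATURE, ni))
  st <- .new_state(year, ages, status, rep(FALSE, nb + ni))
  class(st) <- "ev_state"
  st
}

#' Census a population state
#'
#' Counts the state by class. `pairs` is the number of occupied territories
#' (= breeding females); `adults` doubles that to individuals under a 1:1 sex
#' ratio; `adults_with_floaters` additionally doubles the floater females;
#' `females_adult` is breeding plus floater females (the segment used by the
#' sensitivity analysis); `immatures` and `floaters` are female counts.
#'
#' @param state An `ev_state` population state.
#' @return A one-row tibble.
#' @export
census <- function(state) {
  b <- sum(state$status == .ST_BREEDER)
  f <- sum(state$status == .ST_FLOATER)
  i <- sum(state$status == .ST_IMMATURE)
  tibble::tibble(
    year = state$year,
    pairs = b,
    adults = 2L * b,
    adults_with_floaters = 2L * (b + f),
    females_adult = b + f,
    floaters = f,
    immatures = i,
    n_females = b + f + i,
    rabbit_kg_ev = state$consumed_ev,
    rabbit_kg_gv = state$consumed_gv,
    rabbit_kg_deposited = state$deposited
  )
}

#' @export
print.ev_state <- function(x, ...) {
  cat("<ev_state> year", x$year, "--",
      sum(x$status == .ST_BREEDER), "breeders,",
      sum(x$status == .ST_FLOATER), "floaters,",
      sum(x$status == .ST_IMMATURE), "immatures\n")
  invisible(x)
}
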