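# The core simulator: five synchronized process modules executed in a
# daily/monthly/annual loop over the 6-month residence period.
#   module 1  monthly natural mortality
#   module 2  daily feeding on the rabbit-carcass pool, with griffon
#             carcass interception
#   module 3  daily accounting of park exits (foraging outside the park)
#   module 4  monthly poisoning mortality driven by the month's exit-days
#   module 5  annual exit-dependent reproduction, then aging and territory
#             recruitment
# One simulated year = [module1, (module2, module3) x 30] x 6 with module 4
# closing each month, then module 5.

# ---- per-day feeding primitive -------------------------------------------

# Allocate one day's carcass pool. Carcasses are discrete units of
# `unit_kg`; each unit is intercepted by griffons with probability `p_g`
# (a griffon that finds a carcass consumes it completely). Remaining mass is
# allocated to the vultures in uniformly random order up to each bird's
# daily demand; a bird whose allocation falls short is unfed.
# Exact conservation: ev_kg + gv_kg + leftover_kg == day_kg.
.feed_allocate <- function(demand, day_kg, p_g, unit_kg) {
  n <- length(demand)
  if (day_kg <= 0) {
    return(list(fed = rep(FALSE, n), ev_kg = 0, gv_kg = 0, leftover_kg = 0))
  }
  gv <- 0
  if (p_g > 0) {
    units <- floor(day_kg / unit_kg + 1e-9)
    frac <- day_kg - units * unit_kg
    gv <- stats::rbinom(1L, units, p_g) * unit_kg
    if (frac > 1e-12 && stats::runif(1) < p_g) gv <- gv + frac
  }
  avail <- max(0, day_kg - gv)
  total <- sum(demand)
  if (avail >= total) {
    fed <- rep(TRUE, n)
    ev <- total
  } else {
    ord <- sample.int(n)
    cum <- cumsum(demand[ord])
    k <- findInterval(avail + 1e-12, cum)
    fed <- logical(n)
    if (k > 0) fed[ord[seq_len(k)]] <- TRUE
    ev <- avail
  }
  list(fed = fed, ev_kg = ev, gv_kg = gv, leftover_kg = day_kg - gv - ev)
}

.daily_demand <- function(state, month, params) {
  d <- rep(params$ev_daily_intake_kg, length(state$age))
  if (month >= params$chick_rearing_first_month &&
      month <= params$chick_rearing_last_month) {
    rearing <- state$status == .ST_BREEDER & state$bred
    d[rearing] <- d[rearing] * (1 + params$chick_rearing_increment)
  }
  d
}

.interception_prob <- function(griffon_index, params) {
  min(1, params$kappa_interception * griffon_index)
}

# ---- module 1: monthly natural mortality ---------------------------------

#' Monthly natural mortality (module 1)
#'
#' Each bird survives the month with probability `1 - h` where
#' `h = 1 - (1 - m)^(1/months_in_area)` and `m` is the annual natural rate:
#' `m_natural_annual` for breeders, `m_nonbreeder` for immatures and
#' floaters. Removals are independent draws.
#'
#' @param state An `ev_state`.
#' @param params A calibrated `ev_params` object.
#' @return The updated state.
#' @export
step_monthly_mortality <- function(state, params) {
  n <- length(state$age)
  if (n == 0L) return(state)
  is_b <- state$status == .ST_BREEDER
  m_ann <- ifelse(is_b, params$m_natural_annual, params$m_nonbreeder)
  h <- 1 - (1 - m_ann)^(1 / params$months_in_area)
  die <- stats::runif(n) < h
  if (any(die)) {
    state$deaths_nat_breeder <- state$deaths_nat_breeder +
      sum(die & is_b)
    state$deaths_nat_nonbreeder <- state$deaths_nat_nonbreeder +
      sum(die & !is_b)
    state <- .remove_birds(state, which(die))
  }
  state
}

# ---- module 2: daily feeding ---------------------------------------------

#' One day of feeding (module 2)
#'
#' Splits the day's carcass pool between griffon interception and the
#' simulated vultures, flags each bird fed/unfed in `state$fed_today`, and
#' accumulates the species consumption totals.
#'
#' @param state An `ev_state`.
#' @param day_pool_kg Carcass biomass deposited this day (kg, >= 0).
#' @param griffon_index Griffon abundance index for the year.
#' @param params A calibrated `ev_params` object.
#' @param month Month of the residence period (controls the chick-rearing
#'   increment).
#' @return A list: `state` (with `fed_today` set), `ev_take_kg`,
#'   `gv_take_kg`, `leftover_kg`.
#' @export
daily_feeding <- function(state, day_pool_kg, griffon_index, params,
                          month = 1L) {
  if (day_pool_kg < 0) {
    rlang::abort("day_pool_kg must be non-negative",
                 class = "neophron_config_error")
  }
  demand <- .daily_demand(state, month, params)
  al <- .feed_allocate(demand, day_pool_kg,
                       .interception_prob(griffon_index, params),
                       params$rabbit_carcass_mass_kg)
  state$fed_today <- al$fed
  state$consumed_ev <- state$consumed_ev + al$ev_kg
  state$consumed_gv <- state$consumed_gv + al$gv_kg
  list(state = state, ev_take_kg = al$ev_kg, gv_take_kg = al$gv_kg,
       leftover_kg = al$leftover_kg)
}

# ---- module 3: daily exit accounting -------------------------------------

#' One day of park-exit accounting (module 3)
#'
#' Every unfed breeder leaves the park to forage outside (one exit-day);
#' fed breeders leave with the baseline probability `p_exit_base`. Exits of
#' non-breeders feed nothing downstream (no poisoning applies to them and
#' they do not reproduce), so they are not tracked.
#'
#' @param state An `ev_state` whose `fed_today` reflects today's feeding.
#' @param params A calibrated `ev_params` object.
#' @return The updated state (`exits_year` incremented).
#' @export
step_daily_exit <- function(state, params) {
  b <- which(state$status == .ST_BREEDER)
  if (!length(b)) return(state)
  fed <- state$fed_today[b]
  ex <- !fed
  if (any(fed) && params$p_exit_base > 0) {
    ex[fed] <- stats::runif(sum(fed)) < params$p_exit_base
  }
  state$exits_year[b] <- state$exits_year[b] + ex
  state
}

# ---- module 4: monthly poisoning mortality -------------------------------

#' Monthly poisoning mortality (module 4)
#'
#' Each breeder dies with probability `1 - (1 - p)^e` where `e` is its
#' exit-days this month and `p` the per-exit-day poisoning hazard:
#' `p_poison_pre` before the crash year, `p_poison_per_exit x
#' hazard_multiplier` afterwards.
#'
#' @param state An `ev_state`.
#' @param exits_month Integer vector of this month's exit-days, one per
#'   breeder (in breeder order within the state).
#' @param params A calibrated `ev_params` object.
#' @return The updated state.
#' @export
step_monthly_poisoning <- function(state, exits_month, params) {
  b <- which(state$status == .ST_BREEDER)
  if (!length(b)) return(state)
  stopifnot(length(exits_month) == length(b))
  p <- if (state$year < params$rhd_year) params$p_poison_pre else
    params$p_poison_per_exit * params$hazard_multiplier
  p <- min(1, p)
  if (p <= 0) return(state)
  pr <- 1 - (1 - p)^exits_month
  die <- stats::runif(length(b)) < pr
  if (any(die)) {
    state$deaths_poison <- state$deaths_poison + sum(die)
    state <- .remove_birds(state, b[die])
  }
  state
}

# ---- module 5: annual reproduction ---------------------------------------

#' Annual reproduction, aging and recruitment (module 5)
#'
#' Each surviving breeder fledges one chick with probability
#' `clamp(repro_intercept - repro_slope x exits/days, 0, 1)` where `exits`
#' is its accumulated exit-days for the year. Fledglings enter as age-1
#' immatures at the year boundary. All birds then age one year; birds
#' reaching `age_first_breeding` without a territory become floaters, and
#' vacant territories (up to `territory_cap`) are refilled from eligible
#' floaters, oldest first with random tie-breaks. Exit counters reset.
#'
#' @param state An `ev_state` at the end of the residence period.
#' @param params A calibrated `ev_params` object.
#' @return The updated state.
#' @export
step_annual_reproduction <- function(state, params) {
  b <- which(state$status == .ST_BREEDER)
  n_fledge <- 0L
  if (length(b)) {
    e <- state$exits_year[b] / .days_in_area(params)
    pf <- pmin(1, pmax(0, params$repro_intercept - params$repro_slope * e))
    fledged <- stats::runif(length(b)) < pf
    state$bred[b] <- fledged
    n_fledge <- sum(fledged)
  }
  state$births <- state$births + n_fledge
  state$age <- state$age + 1L
  if (n_fledge > 0L) {
    state$age <- c(state$age, rep(1L, n_fledge))
    state$status <- c(state$status, rep(.ST_IMMATURE, n_fledge))
    state$bred <- c(state$bred, rep(FALSE, n_fledge))
    state$exits_year <- c(state$exits_year, integer(n_fledge))
    state$fed_today <- c(state$fed_today, rep(TRUE, n_fledge))
  }
  # promotion: immatures reaching breeding age become floaters, then vacant
  # territories are refilled oldest-first (ties random)
  mature_nb <- which(state$status != .ST_BREEDER &
                       state$age >= params$age_first_breeding)
  state$status[mature_nb] <- .ST_FLOATER
  vacancies <- params$territory_cap - sum(state$status == .ST_BREEDER)
  if (vacancies > 0L && length(mature_nb)) {
    elig <- which(state$status == .ST_FLOATER)
    ord <- elig[order(-state$age[elig], stats::runif(length(elig)))]
    promote <- ord[seq_len(min(vacancies, length(ord)))]
    state$status[promote] <- .ST_BREEDER
    state$bred[promote] <- FALSE
  }
  state$exits_year[] <- 0L
  state
}

# ---- one simulated year ---------------------------------------------------

#' Simulate one year
#'
#' Runs the full module loop for the state's current calendar year:
#' `[module1, (module2, module3) x days_per_month] x months_in_area`, with
#' module 4 closing each month, then module 5. Returns the advanced state
#' and the year's record: the start-of-year census plus the year's biomass
#' accounting, demographic flows, and the mean breeder exit fraction.
#'
#' @param state An `ev_state`.
#' @param month_kg Rabbit-carcass biomass deposited per month (kg).
#' @param g_index Griffon abundance index for the year.
#' @param params A calibrated `ev_params` object.
#' @return A list with elements `state` (year advanced by one, counters
#'   reset) and `record` (a one-row tibble).
#' @export
simulate_year <- function(state, month_kg, g_index, params) {
  start <- census(state)
  nd <- params$days_per_month
  p_poison <- if (state$year < params$rhd_year) params$p_poison_pre else
    params$p_poison_per_exit * params$hazard_multiplier
  p_poison <- min(1, p_poison)
  p_exit <- params$p_exit_base
  unit_kg <- params$rabbit_carcass_mass_kg
  day_kg <- month_kg / nd

  for (m in seq_len(params$months_in_area)) {
    state <- step_monthly_mortality(state, params)
    n <- length(state$age)
    state$deposited <- state$deposited + month_kg
    if (n == 0L) next
    demand <- .daily_demand(state, m, params)
    p_g <- .interception_prob(g_index, params)
    b <- which(state$status == .ST_BREEDER)
    nb <- length(b)
    exits_m <- integer(nb)
    for (d in seq_len(nd)) {
      al <- .feed_allocate(demand, day_kg, p_g, unit_kg)
      state$consumed_ev <- state$consumed_ev + al$ev_kg
      state$consumed_gv <- state$consumed_gv + al$gv_kg
      if (nb) {
        fed_b <- al$fed[b]
        ex <- !fed_b
        if (p_exit > 0) {
          nf <- sum(fed_b)
          if (nf) ex[fed_b] <- stats::runif(nf) < p_exit
        }
        exits_m <- exits_m + ex
      }
    }
    if (nb) {
      state$exits_year[b] <- state$exits_year[b] + exits_m
      if (p_poison > 0) {
        pr <- 1 - (1 - p_poison)^exits_m
        die <- stats::runif(nb) < pr
        if (any(die)) {
          state$deaths_poison <- state$deaths_poison + sum(die)
          state <- .remove_birds(state, b[die])
        }
      }
    }
  }

  surv_b <- which(state$status == .ST_BREEDER)
  mean_exit <- if (length(surv_b)) {
    mean(state$exits_year[surv_b]) / .days_in_area(params)
  } else NA_real_

  state <- step_annual_reproduction(state, params)

  record <- start |>
    dplyr::mutate(
      rabbit_kg_ev = state$consumed_ev,
      rabbit_kg_gv = state$consumed_gv,
      rabbit_kg_deposited = state$deposited,
      mean_exit_fraction = mean_exit,
      births = state$births,
      deaths_nat_breeder = state$deaths_nat_breeder,
      deaths_nat_nonbreeder = state$deaths_nat_nonbreeder,
      deaths_poison = state$deaths_poison,
      griffon_index = g_index
    )

  state$year <- state$year + 1L
  state$consumed_ev <- 0; state$consumed_gv <- 0; state$deposited <- 0
  state$births <- 0L
  state$deaths_nat_breeder <- 0L
  state$deaths_nat_nonbreeder <- 0L
  state$deaths_poison <- 0L
  list(state = state, record = record)
}

# ---- replicate ensembles --------------------------------------------------

#' Run a replicate ensemble
#'
#' Runs `n_reps` independent replicates of the simulator over the years
#' covered by `drivers`. Replicate `r` runs on its own RNG stream seeded
#' from the root seed, so identical `(seed, params, drivers)` give
#' bit-identical output, and two ensembles sharing a root seed are paired
#' replicate-by-replicate (common random numbers).
#'
#' @param params A calibrated `ev_params` object.
#' @param drivers A driver tibble from [driver_series()].
#' @param n_reps Number of replicates (>= 1).
#' @param seed Root seed (integer).
#' @param init_states Optional list of `n_reps` starting states (e.g. the
#'   `final_states` of a hindcast ensemble); default is a fresh
#'   [init_population()] per replicate.
#' @param keep_states Keep each replicate's final state (needed to chain a
#'   projection onto a hindcast)?
#' @return An `ev_ensemble` object: per-replicate year records, a per-year
#'   summary with ensemble means and percentile 95% intervals, and run
#'   metadata.
#' @export
run_ensemble <- function(params, drivers, n_reps = 100, seed = 1,
                         init_states = NULL, keep_states = FALSE) {
  .require_calibrated(params)
  stopifnot(n_reps >= 1)
  if (!is.null(init_states) && length(init_states) != n_reps) {
    rlang::abort("init_states must have one state per replicate",
                 class = "neophron_config_error")
  }
  yr <- drivers[!duplicated(drivers$year),
                c("year", "rabbit_kg", "griffon_index")]
  yr <- yr[order(yr$year), ]
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  n_years <- nrow(yr)
  rows <- vector("list", n_reps)
  finals <- if (keep_states) vector("list", n_reps) else NULL
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    if (is.null(init_states)) {
      st <- init_population(params, year = yr$year[1])
    } else {
      st <- init_states[[r]]
      if (st$year != yr$year[1]) {
        rlang::abort(paste0(
          "init state year (", st$year, ") does not match the first driver ",
          "year (", yr$year[1], ")"
        ), class = "neophron_config_error")
      }
    }
    recs <- vector("list", n_years + 1L)
    for (i in seq_len(n_years)) {
      out <- simulate_year(st, yr$rabbit_kg[i], yr$griffon_index[i], params)
      st <- out$state
      recs[[i]] <- out$record
    }
    recs[[n_years + 1L]] <- census(st) |>
      dplyr::mutate(
        rabbit_kg_ev = NA_real_, rabbit_kg_gv = NA_real_,
        rabbit_kg_deposited = NA_real_, mean_exit_fraction = NA_real_,
        births = NA_integer_, deaths_nat_breeder = NA_integer_,
        deaths_nat_nonbreeder = NA_integer_, deaths_poison = NA_integer_,
        griffon_index = NA_real_
      )
    rows[[r]] <- dplyr::bind_rows(recs) |>
      dplyr::mutate(replicate = r, .before = 1)
    if (keep_states) finals[[r]] <- st
  }
  records <- dplyr::bind_rows(rows)
  structure(
    list(
      records = records,
      summary = summarize_ensemble(records),
      final_states = finals,
      seed = seed,
      rep_seeds = rep_seeds,
      n_reps = n_reps,
      years = yr$year,
      params = params
    ),
    class = "ev_ensemble"
  )
}

#' Summarize per-replicate records
#'
#' @param records The `records` tibble of an [run_ensemble()] result.
#' @return A long tibble: `year`, `variable`, `mean`, `lo95`, `hi95`,
#'   `n_reps` (percentile-based 95% intervals across replicates).
#' @export
summarize_ensemble <- function(records) {
  records |>
    tidyr::pivot_longer(-c("replicate", "year"),
                        names_to = "variable", values_to = "value") |>
    dplyr::group_by(.data$year, .data$variable) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      lo95 = stats::quantile(.data$value, 0.025, na.rm = TRUE,
                             names = FALSE),
      hi95 = stats::quantile(.data$value, 0.975, na.rm = TRUE,
                             names = FALSE),
      n_reps = dplyr::n(),
      .groups = "drop"
    )
}

#' @export
print.ev_ensemble <- function(x, ...) {
  cat("<ev_ensemble>", x$n_reps, "replicates over",
      min(x$years), "-", max(x$years), "(seed", paste0(x$seed, ")"), "\n")
  fin <- glance(x)
  cat("  final year", fin$year, ": mean pairs", round(fin$pairs, 1),
      ", adults", round(fin$adults, 1),
      ", immatures", round(fin$immatures, 1), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.ev_ensemble <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.ev_ensemble <- function(x, ...) {
  fin <- max(x$records$year)
  x$records |>
    dplyr::filter(.data$year == fin) |>
    dplyr::summarise(
      year = fin,
      pairs = mean(.data$pairs),
      adults = mean(.data$adults),
      females_adult = mean(.data$females_adult),
      floaters = mean(.data$floaters),
      immatures = mean(.data$immatures),
      n_reps = dplyr::n()
    )
}

# ---- hindcast / projection conveniences ----------------------------------

#' Hindcast the historical period
#'
#' Runs the ensemble from the initial population at `start_year` through
#' `hindcast_end` under the historical drivers: pre-crash biomass until
#' `rhd_year`, the residual biomass afterwards, and the observed griffon
#' growth curve.
#'
#' @inheritParams run_ensemble
#' @param keep_states Keep final states (default `TRUE`, to chain
#'   projections).
#' @return An `ev_ensemble`.
#' @export
run_hindcast <- function(params, n_reps = 100, seed = 1, keep_states = TRUE) {
  .require_calibrated(params)
  drv <- driver_series(params, params$start_year:params$hindcast_end)
  run_ensemble(params, drv, n_reps = n_reps, seed = seed,
               keep_states = keep_states)
}

#' Project forward from a hindcast
#'
#' Runs `n_years` of projection starting from the per-replicate final states
#' of a hindcast ensemble, under a chosen rabbit-recovery factor, griffon
#' scenario, and poisoning-hazard multiplier.
#'
#' @param params A calibrated `ev_params` object.
#' @param hindcast An `ev_ensemble` from [run_hindcast()] with
#'   `final_states` kept.
#' @param n_years Projection length in years (default 35).
#' @param seed Root seed for the projection replicates. Reusing a seed
#'   across scenarios pairs them replicate-by-replicate.
#' @param food_factor Rabbit recovery fraction in [0, 1]; `NULL` keeps the
#'   residual post-crash level.
#' @param griffon_scenario `"stable"` or `"doubling"`.
#' @param hazard_multiplier Multiplier on the calibrated poisoning hazard.
#' @param food_multiplier Multiplier on the projection rabbit biomass
#'   (sensitivity analysis dial).
#' @param keep_states Keep final states?
#' @return An `ev_ensemble`.
#' @export
run_projection <- function(params, hindcast, n_years = 35, seed = 1,
                           food_factor = NULL, griffon_scenario = "stable",
                           hazard_multiplier = 1, food_multiplier = 1,
                           keep_states = FALSE) {
  .require_calibrated(params)
  if (is.null(hindcast$final_states)) {
    rlang::abort("hindcast was run without keep_states = TRUE",
                 class = "neophron_config_error")
  }
  p <- params
  p$hazard_multiplier <- params$hazard_multiplier * hazard_multiplier
  years <- (params$hindcast_end + 1):(params$hindcast_end + n_years)
  drv <- driver_series(p, years, food_factor = food_factor,
                       griffon_scenario = griffon_scenario,
                       food_multiplier = food_multiplier)
  run_ensemble(p, drv, n_reps = hindcast$n_reps, seed = seed,
               init_states = hindcast$final_states,
               keep_states = keep_states)
}
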