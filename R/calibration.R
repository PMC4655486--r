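# Calibration: solve the CALIBRATED parameter fields so that the simulator
# reproduces the stated vital rates and the 2013 consumption split before
# any projection is run.
#
# Order (dependencies flow this way): baseline exit probability -> food
# supply R0 -> natural mortality (pre-era closed form) -> poisoning hazard
# <-> post-era exit fraction fixed point (pilot ensembles) -> interception
# coefficient kappa (bisection on the 2013 griffon share) -> reproduction
# line through the two era productivities.

# ---- deterministic pre-era mean-field recursion --------------------------

# Expected population composition propagated from the initial state to the
# crash year under pre-era rates and plentiful food. Used to size the
# pre-crash food supply to the demographic steady state the vital rates
# imply (the non-breeder pool roughly doubles over the first decade).
.pre_era_expected <- function(params) {
  afb <- params$age_first_breeding
  imm <- numeric(afb - 1) # expected immature females by age 1..afb-1
  ages <- seq(params$nonbreeder_age_min, params$nonbreeder_age_max)
  imm[ages] <- params$n_nonbreeders_init / length(ages)
  b <- params$n_pairs_init
  fl <- 0
  s_nb <- 1 - params$m_nonbreeder
  s_b <- 1 - params$m_breeder_pre
  for (y in params$start_year:(params$rhd_year - 1)) {
    b_s <- b * s_b
    imm_s <- imm * s_nb
    fl_s <- fl * s_nb
    fledge <- params$productivity_pre * b_s
    new_fl <- imm_s[afb - 1]
    imm <- c(fledge, imm_s[-(afb - 1)])
    fl <- fl_s + new_fl
    refill <- min(fl, params$territory_cap - b_s)
    b <- b_s + max(0, refill)
    fl <- fl - max(0, refill)
  }
  list(breeders = b, floaters = fl, immatures = sum(imm))
}

#' Calibrate the pre-crash food supply
#'
#' Sizes the monthly rabbit-carcass biomass `R0` so that the pre-crash
#' supply covers the annual demand of the population the pre-era vital rates
#' themselves imply at the crash year (deterministic expectation recursion),
#' divided by `rabbit_diet_fraction_pre`: rabbits made up more than that
#' fraction of the diet, so the carcass supply must exceed that share of
#' total intake, leaving essentially no unfed bird-days before the crash.
#'
#' @param params An `ev_params` object.
#' @return `params` with `rabbit_biomass_monthly_kg` and `p_exit_base` set.
#' @export
calibrate_food_supply <- function(params) {
  comp <- .pre_era_expected(params)
  rearing <- params$productivity_pre * comp$breeders
  counts <- tibble::tibble(
    species = "egyptian",
    status = c("successful_breeder_rearing", "other", "other"),
    n = c(rearing, comp$breeders - rearing, comp$floaters + comp$immatures)
  )
  demand <- annual_population_demand(counts, params)
  params$rabbit_biomass_monthly_kg <-
    demand / params$rabbit_diet_fraction_pre / params$months_in_area
  # with food plentiful before the crash essentially every bird is fed, so
  # the expected pre-era exit fraction equals the baseline exit probability
  params$p_exit_base <- params$exit_fraction_pre
  params
}

# ---- measurements from pilot ensembles -----------------------------------

.era_stats <- function(ens, params) {
  rec <- ens$records |>
    dplyr::filter(!is.na(.data$births), .data$pairs > 0)
  post <- rec |> dplyr::filter(.data$year >= params$rhd_year)
  pre <- rec |> dplyr::filter(.data$year < params$rhd_year)
  share_fin <- ens$records |>
    dplyr::filter(.data$year == params$hindcast_end,
                  .data$rabbit_kg_ev + .data$rabbit_kg_gv > 0) |>
    dplyr::mutate(s = .data$rabbit_kg_gv /
                    (.data$rabbit_kg_ev + .data$rabbit_kg_gv))
  list(
    m_pre = sum(pre$deaths_nat_breeder + pre$deaths_poison) / sum(pre$pairs),
    m_post = sum(post$deaths_nat_breeder + post$deaths_poison) /
      sum(post$pairs),
    exit_pre = stats::weighted.mean(pre$mean_exit_fraction, pre$pairs,
                                    na.rm = TRUE),
    exit_post = stats::weighted.mean(post$mean_exit_fraction, post$pairs,
                                     na.rm = TRUE),
    # fledglings per breeding female surviving to the season end (the
    # fledging function is conditional on survival to module 5)
    prod_pre = sum(pre$births) /
      sum(pre$pairs - pre$deaths_nat_breeder - pre$deaths_poison),
    prod_post = sum(post$births) /
      sum(post$pairs - post$deaths_nat_breeder - post$deaths_poison),
    gv_share_2013 = mean(share_fin$s)
  )
}

# Fill still-unresolved fields with provisional values so pilot ensembles
# can run mid-calibration.
.provisional <- function(params, exit_post_guess = 0.8) {
  g13 <- griffon_index(params$hindcast_end, params)
  if (is.na(params$p_exit_base)) params$p_exit_base <- params$exit_fraction_pre
  if (is.na(params$kappa_interception)) {
    params$kappa_interception <- params$gv_share_target / g13
  }
  if (is.na(params$repro_intercept) || is.na(params$repro_slope)) {
    params <- .solve_repro(params, exit_post_guess)
  }
  if (is.na(params$post_exit_fraction)) {
    params$post_exit_fraction <- exit_post_guess
  }
  if (is.na(params$m_natural_annual)) {
    surv_pois_pre <- (1 - params$p_poison_pre)^
      (.days_in_area(params) * params$exit_fraction_pre)
    params$m_natural_annual <- 1 - (1 - params$m_breeder_pre) / surv_pois_pre
  }
  if (is.na(params$p_poison_per_exit)) {
    params$p_poison_per_exit <- .analytic_poison(params, exit_post_guess)
  }
  params
}

# hazard p solving (1-m_nat)(1-p)^(days * exit_fraction) = 1 - target
.analytic_poison <- function(params, exit_fraction) {
  ratio <- (1 - params$m_breeder_post_target) / (1 - params$m_natural_annual)
  if (ratio > 1) {
    rlang::abort(paste0(
      "no poisoning hazard in [0, 1] can reach the post-era mortality ",
      "target: natural mortality alone already exceeds it"
    ), class = "neophron_calibration_error")
  }
  1 - ratio^(1 / (.days_in_area(params) * exit_fraction))
}

.solve_repro <- function(params, exit_post) {
  if (exit_post <= params$exit_fraction_pre + 1e-9) {
    rlang::abort(paste0(
      "post-era exit fraction (", signif(exit_post, 3),
      ") does not exceed the pre-era fraction (",
      params$exit_fraction_pre,
      "): a declining productivity line cannot be fitted"
    ), class = "neophron_calibration_error")
  }
  slope <- (params$productivity_pre - params$productivity_post_target) /
    (exit_post - params$exit_fraction_pre)
  params$repro_slope <- slope
  params$repro_intercept <- params$productivity_pre +
    slope * params$exit_fraction_pre
  params
}

# ---- operation: mortality ------------------------------------------------

#' Calibrate the mortality parameters
#'
#' Solves the two-era system: the pre-crash overall breeder mortality
#' (`m_breeder_pre`, 2%) at the pre-era exit fraction identifies the annual
#' natural component (the pre-era poisoning hazard `p_poison_pre` is zero:
#' poisoned baits were essentially absent then), and the post-crash overall
#' rate (`m_breeder_post_target`, 17%) at the post-era exit fraction
#' identifies the per-exit-day poisoning hazard. The post-era exit fraction
#' is itself an output of the simulator, so the hazard is solved by a pilot
#' ensemble fixed point: run a hindcast pilot, measure the realized post-era
#' mortality and exit fraction, update the hazard (analytic step, then
#' secant), and repeat until the realized mortality is within `tol` of the
#' target.
#'
#' @param params An `ev_params` object (food supply is auto-calibrated if
#'   still unset).
#' @param seed Calibration seed.
#' @param n_reps Pilot ensemble replicates.
#' @param tol Absolute tolerance on the realized post-era mortality.
#' @param max_iter Maximum pilot iterations.
#' @param p_poison_fixed Optionally pin the hazard (used to expose the
#'   inconsistency when poisoning is forced to zero: the post-era equation
#'   then demands a natural rate incompatible with the pre-era equation).
#' @return `params` with `m_natural_annual`, `p_poison_per_exit`,
#'   `post_exit_fraction` (and provisional reproduction coefficients)
#'   resolved; pilot diagnostics in `attr(, "mortality_diagnostics")`.
#' @export
calibrate_mortality <- function(params, seed = 1, n_reps = 40, tol = 0.005,
                                max_iter = 8, p_poison_fixed = NULL) {
  if (is.na(params$rabbit_biomass_monthly_kg)) {
    params <- calibrate_food_supply(params)
  }
  days <- .days_in_area(params)
  # pre-era equation: 1 - (1-m_nat)(1-p_pre)^(days*e_pre) = m_breeder_pre
  surv_pois_pre <- (1 - params$p_poison_pre)^(days * params$exit_fraction_pre)
  m_nat <- 1 - (1 - params$m_breeder_pre) / surv_pois_pre
  if (m_nat < 0 || m_nat > 1) {
    rlang::abort("no natural mortality rate in [0, 1] satisfies the pre-era equation",
                 class = "neophron_calibration_error")
  }
  params$m_natural_annual <- m_nat

  if (!is.null(p_poison_fixed) && p_poison_fixed == 0) {
    # post-era equation with p = 0 forces m_nat = post target, which the
    # pre-era equation contradicts
    rlang::abort(paste0(
      "with the poisoning hazard forced to 0 the post-era equation requires ",
      "m_natural_annual = ", params$m_breeder_post_target,
      ", inconsistent with the pre-era value ", signif(m_nat, 3)
    ), class = "neophron_calibration_error")
  }

  set.seed(seed)
  pilot_seeds <- sample.int(.Machine$integer.max - 1L, max_iter)
  exit_post <- 0.8 # initial guess, replaced by the first pilot
  params$p_poison_per_exit <- p_poison_fixed %||%
    .analytic_poison(params, exit_post)
  hist <- list()
  target <- params$m_breeder_post_target
  for (i in seq_len(max_iter)) {
    pp <- .provisional(params, exit_post)
    pilot <- run_hindcast(pp, n_reps = n_reps, seed = pilot_seeds[i],
                          keep_states = FALSE)
    st <- .era_stats(pilot, params)
    if (st$exit_post <= params$exit_fraction_pre + 1e-9) {
      rlang::abort(paste0(
        "degenerate calibration: post-era exit fraction equals the pre-era ",
        "fraction, the two mortality eras cannot be distinguished"
      ), class = "neophron_calibration_error")
    }
    exit_post <- st$exit_post
    params$post_exit_fraction <- exit_post
    params <- .solve_repro(params, exit_post)
    hist[[i]] <- tibble::tibble(
      iter = i, p_poison = params$p_poison_per_exit,
      realized_m_post = st$m_post, exit_post = exit_post
    )
    if (!is.null(p_poison_fixed)) break
    if (abs(st$m_post - target) <= tol) break
    if (i >= 2) {
      # secant step on the realized mortality
      h1 <- hist[[i - 1]]; h2 <- hist[[i]]
      dm <- h2$realized_m_post - h1$realized_m_post
      p_new <- if (abs(dm) < 1e-9) .analytic_poison(params, exit_post) else
        h2$p_poison + (target - h2$realized_m_post) *
          (h2$p_poison - h1$p_poison) / dm
      params$p_poison_per_exit <- min(0.999, max(1e-7, p_new))
    } else {
      params$p_poison_per_exit <- .analytic_poison(params, exit_post)
    }
  }
  diag <- dplyr::bind_rows(hist)
  if (is.null(p_poison_fixed) &&
      abs(diag$realized_m_post[nrow(diag)] - target) > tol) {
    rlang::warn(paste0(
      "post-era mortality fixed point stopped at ",
      signif(diag$realized_m_post[nrow(diag)], 3),
      " (target ", target, " +/- ", tol, ")"
    ))
  }
  attr(params, "mortality_diagnostics") <- diag
  params
}

# ---- operation: food & competition ---------------------------------------

#' Calibrate the food supply and the interception coefficient
#'
#' Sets the pre-crash biomass `R0` (see [calibrate_food_supply()]) and
#' solves the griffon carcass-interception coefficient `kappa` by bisection
#' so that the ensemble-mean griffon share of the rabbit-carcass biomass
#' consumed in the final hindcast year matches `gv_share_target` (27%).
#' Only the product `kappa x griffon_index` is identified (the absolute
#' scale of the index is arbitrary), which the scale-invariance property
#' test exploits.
#'
#' @inheritParams calibrate_mortality
#' @param tol Absolute tolerance on the realized share.
#' @param max_iter Maximum bisection iterations.
#' @return `params` with `rabbit_biomass_monthly_kg` and
#'   `kappa_interception` resolved; bisection trace in
#'   `attr(, "kappa_diagnostics")`.
#' @export
calibrate_food_and_competition <- function(params, seed = 1, n_reps = 40,
                                           tol = 0.02, max_iter = 6) {
  if (is.na(params$rabbit_biomass_monthly_kg)) {
    params <- calibrate_food_supply(params)
  }
  g13 <- griffon_index(params$hindcast_end, params)
  kappa0 <- params$gv_share_target / g13
  lo <- 0
  hi <- 2.5 * kappa0
  set.seed(seed)
  pilot_seeds <- sample.int(.Machine$integer.max - 1L, max_iter)
  target <- params$gv_share_target
  hist <- list()
  share <- NA_real_
  for (i in seq_len(max_iter)) {
    mid <- if (i == 1) kappa0 else (lo + hi) / 2
    params$kappa_interception <- mid
    pp <- .provisional(params)
    pilot <- run_hindcast(pp, n_reps = n_reps, seed = pilot_seeds[i],
                          keep_states = FALSE)
    share <- .era_stats(pilot, params)$gv_share_2013
    hist[[i]] <- tibble::tibble(iter = i, kappa = mid,
                                realized_share = share)
    if (abs(share - target) <= tol) break
    if (share > target) hi <- mid else lo <- mid
    if (hi - lo < 1e-9 * kappa0) {
      rlang::abort("kappa bisection bracket collapsed without reaching the target share",
                   class = "neophron_calibration_error")
    }
  }
  attr(params, "kappa_diagnostics") <- dplyr::bind_rows(hist)
  params
}

# ---- operation: reproduction ---------------------------------------------

#' Calibrate the exit-dependent productivity line
#'
#' Fledging probability is linear in the annual exit fraction,
#' `p(e) = repro_intercept - repro_slope x e`, fitted through the two
#' era points: productivity 0.4 at the pre-era exit fraction (0.20) and 0.2
#' at the post-era exit fraction measured from the pilot ensembles.
#'
#' @param params An `ev_params` object.
#' @param post_exit_fraction Post-era mean breeder exit fraction; defaults
#'   to the value stored by [calibrate_mortality()].
#' @return `params` with `repro_intercept` and `repro_slope` resolved.
#' @export
calibrate_reproduction <- function(params,
                                   post_exit_fraction =
                                     params$post_exit_fraction) {
  if (is.na(post_exit_fraction)) {
    rlang::abort("post_exit_fraction unknown; run calibrate_mortality() first",
                 class = "neophron_calibration_error")
  }
  .solve_repro(params, post_exit_fraction)
}

# ---- full calibration ----------------------------------------------------

#' Calibrate the full parameter set
#'
#' Runs the calibration stages in dependency order: food supply, mortality
#' fixed point, interception bisection, reproduction line, then a
#' verification ensemble whose realized rates are stored as the calibration
#' report (`calibration_report()`).
#'
#' @inheritParams calibrate_mortality
#' @param n_reps Pilot/verification ensemble replicates (default 40).
#' @return A calibrated `ev_params` object.
#' @export
calibrate_params <- function(params = ev_params(), seed = 1, n_reps = 40) {
  validate_params(params)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 3L)
  params <- calibrate_food_supply(params)
  params <- calibrate_mortality(params, seed = seeds[1], n_reps = n_reps)
  params <- calibrate_food_and_competition(params, seed = seeds[2],
                                           n_reps = n_reps)
  params <- calibrate_reproduction(params)
  # verification ensemble on a fresh seed
  verify <- run_hindcast(params, n_reps = n_reps, seed = seeds[3],
                         keep_states = FALSE)
  st <- .era_stats(verify, params)
  report <- tibble::tibble(
    quantity = c("pre-era breeder mortality", "post-era breeder mortality",
                 "pre-era exit fraction", "pre-era productivity",
                 "post-era productivity", "2013 griffon share"),
    target = c(params$m_breeder_pre, params$m_breeder_post_target,
               params$exit_fraction_pre, params$productivity_pre,
               params$productivity_post_target, params$gv_share_target),
    achieved = c(st$m_pre, st$m_post, st$exit_pre, st$prod_pre,
                 st$prod_post, st$gv_share_2013)
  ) |>
    dplyr::mutate(residual = .data$achieved - .data$target)
  attr(params, "calibration_report") <- report
  params
}

#' Calibration report
#'
#' @param params A parameter set returned by [calibrate_params()].
#' @return A tibble of calibration targets, achieved values (verification
#'   ensemble) and residuals.
#' @export
calibration_report <- function(params) {
  rep <- attr(params, "calibration_report")
  if (is.null(rep)) {
    rlang::abort("no calibration report: run calibrate_params()",
                 class = "neophron_calibration_error")
  }
  rep
}
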