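# Scenario analysis: factorial / Box-Behnken designs over rabbit recovery
# and poisoning mortality, quadratic response-surface fits, and the
# recovery-threshold bisection.

#' Build a scenario design
#'
#' For two factors, a 3-level full factorial (9 distinct points) plus
#' `n_center` replicate center points; a Box-Behnken design proper is
#' undefined for two factors. For three or more factors, the standard
#' Box-Behnken layout: all (+/-1, +/-1) pairs with the remaining factors at
#' 0, plus `n_center` center points. Factors are coded to [-1, +1]; the
#' coded center maps to the midpoint of each range.
#'
#' @param ranges Named list of length-2 numeric ranges, e.g.
#'   `list(food_factor = c(0, 1), mortality_factor = c(0, 2))`.
#' @param n_center Number of (replicate) center points.
#' @return A tibble with a `point` id, one natural-units column per factor,
#'   and one `<factor>_coded` column per factor.
#' @examples
#' build_design(list(food_factor = c(0, 1), mortality_factor = c(0, 2)),
#'              n_center = 0)
#' @export
build_design <- function(ranges, n_center = 3) {
  k <- length(ranges)
  stopifnot(k >= 2, !is.null(names(ranges)), all(names(ranges) != ""))
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] >= r[2]) {
      rlang::abort(paste0("degenerate range for factor ", nm),
                   class = "neophron_config_error")
    }
  }
  if (k == 2) {
    coded <- as.matrix(expand.grid(c(-1, 0, 1), c(-1, 0, 1)))
  } else {
    pairs <- utils::combn(k, 2)
    rows <- list()
    for (j in seq_len(ncol(pairs))) {
      for (a in c(-1, 1)) for (b in c(-1, 1)) {
        v <- numeric(k)
        v[pairs[1, j]] <- a
        v[pairs[2, j]] <- b
        rows[[length(rows) + 1]] <- v
      }
    }
    coded <- do.call(rbind, rows)
  }
  if (n_center > 0) {
    coded <- rbind(coded, matrix(0, nrow = n_center, ncol = k))
  }
  colnames(coded) <- names(ranges)
  natural <- tibble::as_tibble(lapply(stats::setNames(names(ranges),
                                                      names(ranges)),
    function(nm) {
      r <- ranges[[nm]]
      mean(r) + diff(r) / 2 * coded[, nm]
    }))
  coded_df <- tibble::as_tibble(coded)
  names(coded_df) <- paste0(names(ranges), "_coded")
  dplyr::bind_cols(tibble::tibble(point = seq_len(nrow(coded))),
                   natural, coded_df)
}

#' Map an overall annual breeder mortality to a hazard multiplier
#'
#' The scenario designs vary "mortality" as printed overall annual breeder
#' mortality rates; the model's dial is a multiplier on the calibrated
#' per-exit poisoning hazard. This inverts the mortality model at the
#' calibrated post-era exit fraction:
#' `(1 - m_nat) * (1 - c p)^(days x exit_fraction) = 1 - M`.
#'
#' @param params A calibrated `ev_params` object.
#' @param annual_mortality Target overall annual breeder mortality in
#'   [0, 1).
#' @return The multiplier `c >= 0` (0 when `annual_mortality` is at or
#'   below the natural rate alone).
#' @export
hazard_multiplier_for_mortality <- function(params, annual_mortality) {
  .require_calibrated(params)
  vapply(annual_mortality, function(m) {
    if (m < 0 || m >= 1) {
      rlang::abort("annual_mortality must lie in [0, 1)",
                   class = "neophron_config_error")
    }
    ratio <- (1 - m) / (1 - params$m_natural_annual)
    if (ratio >= 1) return(0)
    p_req <- 1 - ratio^(1 / (.days_in_area(params) *
                               params$post_exit_fraction))
    p_req / params$p_poison_per_exit
  }, numeric(1))
}

#' Evaluate a scenario design
#'
#' Projects every design point forward from the per-replicate 2014 hindcast
#' states, all points sharing the same replicate seeds (common random
#' numbers across the design), and attaches the ensemble summaries: mean
#' final-year breeding pairs, non-breeders (floaters + immatures), adult
#' count, and the mean log growth rate of breeding females.
#'
#' Design columns used: `food_factor` (rabbit recovery fraction) and
#' `mortality_factor` (multiplier on the calibrated poisoning hazard).
#'
#' @param design A design tibble from [build_design()].
#' @param params A calibrated `ev_params` object.
#' @param hindcast An `ev_ensemble` from [run_hindcast()] with kept states.
#' @param griffon_scenario `"stable"` or `"doubling"`.
#' @param n_years Projection length (default 35).
#' @param seed Root seed shared by all points.
#' @return The design tibble with columns `final_pairs`, `final_adults`,
#'   `final_nonbreeders`, `final_immatures`, `growth_rate` appended.
#' @export
run_design <- function(design, params, hindcast,
                       griffon_scenario = "stable", n_years = 35,
                       seed = 1) {
  .require_calibrated(params)
  stopifnot(all(c("food_factor", "mortality_factor") %in% names(design)))
  out <- purrr::pmap_dfr(
    design[c("point", "food_factor", "mortality_factor")],
    function(point, food_factor, mortality_factor) {
      ens <- tryCatch(
        run_projection(params, hindcast, n_years = n_years, seed = seed,
                       food_factor = food_factor,
                       griffon_scenario = griffon_scenario,
                       hazard_multiplier = mortality_factor),
        error = function(e) {
          rlang::abort(paste0("design point ", point, " failed: ",
                              conditionMessage(e)), parent = e)
        }
      )
      fin <- glance(ens)
      first <- min(ens$records$year)
      p0 <- mean(ens$records$pairs[ens$records$year == first])
      tibble::tibble(
        point = point,
        final_pairs = fin$pairs,
        final_adults = fin$adults,
        final_nonbreeders = fin$floaters + fin$immatures,
        final_immatures = fin$immatures,
        growth_rate = (log(pmax(fin$pairs, 1e-3)) -
                         log(pmax(p0, 1e-3))) / n_years
      )
    }
  )
  dplyr::left_join(design, out, by = "point")
}

#' Fit a second-order response surface
#'
#' Ordinary least squares fit of the full quadratic in the coded factors
#' (intercept, linear, pure quadratic and pairwise interaction terms) to a
#' design response, as used to render the scenario surfaces.
#'
#' @param results An evaluated design from [run_design()] (or any tibble
#'   with `<factor>_coded` columns and the response).
#' @param response Name of the response column (string).
#' @return An `ev_surface` object wrapping the `lm` fit; see
#'   [tidy()][generics::tidy] / [glance()][generics::glance] /
#'   [ggplot2::autoplot()].
#' @export
fit_surface <- function(results, response) {
  coded <- grep("_coded$", names(results), value = TRUE)
  if (length(coded) < 2) {
    rlang::abort("results must carry at least two *_coded factor columns",
                 class = "neophron_config_error")
  }
  stopifnot(response %in% names(results))
  n_coef <- 1 + 2 * length(coded) + choose(length(coded), 2)
  if (nrow(dplyr::distinct(results[coded])) < n_coef) {
    rlang::abort("too few distinct design points for a quadratic fit",
                 class = "neophron_config_error")
  }
  quad <- paste0("I(", coded, "^2)")
  inter <- utils::combn(coded, 2, FUN = paste, collapse = ":")
  form <- stats::as.formula(paste(
    response, "~", paste(c(coded, quad, inter), collapse = " + ")
  ))
  fit <- stats::lm(form, data = results)
  if (fit$rank < length(stats::coef(fit))) {
    rlang::abort("rank-deficient design: quadratic surface not identifiable",
                 class = "neophron_config_error")
  }
  structure(
    list(fit = fit, response = response, factors = coded,
         data = results),
    class = "ev_surface"
  )
}

#' @export
print.ev_surface <- function(x, ...) {
  cat("<ev_surface> quadratic response surface for", x$response, "\n")
  print(stats::coef(x$fit))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ev_surface <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @exportS3Method generics::glance
glance.ev_surface <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    df.residual = x$fit$df.residual,
    nobs = length(x$fit$residuals)
  )
}

#' Predict from a response surface on the coded scale
#'
#' @param object An `ev_surface`.
#' @param newdata Tibble of coded factor values (columns named like the
#'   design's `*_coded` columns).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.ev_surface <- function(object, newdata, ...) {
  stats::predict(object$fit, newdata = newdata)
}

#' Rabbit-recovery threshold for a positive population trend
#'
#' Bisects on the rabbit recovery factor in [0, 1], classifying each point
#' by the ensemble-mean log growth rate of breeding females over projection
#' years `window[1]` to `window[2]` (least-squares slope of the log
#' ensemble-mean trajectory; the early years are excluded to let transient
#' age-structure effects wash out). Returns the recovery percentage at
#' which the trend turns positive. If the trend is already positive at 0
#' recovery the threshold is 0; if it is still negative at full recovery
#' the threshold is reported as `NA` with status `"always_negative"`.
#'
#' @param params A calibrated `ev_params` object.
#' @param hindcast An `ev_ensemble` from [run_hindcast()] with kept states.
#' @param griffon_scenario `"stable"` or `"doubling"`.
#' @param n_years Projection length (default 35).
#' @param window Trend-classification window in projection years.
#' @param seed Root seed shared by every bisection point (common random
#'   numbers).
#' @param f_tol Bisection tolerance on the recovery fraction.
#' @return A one-row tibble: `threshold_pct`, the bracketing
#'   `bracket_lo_pct`/`bracket_hi_pct` (the Monte-Carlo/bisection band),
#'   the growth rates at the bracket ends, `status`, `griffon_scenario`,
#'   `n_reps`.
#' @export
recovery_threshold <- function(params, hindcast, griffon_scenario = "stable",
                               n_years = 35, window = c(15, 35), seed = 1,
                               f_tol = 1 / 32) {
  .require_calibrated(params)
  g <- function(f) {
    ens <- run_projection(params, hindcast, n_years = n_years, seed = seed,
                          food_factor = f,
                          griffon_scenario = griffon_scenario)
    yrs <- sort(unique(ens$records$year))
    idx <- window[1]:min(window[2], length(yrs))
    traj <- ens$summary |>
      dplyr::filter(.data$variable == "pairs",
                    .data$year %in% yrs[idx])
    stats::coef(stats::lm(log(pmax(traj$mean, 1e-3)) ~ traj$year))[[2]]
  }
  out <- function(th, lo, hi, glo, ghi, status) {
    tibble::tibble(
      threshold_pct = th, bracket_lo_pct = 100 * lo,
      bracket_hi_pct = 100 * hi, growth_lo = glo, growth_hi = ghi,
      status = status, griffon_scenario = griffon_scenario,
      n_reps = hindcast$n_reps
    )
  }
  g0 <- g(0)
  if (g0 > 0) return(out(0, 0, 0, g0, g0, "always_positive"))
  g1 <- g(1)
  if (g1 <= 0) return(out(NA_real_, 0, 1, g0, g1, "always_negative"))
  lo <- 0; hi <- 1; glo <- g0; ghi <- g1
  while (hi - lo > f_tol) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (gm > 0) { hi <- mid; ghi <- gm } else { lo <- mid; glo <- gm }
  }
  out(100 * (lo + hi) / 2, lo, hi, glo, ghi, "bracketed")
}
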