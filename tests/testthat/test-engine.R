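make_state <- function(n_breeders = 0, n_immatures = 0, params = test_params(),
                       year = 1980) {
  set.seed(1234)
  init_population(
    ev_params(n_pairs_init = n_breeders, n_nonbreeders_init = n_immatures,
              territory_cap = max(n_breeders, params$territory_cap)),
    year = year
  )
}

test_that("monthly natural mortality: limit cases and the binomial closed form", {
  p <- test_params()
  st <- make_state(5, 20)

  # m = 0 leaves the population unchanged
  p0 <- test_params(m_nonbreeder = 0)
  p0$m_natural_annual <- 0
  set.seed(2)
  expect_equal(step_monthly_mortality(st, p0)$age, st$age)

  # m_nonbreeder = 1 kills every non-breeder in the first month
  p1 <- test_params(m_nonbreeder = 1)
  set.seed(2)
  st1 <- step_monthly_mortality(st, p1)
  expect_equal(sum(st1$status != 3L), 0)
  expect_equal(st1$deaths_nat_nonbreeder, 20)

  # 10,000 non-breeders at 10%/yr over 6 months: survivors within 3 binomial
  # standard errors of 9,000
  big <- make_state(0, 10000)
  set.seed(3)
  for (m in 1:6) big <- step_monthly_mortality(big, p)
  se <- sqrt(10000 * 0.1 * 0.9)
  expect_lt(abs(length(big$age) - 9000), 3 * se)
})

test_that("daily feeding conserves biomass exactly and honors the limit cases", {
  p <- test_params()
  st <- make_state(10, 10)

  # no griffons: no interception, everything on offer to the vultures
  set.seed(4)
  out <- daily_feeding(st, 100, griffon_index = 0, params = p)
  expect_equal(out$gv_take_kg, 0)
  expect_equal(out$ev_take_kg + out$leftover_kg, 100)
  expect_true(all(out$state$fed_today))

  # saturating interception: griffons take everything, every bird unfed
  psat <- p; psat$kappa_interception <- 1e9
  set.seed(4)
  out2 <- daily_feeding(st, 100, griffon_index = 1, params = psat)
  expect_equal(out2$gv_take_kg, 100)
  expect_false(any(out2$state$fed_today))

  # exact conservation across random shortage regimes
  set.seed(5)
  for (pool in c(0, 0.4, 1.7, 3, 250)) {
    out3 <- daily_feeding(st, pool, griffon_index = 170, params = p)
    expect_equal(out3$ev_take_kg + out3$gv_take_kg + out3$leftover_kg,
                 pool, tolerance = 1e-12)
    expect_gte(out3$leftover_kg, 0)
  }
  expect_error(daily_feeding(st, -1, 0, p), class = "neophron_config_error")
})

test_that("griffon interception matches the binomial oracle at the 2013 level", {
  # 100 carcass units/day at interception probability 0.27 over 1,000
  # replicate days: the mean griffon share must sit within 3 binomial SEs
  p <- test_params()
  p$kappa_interception <- 0.27 # index 1 -> p_g = 0.27
  st <- make_state(3, 0)
  set.seed(6)
  taken <- vapply(1:1000, function(i) {
    daily_feeding(st, 100, griffon_index = 1, params = p)$gv_take_kg
  }, numeric(1))
  share <- sum(taken) / (1000 * 100)
  se_share <- sqrt(0.27 * 0.73 / (1000 * 100))
  expect_lt(abs(share - 0.27), 3 * se_share)
})

test_that("exit accounting: fed birds use the baseline rate, starvation forces exits", {
  p <- test_params()
  st <- make_state(10, 0)

  # all fed and p_exit_base = 0: nobody leaves
  p0 <- p; p0$p_exit_base <- 0
  st$fed_today <- rep(TRUE, length(st$age))
  set.seed(7)
  expect_equal(sum(step_daily_exit(st, p0)$exits_year), 0)

  # a year with zero park biomass: every breeder out every day
  set.seed(8)
  yr <- simulate_year(make_state(10, 0), month_kg = 0, g_index = 0,
                      params = p)
  expect_equal(yr$record$mean_exit_fraction, 1)
})

test_that("poisoning: no exits means no deaths, certain hazard kills", {
  p <- test_params()
  st <- make_state(8, 0, year = 2000)

  set.seed(9)
  expect_equal(length(step_monthly_poisoning(st, rep(0L, 8), p)$age), 8)

  p1 <- p; p1$p_poison_per_exit <- 1
  set.seed(9)
  st1 <- step_monthly_poisoning(st, rep(1L, 8), p1)
  expect_equal(length(st1$age), 0)
  expect_equal(st1$deaths_poison, 8)

  # before the crash year the pre-era hazard (zero) applies
  st_pre <- make_state(8, 0, year = 1985)
  set.seed(9)
  expect_equal(length(step_monthly_poisoning(st_pre, rep(30L, 8), p1)$age), 8)
})

test_that("reproduction follows the exit-dependent fledging line", {
  # coefficients through (0.2, 0.4) and (0.6, 0.2): slope 0.5, intercept 0.5
  p <- test_params()
  p <- calibrate_reproduction(p, post_exit_fraction = 0.6)
  expect_equal(p$repro_slope, 0.5)
  expect_equal(p$repro_intercept, 0.5)

  # at the pre-era exit level the fledging probability is 0.4
  big <- 4000
  st <- make_state(big, 0)
  st$exits_year <- rep(36L, big) # 0.2 x 180
  set.seed(10)
  st2 <- step_annual_reproduction(st, p)
  se <- sqrt(0.4 * 0.6 / big)
  expect_lt(abs(st2$births / big - 0.4), 3 * se)

  # slope 0: productivity independent of exits
  pflat <- p; pflat$repro_slope <- 0; pflat$repro_intercept <- 0.3
  st$exits_year <- sample(0:180, big, replace = TRUE)
  set.seed(11)
  st3 <- step_annual_reproduction(st, pflat)
  expect_lt(abs(st3$births / big - 0.3), 3 * sqrt(0.3 * 0.7 / big))

  # clamping at zero for extreme exit loads and steep slopes
  psteep <- p; psteep$repro_slope <- 5
  st$exits_year <- rep(180L, big)
  set.seed(12)
  expect_equal(step_annual_reproduction(st, psteep)$births, 0)
})

test_that("a null year changes nothing but ages", {
  p <- test_params(m_nonbreeder = 0, exit_fraction_pre = 0)
  p$m_natural_annual <- 0
  p$p_poison_per_exit <- 0
  p$p_exit_base <- 0
  p$repro_intercept <- 0
  p$repro_slope <- 0
  set.seed(13)
  st <- init_population(p)
  before <- census(st)
  out <- simulate_year(st, p$rabbit_biomass_monthly_kg, 0, p)
  after <- census(out$state)
  expect_equal(after$pairs, before$pairs)
  expect_equal(after$n_females, before$n_females)
  expect_equal(out$state$age, st$age + 1L)
})

test_that("births minus deaths equals the population change, exactly", {
  p <- test_params()
  drv <- driver_series(p, 1988:1996)
  ens <- run_ensemble(p, drv, n_reps = 3, seed = 21)
  by_rep <- split(ens$records, ens$records$replicate)
  for (rec in by_rep) {
    rec <- rec[order(rec$year), ]
    for (i in seq_len(nrow(rec) - 1)) {
      expect_equal(
        rec$n_females[i + 1],
        rec$n_females[i] + rec$births[i] - rec$deaths_nat_breeder[i] -
          rec$deaths_nat_nonbreeder[i] - rec$deaths_poison[i]
      )
    }
  }
})

test_that("breeders never exceed the territory cap and counts stay non-negative", {
  p <- test_params()
  drv <- driver_series(p, 1980:1999)
  ens <- run_ensemble(p, drv, n_reps = 4, seed = 22)
  expect_true(all(ens$records$pairs <= p$territory_cap))
  expect_true(all(ens$records[c("pairs", "floaters", "immatures")] >= 0))
})

test_that("pre-crash years are quasi-stationary at the historical density", {
  p <- test_params()
  drv <- driver_series(p, 1980:1985)
  ens <- run_ensemble(p, drv, n_reps = 100, seed = 23)
  final_pairs <- glance(ens)$pairs
  expect_gt(final_pairs, 47)
  expect_lte(final_pairs, 50)
})

test_that("identical seeds give bit-identical ensembles; one replicate collapses the band", {
  p <- test_params()
  drv <- driver_series(p, 1990:1995)
  e1 <- run_ensemble(p, drv, n_reps = 3, seed = 31)
  e2 <- run_ensemble(p, drv, n_reps = 3, seed = 31)
  expect_identical(e1$records, e2$records)
  expect_identical(e1$summary, e2$summary)

  e3 <- run_ensemble(p, drv, n_reps = 1, seed = 31)
  expect_equal(e3$summary$lo95, e3$summary$mean)
  expect_equal(e3$summary$hi95, e3$summary$mean)
})

test_that("Monte-Carlo means agree with the deterministic expectation recursion", {
  # small population, plentiful food, no poisoning, no recruitment (age at
  # first breeding far above any attainable age): every class evolves
  # linearly, so expected values propagate exactly. The oracle below is an
  # independent hand recursion.
  p <- test_params(age_first_breeding = 30, n_pairs_init = 10,
                   n_nonbreeders_init = 10)
  p$m_natural_annual <- 0.1
  p$p_poison_per_exit <- 0
  p$kappa_interception <- 0
  p$repro_intercept <- 0.5
  p$repro_slope <- 0.5

  n_years <- 5
  # oracle: expected breeders and immatures, year by year
  b <- 10
  imm <- 10
  for (t in seq_len(n_years)) {
    b_end <- b * 0.9           # natural mortality over the 6 months
    births <- b_end * (0.5 - 0.5 * 0.2) # fledging at the baseline exit rate
    imm <- imm * 0.9 + births
    b <- b_end
  }

  drv <- driver_series(p, 1980:(1980 + n_years - 1))
  ens <- run_ensemble(p, drv, n_reps = 200, seed = 33)
  fin <- ens$records[ens$records$year == 1980 + n_years, ]
  se_pairs <- stats::sd(fin$pairs) / sqrt(nrow(fin))
  se_imm <- stats::sd(fin$immatures) / sqrt(nrow(fin))
  expect_lt(abs(mean(fin$pairs) - b), 3 * se_pairs)
  expect_lt(abs(mean(fin$immatures) - imm), 3 * se_imm)
})
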