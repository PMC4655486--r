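test_that("defaults encode the study conditions and validation rejects bad sets", {
  p <- ev_params()
  expect_equal(p$n_pairs_init, 50)
  expect_equal(p$months_in_area * p$days_per_month, 180)
  expect_false(is_calibrated(p))
  expect_true(is_calibrated(test_params()))

  expect_error(ev_params(not_a_field = 1), class = "neophron_config_error")
  expect_error(ev_params(m_nonbreeder = 1.2), class = "neophron_config_error")
  expect_error(ev_params(n_pairs_init = 60, territory_cap = 50),
               class = "neophron_config_error")
  expect_error(ev_params(territory_cap = -1), class = "neophron_config_error")
})

test_that("provenance distinguishes paper, design and calibrated fields", {
  prov <- param_provenance(test_params())
  expect_setequal(unique(prov$provenance), c("paper", "design", "calibrated"))
  expect_equal(prov$provenance[prov$field == "m_breeder_post_target"], "paper")
  expect_equal(prov$provenance[prov$field == "p_poison_per_exit"], "calibrated")
  expect_equal(prov$provenance[prov$field == "ev_daily_intake_kg"], "design")
})

test_that("config files round-trip and reject unknown keys", {
  f <- withr::local_tempfile(fileext = ".yml")
  p <- test_params(rhd_survival_fraction = 0.2)
  write_params(p, f)
  q <- read_params(f)
  expect_equal(unclass(q), unclass(p))

  bad <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("territory_cap: 50", "territorry_cap: 51"), bad)
  expect_error(read_params(bad), class = "neophron_config_error")
})

test_that("initial population matches the 1980 monitoring state", {
  set.seed(1)
  st <- init_population(ev_params())
  cn <- census(st)
  expect_equal(cn$pairs, 50)
  expect_equal(cn$adults, 100)
  expect_equal(cn$immatures, 50)
  expect_equal(cn$year, 1980)

  # all initial non-breeders are aged within the stated 1-5 band
  ages_nb <- st$age[st$status != 3L]
  expect_true(all(ages_nb >= 1 & ages_nb <= 5))

  # no non-breeders requested -> exactly the breeders
  st0 <- init_population(ev_params(n_nonbreeders_init = 0))
  expect_equal(census(st0)$n_females, 50)

  # fixed seed reproduces the age multiset
  set.seed(99); a1 <- sort(init_population(ev_params())$age)
  set.seed(99); a2 <- sort(init_population(ev_params())$age)
  expect_identical(a1, a2)
})

test_that("census categories partition the population", {
  p <- test_params()
  set.seed(3)
  st <- init_population(p)
  for (i in 1:3) {
    st <- simulate_year(st, p$rabbit_biomass_monthly_kg,
                        0, p)$state
    cn <- census(st)
    expect_equal(cn$pairs + cn$floaters + cn$immatures, cn$n_females)
    expect_true(all(cn[c("pairs", "floaters", "immatures")] >= 0))
  }
  # removing one breeder decrements pairs by exactly one
  before <- census(st)$pairs
  st2 <- neophron:::.remove_birds(st, which(st$status == 3L)[1])
  expect_equal(census(st2)$pairs, before - 1)
})
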