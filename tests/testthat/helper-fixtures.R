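# Shared fixtures. Fast unit tests use a hand-resolved parameter set
# (test_params) so they never depend on the calibration runs; the heavier
# ensemble-level tests share one calibration / hindcast / projection pair
# through a lazily-filled cache.

# A fully-resolved parameter set with round, plausible calibrated values
# (close to what calibrate_params() finds under defaults, but fixed by hand
# so unit tests are deterministic and independent of the calibration code).
test_params <- function(...) {
  p <- ev_params(...)
  fill <- list(
    p_exit_base = p$exit_fraction_pre,
    rabbit_biomass_monthly_kg = 1440,
    m_natural_annual = 0.02,
    p_poison_per_exit = 0.00115,
    repro_intercept = 0.4667,
    repro_slope = 0.3339,
    kappa_interception = 0.27 / griffon_index(p$hindcast_end, p),
    post_exit_fraction = 0.8
  )
  for (nm in names(fill)) if (is.na(p[[nm]])) p[[nm]] <- fill[[nm]]
  p
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

cached_cal <- function() {
  cached("cal", calibrate_params(ev_params(), seed = 42, n_reps = 40))
}

cached_hind <- function() {
  cached("hind", run_hindcast(cached_cal(), n_reps = 100, seed = 7))
}

cached_proj_stable <- function() {
  cached("projS", run_projection(cached_cal(), cached_hind(),
                                 n_years = 35, seed = 11,
                                 griffon_scenario = "stable"))
}

cached_proj_doubling <- function() {
  cached("projD", run_projection(cached_cal(), cached_hind(),
                                 n_years = 35, seed = 11,
                                 griffon_scenario = "doubling"))
}

# small hindcast for design-level tests
cached_hind_small <- function() {
  cached("hind_small", run_hindcast(cached_cal(), n_reps = 20, seed = 19))
}
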