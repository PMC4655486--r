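two_ranges <- list(food_factor = c(0, 1), mortality_factor = c(0, 2))

test_that("two factors give the 3-level factorial; centers map to midpoints", {
  d <- build_design(two_ranges, n_center = 0)
  expect_equal(nrow(d), 9)
  expect_equal(nrow(dplyr::distinct(d[c("food_factor_coded",
                                        "mortality_factor_coded")])), 9)
  d3 <- build_design(two_ranges, n_center = 3)
  expect_equal(nrow(d3), 12)
  centers <- d3[d3$food_factor_coded == 0 & d3$mortality_factor_coded == 0, ]
  expect_equal(unique(centers$food_factor), 0.5)
  expect_equal(unique(centers$mortality_factor), 1)
  # coded columns are orthogonal in the factorial part
  dd <- build_design(two_ranges, n_center = 0)
  expect_equal(sum(dd$food_factor_coded * dd$mortality_factor_coded), 0)
  expect_error(build_design(list(a = c(0, 1), b = c(1, 1))),
               class = "neophron_config_error")
})

test_that("three factors give the Box-Behnken edge-midpoint layout", {
  d <- build_design(list(a = c(0, 1), b = c(0, 1), c = c(0, 1)),
                    n_center = 1)
  # brute-force enumeration of the standard construction: every pair of
  # factors at (+/-1, +/-1) with the third at 0, plus the center
  brute <- list()
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    for (x in c(-1, 1)) for (y in c(-1, 1)) {
      v <- c(0, 0, 0)
      v[pair[1]] <- x; v[pair[2]] <- y
      brute[[length(brute) + 1]] <- v
    }
  }
  brute[[length(brute) + 1]] <- c(0, 0, 0)
  brute <- do.call(rbind, brute)
  got <- as.matrix(d[c("a_coded", "b_coded", "c_coded")])
  key <- function(m) sort(apply(m, 1, paste, collapse = ","))
  expect_equal(key(got), key(brute))
  expect_equal(nrow(dplyr::distinct(as.data.frame(got))), 13)
})

test_that("a noiseless quadratic response is recovered to numerical precision", {
  d <- build_design(two_ranges, n_center = 1)
  truth <- c(i = 2, l1 = 0.5, l2 = -1, q1 = 0.25, q2 = -0.75, x12 = 0.4)
  d$y <- truth["i"] +
    truth["l1"] * d$food_factor_coded +
    truth["l2"] * d$mortality_factor_coded +
    truth["q1"] * d$food_factor_coded^2 +
    truth["q2"] * d$mortality_factor_coded^2 +
    truth["x12"] * d$food_factor_coded * d$mortality_factor_coded
  surf <- fit_surface(d, "y")
  co <- suppressWarnings(tidy(surf)) # zero-residual fit: summary() warns
  expect_equal(nrow(co), 6)
  expect_equal(unname(co$estimate), unname(truth), tolerance = 1e-10)
  expect_equal(suppressWarnings(glance(surf))$r.squared, 1,
               tolerance = 1e-10)

  # adding a constant moves only the intercept
  d$y2 <- d$y + 100
  co2 <- suppressWarnings(tidy(fit_surface(d, "y2")))
  expect_equal(co2$estimate[1], co$estimate[1] + 100, tolerance = 1e-8)
  expect_equal(co2$estimate[-1], co$estimate[-1], tolerance = 1e-8)
})

test_that("a pure-noise response yields a near-zero R-squared", {
  d <- build_design(two_ranges, n_center = 0)
  d <- dplyr::bind_rows(d, d, d, d) # 36 runs
  set.seed(14)
  r2 <- replicate(20, {
    d$y <- stats::rnorm(nrow(d))
    glance(fit_surface(d, "y"))$r.squared
  })
  expect_lt(mean(r2), 0.35)
})

test_that("degenerate designs are rejected", {
  d <- build_design(two_ranges, n_center = 0)
  expect_error(fit_surface(d[1:4, ], "food_factor"),
               class = "neophron_config_error")
  expect_error(fit_surface(dplyr::select(d, food_factor), "food_factor"),
               class = "neophron_config_error")
})

test_that("mortality-to-multiplier mapping inverts the mortality model", {
  cal <- cached_cal()
  # the calibrated post-era target maps back to a multiplier of ~1
  expect_equal(
    hazard_multiplier_for_mortality(cal, cal$m_breeder_post_target), 1,
    tolerance = 0.05
  )
  # the natural rate alone maps to zero poisoning
  expect_equal(hazard_multiplier_for_mortality(cal, cal$m_natural_annual), 0)
  expect_error(hazard_multiplier_for_mortality(cal, 1.2),
               class = "neophron_config_error")
})

test_that("an evaluated design is reproducible and ordered sensibly", {
  cal <- cached_cal()
  hind <- cached_hind_small()
  d <- build_design(two_ranges, n_center = 0)
  res <- run_design(d, cal, hind, n_years = 12, seed = 51)
  res2 <- run_design(d, cal, hind, n_years = 12, seed = 51)
  expect_identical(res$final_pairs, res2$final_pairs)
  # the benign corner (full recovery, no poisoning) sits at the top of the
  # design within Monte-Carlo slack, and clearly beats the hostile corner
  best <- res$final_pairs[res$food_factor == 1 & res$mortality_factor == 0]
  worst <- res$final_pairs[res$food_factor == 0 & res$mortality_factor == 2]
  expect_gte(best + 2.5, max(res$final_pairs))
  expect_gt(best, worst)
  surf <- fit_surface(res, "final_pairs")
  expect_s3_class(autoplot(surf), "ggplot")
})
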