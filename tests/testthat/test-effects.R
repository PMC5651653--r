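# Effect functions, extrema, compound rates, porosity-contact relation.

test_that("effect functions reproduce their tabulated anchor values", {
  expect_equal(evaluate_effect("f8", 0), 3)            # anoxic reversion boost
  expect_equal(evaluate_effect("f9", 1), 0.5)          # minimal contact
  expect_equal(evaluate_effect("f6", 25), (10 / 9) / 2, tolerance = 1e-12)
  expect_equal(evaluate_effect("f13", 0.25), 0.5)      # anoxia midpoint
  expect_equal(evaluate_effect("f1", 0), 2)
  expect_equal(evaluate_effect("f4", 0), 0.01)
  expect_equal(evaluate_effect("f7", c(0, 100)), c(1, 2), tolerance = 1e-3)
})

test_that("effect evaluation validates its inputs", {
  expect_error(evaluate_effect("f14", 1), "unknown effect_id")
  expect_error(evaluate_effect("f1", -1), ">= 0")
  expect_error(evaluate_effect("f1", NaN), "finite")
})

test_that("effect extrema match the calibrated table at printed precision", {
  # id, domain, argmin, min, argmax, max; NA skips the location check
  # where the function is flat at its extremum (saturated plateaus)
  cases <- list(
    list("f1", c(0, 100), 3.57, 0.66, 0, 2),
    list("f2", c(0, 100), 3.77, 0.69, 0, 2),
    list("f3", c(0, 100), 3.89, 0.51, 0, 2),
    list("f4", c(0, 100), 0, 0.01, 5.2, 1.257),
    list("f5", c(0, 100), 0, 0.01, 4.6, 1.67),
    list("f6", c(0, 100), 100, 0, 0, 1.03),
    list("f7", c(0, 100), 0, 1, NA, 2),
    list("f8", c(0, 100), 100, 0.14, 0, 3),
    list("f9", c(1, 100), 1, 0.5, 100, 0.99),
    list("f10", c(0, 100), NA, 0, 3.75, 6.37),
    list("f11", c(1, 10), 10, 0.95, 1, 0.99),
    list("f12", c(1, 10), 10, 0.91, 1, 0.99),
    list("f13", c(0, 100), 0, 0.076, NA, 1.00)
  )
  for (cs in cases) {
    ex <- effect_extrema(cs[[1]], cs[[2]])
    if (!is.na(cs[[3]])) {
      expect_lt(abs(ex$argmin - cs[[3]]), 0.011,
                label = paste(cs[[1]], "argmin", signif(ex$argmin, 4)))
    }
    expect_lt(abs(ex$min - cs[[4]]), 0.011,
              label = paste(cs[[1]], "min", signif(ex$min, 4)))
    if (!is.na(cs[[5]])) {
      expect_lt(abs(ex$argmax - cs[[5]]), 0.011,
                label = paste(cs[[1]], "argmax", signif(ex$argmax, 4)))
    }
    expect_lt(abs(ex$max - cs[[6]]), 0.011,
              label = paste(cs[[1]], "max", signif(ex$max, 4)))
    expect_gt(ex$min, -1e-12)  # all effects non-negative on their range
  }
  expect_error(effect_extrema("f1", c(5, 2)), "inverted")
})

test_that("monotone effects are monotone on dense samples", {
  Cs <- seq(1, 10, length.out = 400)
  expect_true(all(diff(evaluate_effect("f9", Cs)) > 0))
  expect_true(all(diff(evaluate_effect("f11", Cs)) < 0))
  expect_true(all(diff(evaluate_effect("f12", Cs)) < 0))
  Os <- seq(0, 100, length.out = 400)
  expect_true(all(diff(evaluate_effect("f8", Os)) < 0))
  Ws <- seq(0, 100, length.out = 400)
  # f7 saturates at 2 in double precision: non-decreasing overall,
  # strictly increasing before saturation
  expect_true(all(diff(evaluate_effect("f7", Ws)) >= 0))
  expect_true(all(diff(evaluate_effect("f7", seq(0, 30, 0.25))) > 0))
  expect_true(all(diff(evaluate_effect("f6", Ws)) < 0))
})

test_that("compound rates multiply baseline rates by the forced effects", {
  # O = 0 forces f1 = 2; W = 16 forces f7 = 1.5
  er <- experimental_rates(1, 1, 1, 1, 1, 1, 1, 1, scale = 1e-5)
  cr <- compound_rates(er, environment_condition(O = 0, W = 16, C = 1))
  expect_equal(cr[["alpha"]], 3e-5, tolerance = 1e-10)
  expect_equal(cr[["r"]], 1e-5 * 3, tolerance = 1e-10)      # f8(0) = 3
  expect_equal(cr[["d1"]], 1e-5 * 0.01 * 0.5, tolerance = 1e-10)

  # multiplicative in the baseline rate
  er2 <- experimental_rates(2, 1, 1, 1, 1, 1, 1, 1, scale = 1e-5)
  cr2 <- compound_rates(er2, environment_condition(O = 0, W = 16, C = 1))
  expect_equal(cr2[["alpha"]], 2 * cr[["alpha"]])
  expect_equal(cr2[["beta"]], cr[["beta"]])
})

test_that("decoupled rates take their overrides regardless of oxygen", {
  er <- growth_experimental_rates()
  m <- coupling_mode(r = 51e-5)
  for (O in c(0, 5, 21, 80)) {
    cr <- compound_rates(er, environment_condition(O, 5, 3.75), m)
    expect_equal(cr[["r"]], 5.1e-4)
  }
  expect_error(coupling_mode(alpha = 1e-5), "d1, d2 and r")
  expect_error(coupling_mode(1e-5), "named")
})

test_that("contact rate from porosity is the affine published relation", {
  expect_equal(contact_from_porosity(23), 7.7)
  expect_equal(contact_from_porosity(40), 6)
  expect_equal(contact_from_porosity(0), 10)
  # affine and decreasing on [0, 90]
  p <- seq(0, 90, by = 5)
  Cs <- vapply(p, contact_from_porosity, 0)
  expect_true(all(diff(Cs) < 0))
  expect_equal(diff(Cs), rep(-0.5, length(p) - 1), tolerance = 1e-12)
  expect_warning(C95 <- contact_from_porosity(95), "adhere")
  expect_equal(as.numeric(C95), 1)
  expect_false(attr(C95, "adherent"))
  expect_error(contact_from_porosity(120), "\\[0, 100\\]")
})

test_that("environment and rate constructors validate ranges", {
  expect_error(environment_condition(-1, 5, 3), "oxygen")
  expect_error(environment_condition(21, 101, 3), "waste")
  expect_error(environment_condition(21, 5, 0.5), "contact")
  expect_silent(environment_condition(200, 5, 0.5, wide = TRUE))
  expect_error(experimental_rates(-1, 1, 1, 1, 1, 1, 1, 1), "negative")
  expect_warning(
    experimental_rates(100, 1.6, 2.6, 100, 100, 12, 8, 5, scale = 1e-5,
                       warn_range = TRUE),
    "outside")
})

test_that("compound bounds bracket the calibrated operating region", {
  b <- compound_rate_bounds()
  expect_true(all(b[, "lower"] <= b[, "upper"]))
  expect_true(all(b[, "lower"] >= 0))
  # spot anchors at the scale of the calibrated table
  expect_equal(b["d1", "lower"], 5e-7, tolerance = 1e-10)
  expect_equal(b["r", "lower"], 0.1e-5 * 15 / 105, tolerance = 1e-10)
  expect_equal(b["r", "upper"], 5.1e-4, tolerance = 1e-10)
  expect_equal(b["gamma", "upper"], 1.04e-4, tolerance = 1e-6)
})
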