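# Sensitivity signs, interior optima, oxygen optimization, scenarios.

test_that("interior optima of the differentiation rates hit their references", {
  # d1 maximising P* with the co-parameters at their P*-optimal values
  co_d1 <- as_compound_rates(6.6e-7, 1.1e-5, 1.04e-4, 0.014, 0.019,
                             d1 = 1e-6, d2 = 3.6e-7, r = 1.4e-7)
  o1 <- interior_optimum("P", "d1", co_d1, bounds = c(5.0e-7, 2.1e-4))
  expect_true(o1$interior)
  expect_equal(o1$optimum, 8.675e-7, tolerance = 0.01)
  # d2 maximising D* with the co-parameters at their D*-optimal values
  co_d2 <- as_compound_rates(6.6e-7, 1.1e-5, 8.16e-6, 0.014, 0.019,
                             d1 = 8.675e-7, d2 = 1e-6, r = 1.4e-7)
  o2 <- interior_optimum("D", "d2", co_d2, bounds = c(3.6e-7, 1.02e-4))
  expect_true(o2$interior)
  expect_equal(o2$optimum, 9.495e-6, tolerance = 0.02)
  # the package's own bounds give the same optima
  rp <- optimal_compound_rates("P")
  expect_equal(rp[["d1"]], 8.675e-7, tolerance = 0.01)
  rd <- optimal_compound_rates("D")
  expect_equal(rd[["d2"]], 9.495e-6, tolerance = 0.02)
})

test_that("sensitivity signs reproduce the published pattern", {
  # stem-cell objective (identical pattern for the total population)
  ss <- sensitivity_signs("S", "spd", optimal_compound_rates("S"))
  expect_identical(ss[c("alpha", "beta", "d1", "d2")],
                   stats::setNames(rep("decreasing", 4),
                                   c("alpha", "beta", "d1", "d2")))
  expect_identical(unname(ss[c("gamma", "p1", "p2", "r")]),
                   rep("increasing", 4))
  st <- sensitivity_signs("T", "spd", optimal_compound_rates("S"))
  expect_identical(unname(st[c("alpha", "beta", "d1", "d2")]),
                   rep("decreasing", 4))
  expect_identical(unname(st[c("gamma", "p1", "p2", "r")]),
                   rep("increasing", 4))
  # progenitor objective: interior optimum in d1
  sp <- sensitivity_signs("P", "spd", optimal_compound_rates("P"))
  expect_identical(sp[["d1"]], "interior-max")
  expect_identical(sp[["d2"]], "decreasing")
  expect_identical(sp[["gamma"]], "increasing")
  # differentiated objective: interior optima in d1 and d2, gamma reversed
  sd <- sensitivity_signs("D", "spd", optimal_compound_rates("D"))
  expect_identical(sd[["d2"]], "interior-max")
  expect_identical(sd[["d1"]], "interior-max")
  expect_identical(sd[["gamma"]], "decreasing")
  # reversion has an interior optimum near the bottom of its range at
  # these co-parameters (the published conditional entry resolves there)
  expect_identical(sp[["r"]], "interior-max")
  b <- compound_rate_bounds()
  P_of_r <- function(r) {
    rr <- unclass(optimal_compound_rates("P")); rr[["r"]] <- r
    spd_asymptote_fixed_point(as_compound_rates(
      rr[["alpha"]], rr[["beta"]], rr[["gamma"]], rr[["p1"]], rr[["p2"]],
      rr[["d1"]], rr[["d2"]], rr[["r"]]))$P_star
  }
  grid <- seq(b["r", "lower"], b["r", "upper"], length.out = 1000)
  i <- which.max(vapply(grid, P_of_r, 0))
  r_star <- stats::optimize(P_of_r, grid[c(i - 1, i + 1)],
                            maximum = TRUE)$maximum
  # within the lowest 1% of the reversion range
  expect_lt(r_star, b["r", "lower"] + 0.01 * diff(range(b["r", ])))
  expect_gt(r_star, b["r", "lower"])
})

test_that("PD sensitivity signs match the published pattern cell-for-cell", {
  b <- compound_rate_bounds()
  pd_opt <- as_compound_rates(b["alpha", "lower"], b["beta", "lower"],
                              b["gamma", "upper"], b["p1", "upper"],
                              b["p2", "upper"], b["d1", "lower"],
                              b["d2", "lower"], b["r", "lower"])
  sp <- sensitivity_signs("P", "pd", pd_opt)
  expect_identical(unname(sp[c("beta", "gamma", "p2", "d2")]),
                   c("decreasing", "increasing", "increasing", "decreasing"))
  rr <- pd_opt; rr[["gamma"]] <- b["gamma", "lower"]
  sd <- sensitivity_signs("D", "pd", rr)
  expect_identical(unname(sd[c("beta", "gamma", "p2", "d2")]),
                   c("decreasing", "decreasing", "increasing",
                     "interior-max"))
  st <- sensitivity_signs("T", "pd", pd_opt)
  expect_identical(st[["gamma"]], "no-effect")
  expect_identical(unname(st[c("beta", "p2", "d2")]),
                   c("decreasing", "increasing", "decreasing"))
})

test_that("oxygen optimization is stable under scan granularity", {
  er <- growth_experimental_rates()
  coarse <- optimize_environment("S", er, n_grid = 2001L)
  fine <- optimize_environment("S", er, n_grid = 10001L)
  expect_lt(abs(coarse$O_star - fine$O_star), 1e-3)
  expect_true(isTRUE(fine$fp_numeric$stable))
})

test_that("decoupling rates from oxygen raises the achievable equilibrium", {
  er <- growth_experimental_rates()
  b <- compound_rate_bounds()
  s_indep <- spd_asymptote_fixed_point(optimal_compound_rates("S"))$S_star
  s_d1d2r <- optimize_environment(
    "S", er, coupling_mode(d1 = 0.05e-5, d2 = 0.03645e-5, r = 51e-5)
  )$fp_asymptote$S_star
  s_d1d2 <- optimize_environment(
    "S", er, coupling_mode(d1 = 0.05e-5, d2 = 0.03645e-5)
  )$fp_asymptote$S_star
  s_coupled <- optimize_environment("S", er)$fp_asymptote$S_star
  expect_true(s_indep >= s_d1d2r)
  expect_true(s_d1d2r >= s_d1d2)
  expect_true(s_d1d2 >= s_coupled)
})

test_that("scenario configs validate and resolve porosity", {
  er <- differentiation_experimental_rates()
  sc <- scenario_config("x", "spd", c(S = 0, P = 5000, D = 0), er,
                        porosity = c(23, 40))
  expect_equal(sc$C, c(7.7, 6))
  expect_error(scenario_config("x", "spd", c(P = 1), er, C = 5,
                               porosity = 23),
               "not both")
  expect_error(scenario_config("x", "spd", c(P = 1), er), "required")
})

test_that("run_scenario compares conditions and summarises endpoints", {
  res <- run_scenario(porosity_comparison_scenario(days = 4))
  expect_length(res$trajectories, 2)
  expect_equal(nrow(res$summary), 2)
  expect_true(all(c("C=7.7", "C=6") %in% res$summary$condition))
  expect_equal(res$summary$day, c(4, 4))
})
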