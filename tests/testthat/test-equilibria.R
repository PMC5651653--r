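# Fixed points, stability, air-level back-solve.

test_that("PD fixed point has the closed-form anchors", {
  # at 2 p2 = 2 (beta + d2) the total is exactly 1
  cr <- as_compound_rates(0, 1e-5, 2e-5, 0, p2 = 1.5e-5, 0, d2 = 5e-6, 0)
  fp <- pd_fixed_point(cr)
  expect_equal(fp$T_star, 1, tolerance = 1e-12)
  # D = d2 P / gamma at any reported equilibrium
  expect_equal(fp$D_star, cr[["d2"]] * fp$P_star / cr[["gamma"]],
               tolerance = 1e-12)
  # below threshold only the stable zero state remains
  cr0 <- as_compound_rates(0, 2e-5, 2e-5, 0, p2 = 5e-6, 0, d2 = 5e-6, 0)
  fp0 <- pd_fixed_point(cr0)
  expect_false(attr(fp0, "exists"))
  expect_true(isTRUE(fp0$stable))
  expect_equal(fp0$T_star, 0)
})

test_that("the progenitor-optimal PD equilibrium reaches its reference value", {
  b <- compound_rate_bounds()
  cr <- as_compound_rates(0, b["beta", "lower"], b["gamma", "upper"],
                          0, b["p2", "upper"], 0, b["d2", "lower"], 0)
  fp <- pd_fixed_point(cr)
  expect_equal(fp$P_star, 3325.2, tolerance = 0.01)
  expect_equal(fp$T_star, 2 * cr[["p2"]] / (cr[["beta"]] + cr[["d2"]]) - 1,
               tolerance = 1e-12)
})

test_that("the PD optimal d2 closed form agrees with direct maximisation", {
  b <- compound_rate_bounds()
  cr <- as_compound_rates(0, b["beta", "lower"], b["gamma", "lower"],
                          0, b["p2", "upper"], 0, b["d2", "lower"], 0)
  cf <- pd_optimal_d2(cr)
  num <- interior_optimum("D", "d2", cr, variant = "pd")
  expect_equal(num$optimum, cf, tolerance = 1e-4)
  expect_equal(num$closed_form, cf)
})

test_that("asymptote fixed point obeys its structural identities", {
  set.seed(31)
  for (k in 1:10) {
    cr <- draw_pd_rates()
    fp <- spd_asymptote_fixed_point(cr)
    expect_equal(fp$T_star, fp$S_star + fp$P_star + fp$D_star,
                 tolerance = 1e-12)
    expect_equal(fp$D_star, cr[["d2"]] * fp$P_star / cr[["gamma"]],
                 tolerance = 1e-9)
  }
  # zero reversion removes the stem population entirely
  cr <- draw_pd_rates()
  cr[["r"]] <- 0
  expect_equal(spd_asymptote_fixed_point(cr)$S_star, 0)
})

test_that("numeric fixed point refines the asymptote and sits on the
          nullclines", {
  eo <- optimize_environment("S", growth_experimental_rates())
  fa <- eo$fp_asymptote; fn <- eo$fp_numeric
  # 0.1% agreement in the growth-dominated regime
  expect_equal(fn$S_star, fa$S_star, tolerance = 1e-3)
  # exact residual at the root
  cr <- eo$rates_at_optimum
  d <- model_rhs("spd", c(S = fn$S_star, P = fn$P_star, D = fn$D_star), cr)
  expect_lt(max(abs(d)), 1e-8)
  expect_equal(fn$D_star, cr[["d2"]] * fn$P_star / cr[["gamma"]],
               tolerance = 1e-6)
  # a supplied guess near the root converges to it
  fg <- spd_numeric_fixed_point(cr, guess = c(S = fn$S_star * 1.01,
                                              P = fn$P_star * 1.01,
                                              D = fn$D_star * 1.01))
  expect_equal(fg$S_star, fn$S_star, tolerance = 1e-6)
})

test_that("asymptote error shrinks as the progenitor equilibrium grows", {
  co <- compound_rates(growth_experimental_rates(),
                       environment_condition(0.6, 5, 3.75))
  err_at <- function(p2) {
    rr <- unclass(co); rr[["p2"]] <- p2
    cr <- as_compound_rates(rr[["alpha"]], rr[["beta"]], rr[["gamma"]],
                            rr[["p1"]], rr[["p2"]], rr[["d1"]], rr[["d2"]],
                            rr[["r"]])
    fa <- spd_asymptote_fixed_point(cr)
    fn <- spd_numeric_fixed_point(cr)
    c(P = fn$P_star, err = abs(fa$T_star - fn$T_star) / fn$T_star)
  }
  lo <- err_at(2e-3); hi <- err_at(2e-2)
  expect_gt(hi[["P"]], lo[["P"]])
  expect_lt(hi[["err"]], lo[["err"]])
})

test_that("Routh-Hurwitz classification matches the eigenvalue oracle", {
  b <- compound_rate_bounds()
  set.seed(41)
  n_checked <- 0
  for (k in 1:500) {
    x <- stats::runif(8, b[, "lower"], b[, "upper"])
    names(x) <- rownames(b)
    cr <- as_compound_rates(x[["alpha"]], x[["beta"]], x[["gamma"]],
                            x[["p1"]], x[["p2"]], x[["d1"]], x[["d2"]],
                            x[["r"]])
    rh <- spd_zero_stability(cr)
    ev <- eigen(model_jacobian("spd", c(S = 0, P = 0, D = 0), cr),
                only.values = TRUE)$values
    if (max(abs(Re(ev))) < 1e-12) next  # skip numerically marginal draws
    expect_identical(rh$stable, all(Re(ev) < 0),
                     label = paste("draw", k))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 450)
})

test_that("zero state is stable exactly when proliferation is weak", {
  # both proliferation rates small relative to losses: stable
  cr <- as_compound_rates(1e-5, 1e-5, 1e-5, p1 = 4e-6, p2 = 6e-6,
                          d1 = 1e-5, d2 = 1e-5, r = 1e-6)
  expect_true(spd_zero_stability(cr)$stable)
  expect_equal(spd_zero_stability(cr)$case, 1L)
  # reversing a Routh-Hurwitz inequality destabilises
  cr2 <- cr; cr2[["p2"]] <- 5e-3
  expect_false(spd_zero_stability(cr2)$stable)
})

test_that("analytic Jacobians match finite differences", {
  set.seed(51)
  cr <- draw_pd_rates()
  fd_jac <- function(f, y, h = 1e-4) {
    n <- length(y)
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      e <- rep(0, n); e[j] <- h * max(1, abs(y[j]))
      J[, j] <- (f(y + e) - f(y - e)) / (2 * e[j])
    }
    J
  }
  y3 <- c(S = 700, P = 1200, D = 300)
  f3 <- function(y) unname(model_rhs("spd",
                                     c(S = y[1], P = y[2], D = y[3]), cr))
  expect_equal(unname(model_jacobian("spd", y3, cr)),
               fd_jac(f3, unname(y3)), tolerance = 1e-6)
  y2 <- c(P = 900, D = 150)
  f2 <- function(y) unname(model_rhs("pd", c(P = y[1], D = y[2]), cr))
  expect_equal(unname(model_jacobian("pd", y2, cr)),
               fd_jac(f2, unname(y2)), tolerance = 1e-6)
})

test_that("the positive PD equilibrium is stable whenever it exists", {
  set.seed(61)
  for (k in 1:20) {
    cr <- draw_pd_rates()
    fp <- pd_fixed_point(cr)
    st <- fixed_point_stability(c(P = fp$P_star, D = fp$D_star), cr, "pd")
    expect_true(isTRUE(st$stable), label = paste("draw", k))
  }
})

test_that("air-level back-solve balances consumption against diffusion", {
  # per-cell rates chosen so the diffusion flux can carry the load
  met <- metabolic_rates(u1 = 2e-14, u2 = 1.5e-14, u3 = 1e-14)
  g <- culture_geometry()
  # no cells: the medium equilibrates with the air
  res0 <- solve_air_levels(0, 0, 0, O = 5, W = 5, met, g, C = 3.75)
  expect_equal(res0$O_air, 5)
  expect_equal(res0$W_air, 5)
  res <- solve_air_levels(3000, 500, 100, O = 5, W = 10, met, g, C = 3.75)
  expect_true(res$feasible)
  # oracle: the flux at the returned air level equals the uptake
  f13 <- evaluate_effect("f13", 5)
  uptake <- f13 * (met$u1 * 3000 + met$u2 * 500 + met$u3 * 100)
  flux <- gas_flux("O", 5, res$O_air, 3600, g, C = 3.75)
  expect_equal(flux, uptake, tolerance = 1e-9)
  # doubling consumption doubles the oxygen head-room
  met2 <- metabolic_rates(u1 = 2 * met$u1, u2 = 2 * met$u2, u3 = 2 * met$u3)
  res2 <- solve_air_levels(3000, 500, 100, O = 5, W = 10, met2, g, C = 3.75)
  expect_equal(res2$O_air - 5, 2 * (res$O_air - 5), tolerance = 1e-9)
  # waste is removed: required air level sits below the local level
  expect_lt(res$W_air, 10)
  # a load the flux cannot carry is reported infeasible
  expect_warning(
    bad <- solve_air_levels(3000, 500, 100, O = 5, W = 5,
                            metabolic_rates(), g, C = 3.75),
    "infeasible")
  expect_false(bad$feasible)
})

test_that("nullcline constants are positive and reproduce the asymptotes", {
  cr <- draw_pd_rates()
  ng <- nullcline_geometry(cr)
  expect_true(ng$a > 0 && ng$b > 0 && ng$c > 0)
  expect_equal(ng$S1A_slope,
               (cr[["beta"]] + cr[["r"]] + cr[["d2"]]) / cr[["d1"]])
  # asymptote intersection reproduces the closed-form P*
  fp <- spd_asymptote_fixed_point(cr)
  P_int <- (ng$S2A_intercept - ng$S1A_intercept) /
    (ng$S1A_slope - ng$S2A_slope)
  expect_equal(P_int, fp$P_star, tolerance = 1e-9)
})
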