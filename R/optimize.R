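# Optimization of equilibrium populations: per-parameter sensitivity
# signs, interior optima of the differentiation rates, and optimization
# of the oxygen level under the model's waste/contact conventions.

#' Reference experimental rate sets
#'
#' Two calibrated baseline rate sets used throughout the examples and
#' scenarios (per-minute units): `growth_experimental_rates()` is the
#' set optimised for stem-cell/total population growth (low death, high
#' proliferation and reversion), and
#' `differentiation_experimental_rates()` is the set used for the
#' differentiation-oriented culture comparisons (lower death rates,
#' higher stem-to-progenitor differentiation, minimal reversion).
#'
#' @return An [experimental_rates()] object.
#' @export
growth_experimental_rates <- function() {
  experimental_rates(alpha = 0.1, beta = 1.6, gamma = 2.6, p1 = 119,
                     p2 = 160, d1 = 10, d2 = 7.29, r = 17, scale = 1e-5)
}

#' @rdname growth_experimental_rates
#' @export
differentiation_experimental_rates <- function() {
  experimental_rates(alpha = 0.01, beta = 0.16, gamma = 0.16, p1 = 119,
                     p2 = 160, d1 = 13.5, d2 = 7.745, r = 0.1, scale = 1e-5)
}

#' Interior optimum of a differentiation rate
#'
#' The equilibrium progenitor population is maximised at an intermediate
#' stem-to-progenitor differentiation rate `d1` (stem cells live longest,
#' so keeping a reservoir pays off), and the equilibrium differentiated
#' population at an intermediate `d2` (differentiation is terminal, so
#' draining the progenitor pool too fast is counterproductive). This
#' maximises the asymptote fixed-point expression of the chosen
#' population over the free rate by dense scan plus golden/Brent
#' refinement; for the PD variant with objective `D` the closed form
#' [pd_optimal_d2()] is evaluated as a cross-check and reported.
#'
#' @param objective `"P"` or `"D"`.
#' @param free_rate `"d1"` or `"d2"`.
#' @param rates Compound rate set supplying the fixed co-parameters (the
#'   free rate's entry is ignored).
#' @param bounds Search interval for the free rate; default the compound
#'   bounds from [compound_rate_bounds()].
#' @param variant `"spd"` (asymptote expressions) or `"pd"` (closed
#'   form).
#' @param tol Relative tolerance of the scalar maximisation.
#' @return List with `optimum` (the maximising rate), `value` (the
#'   population there), `interior` (logical), and `closed_form` (PD `d2`
#'   only).
#' @export
interior_optimum <- function(objective = c("P", "D"),
                             free_rate = c("d1", "d2"), rates,
                             bounds = NULL, variant = c("spd", "pd"),
                             tol = 1e-6) {
  objective <- match.arg(objective)
  free_rate <- match.arg(free_rate)
  variant <- match.arg(variant)
  if (is.null(bounds)) {
    bounds <- compound_rate_bounds()[free_rate, ]
  }
  obj_fun <- function(x) {
    rr <- unclass(rates)
    rr[[free_rate]] <- x
    if (variant == "spd") {
      fp <- spd_asymptote_fixed_point(as_compound_rates(
        rr[["alpha"]], rr[["beta"]], rr[["gamma"]], rr[["p1"]], rr[["p2"]],
        rr[["d1"]], rr[["d2"]], rr[["r"]]))
    } else {
      fp <- pd_fixed_point(rr)
    }
    if (objective == "P") fp$P_star else fp$D_star
  }
  grid <- seq(bounds[1], bounds[2], length.out = 1000L)
  vals <- vapply(grid, obj_fun, 0)
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(obj_fun, c(lo, hi), maximum = TRUE,
                         tol = tol * diff(range(bounds)))
  interior <- opt$maximum > bounds[1] + 1e-3 * diff(range(bounds)) &&
    opt$maximum < bounds[2] - 1e-3 * diff(range(bounds))
  if (!interior) {
    warning("objective is not maximised in the interior of the range; ",
            "best boundary point returned")
  }
  out <- list(optimum = opt$maximum, value = opt$objective,
              interior = interior)
  if (variant == "pd" && free_rate == "d2" && objective == "D") {
    out$closed_form <- pd_optimal_d2(rates)
  }
  out
}

#' Compound rate set optimal for one population
#'
#' Builds the fully independent optimal compound parameter set for a
#' given objective: every rate at the end of its compound range that
#' favours the objective, with the conditional entries resolved at those
#' co-parameter values — `d1` at its interior optimum for the progenitor
#' and differentiated objectives (computed by maximising the progenitor
#' equilibrium), and `d2` at its interior optimum for the differentiated
#' objective (computed sequentially after `d1`). The reversion rate sits
#' at the range end because its interior optimum falls below the allowed
#' minimum at these co-parameters.
#'
#' @param objective One of `"S"`, `"P"`, `"D"`, `"T"`.
#' @param bounds Compound bounds matrix, default [compound_rate_bounds()].
#' @return A `compound_rates` vector.
#' @export
optimal_compound_rates <- function(objective = c("S", "P", "D", "T"),
                                   bounds = compound_rate_bounds()) {
  objective <- match.arg(objective)
  lo <- bounds[, "lower"]; hi <- bounds[, "upper"]
  base <- switch(objective,
    S = ,
    T = as_compound_rates(lo[["alpha"]], lo[["beta"]], hi[["gamma"]],
                          hi[["p1"]], hi[["p2"]], lo[["d1"]], lo[["d2"]],
                          hi[["r"]]),
    P = as_compound_rates(lo[["alpha"]], lo[["beta"]], hi[["gamma"]],
                          hi[["p1"]], hi[["p2"]], lo[["d1"]], lo[["d2"]],
                          lo[["r"]]),
    D = as_compound_rates(lo[["alpha"]], lo[["beta"]], lo[["gamma"]],
                          hi[["p1"]], hi[["p2"]], lo[["d1"]], lo[["d2"]],
                          lo[["r"]]))
  if (objective %in% c("P", "D")) {
    d1_rates <- base
    # d1* is determined with the progenitor objective (gamma at its max)
    d1_rates[["gamma"]] <- hi[["gamma"]]
    d1s <- interior_optimum("P", "d1", d1_rates,
                            bounds = bounds["d1", ])$optimum
    base[["d1"]] <- d1s
    if (objective == "D") {
      d2s <- interior_optimum("D", "d2", base,
                              bounds = bounds["d2", ])$optimum
      base[["d2"]] <- d2s
    }
  }
  base
}

#' Sensitivity signs of an equilibrium population
#'
#' Classifies the effect of each rate on the chosen equilibrium
#' population over its compound range, with the other rates held at the
#' supplied values: `increasing`, `decreasing`, `interior-max` (the sign
#' of the derivative changes inside the range) or `no-effect`.
#' Classification combines endpoint comparison with a bounded
#' maximisation to detect interior optima.
#'
#' @param objective One of `"S"`, `"P"`, `"D"`, `"T"`.
#' @param variant `"spd"` or `"pd"`.
#' @param rates Compound rate set giving the co-parameter values.
#' @param ranges Bounds matrix, default [compound_rate_bounds()].
#' @return Named character vector over the variant's rates.
#' @export
sensitivity_signs <- function(objective = c("S", "P", "D", "T"),
                              variant = c("spd", "pd"), rates,
                              ranges = compound_rate_bounds()) {
  objective <- match.arg(objective)
  variant <- match.arg(variant)
  pars <- if (variant == "pd") c("beta", "gamma", "p2", "d2") else .rate_names
  value_at <- function(rr) {
    fp <- if (variant == "pd") pd_fixed_point(rr) else
      spd_asymptote_fixed_point(rr)
    switch(objective, S = fp$S_star, P = fp$P_star, D = fp$D_star,
           T = fp$T_star)
  }
  out <- character(0)
  for (p in pars) {
    f <- function(x) {
      rr <- unclass(rates)
      rr[[p]] <- x
      value_at(rr)
    }
    lo <- ranges[p, "lower"]; hi <- ranges[p, "upper"]
    span <- hi - lo
    v_lo <- f(lo); v_hi <- f(hi); v_mid <- f((lo + hi) / 2)
    vref <- max(abs(c(v_lo, v_hi, v_mid)), 1e-300)
    if (max(abs(c(v_lo - v_hi, v_lo - v_mid))) < 1e-10 * vref) {
      out[p] <- "no-effect"
      next
    }
    # dense scan before refinement: golden search alone can miss a narrow
    # interior peak on a wide range
    grid <- seq(lo, hi, length.out = 1000L)
    gv <- vapply(grid, f, 0)
    i <- which.max(gv)
    opt <- stats::optimize(f, c(grid[max(1L, i - 1L)],
                                grid[min(length(grid), i + 1L)]),
                           maximum = TRUE, tol = 1e-9 * span)
    if (opt$maximum > lo + 1e-3 * span && opt$maximum < hi - 1e-3 * span &&
        opt$objective > max(v_lo, v_hi) * (1 + 1e-10)) {
      out[p] <- "interior-max"
    } else if (v_hi > v_lo) {
      out[p] <- "increasing"
    } else {
      out[p] <- "decreasing"
    }
  }
  out
}

#' Optimise the equilibrium over the oxygen level
#'
#' Holds waste and contact at the model's conventions (`W = 5`: zero
#' waste would be mathematically optimal, but 5% CO2 also buffers the
#' medium; `C = 3.75`: the contact at which the proliferation effect
#' peaks) and maximises the chosen equilibrium population over the
#' oxygen level by dense scan plus golden/Brent refinement. Rates named
#' in the coupling mode are fixed at their override values rather than
#' tracking oxygen. The optimum found with the fast asymptote fixed
#' point is re-evaluated with the numerically refined fixed point, and
#' both are reported.
#'
#' @param objective One of `"S"`, `"P"`, `"D"`, `"T"`.
#' @param exp_rates An [experimental_rates()] set.
#' @param mode Optional [coupling_mode()].
#' @param W,C Waste and contact conventions.
#' @param O_range Search interval for oxygen (percent).
#' @param n_grid Scan points before refinement.
#' @return List of class `"environment_optimum"` with `O_star`, the
#'   asymptote fixed point `fp_asymptote` and numeric fixed point
#'   `fp_numeric` at the optimum, plus the search metadata.
#' @export
optimize_environment <- function(objective = c("S", "P", "D", "T"),
                                 exp_rates, mode = NULL, W = 5, C = 3.75,
                                 O_range = c(0, 100), n_grid = 10001L) {
  objective <- match.arg(objective)
  value_of <- function(O) {
    cr <- compound_rates(exp_rates, environment_condition(O, W, C), mode)
    fp <- spd_asymptote_fixed_point(cr)
    switch(objective, S = fp$S_star, P = fp$P_star, D = fp$D_star,
           T = fp$T_star)
  }
  grid <- seq(O_range[1], O_range[2], length.out = n_grid)
  vals <- vapply(grid, value_of, 0)
  if (diff(range(vals)) < 1e-12 * max(abs(vals), 1e-300)) {
    warning("objective is flat in oxygen over the search range")
  }
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(n_grid, i + 1L)]
  opt <- stats::optimize(value_of, c(lo, hi), maximum = TRUE, tol = 1e-9)
  O_star <- opt$maximum
  cr <- compound_rates(exp_rates, environment_condition(O_star, W, C), mode)
  fp_a <- fixed_point_stability(spd_asymptote_fixed_point(cr), cr, "spd")
  fp_n <- fixed_point_stability(spd_numeric_fixed_point(cr), cr, "spd")
  structure(list(objective = objective, O_star = O_star, W = W, C = C,
                 mode = mode, rates_at_optimum = cr,
                 fp_asymptote = fp_a, fp_numeric = fp_n),
            class = "environment_optimum")
}

#' @export
print.environment_optimum <- function(x, ...) {
  cat(sprintf("optimal oxygen for %s*: O = %.4f%% (W = %g, C = %g)\n",
              x$objective, x$O_star, x$W, x$C))
  print(x$fp_numeric)
  invisible(x)
}
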