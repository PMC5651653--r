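# Environmental effect functions and compound rate assembly.
#
# Thirteen empirical effect functions modulate the eight baseline
# ("experimental") per-minute rates of the aggregate model. Effects f1-f5,
# f8 and f13 depend on local oxygen O (%), f6 and f7 on local waste
# (CO2 proxy) W (%), and f9-f12 on the cell-scaffold contact rate C
# (dimensionless). Values above 1 speed the affected process up, values
# below 1 slow it down.

.effect_funs <- list(
  f1  = function(O) 1 / (1 + 10 * O) - 0.3 * O * exp(-0.3 * O) + 1,
  f2  = function(O) 1 / (1 + 5 * O)  - 0.3 * O * exp(-0.3 * O) + 1,
  f3  = function(O) 1 / (1 + 2 * O)  - 0.5 * O * exp(-0.3 * O) + 1,
  f4  = function(O) (0.4 * O - 1) * (0.4 * O + 1) * exp(-0.5 * O) + 1.01,
  f5  = function(O) (0.6 * O - 1) * (0.6 * O + 1) * exp(-0.5 * O) + 1.01,
  f6  = function(W) (10 / 9) * (1 - 1 / (1 + exp(-0.1 * (W - 25)))),
  f7  = function(W) 1 + 1 / (1 + exp(-0.5 * (W - 16))),
  f8  = function(O) 15 / (O + 5),
  f9  = function(C) C / (C + 1),
  f10 = function(C) 4 * C^3 * exp(-0.5 - 0.8 * C),
  f11 = function(C) 200 / (200 + C),
  f12 = function(C) 100 / (100 + C),
  f13 = function(O) 1 / (1 + exp(-10 * (O - 0.25)))
)

#' Evaluate an environmental effect function
#'
#' The model carries thirteen effect functions that couple local oxygen
#' (`f1`-`f5`, `f8`, `f13`), waste (`f6`, `f7`) and cell-scaffold contact
#' (`f9`-`f12`) to the per-minute process rates. All are strictly positive
#' except `f6`, `f10` and `f13`, which approach zero asymptotically.
#'
#' @param effect_id Character, one of `"f1"` ... `"f13"`.
#' @param x Numeric vector of argument values (oxygen or waste in percent,
#'   or contact rate); must be finite and non-negative.
#' @return Numeric vector of effect values.
#' @examples
#' evaluate_effect("f8", 0)    # 3: maximal reversion boost under anoxia
#' evaluate_effect("f9", 1)    # 0.5: minimal contact effect
#' @export
evaluate_effect <- function(effect_id, x) {
  if (length(effect_id) != 1L || !effect_id %in% names(.effect_funs)) {
    stop("unknown effect_id: ", paste(effect_id, collapse = ", "),
         " (expected one of f1..f13)")
  }
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("'x' must be finite numeric")
  }
  if (any(x < 0)) {
    stop("'x' must be >= 0 for ", effect_id)
  }
  .effect_funs[[effect_id]](x)
}

#' Locate the extrema of an effect function on an interval
#'
#' Scans the effect on a dense uniform grid (default 10^4 points) and
#' refines the candidate minimum and maximum by golden-section/Brent search,
#' giving extrema to better than 1e-3 in argument and value. The effects
#' are smooth univariate functions, so no derivative bookkeeping is needed.
#'
#' @param effect_id Character, one of `"f1"` ... `"f13"`.
#' @param domain Numeric length-2 interval, e.g. `c(0, 100)` for oxygen or
#'   waste, `c(1, 10)` for the contact rate as used in the model. Note the
#'   reference extrema of the contact effects are tabulated on `[0, 100]`.
#' @param n_grid Number of scan points before refinement.
#' @return List with `argmin`, `min`, `argmax`, `max`.
#' @examples
#' effect_extrema("f10", c(0, 100))  # max ~ (3.75, 6.37)
#' effect_extrema("f1", c(0, 100))   # min ~ (3.57, 0.66)
#' @export
effect_extrema <- function(effect_id, domain, n_grid = 10000L) {
  if (length(domain) != 2L || !is.numeric(domain) || any(!is.finite(domain))) {
    stop("'domain' must be a finite numeric interval of length 2")
  }
  if (domain[1] >= domain[2]) {
    stop("empty or inverted domain: [", domain[1], ", ", domain[2], "]")
  }
  f <- .effect_funs[[match.arg(effect_id, names(.effect_funs))]]
  grid <- seq(domain[1], domain[2], length.out = n_grid)
  vals <- f(grid)
  refine <- function(i, maximum) {
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(n_grid, i + 1L)]
    if (lo == hi) {
      return(c(grid[i], vals[i]))
    }
    opt <- stats::optimize(f, c(lo, hi), maximum = maximum, tol = 1e-10)
    c(opt[[1L]], opt[[2L]])
  }
  mn <- refine(which.min(vals), maximum = FALSE)
  mx <- refine(which.max(vals), maximum = TRUE)
  list(argmin = mn[1], min = mn[2], argmax = mx[1], max = mx[2])
}

#' Environmental condition
#'
#' Bundle of the local oxygen concentration `O` (percent, 0-100), local
#' waste concentration `W` (percent, 0-100) and cell-scaffold contact rate
#' `C` (dimensionless). In the model `C` ranges over `[1, 10]`: 1 stands
#' for a 90% porous scaffold (below which aggregates do not adhere) and 10
#' for a solid scaffold.
#'
#' @param O Oxygen, percent in `[0, 100]`.
#' @param W Waste (CO2 proxy), percent in `[0, 100]`.
#' @param C Contact rate in `[1, 10]`.
#' @param wide Logical; relax the range checks to non-negativity only, for
#'   extremum scans over extended domains.
#' @return Object of class `"environment_condition"`.
#' @examples
#' environment_condition(O = 21, W = 5, C = 7.7)
#' @export
environment_condition <- function(O, W, C = 1, wide = FALSE) {
  for (v in list(O = O, W = W, C = C)) {
    if (length(v) != 1L || !is.finite(v)) {
      stop("O, W and C must be finite scalars")
    }
  }
  if (!wide) {
    if (O < 0 || O > 100) stop("oxygen O must lie in [0, 100], got ", O)
    if (W < 0 || W > 100) stop("waste W must lie in [0, 100], got ", W)
    if (C < 1 || C > 10)  stop("contact rate C must lie in [1, 10], got ", C)
  } else if (O < 0 || W < 0 || C < 0) {
    stop("O, W and C must be non-negative")
  }
  structure(list(O = O, W = W, C = C), class = "environment_condition")
}

#' @export
print.environment_condition <- function(x, ...) {
  cat(sprintf("environment: O = %g%%, W = %g%%, C = %g\n", x$O, x$W, x$C))
  invisible(x)
}

.rate_names <- c("alpha", "beta", "gamma", "p1", "p2", "d1", "d2", "r")

#' Experimental (baseline) per-minute rates
#'
#' The eight baseline rates of the model, before environmental modulation:
#' death rates `alpha` (stem), `beta` (progenitor), `gamma`
#' (differentiated); proliferation rates `p1` (stem), `p2` (progenitor);
#' differentiation rates `d1` (stem to progenitor), `d2` (progenitor to
#' differentiated); and the reversion rate `r` (progenitor back to stem).
#' Units are proportion per minute. Rate tables in configuration files are
#' conventionally stored in units of 1e-5 per minute; use `scale = 1e-5`
#' to enter values on that scale.
#'
#' @param alpha,beta,gamma,p1,p2,d1,d2,r Non-negative rates.
#' @param scale Multiplier applied to all eight values (default 1, i.e.
#'   values given directly in per-minute units).
#' @param warn_range Warn when a rate falls outside its calibrated
#'   experimental range (see [experimental_rate_ranges()]).
#' @return Object of class `"experimental_rates"` (named numeric vector).
#' @examples
#' # growth-optimised reference set, entered on the 1e-5 scale
#' experimental_rates(alpha = 0.1, beta = 1.6, gamma = 2.6, p1 = 119,
#'                    p2 = 160, d1 = 10, d2 = 7.29, r = 17, scale = 1e-5)
#' @export
experimental_rates <- function(alpha, beta, gamma, p1, p2, d1, d2, r,
                               scale = 1, warn_range = FALSE) {
  x <- c(alpha = alpha, beta = beta, gamma = gamma, p1 = p1, p2 = p2,
         d1 = d1, d2 = d2, r = r) * scale
  if (any(!is.finite(x))) stop("all rates must be finite")
  if (any(x < 0)) {
    stop("negative rate(s): ", paste(names(x)[x < 0], collapse = ", "))
  }
  if (warn_range) {
    rng <- experimental_rate_ranges()
    out <- names(x)[x < rng[names(x), "lower"] | x > rng[names(x), "upper"]]
    if (length(out)) {
      warning("rate(s) outside the calibrated experimental range: ",
              paste(out, collapse = ", "))
    }
  }
  structure(x, class = "experimental_rates")
}

#' Calibrated experimental rate ranges
#'
#' Ranges (per minute) within which the eight baseline rates were
#' calibrated from culture data and literature. Useful for validation and
#' for drawing random parameter sets.
#'
#' @return Matrix with rows `alpha` ... `r` and columns `lower`, `upper`.
#' @export
experimental_rate_ranges <- function() {
  m <- matrix(c(0.1, 2.6,
                1.6, 2.6,
                1.6, 2.6,
                69, 120,
                45, 160,
                10, 17,
                7.3, 8.2,
                0.1, 17) * 1e-5,
              ncol = 2, byrow = TRUE,
              dimnames = list(.rate_names, c("lower", "upper")))
  m
}

#' Coupling mode: decoupling selected rates from the environment
#'
#' Differentiation (`d1`, `d2`) and reversion (`r`) can be controlled
#' chemically in culture, in which case they no longer track oxygen,
#' waste and contact. A coupling mode names the decoupled rates and gives
#' the fixed per-minute value that replaces the environment-derived one.
#'
#' @param ... Named per-minute values for the decoupled rates; names must
#'   be among `d1`, `d2`, `r`.
#' @return Object of class `"coupling_mode"`.
#' @examples
#' coupling_mode(r = 51e-5)                    # reversion fixed chemically
#' coupling_mode(d1 = 5e-7, d2 = 3.645e-7, r = 51e-5)
#' @export
coupling_mode <- function(...) {
  overrides <- c(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("all overrides must be named")
    }
    bad <- setdiff(names(overrides), c("d1", "d2", "r"))
    if (length(bad)) {
      stop("only d1, d2 and r can be decoupled; got: ",
           paste(bad, collapse = ", "))
    }
    if (anyDuplicated(names(overrides))) stop("duplicate override names")
    if (any(!is.finite(overrides)) || any(overrides < 0)) {
      stop("override values must be finite and non-negative")
    }
  }
  structure(list(decoupled = names(overrides),
                 overrides = overrides),
            class = "coupling_mode")
}

#' Compound (environment-modulated) rates
#'
#' Multiplies each baseline rate by its product of effect functions at the
#' given environment: `alpha = alpha_bar f1(O) f7(W)`,
#' `beta = beta_bar f2 f7`, `gamma = gamma_bar f3 f7`,
#' `p1 = p1_bar f5 f6 f10`, `p2 = p2_bar f5 f6 f10`,
#' `d1 = d1_bar f4 f9`, `d2 = d2_bar f4 f9` and `r` equal to
#' `r_bar f8(O)`.
#' Rates named in the coupling mode are replaced by their fixed override
#' values instead.
#'
#' @param exp_rates An [experimental_rates()] object.
#' @param env An [environment_condition()].
#' @param mode Optional [coupling_mode()].
#' @return Object of class `"compound_rates"` (named numeric vector) with
#'   the environment and mode attached as attributes.
#' @export
compound_rates <- function(exp_rates, env, mode = NULL) {
  stopifnot(inherits(exp_rates, "experimental_rates"),
            inherits(env, "environment_condition"))
  O <- env$O; W <- env$W; C <- env$C
  eff <- c(alpha = .effect_funs$f1(O) * .effect_funs$f7(W),
           beta  = .effect_funs$f2(O) * .effect_funs$f7(W),
           gamma = .effect_funs$f3(O) * .effect_funs$f7(W),
           p1    = .effect_funs$f5(O) * .effect_funs$f6(W) * .effect_funs$f10(C),
           p2    = .effect_funs$f5(O) * .effect_funs$f6(W) * .effect_funs$f10(C),
           d1    = .effect_funs$f4(O) * .effect_funs$f9(C),
           d2    = .effect_funs$f4(O) * .effect_funs$f9(C),
           r     = .effect_funs$f8(O))
  x <- unclass(exp_rates) * eff
  if (!is.null(mode)) {
    stopifnot(inherits(mode, "coupling_mode"))
    x[mode$decoupled] <- mode$overrides[mode$decoupled]
  }
  structure(x, class = "compound_rates", environment = env, mode = mode)
}

#' Construct compound rates directly
#'
#' Wraps a set of per-minute rates already on the compound scale (for
#' instance the bounds returned by [compound_rate_bounds()], or rates
#' drawn for a recovery study) in the class used throughout the package.
#'
#' @inheritParams experimental_rates
#' @return Object of class `"compound_rates"`.
#' @export
as_compound_rates <- function(alpha, beta, gamma, p1, p2, d1, d2, r) {
  x <- c(alpha = alpha, beta = beta, gamma = gamma, p1 = p1, p2 = p2,
         d1 = d1, d2 = d2, r = r)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("compound rates must be finite and non-negative")
  }
  structure(x, class = "compound_rates")
}

#' @export
print.compound_rates <- function(x, ...) {
  cat("compound per-minute rates:\n")
  print(format(unclass(x), digits = 6), quote = FALSE)
  invisible(x)
}

#' Contact rate implied by scaffold porosity
#'
#' The cell-scaffold contact rate is an affine, decreasing function of
#' porosity: `C = (100 - porosity) * 0.1`, where the factor 0.1 is the
#' maximum possible proportion of aggregate cells in contact with the
#' scaffold (the aggregate is roughly spherical). Porosities above 90%
#' give sub-unit contact, which represents non-adherence: the value is
#' clamped to 1 and flagged with a warning, since aggregates fall through
#' the gaps of such scaffolds and the model is undefined there.
#'
#' @param porosity Scaffold porosity, percent in `[0, 100]`.
#' @return Contact rate `C`, clamped to `[1, 10]`, with attribute
#'   `adherent = FALSE` when clamping occurred.
#' @examples
#' contact_from_porosity(23)  # 7.7
#' contact_from_porosity(40)  # 6.0
#' contact_from_porosity(0)   # 10: solid scaffold
#' @export
contact_from_porosity <- function(porosity) {
  if (length(porosity) != 1L || !is.finite(porosity) ||
      porosity < 0 || porosity > 100) {
    stop("porosity must be a percentage in [0, 100]")
  }
  C <- (100 - porosity) * 0.1
  if (C < 1) {
    warning("porosity ", porosity,
            "% implies contact below 1: aggregates do not adhere; ",
            "returning C = 1")
    return(structure(1, adherent = FALSE))
  }
  C
}

#' Compound rate bounds
#'
#' The box constraints used for optimization over the compound parameter
#' space: each bound is the corresponding experimental-rate bound times
#' the extreme value of its effect product over the environmental domain
#' (oxygen and waste over `[0, 100]`; contact over `[0, 100]`, the domain
#' on which the contact-effect extrema are tabulated). Effect extrema are
#' computed from the formulas at full precision rather than from rounded
#' tabulations, with one exception: the proliferation-effect product
#' `f5 f6 f10` is capped at 11.81, the model's calibrated operating bound
#' for that product.
#'
#' @return Matrix with rows `alpha` ... `r` and columns `lower`, `upper`
#'   (per-minute units).
#' @export
compound_rate_bounds <- function() {
  exp_rng <- experimental_rate_ranges()
  f <- .effect_funs
  f1min <- effect_extrema("f1", c(0, 100))$min
  f2min <- effect_extrema("f2", c(0, 100))$min
  f3min <- effect_extrema("f3", c(0, 100))$min
  f4max <- effect_extrema("f4", c(0, 100))$max
  f7min <- f$f7(0); f7max <- f$f7(100)
  prolif_cap <- 11.81
  surv_eff <- function(fmin) c(fmin * f7min, 2 * f7max)
  d_eff <- c(0.01 * 0.5, f4max * f$f9(100))
  r_eff <- c(f$f8(100), f$f8(0))
  eff <- rbind(alpha = surv_eff(f1min),
               beta  = surv_eff(f2min),
               gamma = surv_eff(f3min),
               p1    = c(0, prolif_cap),
               p2    = c(0, prolif_cap),
               d1    = d_eff,
               d2    = d_eff,
               r     = r_eff)
  m <- exp_rng * eff
  colnames(m) <- c("lower", "upper")
  m
}
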