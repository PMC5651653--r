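# Fixed points, Jacobians and stability for the PD and SPD systems.
#
# The PD system has a closed-form positive fixed point whenever
# 2 p2 > beta + d2. The SPD fixed points are intersections of two
# hyperbolic nullclines in the (P, S) plane; the positive intersection is
# approximated in closed form by intersecting the large-P asymptotes of
# the nullclines, and refined numerically by damped Newton iteration on
# the full nullcline system.

#' Fixed-point report
#'
#' Internal constructor for the common return shape of the fixed-point
#' routines.
#'
#' @keywords internal
.fixed_point <- function(S, P, D, method, O = NA_real_, W = NA_real_) {
  structure(list(S_star = S, P_star = P, D_star = D, T_star = S + P + D,
                 O_star = O, W_star = W, method = method,
                 stable = NA, eigenvalues = NULL),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(sprintf(
    "fixed point (%s): S* = %.4g, P* = %.4g, D* = %.4g, T* = %.4g\n",
    x$method, x$S_star, x$P_star, x$D_star, x$T_star))
  if (!is.na(x$stable)) {
    cat("  stability:", if (isTRUE(x$stable)) "stable" else
      if (identical(x$stable, "marginal")) "marginal" else "unstable", "\n")
  }
  invisible(x)
}

.check_rates <- function(rates, need) {
  if (!all(need %in% names(rates))) {
    stop("rates must contain: ", paste(need, collapse = ", "))
  }
  if (any(rates[need] < 0)) stop("rates must be non-negative")
}

#' Closed-form fixed point of the PD system
#'
#' The progenitor-differentiated system has a unique positive fixed point
#' if and only if `2 p2 > beta + d2`:
#' `P* = gamma (2 p2 - beta - d2) / ((beta + d2)(gamma + d2))`,
#' `D* = d2 (2 p2 - beta - d2) / ((beta + d2)(gamma + d2))`,
#' `T* = 2 p2 / (beta + d2) - 1`. Below the threshold only the stable
#' zero fixed point exists and all cultures decay to extinction.
#'
#' @param rates Named rates containing `beta`, `gamma`, `p2`, `d2`
#'   (a `compound_rates` vector works; `alpha`, `p1`, `d1`, `r` are
#'   ignored).
#' @return A `"fixed_point"` (method `"closed_form"`) with `exists`
#'   attribute; when the positive fixed point does not exist the zero
#'   state is returned with `stable = TRUE`.
#' @export
pd_fixed_point <- function(rates) {
  .check_rates(rates, c("beta", "gamma", "p2", "d2"))
  b <- rates[["beta"]]; g <- rates[["gamma"]]
  p2 <- rates[["p2"]]; d2 <- rates[["d2"]]
  if (b + d2 <= 0 || g + d2 <= 0 || g <= 0) {
    stop("beta + d2 and gamma must be positive")
  }
  margin <- 2 * p2 - (b + d2)
  if (margin <= 0) {
    fp <- .fixed_point(0, 0, 0, "closed_form")
    fp$stable <- TRUE
    attr(fp, "exists") <- FALSE
    return(fp)
  }
  P <- g * margin / ((b + d2) * (g + d2))
  D <- d2 * margin / ((b + d2) * (g + d2))
  fp <- .fixed_point(0, P, D, "closed_form")
  fp$stable <- TRUE  # globally stable within the invariant region
  attr(fp, "exists") <- TRUE
  fp
}

#' Optimal progenitor differentiation rate for the PD system
#'
#' Closed-form maximiser of the differentiated-cell equilibrium `D*`
#' over `d2`:
#' `d2* = (-beta gamma + sqrt(beta^2 gamma^2 +
#'         beta gamma (2 p2 + gamma)(2 p2 - beta))) / (2 p2 + gamma)`.
#' The optimum is interior because differentiation is terminal: pushing
#' progenitors out too fast starves the pool that produces them.
#'
#' @param rates Named rates containing `beta`, `gamma`, `p2`.
#' @return Optimal `d2` (per minute).
#' @export
pd_optimal_d2 <- function(rates) {
  .check_rates(rates, c("beta", "gamma", "p2"))
  b <- rates[["beta"]]; g <- rates[["gamma"]]; p2 <- rates[["p2"]]
  (-b * g + sqrt(b^2 * g^2 + b * g * (2 * p2 + g) * (2 * p2 - b))) /
    (2 * p2 + g)
}

#' Nullcline geometry of the SPD system
#'
#' After eliminating `D = d2 P / gamma`, the P-nullcline becomes the
#' hyperbola `S = P (a - b / (c + P))` with `a = (beta + r + d2) / d1`,
#' `c = gamma / (gamma + d2)` and `b = 2 p2 c / d1`; the S-nullcline is a
#' second hyperbola. Their large-P asymptotes are
#' `S1A = P a - 2 p2 gamma / (d1 (d2 + gamma))` and
#' `S2A = P r / (alpha + d1) + 2 p1 r gamma /
#'        ((alpha + d1)((alpha + d1)(gamma + d2) + r gamma))`.
#'
#' @param rates Full compound rate set.
#' @return List with the hyperbola constants `a`, `b`, `c` and the
#'   asymptote slopes/intercepts `S1A_slope`, `S1A_intercept`,
#'   `S2A_slope`, `S2A_intercept`.
#' @export
nullcline_geometry <- function(rates) {
  .check_rates(rates, .rate_names)
  al <- rates[["alpha"]]; b <- rates[["beta"]]; g <- rates[["gamma"]]
  p1 <- rates[["p1"]]; p2 <- rates[["p2"]]
  d1 <- rates[["d1"]]; d2 <- rates[["d2"]]; r <- rates[["r"]]
  if (d1 <= 0 || g + d2 <= 0) stop("d1 and gamma + d2 must be positive")
  a <- (b + r + d2) / d1
  cc <- g / (g + d2)
  bb <- 2 * p2 * cc / d1
  A <- al + d1
  list(a = a, b = bb, c = cc,
       S1A_slope = a,
       S1A_intercept = -2 * p2 * g / (d1 * (d2 + g)),
       S2A_slope = r / A,
       S2A_intercept = 2 * p1 * r * g / (A * (A * (g + d2) + r * g)))
}

#' Asymptote approximation to the positive SPD fixed point
#'
#' Intersects the large-P asymptotes of the two nullcline hyperbolas,
#' giving the explicit approximate equilibrium populations. The
#' approximation is accurate when the equilibrium progenitor population
#' is large (relative error falls as `P*` grows).
#'
#' @param rates Full compound rate set (a zero reversion rate is allowed
#'   and gives `S* = 0`).
#' @return A `"fixed_point"` with method `"asymptote"`.
#' @export
spd_asymptote_fixed_point <- function(rates) {
  .check_rates(rates, .rate_names)
  al <- rates[["alpha"]]; b <- rates[["beta"]]; g <- rates[["gamma"]]
  p1 <- rates[["p1"]]; p2 <- rates[["p2"]]
  d1 <- rates[["d1"]]; d2 <- rates[["d2"]]; r <- rates[["r"]]
  A <- al + d1
  if (g + d2 <= 0 || A <= 0 || g <= 0) {
    stop("degenerate rates: need alpha + d1 > 0, gamma > 0, gamma + d2 > 0")
  }
  den <- (A * (b + d2) + r * al) * (A * (g + d2) + r * g)
  if (den <= 0) stop("degenerate rates: zero nullcline denominator")
  S <- 2 * g * r * (p1 * (b + d2 + r) + p2 * (A + r * g / (g + d2))) / den
  P <- 2 * g * (p1 * r * d1 + p2 * A^2 + p2 * r * g * A / (g + d2)) / den
  D <- d2 * P / g
  .fixed_point(S, P, D, "asymptote")
}

#' Analytic Jacobian of a model variant
#'
#' @param variant `"pd"` or `"spd"` (the constant-environment systems).
#' @param state Named state vector (`S`, `P`, `D` or `P`, `D`).
#' @param rates Compound rate set.
#' @return The Jacobian matrix of the population equations.
#' @export
model_jacobian <- function(variant = c("spd", "pd"), state, rates) {
  variant <- match.arg(variant)
  b <- rates[["beta"]]; g <- rates[["gamma"]]
  p2 <- rates[["p2"]]; d2 <- rates[["d2"]]
  P <- state[["P"]]; D <- state[["D"]]
  if (variant == "pd") {
    q <- (1 + P + D)^2
    return(matrix(c(-b - d2 + 2 * p2 * (1 + D) / q, -2 * p2 * P / q,
                    d2, -g),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("P", "D"), c("P", "D"))))
  }
  al <- rates[["alpha"]]; p1 <- rates[["p1"]]
  d1 <- rates[["d1"]]; r <- rates[["r"]]
  S <- state[["S"]]
  qs <- (1 + S + P + D)^2
  qp <- (1 + P + D)^2
  matrix(c(2 * p1 * (1 + P + D) / qs - (al + d1),
           r - 2 * p1 * S / qs,
           -2 * p1 * S / qs,
           d1,
           2 * p2 * (1 + D) / qp - (b + d2 + r),
           -2 * p2 * P / qp,
           0, d2, -g),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("S", "P", "D"), c("S", "P", "D")))
}

#' Numerically refined positive SPD fixed point
#'
#' Damped Newton iteration on the steady-state equations, seeded at the
#' asymptote approximation (or a caller-supplied guess), with a fallback
#' coarse grid search over the positive quadrant if Newton leaves it.
#' Residuals are driven below `1e-10` relative to the population scale.
#'
#' @param rates Full compound rate set.
#' @param guess Optional named numeric `c(S=, P=, D=)` starting point.
#' @param max_iter Newton iteration cap.
#' @return A `"fixed_point"` with method `"numeric"`.
#' @export
spd_numeric_fixed_point <- function(rates, guess = NULL, max_iter = 200L) {
  .check_rates(rates, .rate_names)
  F <- function(y) .pop_deriv(y[1], y[2], y[3], rates, with_stem = TRUE)
  newton <- function(y) {
    for (i in seq_len(max_iter)) {
      fy <- F(y)
      scale <- max(1, max(abs(y)))
      rate_scale <- max(unclass(rates)[c("beta", "gamma", "d2")])
      if (max(abs(fy)) < 1e-10 * scale * rate_scale) {
        return(list(y = y, ok = TRUE))
      }
      J <- model_jacobian("spd", c(S = y[1], P = y[2], D = y[3]), rates)
      step <- tryCatch(solve(J, -fy), error = function(e) NULL)
      if (is.null(step)) return(list(y = y, ok = FALSE))
      lam <- 1
      repeat {
        y_new <- y + lam * step
        if (all(y_new > 0) &&
            sum(F(y_new)^2) < sum(fy^2) * (1 - 1e-4 * lam)^2 * 1.0001) break
        lam <- lam / 2
        if (lam < 1e-10) return(list(y = y, ok = FALSE))
      }
      y <- unname(y_new)
    }
    list(y = y, ok = FALSE)
  }
  if (!is.null(guess)) {
    res <- newton(unname(guess[c("S", "P", "D")]))
    if (!res$ok) stop("Newton iteration failed from the supplied guess")
    return(.fixed_point(res$y[1], res$y[2], res$y[3], "numeric"))
  }

  al <- rates[["alpha"]]; g <- rates[["gamma"]]
  p1 <- rates[["p1"]]; d1 <- rates[["d1"]]
  d2 <- rates[["d2"]]; r <- rates[["r"]]
  fp0 <- spd_asymptote_fixed_point(rates)

  if (r == 0) {
    # the S equation decouples: S* = 0 and (P, D) solve the PD problem
    pd <- pd_fixed_point(rates)
    res <- newton(pmax(c(1e-12, pd$P_star, pd$D_star), 1e-12))
    if (res$ok) return(.fixed_point(0, res$y[2], res$y[3], "numeric"))
  }

  # reduce along the nullclines: D = d2 P / gamma and, on the P-nullcline,
  # S = P (a - b / (c + P)); the S equation then becomes scalar in P.
  ng <- nullcline_geometry(rates)
  S_of_P <- function(P) P * (ng$a - ng$b / (ng$c + P))
  g_of_P <- function(P) {
    S <- S_of_P(P)
    D <- d2 * P / g
    -(al + d1) * S + 2 * p1 * S / (1 + S + P + D) + r * P
  }
  P_seed <- max(fp0$P_star, 1e-6)
  Ps <- P_seed * 10^seq(-4, 4, length.out = 800L)
  Ps <- Ps[S_of_P(Ps) >= 0]
  root <- NA_real_
  if (length(Ps) > 1L) {
    gv <- vapply(Ps, g_of_P, 0)
    sgn <- sign(gv)
    flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    if (length(flips)) {
      cand <- vapply(flips, function(i) {
        stats::uniroot(g_of_P, c(Ps[i], Ps[i + 1L]), tol = 1e-14)$root
      }, 0)
      root <- cand[which.min(abs(log(cand / P_seed)))]
    }
  }
  seed <- if (is.finite(root)) {
    pmax(c(S_of_P(root), root, d2 * root / g), 1e-12)
  } else {
    pmax(c(fp0$S_star, fp0$P_star, fp0$D_star), 1e-8)
  }
  res <- newton(seed)
  if (!res$ok || (sum(res$y) < 1 && sum(seed) > 1)) {
    # last resort: relax along the flow toward the stable equilibrium
    y <- pmax(seed, 1e-3)
    for (k in 1:12) {
      traj <- simulate_population("spd", c(S = y[1], P = y[2], D = y[3]),
                                  rates, days = 2000,
                                  grid_minutes = 2000 * 1440)
      y_new <- as.numeric(traj[nrow(traj), c("S", "P", "D")])
      conv <- max(abs(y_new - y)) < 1e-8 * max(1, max(y_new))
      y <- y_new
      if (conv) break
    }
    res <- newton(pmax(y, 1e-12))
    if (!res$ok) stop("Newton iteration failed to converge to a fixed point")
  }
  .fixed_point(res$y[1], res$y[2], res$y[3], "numeric")
}

#' Routh-Hurwitz stability of the extinction state (SPD)
#'
#' The zero fixed point is stable when both
#' `2 p1 + 2 p2 < alpha + beta + d1 + d2 + r` and
#' `(2 p1 - alpha - d1)(2 p2 - beta - d2) > (2 p1 - alpha) r`,
#' and unstable when either inequality is reversed. Stability requires
#' low proliferation; the three qualitative routes to a stable
#' extinction state are also reported: (1) both proliferation rates
#' small (`2 p1 < alpha` and `2 p2 < beta + d2`); (2) progenitor
#' proliferation high but reversion large enough; (3) stem proliferation
#' moderately high (`alpha < 2 p1 < alpha + d1`) and reversion small
#' enough.
#'
#' @param rates Full compound rate set.
#' @return List with `stable`, the two Routh-Hurwitz conditions
#'   `trace_condition` and `product_condition`, and `case`
#'   (1, 2, 3 or `NA` when unstable).
#' @export
spd_zero_stability <- function(rates) {
  .check_rates(rates, .rate_names)
  al <- rates[["alpha"]]; b <- rates[["beta"]]
  p1 <- rates[["p1"]]; p2 <- rates[["p2"]]
  d1 <- rates[["d1"]]; d2 <- rates[["d2"]]; r <- rates[["r"]]
  cond1 <- 2 * p1 + 2 * p2 < al + b + d1 + d2 + r
  cond2 <- (2 * p1 - al - d1) * (2 * p2 - b - d2) > (2 * p1 - al) * r
  stable <- cond1 && cond2
  case <- NA_integer_
  if (stable) {
    if (2 * p1 < al && 2 * p2 < b + d2) {
      case <- 1L
    } else if (2 * p1 < al && 2 * p2 > b + d2 &&
               r > (2 * p2 - b - d2) * (d1 / (al - 2 * p1) + 1)) {
      case <- 2L
    } else if (al < 2 * p1 && 2 * p1 < al + d1 && 2 * p2 < b + d2 &&
               r < (b + d2 - 2 * p2) * (d1 / (2 * p1 - al) - 1)) {
      case <- 3L
    }
  }
  list(stable = stable, trace_condition = cond1, product_condition = cond2,
       case = case)
}

#' Eigenvalue stability of a fixed point
#'
#' Classifies a fixed point by the real parts of the eigenvalues of the
#' analytic Jacobian. Real parts within `tol` of zero give the verdict
#' `"marginal"` rather than being silently rounded.
#'
#' @param fp A `"fixed_point"` (or named state vector).
#' @param rates Compound rate set.
#' @param variant `"spd"` or `"pd"`.
#' @param tol Marginality tolerance on eigenvalue real parts.
#' @return The `fp` with `stable` (`TRUE`, `FALSE` or `"marginal"`) and
#'   `eigenvalues` filled in; a bare state vector returns the same
#'   information as a list.
#' @export
fixed_point_stability <- function(fp, rates, variant = c("spd", "pd"),
                                  tol = 1e-12) {
  variant <- match.arg(variant)
  state <- if (inherits(fp, "fixed_point")) {
    c(S = fp$S_star, P = fp$P_star, D = fp$D_star)
  } else {
    fp
  }
  J <- model_jacobian(variant, state, rates)
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  verdict <- if (any(abs(re) <= tol)) "marginal" else all(re < 0)
  if (inherits(fp, "fixed_point")) {
    fp$stable <- verdict
    fp$eigenvalues <- ev
    fp
  } else {
    list(stable = verdict, eigenvalues = ev)
  }
}

#' Air levels sustaining a target local environment at equilibrium
#'
#' At a population equilibrium the oxygen consumed by the cells must be
#' resupplied by diffusion, and the waste produced must be removed. Since
#' the flux is linear in the air-interface level, the required `O_air`
#' and `W_air` solve linear balance equations with the populations held
#' frozen at their equilibrium values:
#' `f13(O) (u1 S + u2 P + u3 D) = flux_O(O, O_air)` and
#' `f13(O) (w1 S + w2 P + w3 D) = -flux_W(W, W_air)`.
#'
#' @param S,P,D Equilibrium populations (cells).
#' @param O,W Target local levels, percent.
#' @param metabolic A [metabolic_rates()] set.
#' @param geometry A [culture_geometry()].
#' @param C Contact rate.
#' @param attenuation See [gas_flux()].
#' @return List with `O_air`, `W_air` and `feasible` (both within
#'   `[0, 100]`).
#' @export
solve_air_levels <- function(S, P, D, O, W,
                             metabolic = metabolic_rates(),
                             geometry = culture_geometry(), C = 1,
                             attenuation = "f11f12") {
  if (min(O, W) < 0 || max(O, W) > 100) {
    stop("target levels must lie in [0, 100]")
  }
  total <- S + P + D
  if (total == 0) {
    # nothing consumes or produces: the medium equilibrates with the air
    return(list(O_air = O, W_air = W, feasible = TRUE))
  }
  f13 <- .effect_funs$f13(O)
  uptake <- f13 * (metabolic$u1 * S + metabolic$u2 * P + metabolic$u3 * D)
  prod_w <- f13 * (metabolic$w1 * S + metabolic$w2 * P + metabolic$w3 * D)
  # flux per unit air-minus-local difference
  slope_O <- gas_flux("O", 0, 1, total, geometry, C, attenuation)
  slope_W <- gas_flux("W", 0, 1, total, geometry, C, attenuation)
  O_air <- O + uptake / slope_O
  W_air <- W - prod_w / slope_W
  feasible <- O_air >= 0 && O_air <= 100 && W_air >= 0 && W_air <= 100
  if (!feasible) {
    warning("required air level outside [0, 100]: infeasible target")
  }
  list(O_air = O_air, W_air = W_air, feasible = feasible)
}
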