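# Right-hand sides and time integration for the four model variants:
#   PD     progenitor + differentiated cells, constant environment
#   PDOW   PD plus local oxygen and waste dynamics
#   SPD    stem + progenitor + differentiated, constant environment
#   SPDOW  the full five-variable system
#
# Populations are in cells, gas levels in percent, time in minutes.
# Proliferation of each compartment is inhibited by its own and all later
# compartments through a saturating 2p/(1 + crowd) term; with constant
# environment the per-minute rates are constants, while in the *OW
# variants they are recomputed from the instantaneous O and W at every
# derivative evaluation.

.variants <- c("pd", "pdow", "spd", "spdow")

.variant_states <- list(
  pd    = c("P", "D"),
  pdow  = c("P", "D", "O", "W"),
  spd   = c("S", "P", "D"),
  spdow = c("S", "P", "D", "O", "W")
)

# population part of the derivative; cr is a compound_rates vector
.pop_deriv <- function(S, P, D, cr, with_stem) {
  if (with_stem) {
    dS <- -cr[["alpha"]] * S - cr[["d1"]] * S +
      2 * cr[["p1"]] * S / (1 + S + P + D) + cr[["r"]] * P
    dP <- -cr[["beta"]] * P - cr[["d2"]] * P - cr[["r"]] * P +
      2 * cr[["p2"]] * P / (1 + P + D) + cr[["d1"]] * S
  } else {
    dS <- 0
    dP <- -cr[["beta"]] * P - cr[["d2"]] * P +
      2 * cr[["p2"]] * P / (1 + P + D)
  }
  dD <- -cr[["gamma"]] * D + cr[["d2"]] * P
  c(dS, dP, dD)
}

#' Model right-hand side
#'
#' Derivative vector of the chosen variant at a given state. For the
#' `*ow` variants the compound rates are re-derived from the
#' instantaneous oxygen and waste, oxygen consumption and waste
#' production are scaled by `f13(O)` (metabolic shutdown under anoxia),
#' and gas exchange with the air above the medium enters through
#' [gas_flux()].
#'
#' @param variant One of `"pd"`, `"pdow"`, `"spd"`, `"spdow"`.
#' @param state Named numeric state: `P`, `D` (plus `S` for the stem
#'   variants, plus `O`, `W` for the `*ow` variants).
#' @param rates A `compound_rates` vector (constant-environment variants)
#'   or an [experimental_rates()] set, which the `*ow` variants combine
#'   with the instantaneous environment.
#' @param env [environment_condition()]; supplies `C` always, and the
#'   constant `O`, `W` when `rates` is an `experimental_rates` set used
#'   with a constant-environment variant.
#' @param mode Optional [coupling_mode()] applied when rates are
#'   re-derived.
#' @param air Named vector `c(O = , W = )` of air-interface levels
#'   (required for the `*ow` variants).
#' @param metabolic A [metabolic_rates()] set (`*ow` variants).
#' @param geometry A [culture_geometry()] (`*ow` variants).
#' @param attenuation Scaffold diffusion-attenuation convention, see
#'   [gas_flux()].
#' @return Named derivative vector matching `state`.
#' @export
model_rhs <- function(variant = .variants, state, rates, env = NULL,
                      mode = NULL, air = NULL,
                      metabolic = metabolic_rates(),
                      geometry = culture_geometry(),
                      attenuation = "f11f12") {
  variant <- match.arg(variant)
  need <- .variant_states[[variant]]
  if (!all(need %in% names(state))) {
    stop("state for variant '", variant, "' must contain: ",
         paste(need, collapse = ", "))
  }
  state <- state[need]
  pops <- intersect(c("S", "P", "D"), need)
  # adaptive solvers probe marginally negative trial states; the raw ODE
  # extends smoothly there, so only substantial negativity is an error
  if (any(state[pops] < -1e-6)) stop("negative population in state")
  with_stem <- "S" %in% need
  with_ow <- "O" %in% need

  S <- if (with_stem) state[["S"]] else 0
  P <- state[["P"]]; D <- state[["D"]]

  if (with_ow) {
    O <- min(max(state[["O"]], 0), 100)
    W <- min(max(state[["W"]], 0), 100)
    if (is.null(env) || is.null(air)) {
      stop("'env' (for C) and 'air' are required for the *ow variants")
    }
    cr <- compound_rates(rates,
                         environment_condition(O, W, env$C),
                         mode)
  } else if (inherits(rates, "compound_rates")) {
    cr <- rates
  } else {
    if (is.null(env)) stop("'env' is required to compound experimental rates")
    cr <- compound_rates(rates, env, mode)
  }

  dpop <- .pop_deriv(S, P, D, cr, with_stem)
  out <- if (with_stem) c(S = dpop[1], P = dpop[2], D = dpop[3]) else
    c(P = dpop[2], D = dpop[3])

  if (with_ow) {
    f13 <- .effect_funs$f13(O)
    total <- S + P + D
    uptake <- f13 * (metabolic$u1 * S + metabolic$u2 * P + metabolic$u3 * D)
    prod_w <- f13 * (metabolic$w1 * S + metabolic$w2 * P + metabolic$w3 * D)
    oflux <- gas_flux("O", O, air[["O"]], total, geometry, env$C, attenuation)
    wflux <- gas_flux("W", W, air[["W"]], total, geometry, env$C, attenuation)
    dO <- -uptake + oflux
    dW <- prod_w + wflux
    # hard clamp: percentages cannot leave [0, 100]
    if ((state[["O"]] <= 0 && dO < 0) || (state[["O"]] >= 100 && dO > 0)) dO <- 0
    if ((state[["W"]] <= 0 && dW < 0) || (state[["W"]] >= 100 && dW > 0)) dW <- 0
    out <- c(out, O = dO, W = dW)
  }
  out
}

#' Integrate the model
#'
#' Stiff-capable adaptive integration (`deSolve::ode`, `lsoda`) of the
#' chosen variant, reported on a regular output grid (daily by default).
#' Tiny negative populations produced by the solver (above `-1e-6` cells)
#' are zeroed; anything more negative aborts.
#'
#' @inheritParams model_rhs
#' @param initial Named initial state (see [model_rhs()]); `O` and `W`
#'   default to the air levels when omitted in the `*ow` variants.
#' @param days Simulation horizon in days (1 day = 1440 minutes).
#' @param grid_minutes Output spacing in minutes.
#' @param rtol,atol Solver tolerances.
#' @return A `data.frame` of class `"trajectory"` with columns `t_min`,
#'   `day`, the state variables, `total` and `area_mm2`, plus metadata
#'   attributes (`variant`, `rates`, `env`, `air`).
#' @examples
#' cr <- as_compound_rates(alpha = 1e-6, beta = 1.1e-5, gamma = 2e-5,
#'                         p1 = 1e-3, p2 = 2e-3, d1 = 1e-6, d2 = 5e-6,
#'                         r = 1e-6)
#' traj <- simulate_population("spd", c(S = 0, P = 5000, D = 0), cr,
#'                             days = 12)
#' @export
simulate_population <- function(variant = .variants, initial, rates,
                                days, env = NULL, mode = NULL, air = NULL,
                                metabolic = metabolic_rates(),
                                geometry = culture_geometry(),
                                attenuation = "f11f12",
                                grid_minutes = 1440,
                                rtol = 1e-8, atol = 1e-8) {
  variant <- match.arg(variant)
  if (!is.finite(days) || days <= 0) stop("'days' must be > 0")
  need <- .variant_states[[variant]]
  with_ow <- "O" %in% need
  if (with_ow) {
    if (is.null(air)) stop("'air' levels are required for the *ow variants")
    if (!("O" %in% names(initial))) initial <- c(initial, O = air[["O"]])
    if (!("W" %in% names(initial))) initial <- c(initial, W = air[["W"]])
  }
  miss <- setdiff(need, names(initial))
  if (length(miss)) {
    initial <- c(initial, stats::setNames(rep(0, length(miss)), miss))
  }
  y0 <- initial[need]
  if (any(y0[intersect(c("S", "P", "D"), need)] < 0)) {
    stop("negative initial population")
  }

  times <- unique(c(seq(0, days * 1440, by = grid_minutes), days * 1440))
  pops_idx <- which(need %in% c("S", "P", "D"))
  deriv <- function(t, y, parms) {
    # clamp marginally negative trial states: the projection keeps
    # adaptive steps well-behaved near extinction
    y[pops_idx] <- pmax(y[pops_idx], 0)
    list(model_rhs(variant, y, rates, env = env, mode = mode, air = air,
                   metabolic = metabolic, geometry = geometry,
                   attenuation = attenuation))
  }
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  sol <- as.data.frame(sol)
  pops <- intersect(c("S", "P", "D"), need)
  pop_vals <- as.matrix(sol[pops])
  if (any(pop_vals < -1e-6)) {
    stop("integration produced a substantially negative population; ",
         "check rates and tolerances")
  }
  pop_vals[pop_vals < 0] <- 0
  sol[pops] <- pop_vals
  if (with_ow) {
    sol$O <- pmin(pmax(sol$O, 0), 100)
    sol$W <- pmin(pmax(sol$W, 0), 100)
  }
  total <- rowSums(sol[, pops, drop = FALSE])
  out <- data.frame(t_min = sol$time, day = sol$time / 1440)
  out <- cbind(out, sol[need])
  out$total <- total
  out$area_mm2 <- area_from_population(total)
  structure(out,
            class = c("trajectory", "data.frame"),
            variant = variant, rates = rates, env = env, air = air)
}

#' Check the invariant region of the progenitor-differentiated system
#'
#' For the PD system the box `P <= 2 p2 / (beta + d2)`,
#' `D <= 2 p2 d2 / (gamma (beta + d2))` is forward-invariant, and
#' trajectories starting outside it fall into it. This verifies a
#' trajectory against that property: once a sample point is inside the
#' box, all later points must remain inside (up to a small numerical
#' tolerance).
#'
#' @param traj A `"trajectory"` from [simulate_population()] (variants
#'   `pd` or `pdow`).
#' @param rates The compound rates used for the run.
#' @param tol Relative tolerance on the bounds.
#' @return List with `compliant` (logical), the bounds `P_max`, `D_max`,
#'   and `first_violation` (row index, or `NA`).
#' @export
invariant_region_check <- function(traj, rates, tol = 1e-8) {
  if (!inherits(traj, "trajectory") ||
      !attr(traj, "variant") %in% c("pd", "pdow")) {
    stop("invariant_region_check applies to pd/pdow trajectories")
  }
  P_max <- 2 * rates[["p2"]] / (rates[["beta"]] + rates[["d2"]])
  D_max <- 2 * rates[["p2"]] * rates[["d2"]] /
    (rates[["gamma"]] * (rates[["beta"]] + rates[["d2"]]))
  if (nrow(traj) == 0L) {
    return(list(compliant = TRUE, P_max = P_max, D_max = D_max,
                first_violation = NA_integer_))
  }
  inside <- traj$P <= P_max * (1 + tol) & traj$D <= D_max * (1 + tol)
  entered <- cumsum(inside) > 0
  bad <- which(entered & !inside)
  list(compliant = length(bad) == 0L, P_max = P_max, D_max = D_max,
       first_violation = if (length(bad)) bad[1] else NA_integer_)
}
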