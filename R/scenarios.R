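# Named culture scenarios: porosity comparison, oxygen comparison, and
# the two-stage expand-then-differentiate strategy.

#' Scenario configuration
#'
#' Bundles everything needed to run one simulation scenario: variant,
#' initial populations, baseline rates, environment, one contact rate or
#' a pair to compare, the horizon, and an optional parameter switch
#' applied at the start from a precomputed state.
#'
#' @param name Scenario label.
#' @param variant Model variant, see [simulate_population()].
#' @param initial Named initial populations.
#' @param exp_rates An [experimental_rates()] set.
#' @param O,W Constant local environment (constant-environment variants)
#'   or initial levels (`*ow` variants).
#' @param C Contact rate, or length-2 vector to compare two scaffolds.
#' @param porosity Alternative to `C`: scaffold porosity in percent
#'   (scalar or length 2), resolved through [contact_from_porosity()].
#'   Supply `C` or `porosity`, not both.
#' @param days Horizon in days.
#' @param mode Optional [coupling_mode()].
#' @param air Optional air levels for the `*ow` variants.
#' @param O_pair Optional length-2 oxygen comparison (overrides `O`).
#' @return Object of class `"scenario_config"`.
#' @export
scenario_config <- function(name, variant, initial, exp_rates,
                            O = 21, W = 5, C = NULL, porosity = NULL,
                            days = 12, mode = NULL, air = NULL,
                            O_pair = NULL) {
  if (!is.null(C) && !is.null(porosity)) {
    stop("supply either 'C' or 'porosity', not both")
  }
  if (is.null(C)) {
    if (is.null(porosity)) stop("one of 'C' or 'porosity' is required")
    C <- vapply(porosity, function(p) as.numeric(contact_from_porosity(p)), 0)
  }
  stopifnot(inherits(exp_rates, "experimental_rates"))
  structure(list(name = name, variant = variant, initial = initial,
                 exp_rates = exp_rates, O = O, W = W, C = C,
                 days = days, mode = mode, air = air, O_pair = O_pair),
            class = "scenario_config")
}

#' Canonical scenarios
#'
#' Three reference scenarios for seeded neural aggregates:
#'
#' * `porosity_comparison_scenario()`: 5000 progenitor cells at ambient
#'   oxygen (21%), compared across 23% porosity (`C = 7.7`) and 40%
#'   porosity (`C = 6`) scaffolds. The less porous scaffold ends up with
#'   the smaller aggregate.
#' * `oxygen_comparison_scenario()`: 5000 stem cells on a solid scaffold
#'   (`C = 10`), ambient (21%) versus physiologic (5%) oxygen. Growth
#'   and differentiation are both larger at physiologic oxygen.
#' * `two_stage_scenario()`: expand the stem pool first at its optimal
#'   conditions (reversion and both differentiation rates fixed
#'   chemically), then switch the culture to the
#'   differentiated-cell-optimal conditions. The differentiated
#'   population overshoots its eventual equilibrium.
#'
#' @param days Horizon in days (the two-stage default is long enough to
#'   approach the post-switch equilibrium).
#' @return A `"scenario_config"`.
#' @export
porosity_comparison_scenario <- function(days = 12) {
  scenario_config("porosity comparison", "spd",
                  initial = c(S = 0, P = 5000, D = 0),
                  exp_rates = differentiation_experimental_rates(),
                  O = 21, W = 5, C = c(7.7, 6), days = days)
}

#' @rdname porosity_comparison_scenario
#' @export
oxygen_comparison_scenario <- function(days = 12) {
  scenario_config("oxygen comparison", "spd",
                  initial = c(S = 5000, P = 0, D = 0),
                  exp_rates = differentiation_experimental_rates(),
                  O = 21, W = 5, C = 10, days = days,
                  O_pair = c(21, 5))
}

#' @rdname porosity_comparison_scenario
#' @export
two_stage_scenario <- function(days = 4000) {
  # stage 1: stem-optimal culture with chemically fixed d1, d2, r
  stage1_mode <- coupling_mode(d1 = 0.05e-5, d2 = 0.03645e-5, r = 51e-5)
  stage1_opt <- optimize_environment("S", growth_experimental_rates(),
                                     mode = stage1_mode)
  start <- c(S = stage1_opt$fp_numeric$S_star,
             P = stage1_opt$fp_numeric$P_star,
             D = stage1_opt$fp_numeric$D_star)
  # stage 2: differentiated-cell-optimal conditions, d1, d2, r fixed at
  # their interior/extreme optima
  bounds <- compound_rate_bounds()
  d_opt <- optimal_compound_rates("D", bounds)
  stage2_mode <- coupling_mode(d1 = d_opt[["d1"]], d2 = d_opt[["d2"]],
                               r = bounds["r", "lower"])
  stage2_opt <- optimize_environment("D", differentiation_experimental_rates(),
                                     mode = stage2_mode)
  scenario_config("two-stage differentiation", "spd",
                  initial = start,
                  exp_rates = differentiation_experimental_rates(),
                  O = stage2_opt$O_star, W = 5, C = 3.75, days = days,
                  mode = stage2_mode)
}

#' Run a scenario
#'
#' Simulates the scenario for each contact rate (or oxygen level) it
#' compares and summarises the endpoint populations and aggregate area.
#'
#' @param cfg A `"scenario_config"`.
#' @param grid_minutes Output spacing, minutes.
#' @return List of class `"scenario_result"` with `trajectories` (one per
#'   compared condition, named) and `summary` (endpoint `data.frame`).
#' @export
run_scenario <- function(cfg, grid_minutes = 1440) {
  stopifnot(inherits(cfg, "scenario_config"))
  conds <- if (!is.null(cfg$O_pair)) {
    lapply(cfg$O_pair, function(o) list(O = o, C = cfg$C[1],
                                        label = paste0("O=", o)))
  } else {
    lapply(cfg$C, function(cc) list(O = cfg$O, C = cc,
                                    label = paste0("C=", cc)))
  }
  trajs <- list()
  rows <- list()
  for (cond in conds) {
    env <- environment_condition(cond$O, cfg$W, cond$C)
    traj <- simulate_population(cfg$variant, cfg$initial, cfg$exp_rates,
                                days = cfg$days, env = env, mode = cfg$mode,
                                air = cfg$air, grid_minutes = grid_minutes)
    trajs[[cond$label]] <- traj
    last <- traj[nrow(traj), ]
    rows[[cond$label]] <- data.frame(
      condition = cond$label, day = last$day,
      S = if ("S" %in% names(last)) last$S else 0,
      P = last$P, D = last$D, total = last$total,
      area_mm2 = last$area_mm2, peak_D = max(traj$D))
  }
  structure(list(name = cfg$name, trajectories = trajs,
                 summary = do.call(rbind, c(rows, make.row.names = FALSE))),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("scenario:", x$name, "\n")
  print(x$summary, digits = 5)
  invisible(x)
}
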