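# Synthetic daily area measurements and parameter-recovery utilities.
#
# No public repository of daily aggregate-area series exists, so every
# pipeline stage is exercised against synthetic data: a scenario is
# simulated, totals are converted to imaged cluster areas, and
# measurement noise is applied. All randomness flows through explicit
# seeds.

#' Measurement noise model
#'
#' Areas are positive and their measurement error scales with size, so
#' the default is multiplicative lognormal noise (`sd` interpreted as the
#' relative scale); `"additive-gaussian"` (`sd` in mm^2, values clamped
#' positive) is available for robustness checks.
#'
#' @param kind `"multiplicative-lognormal"` or `"additive-gaussian"`.
#' @param sd Noise scale (relative, or mm^2), `>= 0`.
#' @param seed Integer seed making generation reproducible.
#' @return Object of class `"noise_model"`.
#' @export
noise_model <- function(kind = c("multiplicative-lognormal",
                                 "additive-gaussian"),
                        sd = 0.05, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.finite(sd) || sd < 0) stop("'sd' must be >= 0")
  structure(list(kind = kind, sd = sd, seed = as.integer(seed)),
            class = "noise_model")
}

# run `expr` under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Apply measurement noise to an area series
#'
#' @param series An [area_series()].
#' @param noise A [noise_model()]; `sd = 0` returns the series unchanged.
#' @return A noisy `area_series` with the same layout.
#' @export
apply_area_noise <- function(series, noise) {
  stopifnot(inherits(series, "area_series"), inherits(noise, "noise_model"))
  if (noise$sd == 0) return(series)
  n <- nrow(series)
  a <- .with_seed(noise$seed, {
    if (noise$kind == "multiplicative-lognormal") {
      # mean-one multiplicative factors
      sdlog <- sqrt(log(1 + noise$sd^2))
      series$area_mm2 * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      pmax(series$area_mm2 + stats::rnorm(n, 0, noise$sd),
           .Machine$double.eps)
    }
  })
  series$area_mm2 <- a
  series
}

#' Generate a synthetic daily area series
#'
#' Simulates the scenario, converts the total population to cluster area
#' at the requested days, and applies measurement noise. With
#' `noise$sd = 0` the deterministic conversion of the trajectory is
#' returned.
#'
#' @param scenario A [scenario_config()] comparing a single condition.
#' @param noise A [noise_model()].
#' @param days Measurement days (default every second day to 12, the
#'   usual imaging cadence).
#' @param scaffold_label Label recorded in the series.
#' @return An [area_series()].
#' @export
generate_area_series <- function(scenario, noise = noise_model(sd = 0),
                                 days = seq(0, 12, by = 2),
                                 scaffold_label = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (length(scenario$C) != 1L || !is.null(scenario$O_pair)) {
    stop("generate_area_series needs a single-condition scenario")
  }
  if (is.null(scaffold_label)) scaffold_label <- scenario$name
  env <- environment_condition(scenario$O, scenario$W, scenario$C)
  traj <- simulate_population(scenario$variant, scenario$initial,
                              scenario$exp_rates,
                              days = max(days, scenario$days),
                              env = env, mode = scenario$mode,
                              air = scenario$air)
  idx <- match(days, traj$day)
  if (any(is.na(idx))) stop("requested days not on the trajectory grid")
  series <- area_series(days, traj$area_mm2[idx], scaffold_label)
  apply_area_noise(series, noise)
}

#' Fit the contact rate to an observed area series
#'
#' Least-squares recovery of the cell-scaffold contact rate `C` from a
#' daily area series, with all other rates and the environment known:
#' the scenario is simulated as a function of `C`, and the residual sum
#' of squares against the observed areas is minimised by a coarse scan
#' over the bounds followed by golden/Brent refinement (tolerance 1e-3).
#' The contact effect on proliferation is single-peaked, so the scan
#' guards against the two-sided ambiguity around its peak.
#'
#' @param series An [area_series()] with at least 4 time points.
#' @param exp_rates Known baseline rates.
#' @param O,W Known environment.
#' @param initial Known initial populations.
#' @param variant Model variant.
#' @param mode Optional [coupling_mode()].
#' @param bounds Search interval for `C`.
#' @return List with `C_hat`, `rss`, `rel_rms` (root-mean-square relative
#'   residual) and `identifiable` (`FALSE` when the residual is flat in
#'   `C` or no contact rate reproduces the series).
#' @export
fit_contact_rate <- function(series, exp_rates, O = 21, W = 5,
                             initial = c(S = 0, P = 5000, D = 0),
                             variant = "spd", mode = NULL,
                             bounds = c(1, 10)) {
  stopifnot(inherits(series, "area_series"))
  if (nrow(series) < 4L) stop("need at least 4 time points to fit C")
  days <- series$day
  obs <- series$area_mm2
  sim_areas <- function(C) {
    env <- environment_condition(O, W, C)
    traj <- simulate_population(variant, initial, exp_rates,
                                days = max(days), env = env, mode = mode)
    traj$area_mm2[match(days, traj$day)]
  }
  rss <- function(C) sum((sim_areas(C) - obs)^2)
  grid <- seq(bounds[1], bounds[2], length.out = 25L)
  vals <- vapply(grid, rss, 0)
  flat <- diff(range(vals)) < 1e-12 * max(vals, .Machine$double.eps)
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(rss, c(lo, hi), tol = 1e-4)
  C_hat <- opt$minimum
  fit <- sim_areas(C_hat)
  rel_rms <- sqrt(mean(((fit - obs) / obs)^2))
  list(C_hat = C_hat, rss = opt$objective, rel_rms = rel_rms,
       identifiable = !flat && rel_rms < 0.5)
}

#' Generate a parameter-recovery suite
#'
#' Draws random progenitor-differentiated compound rate sets uniformly
#' within the compound bounds, rejecting draws that do not admit a
#' positive equilibrium (`2 p2 > beta + d2`) or whose equilibrium total
#' falls below `min_total` cells (continuum population models are only
#' meaningful at hundreds of cells and above), simulates each from a
#' small seeding population, perturbs the daily areas with the given noise,
#' and returns the paired truths and observations together with a
#' manifest of the seeds used. Re-running with the same seed reproduces
#' the suite exactly.
#'
#' @param n_draws Number of parameter draws, `>= 1`.
#' @param seed Master seed.
#' @param noise A [noise_model()] (its seed is re-derived per draw).
#' @param days Simulated horizon in days.
#' @param min_total Smallest admissible equilibrium total population.
#' @return List of class `"recovery_suite"`: `draws` (each with `rates`,
#'   `trajectory`, `series`) and `manifest` (data.frame of seeds and
#'   rates).
#' @export
generate_recovery_suite <- function(n_draws, seed = 1L,
                                    noise = noise_model(sd = 0.05),
                                    days = 12, min_total = 100) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  bounds <- compound_rate_bounds()
  draw_seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                            n_draws))
  draws <- vector("list", n_draws)
  rows <- vector("list", n_draws)
  for (k in seq_len(n_draws)) {
    rr <- .with_seed(draw_seeds[k], {
      repeat {
        x <- stats::runif(nrow(bounds), bounds[, "lower"], bounds[, "upper"])
        names(x) <- rownames(bounds)
        if (2 * x[["p2"]] > x[["beta"]] + x[["d2"]] &&
            2 * x[["p2"]] / (x[["beta"]] + x[["d2"]]) - 1 >= min_total) break
      }
      x
    })
    cr <- as_compound_rates(rr[["alpha"]], rr[["beta"]], rr[["gamma"]],
                            rr[["p1"]], rr[["p2"]], rr[["d1"]], rr[["d2"]],
                            rr[["r"]])
    traj <- simulate_population("pd", c(P = 1000, D = 0), cr, days = days)
    series <- area_series(traj$day[traj$day == floor(traj$day)],
                          traj$area_mm2[traj$day == floor(traj$day)],
                          paste0("draw-", k))
    nz <- noise_model(noise$kind, noise$sd, draw_seeds[k])
    draws[[k]] <- list(rates = cr, trajectory = traj,
                       series = apply_area_noise(series, nz))
    rows[[k]] <- data.frame(draw = k, seed = draw_seeds[k],
                            as.list(unclass(cr)))
  }
  structure(list(draws = draws,
                 manifest = do.call(rbind, rows),
                 seed = seed, noise = noise),
            class = "recovery_suite")
}
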