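# Aggregate geometry, gas flux through the medium column, and the
# conversion between imaged cell-body-cluster area and cell number.
#
# The aggregate is treated as a sphere of constant cell density anchored
# at 4500 cells for a radius of 0.05 cm, sitting at the bottom of a
# culture well with base area 9.6 cm^2. Gas exchange with the air above
# the medium is a lumped 1-D diffusion flux across the medium column of
# height d = H - R.

#' Culture-well geometry
#'
#' @param V_medium Medium volume in cm^3. The default 2.4 cm^3 is a
#'   package convention for a 9.6 cm^2 well; override to match a protocol.
#' @param base_area Plate base area in cm^2.
#' @return Object of class `"culture_geometry"`.
#' @export
culture_geometry <- function(V_medium = 2.4, base_area = 9.6) {
  if (!is.finite(V_medium) || V_medium <= 0) stop("V_medium must be > 0")
  if (!is.finite(base_area) || base_area <= 0) stop("base_area must be > 0")
  structure(list(V_medium = V_medium, base_area = base_area),
            class = "culture_geometry")
}

# cells per cm^3 at the reference density: 4500 cells in a 0.05 cm sphere
.cells_per_cm3 <- 8 * 4500 * 1000

#' Aggregate radius from total cell number
#'
#' Inverts the constant-density sphere: `R = (T / 3.6e7)^(1/3)` cm, so
#' that 4500 cells give the reference radius 0.05 cm (0.5 mm).
#'
#' @param total Total cell number, `>= 0`.
#' @return Radius in cm.
#' @export
radius_from_population <- function(total) {
  if (any(!is.finite(total)) || any(total < 0)) {
    stop("total cell number must be finite and >= 0")
  }
  (total / .cells_per_cm3)^(1 / 3)
}

#' Cell number from imaged cluster area
#'
#' Live-imaging platforms report the cross-sectional cell-body-cluster
#' area A (mm^2) of the roughly spherical aggregate. Assuming constant
#' cell density `CD0 = 6 * 4500 / pi` cells/mm^3 (4500 cells in a sphere
#' of radius 0.5 mm), the cell number is
#' `N = CD0 * (4/3) * pi * (A/pi)^(3/2) = 36000 * (A/pi)^(3/2)`,
#' rounded half away from zero to a whole cell.
#'
#' @param area Cluster area in mm^2, `> 0` (vectorised).
#' @return Integer cell counts.
#' @examples
#' cells_from_area(0.85)  # 5066 cells on day 0
#' @export
cells_from_area <- function(area) {
  if (any(!is.finite(area)) || any(area <= 0)) {
    stop("area must be finite and > 0 (mm^2)")
  }
  n <- 36000 * (area / pi)^(3 / 2)
  as.integer(floor(n + 0.5))
}

#' Cluster area from total cell number
#'
#' Inverse of [cells_from_area()] (before rounding):
#' `A = pi * (T / 36000)^(2/3)` mm^2. Round-tripping through
#' `cells_from_area()` recovers the cell count within one cell.
#'
#' @param total Total cell number, `>= 0` (vectorised).
#' @return Area in mm^2.
#' @export
area_from_population <- function(total) {
  if (any(!is.finite(total)) || any(total < 0)) {
    stop("total cell number must be finite and >= 0")
  }
  pi * (total / 36000)^(2 / 3)
}

#' Medium-column geometry above the aggregate
#'
#' Computes the medium height `H = (V_medium + (4/3) pi R^3) / base_area`,
#' the diffusion distance `d = H - R` from the medium surface to the
#' aggregate centre, and the aggregate cross-section `A_agg = pi R^2`.
#'
#' @param geometry A [culture_geometry()].
#' @param total Total cell number.
#' @return List with `R`, `H`, `d` (cm) and `A_agg` (cm^2).
#' @export
medium_geometry <- function(geometry = culture_geometry(), total) {
  stopifnot(inherits(geometry, "culture_geometry"))
  R <- radius_from_population(total)
  H <- (geometry$V_medium + (4 / 3) * pi * R^3) / geometry$base_area
  d <- H - R
  if (d <= 0) {
    stop("aggregate taller than the medium column (d = H - R <= 0); ",
         "increase V_medium")
  }
  list(R = R, H = H, d = d, A_agg = pi * R^2)
}

# diffusion coefficients (cm^2/s) and the fixed unit-conversion factor
# (mmHg per percent x solubility x seconds per minute)
.diff_coef <- c(O = 3.0e-5, W = 2.5e-5)
.flux_unit <- (760 / 100) * 5.1737e-8 * 60

#' Per-cell metabolic rates
#'
#' Oxygen consumption (`u1`, `u2`, `u3`) and waste production
#' (`w1`, `w2`, `w3`) per cell, in percent per minute, for stem,
#' progenitor and differentiated cells respectively. Stem cells cycle
#' fastest and consume the most oxygen, so a warning is issued unless
#' `u1 >= u2 >= u3`. At evaluation time all six rates are scaled by
#' `f13(O)`, which models metabolic shutdown under anoxia.
#'
#' The defaults are package conventions honouring the stem > progenitor >
#' differentiated ordering, with waste production tied to oxygen
#' consumption by the ratio of the two diffusion coefficients
#' (CO2 production tracks O2 consumption mole for mole); they are not
#' measured values and should be overridden when calibrated rates are
#' available.
#'
#' @param u1,u2,u3 Oxygen consumption, %/min/cell.
#' @param w1,w2,w3 Waste production, %/min/cell; default `u_i * 2.5/3.0`.
#' @return Object of class `"metabolic_rates"`.
#' @export
metabolic_rates <- function(u1 = 2e-9, u2 = 1.5e-9, u3 = 1e-9,
                            w1 = u1 * 2.5 / 3.0,
                            w2 = u2 * 2.5 / 3.0,
                            w3 = u3 * 2.5 / 3.0) {
  x <- c(u1 = u1, u2 = u2, u3 = u3, w1 = w1, w2 = w2, w3 = w3)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("metabolic rates must be finite and >= 0")
  }
  if (!(u1 >= u2 && u2 >= u3)) {
    warning("expected u1 >= u2 >= u3 (stem cells consume the most oxygen)")
  }
  structure(as.list(x), class = "metabolic_rates")
}

#' Gas flux between the air interface and the aggregate
#'
#' Lumped 1-D diffusion flux, per minute, in percent units:
#' `flux = Dcoef * (760/100) * (air_level - level) * 5.1737e-8 * 60 / d`
#' times the aggregate cross-section `A_agg`, where `Dcoef` is
#' `3.0e-5` cm^2/s for oxygen and `2.5e-5` for waste and `d` is the
#' diffusion distance from [medium_geometry()]. Scaffold density slows
#' diffusion under the aggregate: the flux is attenuated by the near-unity
#' decreasing contact effects, `f11(C)` for oxygen and `f12(C)` for waste
#' (the default convention); `attenuation = "f10f11"` instead multiplies
#' the oxygen flux by `f10(C)` and the waste flux by `f11(C)`, and
#' `"none"` disables the attenuation.
#'
#' @param gas `"O"` or `"W"`.
#' @param level Local concentration, percent in `[0, 100]`.
#' @param air_level Concentration in the air above the medium, percent.
#' @param total Total cell number (sets the aggregate geometry).
#' @param geometry A [culture_geometry()].
#' @param C Contact rate.
#' @param attenuation Scaffold diffusion-attenuation convention.
#' @return Flux in percent per minute (positive into the medium).
#' @export
gas_flux <- function(gas = c("O", "W"), level, air_level, total,
                     geometry = culture_geometry(), C = 1,
                     attenuation = c("f11f12", "f10f11", "none")) {
  gas <- match.arg(gas)
  attenuation <- match.arg(attenuation)
  if (level < 0 || level > 100 || air_level < 0 || air_level > 100) {
    stop("gas levels must lie in [0, 100] percent")
  }
  mg <- medium_geometry(geometry, total)
  att <- switch(attenuation,
    f11f12 = if (gas == "O") .effect_funs$f11(C) else .effect_funs$f12(C),
    f10f11 = if (gas == "O") .effect_funs$f10(C) else .effect_funs$f11(C),
    none = 1)
  .diff_coef[[gas]] * .flux_unit * (air_level - level) / mg$d * mg$A_agg * att
}

#' Area time series
#'
#' Tidy record of daily cell-body-cluster areas for one or more scaffolds,
#' matching the layout produced by live-imaging software exports.
#'
#' @param day Integer day of measurement, `>= 0`, non-decreasing within
#'   each scaffold.
#' @param area_mm2 Cluster area, mm^2, `> 0`.
#' @param scaffold Scaffold label.
#' @return A `data.frame` of class `"area_series"` with columns `day`,
#'   `area_mm2`, `scaffold`.
#' @export
area_series <- function(day, area_mm2, scaffold = "scaffold") {
  if (any(!is.finite(day)) || any(day < 0) || any(day != floor(day))) {
    stop("'day' must contain non-negative integers")
  }
  if (any(!is.finite(area_mm2)) || any(area_mm2 <= 0)) {
    stop("'area_mm2' must be positive")
  }
  df <- data.frame(day = as.integer(day), area_mm2 = as.numeric(area_mm2),
                   scaffold = as.character(scaffold),
                   stringsAsFactors = FALSE)
  for (s in unique(df$scaffold)) {
    if (is.unsorted(df$day[df$scaffold == s])) {
      stop("days must be non-decreasing within scaffold '", s, "'")
    }
  }
  class(df) <- c("area_series", "data.frame")
  df
}
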