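# Configuration parsing and the CSV/JSON interchange formats.
#
# Run configurations are YAML (or JSON) with rates stored in units of
# 1e-5 per minute — the convention of the calibrated rate table — so
# values can be transcribed without exponent bookkeeping. Area series
# travel as CSV with columns day, area_mm2, scaffold.

.config_keys <- c("rates", "environment", "air", "porosity", "contact",
                  "volume_medium", "metabolic", "initial", "variant",
                  "days", "decoupled", "seed", "out")

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration and resolves it into validated
#' package objects. Rates are given in units of 1e-5 per minute;
#' environment values in percent; scaffold geometry as either `porosity`
#' (percent, resolved through [contact_from_porosity()]) or `contact`,
#' never both. Unknown keys are rejected; rates outside the calibrated
#' experimental ranges warn but load.
#'
#' @param path Path to the configuration file.
#' @return List of class `"run_config"` with elements `exp_rates`, `env`
#'   (or `NULL` when only air levels are given), `air`, `mode`,
#'   `geometry`, `metabolic`, `initial`, `variant`, `days`, `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$rates)) stop("config must contain a 'rates' block")
  need <- .rate_names
  miss <- setdiff(need, names(cfg$rates))
  if (length(miss)) {
    stop("rates block missing: ", paste(miss, collapse = ", "))
  }
  exp_rates <- withCallingHandlers(
    experimental_rates(cfg$rates$alpha, cfg$rates$beta, cfg$rates$gamma,
                       cfg$rates$p1, cfg$rates$p2, cfg$rates$d1,
                       cfg$rates$d2, cfg$rates$r,
                       scale = 1e-5, warn_range = TRUE),
    warning = function(w) {
      warning("config '", path, "': ", conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })

  if (!is.null(cfg$porosity) && !is.null(cfg$contact)) {
    stop("config gives both 'porosity' and 'contact'; supply one")
  }
  C <- if (!is.null(cfg$porosity)) {
    as.numeric(contact_from_porosity(cfg$porosity))
  } else if (!is.null(cfg$contact)) {
    cfg$contact
  } else {
    1
  }
  env <- if (!is.null(cfg$environment)) {
    environment_condition(cfg$environment$O, cfg$environment$W, C)
  } else {
    NULL
  }
  air <- if (!is.null(cfg$air)) {
    c(O = cfg$air$O, W = cfg$air$W)
  } else {
    NULL
  }
  mode <- if (!is.null(cfg$decoupled)) {
    do.call(coupling_mode, lapply(cfg$decoupled, function(v) v * 1e-5))
  } else {
    NULL
  }
  geometry <- culture_geometry(
    V_medium = if (is.null(cfg$volume_medium)) 2.4 else cfg$volume_medium)
  metabolic <- if (!is.null(cfg$metabolic)) {
    do.call(metabolic_rates, cfg$metabolic)
  } else {
    metabolic_rates()
  }
  initial <- if (!is.null(cfg$initial)) {
    unlist(cfg$initial)
  } else {
    c(S = 0, P = 5000, D = 0)
  }
  structure(list(exp_rates = exp_rates, env = env, C = C, air = air,
                 mode = mode, geometry = geometry, metabolic = metabolic,
                 initial = initial,
                 variant = if (is.null(cfg$variant)) "spd" else cfg$variant,
                 days = if (is.null(cfg$days)) 12 else cfg$days,
                 seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
                 path = path),
            class = "run_config")
}

#' Read an area time series from CSV
#'
#' Expects columns `day`, `area_mm2`, `scaffold`. Malformed rows are
#' reported with their line numbers.
#'
#' @param path CSV path.
#' @return An [area_series()].
#' @export
read_area_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("day", "area_mm2", "scaffold")
  if (!all(need %in% names(df))) {
    stop("area CSV must have columns: ", paste(need, collapse = ", "))
  }
  bad <- which(!is.finite(df$day) | df$day < 0 |
                 !is.finite(df$area_mm2) | df$area_mm2 <= 0)
  if (length(bad)) {
    stop("malformed area rows at line(s): ",
         paste(bad + 1L, collapse = ", "),
         " (day must be >= 0, area_mm2 > 0)")
  }
  area_series(df$day, df$area_mm2, df$scaffold)
}

#' @rdname read_area_csv
#' @param series An [area_series()] to write.
#' @export
write_area_csv <- function(series, path) {
  stopifnot(inherits(series, "area_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a machine-readable run report
#'
#' Serialises any report-like list (fixed points, scenario summaries,
#' fit results) as JSON together with provenance: the package version,
#' the seed, and a digest of the configuration file if one is supplied.
#'
#' @param report A list (or object convertible to one).
#' @param path Output JSON path.
#' @param config Optional `"run_config"` whose file digest is recorded.
#' @param seed Seed to record.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path, config = NULL, seed = NULL) {
  payload <- list(
    package = "scaffpop",
    version = as.character(utils::packageVersion("scaffpop")),
    seed = seed,
    config_digest = if (!is.null(config) && !is.null(config$path) &&
                        file.exists(config$path)) {
      unname(tools::md5sum(config$path))
    } else {
      NULL
    },
    report = report)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
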