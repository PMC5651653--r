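# Shared fixtures for the test suite.

# reference daily cluster areas (mm^2) for the two scaffold types and the
# cell counts they convert to; the loop-mesh-500 day-10/12 counts are
# known misprints in the source table and excluded from comparisons
ref_area_csv <- function() {
  system.file("extdata", "aggregate_areas.csv", package = "scaffpop")
}

ref_counts_lm200 <- c(5066, 5706, 7561, 11172, 13953, 15874, 21675)
ref_counts_lm500_d0_8 <- c(4199, 4454, 4626, 5337, 5612)

# draw a random compound rate set admitting a meaningful positive PD
# equilibrium (existence condition plus at least `min_total` cells)
draw_pd_rates <- function(bounds = compound_rate_bounds(), min_total = 100) {
  repeat {
    x <- stats::runif(nrow(bounds), bounds[, "lower"], bounds[, "upper"])
    names(x) <- rownames(bounds)
    if (2 * x[["p2"]] > x[["beta"]] + x[["d2"]] &&
        2 * x[["p2"]] / (x[["beta"]] + x[["d2"]]) - 1 >= min_total) {
      return(as_compound_rates(x[["alpha"]], x[["beta"]], x[["gamma"]],
                               x[["p1"]], x[["p2"]], x[["d1"]], x[["d2"]],
                               x[["r"]]))
    }
  }
}
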