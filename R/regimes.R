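# Transfer regimes and growth-cycle segment grids.
#
# A regime is one serial-batch condition: medium plus days between
# transfers. Cultures reach maximum density within a fixed number of
# hours (growth_saturation_hours) and spend the remainder of the cycle
# in stationary phase. The segment grid divides the cycle into the
# growth interval followed by 48-hour stationary-phase blocks; a
# lineage's per-cycle fitness is the sum over segments of its hourly
# advantage times the hours the segment contributes to that cycle.

#' Transfer regime specification
#'
#' Describes one serial-batch transfer condition: the medium, the number
#' of days between transfers, the dilution factor at transfer, and the
#' number of cells passing the transfer bottleneck.
#'
#' @param cycle_days integer days between transfers (>= 1).
#' @param medium `"GlyEth"` (glycerol/ethanol; saturation at 48 h) or
#'   `"glucose"` (saturation at 24 h).
#' @param dilution_factor dilution at transfer (> 1); generations per
#'   cycle is `log2(dilution_factor)`.
#' @param bottleneck_cells number of cells transferred each cycle.
#' @param growth_saturation_hours hours until maximum density; defaults
#'   to 48 for Gly/Eth and 24 for glucose.
#' @return an object of class `regime_spec`.
#' @examples
#' regime_spec(6, "GlyEth")
#' @export
regime_spec <- function(cycle_days, medium = c("GlyEth", "glucose"),
                        dilution_factor = 250, bottleneck_cells = 1e5,
                        growth_saturation_hours = NULL) {
  medium <- match.arg(medium)
  check_field(is_count(cycle_days) && cycle_days >= 1, "cycle_days", "must be an integer >= 1")
  check_field(is_num1(dilution_factor) && dilution_factor > 1, "dilution_factor", "must be > 1")
  check_field(is_count(bottleneck_cells) && bottleneck_cells > 0, "bottleneck_cells", "must be a positive count")
  if (is.null(growth_saturation_hours))
    growth_saturation_hours <- if (medium == "glucose") 24 else 48
  check_field(is_num1(growth_saturation_hours) && growth_saturation_hours > 0,
              "growth_saturation_hours", "must be positive")
  structure(list(
    cycle_days = as.integer(cycle_days),
    medium = medium,
    dilution_factor = dilution_factor,
    bottleneck_cells = bottleneck_cells,
    growth_saturation_hours = growth_saturation_hours,
    generations_per_cycle = log2(dilution_factor)
  ), class = "regime_spec")
}

#' @export
print.regime_spec <- function(x, ...) {
  cat(sprintf("<regime_spec> %s, %d-day transfers (1:%g dilution, %.2f generations/cycle)\n",
              x$medium, x$cycle_days, x$dilution_factor, x$generations_per_cycle))
  invisible(x)
}

#' Condition label for a regime
#'
#' Short label used as the `condition` field of count matrices and
#' fitness tables, e.g. `"GE_6day"` or `"gluc_3day"`.
#'
#' @param regime a [regime_spec()].
#' @return character scalar.
#' @export
condition_label <- function(regime) {
  stopifnot(inherits(regime, "regime_spec"))
  prefix <- if (regime$medium == "glucose") "gluc" else "GE"
  sprintf("%s_%dday", prefix, regime$cycle_days)
}

#' Growth-cycle segment grid for a medium
#'
#' Returns the hour breakpoints of the segment grid used for
#' phase-structured phenotypes: one growth segment up to saturation,
#' then stationary-phase blocks of 48 hours. Gly/Eth saturates at 48 h
#' (grid 0,48,...,240); glucose at 24 h (grid 0,24,72,120).
#'
#' @param medium `"GlyEth"` or `"glucose"`.
#' @return named numeric vector of segment start hours with an attribute
#'   `breaks` (the full breakpoints).
#' @export
segment_grid <- function(medium = c("GlyEth", "glucose")) {
  medium <- match.arg(medium)
  if (medium == "GlyEth") {
    breaks <- c(0, 48, 96, 144, 192, 240)
    nm <- c("growth_0_48", "sp_48_96", "sp_96_144", "sp_144_192", "sp_192_240")
  } else {
    breaks <- c(0, 24, 72, 120)
    nm <- c("gluc_growth_0_24", "gluc_sp_24_72", "gluc_sp_72_120")
  }
  structure(stats::setNames(breaks[-length(breaks)], nm), breaks = breaks)
}

#' Generations per growth cycle from the dilution factor
#'
#' Each cycle the culture regrows by the dilution factor, so the number
#' of generations is `log2(dilution_factor)` (a 1:250 dilution gives
#' ~7.97, i.e. roughly 8 generations).
#'
#' @param dilution_factor dilution at transfer (> 1).
#' @return list with `generations` (exact) and `rounded`.
#' @examples
#' generations_per_cycle(250)
#' @export
generations_per_cycle <- function(dilution_factor) {
  if (!is_num1(dilution_factor) || dilution_factor <= 1)
    stopf("dilution_factor must be > 1")
  g <- log2(dilution_factor)
  list(generations = g, rounded = round(g))
}
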