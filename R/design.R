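#' Cell-loading plan for a droplet run
#'
#' Captures the arithmetic used to predict how many cells a droplet run will
#' recover from the post-dilution concentration of the loaded suspension.
#' When several cultures are pooled (e.g. a 50-50 glucose/maltose mix), each
#' contributes in proportion to its mixing weight.
#'
#' @param concentrations Non-negative cell concentrations (cells/mL) of the
#'   pooled cultures after the final dilution.
#' @param mix_weights Non-negative weights summing to 1, one per culture.
#'   Default: a single culture with weight 1.
#' @param recovery_divisor Positive scalar mapping concentration to expected
#'   recovered cells (default 100, the consistent concentration-to-expected
#'   mapping of the loading table: 2.15e5 cells/mL -> 2150 cells).
#' @return An object of class `loading_plan`.
#' @export
loading_plan <- function(concentrations, mix_weights = NULL,
                         recovery_divisor = 100) {
  concentrations <- as.numeric(concentrations)
  if (anyNA(concentrations) || any(concentrations < 0))
    stop("concentrations must be non-negative")
  if (is.null(mix_weights))
    mix_weights <- rep(1 / length(concentrations), length(concentrations))
  mix_weights <- as.numeric(mix_weights)
  if (length(mix_weights) != length(concentrations))
    stop("mix_weights and concentrations lengths differ")
  if (any(mix_weights < 0)) stop("mix_weights must be non-negative")
  if (abs(sum(mix_weights) - 1) > 1e-9)
    stop("mix_weights must sum to 1")
  if (recovery_divisor <= 0) stop("recovery_divisor must be positive")
  structure(list(concentrations = concentrations,
                 mix_weights = mix_weights,
                 recovery_divisor = recovery_divisor),
            class = "loading_plan")
}

#' Expected number of recovered cells
#'
#' `sum(weight_i * concentration_i) / recovery_divisor`. With the default
#' divisor this reproduces the loading table of the droplet experiment, e.g.
#' a 50-50 pool at 6.06e4 and 1.32e5 cells/mL gives 963 expected cells.
#'
#' @param plan A [loading_plan()].
#' @param integer_report If `TRUE`, round half away from zero to an integer.
#' @return Expected recovered cell count (scalar).
#' @export
expected_cells <- function(plan, integer_report = FALSE) {
  stopifnot(inherits(plan, "loading_plan"))
  val <- sum(plan$mix_weights * plan$concentrations) / plan$recovery_divisor
  if (integer_report) val <- round_half_away(val)
  val
}

#' Concentration required to target a recovered-cell count
#'
#' Trivial inverse of [expected_cells()] for a single culture.
#'
#' @param target_cells Desired expected recovered cells.
#' @param recovery_divisor As in [loading_plan()].
#' @return Required concentration in cells/mL.
#' @export
required_concentration <- function(target_cells, recovery_divisor = 100) {
  if (target_cells < 0) stop("target_cells must be non-negative")
  target_cells * recovery_divisor
}

# round half away from zero (round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
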