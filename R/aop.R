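# Domain types: Areas of Protection, impact vectors, handprints, scenarios.

#' Areas of Protection
#'
#' The three endpoint damage categories of endpoint life-cycle impact
#' assessment: Human Health (DALY), Ecosystems (species.yr) and Resources
#' (USD surplus cost).  All burden containers in this package are indexed by
#' these three keys, in this order.
#'
#' @return `aop_keys()` returns the three key strings; `aop_units()` the named
#'   character vector mapping each key to its canonical unit.
#' @examples
#' aop_keys()
#' aop_units()
#' @export
aop_keys <- function() c("HUMAN_HEALTH", "ECOSYSTEMS", "RESOURCES")

#' @rdname aop_keys
#' @export
aop_units <- function() {
  c(HUMAN_HEALTH = "DALY", ECOSYSTEMS = "species.yr", RESOURCES = "USD")
}

# Classed validation error so callers (and the CLI) can distinguish bad input
# from programming errors.
stop_validation <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("rsbr_validation_error", "error", "condition")))
}

assert_scalar_number <- function(x, what, allow_na = FALSE) {
  if (allow_na && length(x) == 1L && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_validation(sprintf("%s must be a single non-missing number", what))
  }
  invisible(x)
}

#' Per-scenario burden on the three Areas of Protection
#'
#' An impact vector carries one non-negative burden per Area of Protection,
#' per functional unit, in the canonical units (DALY, species.yr, USD).  An
#' entry may be missing (`NA`) when that burden was not assessed; missing is
#' distinct from zero and survives serialization round-trips.
#'
#' @param human_health DALY burden per functional unit, or `NA`.
#' @param ecosystems species.yr burden, or `NA`.
#' @param resources USD surplus-cost burden, or `NA`.
#' @return An object of class `impact_vector`: a named numeric vector over
#'   [aop_keys()].
#' @examples
#' impact_vector(5.75, 2.87e-2, 2.23e5)
#' impact_vector()  # nothing assessed
#' @export
impact_vector <- function(human_health = NA_real_, ecosystems = NA_real_,
                          resources = NA_real_) {
  v <- c(HUMAN_HEALTH = as.numeric(human_health),
         ECOSYSTEMS = as.numeric(ecosystems),
         RESOURCES = as.numeric(resources))
  if (any(!is.na(v) & v < 0)) {
    stop_validation("impact_vector entries must be non-negative burdens")
  }
  structure(v, class = "impact_vector")
}

#' @export
print.impact_vector <- function(x, ...) {
  cat("<impact_vector>\n")
  u <- aop_units()
  for (k in aop_keys()) {
    cat(sprintf("  %-13s %s %s\n", k,
                if (is.na(x[[k]])) "NA" else format_sci(x[[k]]), u[[k]]))
  }
  invisible(x)
}

is_impact_vector <- function(x) inherits(x, "impact_vector")

#' Patient-health DALY burden with sensitivity bounds
#'
#' A handprint estimate is the Human Health burden of a scenario's patient
#' population, in DALY per functional unit, with base/min/max values taken
#' from a sensitivity analysis of the underlying disease model.
#'
#' @param base base-case DALY burden (non-negative).
#' @param min,max lower and upper bounds; must satisfy
#'   `0 <= min <= base <= max`.  Default to `base`.
#' @return An object of class `handprint_estimate`.
#' @examples
#' handprint_estimate(89946, 58812, 124840)
#' @export
handprint_estimate <- function(base, min = base, max = base) {
  assert_scalar_number(base, "base")
  assert_scalar_number(min, "min")
  assert_scalar_number(max, "max")
  if (!(0 <= min && min <= base && base <= max)) {
    stop_validation("handprint_estimate requires 0 <= min <= base <= max")
  }
  structure(list(base = as.numeric(base), min = as.numeric(min),
                 max = as.numeric(max)),
            class = "handprint_estimate")
}

#' @export
print.handprint_estimate <- function(x, ...) {
  cat(sprintf("<handprint_estimate> base %s [min %s, max %s] DALY\n",
              format_sci(x$base), format_sci(x$min), format_sci(x$max)))
  invisible(x)
}

#' A named scenario: footprint and/or handprint
#'
#' @param name non-empty scenario name.
#' @param footprint an [impact_vector()], or `NULL` if no footprint was
#'   assessed.
#' @param handprint a [handprint_estimate()], or `NULL`.
#' @return An object of class `scenario`.  At least one of footprint and
#'   handprint must be supplied.
#' @examples
#' scenario("treatment", impact_vector(5.75, 2.87e-2, 2.23e5),
#'          handprint_estimate(89946, 58812, 124840))
#' @export
scenario <- function(name, footprint = NULL, handprint = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_validation("scenario name must be a non-empty string")
  }
  if (is.null(footprint) && is.null(handprint)) {
    stop_validation("scenario needs at least one of footprint and handprint")
  }
  if (!is.null(footprint) && !is_impact_vector(footprint)) {
    stop_validation("footprint must be an impact_vector")
  }
  if (!is.null(handprint) && !inherits(handprint, "handprint_estimate")) {
    stop_validation("handprint must be a handprint_estimate")
  }
  structure(list(name = name, footprint = footprint, handprint = handprint),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s (footprint: %s, handprint: %s)\n", x$name,
              if (is.null(x$footprint)) "absent" else "present",
              if (is.null(x$handprint)) "absent" else "present"))
  invisible(x)
}

#' A two-scenario comparison
#'
#' Pairs a treatment scenario with its comparator (the 'no treatment' or
#' treatment-interruption arm) under a shared functional unit.
#'
#' @param name case-study name.
#' @param treatment,comparator [scenario()] objects with distinct names.
#' @param functional_unit free-text description of the shared functional unit.
#' @return An object of class `case_study`.
#' @seealso [builtin_case()] for the two built-in pharmaceutical cases.
#' @export
case_study <- function(name, treatment, comparator, functional_unit = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_validation("case_study name must be a non-empty string")
  }
  for (s in list(treatment, comparator)) {
    if (!inherits(s, "scenario")) stop_validation("arms must be scenario objects")
  }
  if (identical(treatment$name, comparator$name)) {
    stop_validation("treatment and comparator must have distinct names")
  }
  structure(list(name = name, treatment = treatment, comparator = comparator,
                 functional_unit = as.character(functional_unit)),
            class = "case_study")
}

#' @export
print.case_study <- function(x, ...) {
  cat(sprintf("<case_study> %s: '%s' vs '%s'\n", x$name, x$treatment$name,
              x$comparator$name))
  if (nzchar(x$functional_unit)) cat("  FU:", x$functional_unit, "\n")
  invisible(x)
}
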