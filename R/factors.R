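# Value-choice objects: external normalization and panel weighting sets.

#' External normalization set for the footprint
#'
#' One normalization factor per Area of Protection: the total global (or
#' regional) burden of that category in a reference year, in the category's
#' own unit per year.  Dividing a footprint by these factors makes it
#' dimensionless (per year) and comparable across categories.
#'
#' @param id identifier string.
#' @param source label of the providing framework, e.g.
#'   `"ReCiPe-Hierarchist"`, `"PROSUITE"`, or `"derived"`.
#' @param year reference year.
#' @param human_health total DALY/yr; strictly positive.
#' @param ecosystems total species.yr/yr; strictly positive.
#' @param resources total USD/yr; strictly positive.
#' @return An object of class `normalization_set` with a `factors` element
#'   (named numeric over [aop_keys()]).
#' @export
normalization_set <- function(id, source, year, human_health, ecosystems,
                              resources) {
  f <- c(HUMAN_HEALTH = as.numeric(human_health),
         ECOSYSTEMS = as.numeric(ecosystems),
         RESOURCES = as.numeric(resources))
  if (any(is.na(f)) || any(f <= 0)) {
    stop_validation("normalization factors must all be present and > 0")
  }
  structure(list(id = as.character(id), source = as.character(source),
                 year = as.integer(year), factors = f),
            class = "normalization_set")
}

#' @export
print.normalization_set <- function(x, ...) {
  cat(sprintf("<normalization_set> %s (%s, %d): HH %s, ECO %s, RES %s\n",
              x$id, x$source, x$year, format_sci(x$factors[[1]]),
              format_sci(x$factors[[2]]), format_sci(x$factors[[3]])))
  invisible(x)
}

#' Normalization set for the handprint
#'
#' The handprint (direct patient burden) has a different cause-effect chain
#' than the environmentally mediated footprint, so it is normalized
#' separately, against the total global burden of disease (all causes) in a
#' reference year.
#'
#' @param id identifier string.
#' @param year reference year.
#' @param factor total global disease burden, DALY/yr; strictly positive.
#' @return An object of class `handprint_normalization_set`.
#' @export
handprint_normalization_set <- function(id, year, factor) {
  assert_scalar_number(factor, "factor")
  if (factor <= 0) stop_validation("handprint normalization factor must be > 0")
  structure(list(id = as.character(id), year = as.integer(year),
                 factor = as.numeric(factor)),
            class = "handprint_normalization_set")
}

#' @export
print.handprint_normalization_set <- function(x, ...) {
  cat(sprintf("<handprint_normalization_set> %s (%d): %s DALY/yr\n",
              x$id, x$year, format_sci(x$factor)))
  invisible(x)
}

#' Main weighting-set families
#'
#' Panel weighting sets are grouped into three main families: Eco-Indicator
#' 99, the Itsubo country panels, and the European Commission JRC
#' Environmental Footprint weights.
#' @return Character vector of the three family labels.
#' @export
wf_main_sets <- function() c("EI99", "ITSUBO", "EC_JRC_EF")

#' Panel weighting set
#'
#' A panel-elicited importance weight per Area of Protection.  Weights lie in
#' \[0, 1\] and must sum to 1 within `1e-9`; sets violating this are rejected
#' rather than silently renormalized.
#'
#' @param id identifier string.
#' @param main_set family label, one of [wf_main_sets()].
#' @param human_health,ecosystems,resources weights in \[0, 1\].
#' @return An object of class `weighting_set` with a `weights` element.
#' @examples
#' weighting_set("EI99-default", "EI99", 0.4, 0.4, 0.2)
#' @export
weighting_set <- function(id, main_set, human_health, ecosystems, resources) {
  main_set <- match.arg(main_set, wf_main_sets())
  w <- c(HUMAN_HEALTH = as.numeric(human_health),
         ECOSYSTEMS = as.numeric(ecosystems),
         RESOURCES = as.numeric(resources))
  if (any(is.na(w)) || any(w < 0) || any(w > 1)) {
    stop_validation("weights must all lie in [0, 1]")
  }
  if (abs(sum(w) - 1) > 1e-9) {
    stop_validation(sprintf(
      "weights must sum to 1 within 1e-9 (got %.12f); refusing to renormalize",
      sum(w)))
  }
  structure(list(id = as.character(id), main_set = main_set, weights = w),
            class = "weighting_set")
}

#' @export
print.weighting_set <- function(x, ...) {
  cat(sprintf("<weighting_set> %s [%s]: (%.3f, %.3f, %.3f)\n", x$id,
              x$main_set, x$weights[[1]], x$weights[[2]], x$weights[[3]]))
  invisible(x)
}
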