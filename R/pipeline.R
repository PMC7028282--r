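# Deterministic aggregation pipeline:
# normalize -> weight -> combine on Human Health -> single score -> RSBR.

new_aop_vector <- function(values, class, provenance) {
  structure(values, class = class, provenance = provenance)
}

#' Normalize a footprint by an external normalization set
#'
#' Divides each Area-of-Protection burden by the corresponding normalization
#' factor, yielding dimensionless per-year values.  Missing entries stay
#' missing.
#'
#' @param fp an [impact_vector()].
#' @param nf a [normalization_set()].
#' @return A `normalized_vector`: named numeric over [aop_keys()] with a
#'   `provenance` attribute recording the normalization-set id.
#' @examples
#' nf <- normalization_set("nf", "demo", 2000, 100, 100, 100)
#' normalize_footprint(impact_vector(10, 10, 10), nf)
#' @export
normalize_footprint <- function(fp, nf) {
  if (!is_impact_vector(fp)) stop_validation("fp must be an impact_vector")
  if (!inherits(nf, "normalization_set")) {
    stop_validation("nf must be a normalization_set")
  }
  v <- unclass(fp) / nf$factors
  new_aop_vector(v, "normalized_vector", list(nf_id = nf$id))
}

#' Normalize a handprint DALY burden
#'
#' Divides the patient-health DALY burden by the total global burden of
#' disease of the reference year, yielding a dimensionless per-year value.
#'
#' @param h DALY burden, non-negative scalar.
#' @param nf a [handprint_normalization_set()].
#' @return Dimensionless per-year scalar.
#' @export
normalize_handprint <- function(h, nf) {
  assert_scalar_number(h, "handprint burden")
  if (h < 0) stop_validation("handprint burden must be non-negative")
  if (!inherits(nf, "handprint_normalization_set")) {
    stop_validation("nf must be a handprint_normalization_set")
  }
  h / nf$factor
}

#' Apply panel weights to a normalized vector
#'
#' Multiplies each present entry by its Area-of-Protection weight; missing
#' entries are preserved.
#'
#' @param nv a `normalized_vector` from [normalize_footprint()] (any named
#'   numeric over [aop_keys()] is accepted).
#' @param wf a [weighting_set()].
#' @return A `weighted_vector` with provenance carrying both set ids.
#' @export
apply_weights <- function(nv, wf) {
  if (!inherits(wf, "weighting_set")) stop_validation("wf must be a weighting_set")
  if (is.null(names(nv)) || !all(aop_keys() %in% names(nv))) {
    stop_validation("nv must be named over the three Areas of Protection")
  }
  prov <- attr(nv, "provenance")
  v <- unclass(nv)[aop_keys()] * wf$weights
  new_aop_vector(v, "weighted_vector",
                 c(prov[!vapply(prov, is.null, TRUE)], list(wf_id = wf$id)))
}

#' Combine weighted handprint and footprint on Human Health
#'
#' Handprint and footprint are normalized and weighted separately; only then
#' are they combined, by addition, on the Human Health Area of Protection.
#' A missing side is treated as absent (contributes nothing).
#'
#' @param handprint_weighted weighted handprint Human Health value, or `NA`.
#' @param footprint_weighted_hh weighted footprint Human Health value, or `NA`.
#' @return The sum of the present inputs (`0` if both are missing).
#' @export
combine_hh <- function(handprint_weighted, footprint_weighted_hh) {
  vals <- c(handprint_weighted, footprint_weighted_hh)
  sum(vals[!is.na(vals)])
}

#' Sum a weighted vector into a single score
#'
#' The single score, in dimensionless points, is the sum of the present
#' weighted components, with the Human Health component replaced by the
#' combined handprint+footprint value when one is supplied.
#'
#' @param wv a `weighted_vector`.
#' @param combined_hh optional replacement for the Human Health component,
#'   from [combine_hh()].
#' @return An object of class `single_score_result` with elements `score`,
#'   `components`, `handprint_included` and `provenance`.
#' @export
single_score <- function(wv, combined_hh = NULL) {
  if (is.null(names(wv)) || !all(aop_keys() %in% names(wv))) {
    stop_validation("wv must be named over the three Areas of Protection")
  }
  comp <- unclass(wv)[aop_keys()]
  if (!is.null(combined_hh)) {
    assert_scalar_number(combined_hh, "combined_hh")
    comp[["HUMAN_HEALTH"]] <- combined_hh
  }
  if (all(is.na(comp))) {
    stop_validation("single_score of an empty scenario: all components missing")
  }
  structure(list(score = sum(comp[!is.na(comp)]),
                 components = comp,
                 handprint_included = !is.null(combined_hh),
                 provenance = attr(wv, "provenance")),
            class = "single_score_result")
}

#' @export
print.single_score_result <- function(x, ...) {
  cat(sprintf("<single_score_result> %s points (handprint %s)\n",
              format_sci(x$score),
              if (x$handprint_included) "included" else "excluded"))
  invisible(x)
}

#' Relative Sustainability Benefit Rate
#'
#' The signed relative difference between two single scores:
#' `(comparator - treatment) / comparator * 100`.  Positive values mean the
#' treatment carries the lower burden (is beneficial).  Results tables in
#' this field often print the negated value, so that a reduced burden shows
#' as a negative percentage; `table_sign = TRUE` applies that convention.
#'
#' @param score_comparator single score of the comparator ('no treatment')
#'   scenario; must be non-negative.
#' @param score_treatment single score of the treatment scenario.
#' @param table_sign negate the result for display (default `FALSE`).
#' @return RSBR in percent, or `NA` when the comparator score is zero (the
#'   rate is then undefined).
#' @examples
#' rsbr_percent(100, 90)                    # 10: treatment 10% better
#' rsbr_percent(100, 90, table_sign = TRUE) # -10: burden reduced by 10%
#' @export
rsbr_percent <- function(score_comparator, score_treatment, table_sign = FALSE) {
  assert_scalar_number(score_comparator, "score_comparator")
  assert_scalar_number(score_treatment, "score_treatment")
  if (score_comparator < 0 || score_treatment < 0) {
    stop_validation("single scores are burdens and must be non-negative")
  }
  if (score_comparator == 0) return(NA_real_)
  val <- (score_comparator - score_treatment) / score_comparator * 100
  if (table_sign) -val else val
}

# Weighted HH handprint/footprint split and full score for one scenario.
# Missing footprint entries contribute zero to the sum but stay NA in the
# reported components (absence-as-zero aggregation).
score_scenario <- function(scen, nf, hnf, wf, variant = "base",
                           include_handprint = TRUE) {
  if (!inherits(scen, "scenario")) stop_validation("scen must be a scenario")
  variant <- match.arg(variant, c("base", "min", "max"))

  if (!is.null(scen$footprint)) {
    wv <- apply_weights(normalize_footprint(scen$footprint, nf), wf)
  } else {
    wv <- new_aop_vector(
      stats::setNames(rep(NA_real_, 3), aop_keys()),
      "weighted_vector", list(nf_id = nf$id, wf_id = wf$id))
  }
  comp <- unclass(wv)[aop_keys()]

  hp_weighted <- NA_real_
  if (include_handprint && !is.null(scen$handprint)) {
    hn <- normalize_handprint(scen$handprint[[variant]], hnf)
    hp_weighted <- hn * wf$weights[["HUMAN_HEALTH"]]
  }
  fp_hh <- comp[["HUMAN_HEALTH"]]
  combined <- combine_hh(hp_weighted, fp_hh)

  present <- comp[!is.na(comp)]
  score <- sum(present) - (if (is.na(fp_hh)) 0 else fp_hh) + combined
  if (!include_handprint || is.null(scen$handprint)) {
    # footprint-only view: combined_hh reduces to the footprint HH itself
    score <- sum(present)
  }

  structure(list(scenario = scen$name,
                 score = score,
                 components = comp,
                 hh_handprint = hp_weighted,
                 hh_footprint = fp_hh,
                 handprint_included = include_handprint && !is.null(scen$handprint),
                 provenance = list(nf_id = nf$id, hnf_id = hnf$id,
                                   wf_id = wf$id, variant = variant)),
            class = "single_score_result")
}

#' Score one scenario through the full pipeline
#'
#' Normalizes the footprint with `nf` and the handprint with `hnf`, applies
#' the panel weights, combines handprint and footprint on Human Health, and
#' sums to a single score.  Missing footprint entries contribute zero to the
#' sum but remain missing in the reported components.
#'
#' @param scen a [scenario()].
#' @param nf a [normalization_set()] for the footprint.
#' @param hnf a [handprint_normalization_set()] for the handprint.
#' @param wf a [weighting_set()].
#' @param variant which handprint value to use: `"base"`, `"min"` or `"max"`.
#' @param include_handprint include the handprint in the Human Health
#'   component (default `TRUE`); set `FALSE` for a footprint-only score.
#' @return A `single_score_result` with the score, the weighted footprint
#'   components, the weighted handprint/footprint Human Health split and full
#'   provenance.
#' @export
scenario_single_score <- function(scen, nf, hnf, wf, variant = "base",
                                  include_handprint = TRUE) {
  score_scenario(scen, nf, hnf, wf, variant, include_handprint)
}

#' Share of the Human Health single-score component due to the handprint
#'
#' @param ss a `single_score_result` from [scenario_single_score()] that
#'   recorded a handprint/footprint Human Health split.
#' @return Percent of the weighted Human Health component attributable to the
#'   handprint, or `NA` when the Human Health total is zero.
#' @export
hh_handprint_share <- function(ss) {
  if (!inherits(ss, "single_score_result") || is.null(ss$hh_handprint)) {
    stop_validation("ss must be a scored scenario with a Human Health split")
  }
  hp <- if (is.na(ss$hh_handprint)) 0 else ss$hh_handprint
  fp <- if (is.na(ss$hh_footprint)) 0 else ss$hh_footprint
  tot <- hp + fp
  if (tot == 0) return(NA_real_)
  hp / tot * 100
}

#' Decide whether the RSBR is reported combined or separate
#'
#' When treatment moves the footprint and the handprint burdens in the same
#' direction (both increase or both decrease), a combined rate would be
#' dominated by the larger absolute term and misrepresent the smaller one,
#' so the two rates are kept separate.  When they move in opposite
#' directions — the usual benefit-vs-burden trade-off — they are combined.
#' A zero or absent delta on either side also yields `COMBINED`.
#'
#' @inheritParams compare_case
#' @return `"SEPARATE"` or `"COMBINED"`.
#' @export
decide_rsbr_mode <- function(case, nf, hnf, wf, variant = "base") {
  fp_c <- score_scenario(case$comparator, nf, hnf, wf, variant,
                         include_handprint = FALSE)$score
  fp_t <- score_scenario(case$treatment, nf, hnf, wf, variant,
                         include_handprint = FALSE)$score
  hp_c <- hp_t <- 0
  if (!is.null(case$comparator$handprint)) {
    hp_c <- normalize_handprint(case$comparator$handprint[[variant]], hnf) *
      wf$weights[["HUMAN_HEALTH"]]
  }
  if (!is.null(case$treatment$handprint)) {
    hp_t <- normalize_handprint(case$treatment$handprint[[variant]], hnf) *
      wf$weights[["HUMAN_HEALTH"]]
  }
  d_fp <- fp_c - fp_t
  d_hp <- hp_c - hp_t
  if (d_fp != 0 && d_hp != 0 && sign(d_fp) == sign(d_hp)) "SEPARATE" else "COMBINED"
}

#' Compare the two arms of a case study
#'
#' Runs the full pipeline on both scenarios and reports the RSBR.  The
#' combined rate uses single scores with handprint and footprint merged on
#' Human Health; the separate rates use footprint-only and handprint-only
#' scores.  `mode = "auto"` applies [decide_rsbr_mode()].
#'
#' @param case a [case_study()].
#' @param nf,hnf,wf value-choice sets, as in [scenario_single_score()].
#' @param variant handprint variant: `"base"`, `"min"` or `"max"`.
#' @param mode `"auto"`, `"combined"` or `"separate"`.
#' @param table_sign negate reported rates for display (see [rsbr_percent()]).
#' @return An object of class `rsbr_result`: mode, the three rates (percent
#'   or `NA`), the four underlying scores, and provenance.
#' @examples
#' case <- builtin_case("sth_vietnam")
#' f <- reference_factors("sth_vietnam")
#' compare_case(case, f$nf, f$hnf, f$wf, table_sign = TRUE)
#' @export
compare_case <- function(case, nf, hnf, wf, variant = "base",
                         mode = c("auto", "combined", "separate"),
                         table_sign = FALSE) {
  if (!inherits(case, "case_study")) stop_validation("case must be a case_study")
  mode <- match.arg(mode)
  resolved <- switch(mode,
    auto = decide_rsbr_mode(case, nf, hnf, wf, variant),
    combined = "COMBINED",
    separate = "SEPARATE")

  sc_c <- score_scenario(case$comparator, nf, hnf, wf, variant)
  sc_t <- score_scenario(case$treatment, nf, hnf, wf, variant)
  fp_c <- score_scenario(case$comparator, nf, hnf, wf, variant,
                         include_handprint = FALSE)
  fp_t <- score_scenario(case$treatment, nf, hnf, wf, variant,
                         include_handprint = FALSE)

  hp_score <- function(scen) {
    if (is.null(scen$handprint)) return(NA_real_)
    normalize_handprint(scen$handprint[[variant]], hnf) *
      wf$weights[["HUMAN_HEALTH"]]
  }
  hp_c <- hp_score(case$comparator)
  hp_t <- hp_score(case$treatment)

  rate <- function(comp, treat) {
    if (is.na(comp) || is.na(treat)) return(NA_real_)
    rsbr_percent(comp, treat, table_sign)
  }
  structure(list(
    case = case$name,
    mode = resolved,
    combined_rsbr = rate(sc_c$score, sc_t$score),
    footprint_rsbr = rate(fp_c$score, fp_t$score),
    handprint_rsbr = rate(hp_c, hp_t),
    scores = list(combined = c(comparator = sc_c$score, treatment = sc_t$score),
                  footprint = c(comparator = fp_c$score, treatment = fp_t$score),
                  handprint = c(comparator = hp_c, treatment = hp_t)),
    table_sign = table_sign,
    provenance = sc_t$provenance),
    class = "rsbr_result")
}

#' @export
print.rsbr_result <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", v)
  cat(sprintf("<rsbr_result> %s [mode %s]\n", x$case, x$mode))
  if (identical(x$mode, "COMBINED")) {
    cat("  combined RSBR: ", fmt(x$combined_rsbr), "\n", sep = "")
  } else {
    cat("  footprint RSBR: ", fmt(x$footprint_rsbr),
        "; handprint RSBR: ", fmt(x$handprint_rsbr), "\n", sep = "")
  }
  invisible(x)
}

#' Raw-DALY handprint benefit of treatment
#'
#' The relative reduction in patient DALY burden of the treatment arm versus
#' the comparator, computed on raw DALYs before any normalization or
#' weighting (which cancel in the ratio).
#'
#' @param case a [case_study()] whose arms both carry handprints.
#' @param variant handprint variant.
#' @param table_sign negate for display.
#' @return Percent reduction, or `NA` when the comparator burden is zero.
#' @export
handprint_benefit <- function(case, variant = "base", table_sign = FALSE) {
  variant <- match.arg(variant, c("base", "min", "max"))
  hc <- case$comparator$handprint
  ht <- case$treatment$handprint
  if (is.null(hc) || is.null(ht)) {
    stop_validation("both arms need a handprint to compute the benefit")
  }
  rsbr_percent(hc[[variant]], ht[[variant]], table_sign)
}
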