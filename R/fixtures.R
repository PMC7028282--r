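# Built-in case studies, derived reference factors, and random generators.

# Published reference values shipped with the two built-in case studies:
# raw footprints (Table of treatment footprints), raw handprints with
# sensitivity bounds, and the reference-report normalized / weighted /
# single-score cells used to derive the reference factors and for
# regression checks.  Provenance: "transcribed" = copied from the published
# tables; "derived" = computed from ratios of transcribed cells.
.case_registry <- local({
  sth <- list(
    case = list(
      name = "sth_vietnam",
      functional_unit = "MDA for 8,000,000 Vietnamese children aged 5-14, mebendazole 500 mg every six months for 5 years, 80% coverage",
      comparator = list(
        name = "no treatment",
        footprint = c(NA_real_, NA_real_, NA_real_),
        handprint = c(206533, 98819, 336790)),
      treatment = list(
        name = "mebendazole MDA",
        footprint = c(5.75, 2.87e-2, 2.23e5),
        handprint = c(89946, 58812, 124840))),
    reference = list(
      # normalized footprint rows (/yr) as printed in the reference report
      footprint_normalized = list(
        comparator = c(HUMAN_HEALTH = 0, ECOSYSTEMS = 0, RESOURCES = 0),
        treatment = c(HUMAN_HEALTH = 6.94e-8, ECOSYSTEMS = 5.15e-9,
                      RESOURCES = 1.50e-7)),
      handprint_normalized = c(comparator = 7.38e-5, treatment = 3.22e-5),
      footprint_weighted = list(
        comparator = c(HUMAN_HEALTH = 0, ECOSYSTEMS = 0, RESOURCES = 0),
        treatment = c(HUMAN_HEALTH = 2.77e-8, ECOSYSTEMS = 2.06e-9,
                      RESOURCES = 2.99e-8)),
      single_score_footprint = c(comparator = 0, treatment = 5.98e-8),
      single_score_combined = c(comparator = 2.95e-5, treatment = 1.29e-5),
      combined_rsbr_table_sign = -56.25,
      # rows used to derive reference factors (comparator footprint is NA,
      # so footprint factors come from the treatment row)
      nf_derivation_row = "treatment",
      hnf_derivation_row = "comparator"))
  scz <- list(
    case = list(
      name = "schizophrenia_belgium",
      functional_unit = "Maintenance treatment of 1000 Belgian patients with schizophrenia for 1 year, paliperidone palmitate 100 mg once-monthly",
      comparator = list(
        name = "treatment interruption",
        footprint = c(8.55e-1, 5.00e-3, 3.35e4),
        handprint = c(973.03, 942.08, 1017.71)),
      treatment = list(
        name = "paliperidone palmitate",
        footprint = c(5.12e-1, 2.92e-3, 1.93e4),
        handprint = c(904.12, 889.54, 920.16))),
    reference = list(
      footprint_normalized = list(
        comparator = c(HUMAN_HEALTH = 9.81e-9, ECOSYSTEMS = 8.97e-10,
                       RESOURCES = 2.25e-8),
        treatment = c(HUMAN_HEALTH = 6.18e-9, ECOSYSTEMS = 5.24e-10,
                      RESOURCES = 1.30e-8)),
      handprint_normalized = c(comparator = 3.48e-7, treatment = 3.16e-7),
      footprint_weighted = list(
        comparator = c(HUMAN_HEALTH = 3.93e-9, ECOSYSTEMS = 3.59e-10,
                       RESOURCES = 4.50e-9),
        treatment = c(HUMAN_HEALTH = 2.47e-9, ECOSYSTEMS = 2.09e-10,
                      RESOURCES = 2.60e-9)),
      single_score_footprint = c(comparator = 8.79e-9, treatment = 5.28e-9),
      single_score_combined = c(comparator = NA_real_, treatment = NA_real_),
      footprint_rsbr_table_sign = -39.9,
      nf_derivation_row = "comparator",
      hnf_derivation_row = "comparator"))
  list(sth_vietnam = sth, schizophrenia_belgium = scz)
})

registry_entry <- function(name) {
  entry <- .case_registry[[name]]
  if (is.null(entry)) {
    stop_validation(sprintf("unknown case '%s'; available: %s", name,
                            paste(names(.case_registry), collapse = ", ")))
  }
  entry
}

build_scenario <- function(spec) {
  fp <- spec$footprint
  scenario(spec$name,
           footprint = impact_vector(fp[1], fp[2], fp[3]),
           handprint = handprint_estimate(spec$handprint[1], spec$handprint[2],
                                          spec$handprint[3]))
}

#' Built-in pharmaceutical case studies
#'
#' Two fully specified treatment-vs-comparator cases ship with the package:
#'
#' * `"sth_vietnam"` — mebendazole mass drug administration against
#'   soil-transmitted helminthiases in Vietnamese school children versus no
#'   treatment.  The comparator has no assessed footprint (all missing).
#' * `"schizophrenia_belgium"` — once-monthly paliperidone palmitate
#'   maintenance treatment versus treatment interruption in Belgium.
#'
#' Footprint and handprint values are transcribed from the published tables
#' of the underlying studies.
#'
#' @param name case name.
#' @return A [case_study()].
#' @examples
#' builtin_case("sth_vietnam")
#' @export
builtin_case <- function(name) {
  entry <- registry_entry(name)
  case_study(entry$case$name,
             treatment = build_scenario(entry$case$treatment),
             comparator = build_scenario(entry$case$comparator),
             functional_unit = entry$case$functional_unit)
}

#' Names of the built-in cases
#' @return Character vector of case names accepted by [builtin_case()].
#' @export
builtin_case_names <- function() names(.case_registry)

#' Published reference cells for a built-in case
#'
#' The normalized, weighted and single-score values of the published
#' reference run (footprint normalization: ReCiPe Hierarchist World 2000;
#' handprint normalization: GBD World 2000; weighting: Eco-Indicator 99
#' default), as printed at three significant figures.  Used to derive the
#' reference factors and as regression anchors.
#'
#' @param name case name.
#' @return A list of printed reference values (`footprint_normalized`,
#'   `handprint_normalized`, `footprint_weighted`, `single_score_footprint`,
#'   `single_score_combined`, and the reported signed rates).
#' @export
reference_values <- function(name) registry_entry(name)$reference

#' Derived reference normalization and weighting factors
#'
#' The numeric normalization-factor tables of the reference frameworks are
#' not shipped; instead each factor is derived as (raw burden) / (printed
#' normalized value) from one row of the published reference report:
#' the comparator row where possible, the treatment row for the STH
#' footprint (whose comparator footprint was not assessed).  The weighting
#' set is the Eco-Indicator 99 default (0.4, 0.4, 0.2), recovered as the
#' weighted/normalized column ratio.  Because each case is derived from its
#' own rows, the two cases carry slightly different Human Health footprint
#' factors (about 8.29e7 vs 8.72e7 DALY/yr) — a rounding artefact of the
#' three-significant-figure source cells.
#'
#' @param name case name.
#' @return List with `nf` ([normalization_set()]), `hnf`
#'   ([handprint_normalization_set()]) and `wf` ([weighting_set()]), all
#'   labelled as derived.
#' @export
reference_factors <- function(name) {
  entry <- registry_entry(name)
  ref <- entry$reference
  raw_fp <- entry$case[[ref$nf_derivation_row]]$footprint
  norm_fp <- ref$footprint_normalized[[ref$nf_derivation_row]]
  nf <- normalization_set(
    id = paste0("derived-recipe-hierarchist-", name),
    source = "derived", year = 2000L,
    human_health = raw_fp[1] / norm_fp[["HUMAN_HEALTH"]],
    ecosystems = raw_fp[2] / norm_fp[["ECOSYSTEMS"]],
    resources = raw_fp[3] / norm_fp[["RESOURCES"]])
  raw_hp <- entry$case[[ref$hnf_derivation_row]]$handprint[1]
  hnf <- handprint_normalization_set(
    id = paste0("derived-gbd-", name), year = 2000L,
    factor = raw_hp / ref$handprint_normalized[[ref$hnf_derivation_row]])
  wf <- weighting_set("EI99-default", "EI99", 0.4, 0.4, 0.2)
  list(nf = nf, hnf = hnf, wf = wf)
}

runif_log <- function(n, center, spread) {
  center * exp(stats::runif(n, -log(spread), log(spread)))
}

# Random simplex point (flat Dirichlet) for synthetic weighting sets.
rsimplex3 <- function() {
  g <- stats::rgamma(3, shape = 1)
  g / sum(g)
}

#' Synthetic value-choice pools with the canonical structure
#'
#' Generates a [factor_pools()] with the structure of the published
#' sensitivity design — 4 footprint normalization sets, 4 handprint
#' normalization sets, and 26 weighting sub-sets grouped as Eco-Indicator 99
#' (4), Itsubo country panels (19) and EC-JRC Environmental Footprint (3;
#' inferred group size), with all three handprint variants enabled — for
#' 1248 combinations.  The numeric values are synthetic: normalization
#' factors are log-uniform perturbations (within a factor `spread`) around
#' the derived reference factors of a built-in case, and weights are drawn
#' uniformly on the simplex.  The pool is flagged `synthetic`; supply real
#' factor tables through [read_factor_pools()] to replace it.
#'
#' @param seed integer seed.
#' @param case built-in case whose derived reference factors anchor the
#'   magnitudes (default `"sth_vietnam"`).
#' @param spread maximal multiplicative perturbation of the normalization
#'   factors (default 3, mirroring the order-of-magnitude spread of
#'   published factor families).
#' @return A [factor_pools()] with `n_combinations()` of 1248.
#' @export
synthetic_pools <- function(seed = 0, case = "sth_vietnam", spread = 3) {
  ref <- reference_factors(case)
  set.seed(as.integer(seed))
  nf_sources <- c("ReCiPe-Individualist", "ReCiPe-Hierarchist",
                  "ReCiPe-Egalitarian", "PROSUITE")
  fps <- lapply(seq_along(nf_sources), function(i) {
    f <- ref$nf$factors * runif_log(3, 1, spread)
    normalization_set(sprintf("synthetic-nf-%d", i), nf_sources[i],
                      if (i == 4) 2010L else 2000L, f[1], f[2], f[3])
  })
  years <- c(2000L, 2005L, 2010L, 2015L)
  hps <- lapply(seq_along(years), function(i) {
    handprint_normalization_set(sprintf("synthetic-hnf-%d", i), years[i],
                                ref$hnf$factor * runif_log(1, 1, spread))
  })
  group_sizes <- c(EI99 = 4L, ITSUBO = 19L, EC_JRC_EF = 3L)
  wfs <- lapply(names(group_sizes), function(lbl) {
    lapply(seq_len(group_sizes[[lbl]]), function(j) {
      w <- rsimplex3()
      weighting_set(sprintf("synthetic-%s-%d", lbl, j), lbl, w[1], w[2], w[3])
    })
  })
  names(wfs) <- names(group_sizes)
  factor_pools(fps, hps, wfs, synthetic = TRUE)
}

#' Generate a random valid case study
#'
#' Draws log-uniform footprints on both arms and ordered handprint bounds,
#' reproducibly per seed.  Intended for property tests and examples.
#'
#' @param seed integer seed.
#' @param fp_range magnitude range (min, max) for footprint burdens; the
#'   three Areas of Protection are drawn independently within it.
#' @param hp_range magnitude range for the base handprint burden.
#' @return A validated [case_study()].
#' @export
generate_random_case <- function(seed = 0, fp_range = c(1e-3, 1e6),
                                 hp_range = c(1, 1e6)) {
  if (any(fp_range <= 0) || any(hp_range <= 0) || fp_range[1] > fp_range[2] ||
      hp_range[1] > hp_range[2]) {
    stop_validation("ranges must be positive and ordered")
  }
  set.seed(as.integer(seed))
  rlog <- function(n, r) exp(stats::runif(n, log(r[1]), log(r[2])))
  arm <- function(nm) {
    fp <- rlog(3, fp_range)
    base <- rlog(1, hp_range)
    lo <- base * stats::runif(1, 0.5, 1)
    hi <- base * stats::runif(1, 1, 2)
    scenario(nm, impact_vector(fp[1], fp[2], fp[3]),
             handprint_estimate(base, lo, hi))
  }
  case_study(sprintf("random-%d", as.integer(seed)),
             treatment = arm("treatment"), comparator = arm("comparator"))
}
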