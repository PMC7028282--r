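# Uncertainty over value choices: hierarchical Monte Carlo over pools of
# normalization/weighting sets, exhaustive enumeration, one-way sensitivity.

#' Pools of value-choice sets
#'
#' Bundles the candidate normalization sets for footprint and handprint, the
#' panel weighting sets grouped by main family, and the enabled handprint
#' variants.  These pools are what the Monte Carlo and the exhaustive
#' enumeration range over.
#'
#' @param footprint_nfs list of [normalization_set()] objects.
#' @param handprint_nfs list of [handprint_normalization_set()] objects.
#' @param weighting_sets named list over main-set labels (see
#'   [wf_main_sets()]), each element a non-empty list of [weighting_set()]
#'   objects belonging to that family.
#' @param variants subset of `c("base", "min", "max")`.
#' @param synthetic flag recording that the numeric values are generated, not
#'   transcribed from published factor tables.
#' @return An object of class `factor_pools`.
#' @seealso [synthetic_pools()] for a generated pool with the canonical
#'   4 x 4 x 26 x 3 structure.
#' @export
factor_pools <- function(footprint_nfs, handprint_nfs, weighting_sets,
                         variants = c("base", "min", "max"),
                         synthetic = FALSE) {
  if (length(footprint_nfs) == 0 || length(handprint_nfs) == 0 ||
      length(weighting_sets) == 0 || length(variants) == 0) {
    stop_validation("every factor pool must be non-empty")
  }
  for (nf in footprint_nfs) {
    if (!inherits(nf, "normalization_set")) {
      stop_validation("footprint_nfs must contain normalization_set objects")
    }
  }
  for (nf in handprint_nfs) {
    if (!inherits(nf, "handprint_normalization_set")) {
      stop_validation("handprint_nfs must contain handprint_normalization_set objects")
    }
  }
  if (is.null(names(weighting_sets)) ||
      !all(names(weighting_sets) %in% wf_main_sets())) {
    stop_validation("weighting_sets must be named by main-set label")
  }
  for (lbl in names(weighting_sets)) {
    grp <- weighting_sets[[lbl]]
    if (length(grp) == 0) stop_validation("empty weighting main set: ", lbl)
    for (wf in grp) {
      if (!inherits(wf, "weighting_set") || !identical(wf$main_set, lbl)) {
        stop_validation(sprintf("weighting set grouped under %s must carry that main_set", lbl))
      }
    }
  }
  variants <- match.arg(variants, c("base", "min", "max"), several.ok = TRUE)
  structure(list(footprint_nfs = footprint_nfs,
                 handprint_nfs = handprint_nfs,
                 weighting_sets = weighting_sets,
                 variants = variants,
                 synthetic = isTRUE(synthetic)),
            class = "factor_pools")
}

#' Number of value-choice combinations in a pool
#'
#' The product |footprint NFs| x |handprint NFs| x |all WF sub-sets| x
#' |variants|.  With 4, 4, 26 and 3 this is 1248.
#'
#' @param pools a [factor_pools()].
#' @return Integer combination count.
#' @export
n_combinations <- function(pools) {
  length(pools$footprint_nfs) * length(pools$handprint_nfs) *
    sum(lengths(pools$weighting_sets)) * length(pools$variants)
}

#' @export
print.factor_pools <- function(x, ...) {
  cat(sprintf(
    "<factor_pools>%s %d footprint NF, %d handprint NF, %d WF (%s), %d variant(s); %d combinations\n",
    if (x$synthetic) " [synthetic]" else "",
    length(x$footprint_nfs), length(x$handprint_nfs),
    sum(lengths(x$weighting_sets)),
    paste(sprintf("%s:%d", names(x$weighting_sets), lengths(x$weighting_sets)),
          collapse = ", "),
    length(x$variants), n_combinations(x)))
  invisible(x)
}

#' Draw one value-choice combination
#'
#' Samples the footprint and handprint normalization sets uniformly from
#' their pools; the weighting set hierarchically — first a main family,
#' uniformly over families, then a sub-set uniformly within that family —
#' and the handprint variant uniformly over the enabled variants.  All draws
#' are independent and consume the current R random stream (seed with
#' [set.seed()]).
#'
#' @param pools a [factor_pools()].
#' @return List with elements `nf`, `hnf`, `wf`, `variant`.
#' @export
sample_iteration <- function(pools) {
  if (!inherits(pools, "factor_pools")) {
    stop_validation("pools must be a factor_pools object")
  }
  nf <- pools$footprint_nfs[[sample.int(length(pools$footprint_nfs), 1L)]]
  hnf <- pools$handprint_nfs[[sample.int(length(pools$handprint_nfs), 1L)]]
  main <- names(pools$weighting_sets)[sample.int(length(pools$weighting_sets), 1L)]
  grp <- pools$weighting_sets[[main]]
  wf <- grp[[sample.int(length(grp), 1L)]]
  variant <- pools$variants[[sample.int(length(pools$variants), 1L)]]
  list(nf = nf, hnf = hnf, wf = wf, variant = variant)
}

summarize_draws <- function(x) {
  ok <- x[!is.na(x)]
  if (length(ok) == 0) {
    return(c(median = NA_real_, min = NA_real_, max = NA_real_,
             p2.5 = NA_real_, p97.5 = NA_real_, n = 0))
  }
  q <- stats::quantile(ok, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  c(median = q[2], min = min(ok), max = max(ok), p2.5 = q[1], p97.5 = q[3],
    n = length(ok))
}

run_pool_iterations <- function(case, combos, table_sign = FALSE) {
  n <- length(combos)
  draws <- data.frame(
    iteration = seq_len(n),
    nf_id = character(n), hnf_id = character(n), wf_id = character(n),
    variant = character(n), mode = character(n),
    combined_rsbr = numeric(n), footprint_rsbr = numeric(n),
    handprint_rsbr = numeric(n),
    score_combined_comparator = numeric(n), score_combined_treatment = numeric(n),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    d <- combos[[i]]
    res <- compare_case(case, d$nf, d$hnf, d$wf, d$variant,
                        table_sign = table_sign)
    draws$nf_id[i] <- d$nf$id
    draws$hnf_id[i] <- d$hnf$id
    draws$wf_id[i] <- d$wf$id
    draws$variant[i] <- d$variant
    draws$mode[i] <- res$mode
    draws$combined_rsbr[i] <- res$combined_rsbr
    draws$footprint_rsbr[i] <- res$footprint_rsbr
    draws$handprint_rsbr[i] <- res$handprint_rsbr
    draws$score_combined_comparator[i] <- res$scores$combined[["comparator"]]
    draws$score_combined_treatment[i] <- res$scores$combined[["treatment"]]
  }
  draws
}

#' Monte Carlo over value choices
#'
#' Re-runs the full pipeline `iterations` times, each time with a fresh
#' hierarchical draw from the pools (see [sample_iteration()]), and
#' summarizes the resulting RSBR and single-score distributions.  Identical
#' seeds give identical output.
#'
#' @param case a [case_study()].
#' @param pools a [factor_pools()].
#' @param iterations number of iterations (default 10000).
#' @param seed integer seed; mandatory for reproducible published runs.
#' @param variant `"sample"` (default) draws the handprint variant uniformly
#'   per iteration; `"base"`, `"min"` or `"max"` pin it.
#' @param table_sign negate reported rates for display.
#' @return An object of class `mc_summary`: a `summary` matrix (rows =
#'   outputs, columns = median/min/max/2.5%/97.5%/n), NA-iteration counts,
#'   the per-iteration `draws` data frame with full provenance, and the seed.
#' @export
run_monte_carlo <- function(case, pools, iterations = 10000, seed = 0,
                            variant = c("sample", "base", "min", "max"),
                            table_sign = FALSE) {
  variant <- match.arg(variant)
  if (!is.numeric(iterations) || iterations < 1) {
    stop_validation("iterations must be >= 1")
  }
  iterations <- as.integer(iterations)
  eff_pools <- pools
  if (variant != "sample") {
    if (!variant %in% pools$variants) {
      stop_validation(sprintf("variant '%s' is not enabled in the pools", variant))
    }
    eff_pools$variants <- variant
  }
  set.seed(as.integer(seed))
  combos <- lapply(seq_len(iterations), function(i) sample_iteration(eff_pools))
  draws <- run_pool_iterations(case, combos, table_sign)

  outputs <- c("combined_rsbr", "footprint_rsbr", "handprint_rsbr",
               "score_combined_comparator", "score_combined_treatment")
  summ <- t(vapply(outputs, function(o) summarize_draws(draws[[o]]),
                   numeric(6)))
  na_counts <- vapply(outputs, function(o) sum(is.na(draws[[o]])), integer(1))
  modes <- unique(draws$mode)
  structure(list(case = case$name,
                 summary = summ,
                 na_iterations = na_counts,
                 mode = if (length(modes) == 1) modes else "MIXED",
                 iterations = iterations,
                 seed = as.integer(seed),
                 variant_policy = variant,
                 table_sign = table_sign,
                 draws = draws),
            class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("<mc_summary> %s: %d iterations, seed %d, mode %s\n",
              x$case, x$iterations, x$seed, x$mode))
  print(signif(x$summary, 4))
  invisible(x)
}

#' Enumerate every value-choice combination exactly
#'
#' Runs the pipeline once for each element of the Cartesian product of the
#' pools (footprint NF x handprint NF x WF sub-set x variant) and returns
#' the full result table.  The enumeration supplies exact medians and
#' extremes; any Monte Carlo sample from the same pools takes values from
#' this table.
#'
#' @inheritParams run_monte_carlo
#' @return A data frame with one row per combination and full provenance
#'   columns, plus an attribute `n_combinations`.
#' @export
enumerate_combinations <- function(case, pools, table_sign = FALSE) {
  if (!inherits(pools, "factor_pools")) {
    stop_validation("pools must be a factor_pools object")
  }
  wf_flat <- unlist(unname(pools$weighting_sets), recursive = FALSE)
  grid <- expand.grid(i_nf = seq_along(pools$footprint_nfs),
                      i_hnf = seq_along(pools$handprint_nfs),
                      i_wf = seq_along(wf_flat),
                      i_v = seq_along(pools$variants))
  combos <- lapply(seq_len(nrow(grid)), function(r) {
    list(nf = pools$footprint_nfs[[grid$i_nf[r]]],
         hnf = pools$handprint_nfs[[grid$i_hnf[r]]],
         wf = wf_flat[[grid$i_wf[r]]],
         variant = pools$variants[[grid$i_v[r]]])
  })
  draws <- run_pool_iterations(case, combos, table_sign)
  draws$iteration <- NULL
  attr(draws, "n_combinations") <- nrow(grid)
  draws
}

#' One-way sensitivity of the single scores to value choices
#'
#' Attributes single-score variability to either the weighting or the
#' normalization step by fixing one side to a reference set and sampling the
#' other: axis `"FIX_NF_VARY_WF"` holds the reference normalization sets and
#' samples weighting sets hierarchically; `"FIX_WF_VARY_NF"` holds the
#' reference weighting set and samples both normalization pools.
#'
#' @inheritParams run_monte_carlo
#' @param axis which side to vary.
#' @param reference list with elements `nf`, `hnf`, `wf`: the sets held
#'   fixed on the non-varying side.
#' @param iterations number of iterations (default 2000).
#' @return An object of class `sensitivity_result` with per-scenario spread
#'   statistics (min, max, range, interquartile range) of the combined
#'   single scores and the per-iteration draws.
#' @export
one_way_sensitivity <- function(case, pools, axis = c("FIX_NF_VARY_WF",
                                                      "FIX_WF_VARY_NF"),
                                reference, iterations = 2000, seed = 0,
                                variant = "base") {
  axis <- match.arg(axis)
  variant <- match.arg(variant, c("base", "min", "max"))
  if (!all(c("nf", "hnf", "wf") %in% names(reference))) {
    stop_validation("reference must carry nf, hnf and wf")
  }
  set.seed(as.integer(seed))
  iterations <- as.integer(iterations)
  combos <- lapply(seq_len(iterations), function(i) {
    d <- sample_iteration(pools)
    if (axis == "FIX_NF_VARY_WF") {
      list(nf = reference$nf, hnf = reference$hnf, wf = d$wf, variant = variant)
    } else {
      list(nf = d$nf, hnf = d$hnf, wf = reference$wf, variant = variant)
    }
  })
  draws <- run_pool_iterations(case, combos)
  spread <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    c(min = min(x), max = max(x), range = max(x) - min(x),
      iqr = q[2] - q[1])
  }
  structure(list(case = case$name, axis = axis, iterations = iterations,
                 seed = as.integer(seed),
                 spread = rbind(
                   comparator = spread(draws$score_combined_comparator),
                   treatment = spread(draws$score_combined_treatment)),
                 draws = draws),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> %s, axis %s, %d iterations\n",
              x$case, x$axis, x$iterations))
  print(signif(x$spread, 4))
  invisible(x)
}
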