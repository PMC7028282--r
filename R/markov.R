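# Cohort state-transition (Markov) engine generating DALY handprints.

#' Cohort state-transition model
#'
#' A Markov cohort model: a set of health states with disability weights, a
#' row-stochastic per-cycle transition matrix, a cycle length in years and a
#' horizon in cycles.  Propagating a cohort through the model and weighting
#' state occupancy by disability yields years lived with disability (YLD);
#' entries into death states weighted by remaining life expectancy yield
#' years of life lost (YLL).  YLD + YLL is the DALY burden — the handprint
#' of the modelled scenario.
#'
#' @param states data frame with columns `id` (unique state names), `dw`
#'   (disability weight in \[0, 1\]), and optionally `absorbing` (logical)
#'   and `death` (logical; death states must be absorbing).
#' @param transition square matrix of per-cycle transition probabilities,
#'   rows = source states in the order of `states$id`; every row must sum to
#'   1 within `1e-9` and absorbing states must have self-transition 1.
#' @param cycle_length_years length of one cycle in years (> 0).
#' @param horizon_cycles number of cycles to simulate (>= 1).
#' @param initial initial distribution over states (sums to 1 within `1e-9`);
#'   defaults to everyone in the first state.
#' @param cohort cohort size in persons (> 0).
#' @param life_expectancy named numeric: remaining life expectancy in years
#'   for each death state (defaults to 0 — no YLL unless specified).
#' @return An object of class `markov_model`.
#' @examples
#' m <- markov_model(
#'   states = data.frame(id = c("sick", "well"), dw = c(0.2, 0)),
#'   transition = rbind(c(0.8, 0.2), c(0, 1)),
#'   cycle_length_years = 1, horizon_cycles = 10, cohort = 100)
#' run_cohort(m)$yld
#' @export
markov_model <- function(states, transition, cycle_length_years = 1,
                         horizon_cycles = 1, initial = NULL, cohort = 1,
                         life_expectancy = NULL) {
  if (!is.data.frame(states) || !all(c("id", "dw") %in% names(states))) {
    stop_validation("states must be a data frame with columns id and dw")
  }
  n <- nrow(states)
  if (n < 1 || anyDuplicated(states$id)) {
    stop_validation("states must be non-empty with unique ids")
  }
  if (any(is.na(states$dw)) || any(states$dw < 0 | states$dw > 1)) {
    stop_validation("disability weights must lie in [0, 1]")
  }
  if (is.null(states$absorbing)) states$absorbing <- FALSE
  if (is.null(states$death)) states$death <- FALSE
  if (any(states$death & !states$absorbing)) {
    stop_validation("death states must be absorbing")
  }
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(n, n))) {
    stop_validation(sprintf("transition matrix must be %d x %d", n, n))
  }
  validate_stochastic(transition)
  for (i in which(states$absorbing)) {
    if (abs(transition[i, i] - 1) > 1e-9) {
      stop_validation(sprintf("absorbing state '%s' must have self-transition 1",
                              states$id[i]))
    }
  }
  if (!is.numeric(cycle_length_years) || cycle_length_years <= 0) {
    stop_validation("cycle_length_years must be > 0")
  }
  if (!is.numeric(horizon_cycles) || horizon_cycles < 1) {
    stop_validation("horizon_cycles must be >= 1")
  }
  if (is.null(initial)) initial <- c(1, rep(0, n - 1))
  if (length(initial) != n || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-9) {
    stop_validation("initial must be a distribution over the states")
  }
  if (!is.numeric(cohort) || cohort <= 0) {
    stop_validation("cohort size must be > 0 persons")
  }
  le <- stats::setNames(rep(0, n), states$id)
  if (!is.null(life_expectancy)) {
    if (is.null(names(life_expectancy)) ||
        !all(names(life_expectancy) %in% states$id)) {
      stop_validation("life_expectancy must be named by state id")
    }
    if (any(life_expectancy < 0)) {
      stop_validation("life expectancy must be non-negative")
    }
    le[names(life_expectancy)] <- life_expectancy
  }
  dimnames(transition) <- list(states$id, states$id)
  structure(list(states = states, transition = transition,
                 cycle_length_years = as.numeric(cycle_length_years),
                 horizon_cycles = as.integer(horizon_cycles),
                 initial = as.numeric(initial), cohort = as.numeric(cohort),
                 life_expectancy = le),
            class = "markov_model")
}

validate_stochastic <- function(m, tol = 1e-9) {
  if (any(is.na(m)) || any(m < 0) || any(m > 1)) {
    stop_validation("transition probabilities must lie in [0, 1]")
  }
  bad <- which(abs(rowSums(m) - 1) > tol)
  if (length(bad) > 0) {
    stop_validation(sprintf("transition matrix row %d does not sum to 1", bad[1]))
  }
  invisible(m)
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf(
    "<markov_model> %d states, %d cycles of %g yr, cohort %g persons\n",
    nrow(x$states), x$horizon_cycles, x$cycle_length_years, x$cohort))
  invisible(x)
}

#' Advance a cohort distribution by one cycle
#'
#' @param distribution non-negative occupancy vector (persons or
#'   probability mass).
#' @param transition row-stochastic transition matrix.
#' @return `distribution %*% transition` as a plain vector; total mass is
#'   conserved.
#' @export
markov_step <- function(distribution, transition) {
  transition <- as.matrix(transition)
  validate_stochastic(transition)
  if (length(distribution) != nrow(transition) || any(distribution < 0)) {
    stop_validation("distribution must be non-negative and match the matrix")
  }
  as.numeric(distribution %*% transition)
}

#' Run a cohort through a Markov model
#'
#' Propagates the occupancy over the horizon and accumulates the DALY
#' burden.  Rewards accrue on the occupancy at the start of each cycle:
#' `YLD = sum over cycles of occupancy x disability weight x cycle length`.
#' YLL adds, for each entry into a death state, that state's remaining life
#' expectancy.  With `half_cycle = TRUE` the first and last cycle's YLD
#' contributions are halved (the standard half-cycle correction); the
#' default is off.
#'
#' @param model a [markov_model()].
#' @param half_cycle apply the half-cycle correction to YLD (default
#'   `FALSE`).
#' @return An object of class `markov_result`: `trajectory` (matrix, rows =
#'   cycles 0..horizon, columns = states, in persons), `yld`, `yll`, `daly`.
#' @export
run_cohort <- function(model, half_cycle = FALSE) {
  if (!inherits(model, "markov_model")) {
    stop_validation("model must be a markov_model")
  }
  n <- nrow(model$states)
  h <- model$horizon_cycles
  traj <- matrix(0, nrow = h + 1, ncol = n,
                 dimnames = list(0:h, model$states$id))
  occ <- model$initial * model$cohort
  traj[1, ] <- occ
  dw <- model$states$dw
  death <- model$states$death
  le <- model$life_expectancy

  yld <- 0
  yll <- 0
  for (k in seq_len(h)) {
    w <- if (half_cycle && (k == 1 || k == h)) 0.5 else 1
    yld <- yld + w * sum(occ * dw) * model$cycle_length_years
    nxt <- as.numeric(occ %*% model$transition)
    if (any(death)) {
      entries <- pmax(nxt[death] - occ[death], 0)
      yll <- yll + sum(entries * le[death])
    }
    occ <- nxt
    traj[k + 1, ] <- occ
  }
  structure(list(trajectory = traj, yld = yld, yll = yll, daly = yld + yll),
            class = "markov_result")
}

#' @export
print.markov_result <- function(x, ...) {
  cat(sprintf("<markov_result> YLD %s + YLL %s = %s DALY over %d cycles\n",
              format_sci(x$yld), format_sci(x$yll), format_sci(x$daly),
              nrow(x$trajectory) - 1))
  invisible(x)
}

#' Constant-prevalence DALY burden
#'
#' The burden of a 'no treatment' arm in which the initial disease state
#' persists unchanged: `cases x disability weight x horizon years`.
#' Equivalent to [run_cohort()] with an identity transition matrix.
#'
#' @param cases prevalent cases (persons, >= 0).
#' @param dw disability weight in \[0, 1\].
#' @param years horizon in years (>= 0).
#' @return DALY burden.
#' @export
constant_burden <- function(cases, dw, years) {
  for (v in list(cases, dw, years)) assert_scalar_number(v, "inputs")
  if (cases < 0 || years < 0) stop_validation("inputs must be non-negative")
  if (dw < 0 || dw > 1) stop_validation("disability weight must lie in [0, 1]")
  cases * dw * years
}

#' Build a handprint estimate from two cohort models
#'
#' Runs the treated and untreated models (the latter may be a constant
#' burden specification `list(cases=, dw=, years=)`) and packages their DALY
#' burdens as base-case handprints.  Min/max bounds are produced by
#' rescaling every disability weight by `1 -/+ dw_perturbation` (capped at
#' 1), the simplest one-parameter sensitivity analysis.
#'
#' @param treated a [markov_model()].
#' @param untreated a [markov_model()] or a list with `cases`, `dw`, `years`
#'   for [constant_burden()].
#' @param dw_perturbation relative perturbation of disability weights used
#'   for the min/max bounds (default 0.2); 0 collapses bounds to base.
#' @param half_cycle passed to [run_cohort()].
#' @return List with `treatment` and `comparator` [handprint_estimate()]s.
#' @export
handprint_from_models <- function(treated, untreated, dw_perturbation = 0.2,
                                  half_cycle = FALSE) {
  if (!inherits(treated, "markov_model")) {
    stop_validation("treated must be a markov_model")
  }
  if (dw_perturbation < 0 || dw_perturbation >= 1) {
    stop_validation("dw_perturbation must lie in [0, 1)")
  }
  const_spec <- !inherits(untreated, "markov_model")
  if (const_spec) {
    if (!all(c("cases", "dw", "years") %in% names(untreated))) {
      stop_validation("untreated must be a markov_model or cases/dw/years list")
    }
    horizon_years_u <- untreated$years
    cohort_u <- untreated$cases
  } else {
    horizon_years_u <- untreated$horizon_cycles * untreated$cycle_length_years
    cohort_u <- untreated$cohort
  }
  horizon_years_t <- treated$horizon_cycles * treated$cycle_length_years
  if (abs(horizon_years_t - horizon_years_u) > 1e-9 ||
      abs(treated$cohort - cohort_u) > 1e-9) {
    stop_validation("treated and untreated arms must share cohort size and horizon")
  }

  scale_dw <- function(model, f) {
    model$states$dw <- pmin(model$states$dw * f, 1)
    model
  }
  burden_t <- function(f) run_cohort(scale_dw(treated, f), half_cycle)$daly
  burden_u <- function(f) {
    if (const_spec) {
      constant_burden(untreated$cases, min(untreated$dw * f, 1), untreated$years)
    } else {
      run_cohort(scale_dw(untreated, f), half_cycle)$daly
    }
  }
  lo <- 1 - dw_perturbation
  hi <- 1 + dw_perturbation
  list(
    treatment = handprint_estimate(burden_t(1), burden_t(lo), burden_t(hi)),
    comparator = handprint_estimate(burden_u(1), burden_u(lo), burden_u(hi)))
}

#' Built-in synthetic cohort-model presets
#'
#' Structurally analogous stand-ins for the disease models behind the
#' built-in case studies; the numeric parameters are synthetic, not the
#' published ones.
#'
#' * `"sth_toy"` — a worm-infection intensity ladder (heavy/moderate/light/
#'   uninfected) with periodic-treatment recovery, 10 half-year cycles;
#'   its comparator is the constant initial burden.
#' * `"relapse_toy"` — a stable/relapse maintenance-treatment model with a
#'   death state, 12 monthly cycles.
#'
#' @param name preset name.
#' @return A list with elements `treated` (a [markov_model()]) and
#'   `untreated` (a model or constant-burden spec, as accepted by
#'   [handprint_from_models()]).
#' @export
markov_preset <- function(name = c("sth_toy", "relapse_toy")) {
  name <- match.arg(name)
  if (name == "sth_toy") {
    states <- data.frame(
      id = c("heavy", "moderate", "light", "uninfected"),
      dw = c(0.15, 0.05, 0.01, 0))
    trans <- rbind(c(0.30, 0.45, 0.20, 0.05),
                   c(0.02, 0.28, 0.45, 0.25),
                   c(0.01, 0.04, 0.35, 0.60),
                   c(0.01, 0.04, 0.15, 0.80))
    treated <- markov_model(states, trans, cycle_length_years = 0.5,
                            horizon_cycles = 10,
                            initial = c(0.25, 0.45, 0.30, 0),
                            cohort = 1000)
    start_dw <- sum(treated$initial * states$dw)
    untreated <- list(cases = 1000, dw = start_dw, years = 5)
  } else {
    states <- data.frame(
      id = c("stable", "relapse", "dead"),
      dw = c(0.35, 0.60, 0),
      absorbing = c(FALSE, FALSE, TRUE),
      death = c(FALSE, FALSE, TRUE))
    treated <- markov_model(
      states,
      rbind(c(0.975, 0.024, 0.001),
            c(0.300, 0.698, 0.002),
            c(0, 0, 1)),
      cycle_length_years = 1 / 12, horizon_cycles = 12,
      initial = c(1, 0, 0), cohort = 1000,
      life_expectancy = c(dead = 20))
    untreated <- markov_model(
      states,
      rbind(c(0.930, 0.068, 0.002),
            c(0.250, 0.746, 0.004),
            c(0, 0, 1)),
      cycle_length_years = 1 / 12, horizon_cycles = 12,
      initial = c(1, 0, 0), cohort = 1000,
      life_expectancy = c(dead = 20))
  }
  list(treated = treated, untreated = untreated)
}

#' Read and write Markov model specifications as JSON
#'
#' The JSON schema mirrors the [markov_model()] arguments: `states` (array
#' of objects with `id`, `dw`, optional `absorbing`, `death`),
#' `transition` (array of rows), `cycle_length_years`, `horizon_cycles`,
#' `initial`, `cohort`, optional `life_expectancy` (object keyed by death
#' state).
#'
#' @param path file path.
#' @param model a [markov_model()] (for writing).
#' @return `read_markov_model()` returns a validated [markov_model()];
#'   `write_markov_model()` returns `path` invisibly.
#' @export
read_markov_model <- function(path) {
  if (!file.exists(path)) stop_validation("no such model file: ", path)
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  states <- as.data.frame(x$states)
  le <- NULL
  if (!is.null(x$life_expectancy)) le <- unlist(x$life_expectancy)
  markov_model(states = states,
               transition = as.matrix(x$transition),
               cycle_length_years = x$cycle_length_years,
               horizon_cycles = x$horizon_cycles,
               initial = if (is.null(x$initial)) NULL else as.numeric(x$initial),
               cohort = x$cohort,
               life_expectancy = le)
}

#' @rdname read_markov_model
#' @export
write_markov_model <- function(model, path) {
  if (!inherits(model, "markov_model")) {
    stop_validation("model must be a markov_model")
  }
  x <- list(states = model$states,
            transition = unname(apply(model$transition, 1, as.numeric,
                                      simplify = FALSE)),
            cycle_length_years = model$cycle_length_years,
            horizon_cycles = model$horizon_cycles,
            initial = model$initial,
            cohort = model$cohort,
            life_expectancy = as.list(
              model$life_expectancy[model$states$death]))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
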