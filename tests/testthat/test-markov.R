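# Cohort state-transition engine: stepping, DALY accounting, invariants.

random_stochastic <- function(n) {
  m <- matrix(rgamma(n * n, 1), n, n)
  m / rowSums(m)
}

test_that("stepping multiplies by the matrix and conserves mass", {
  expect_equal(markov_step(c(0.3, 0.7), diag(2)), c(0.3, 0.7))
  expect_equal(markov_step(c(1, 0), rbind(c(0.5, 0.5), c(0, 1))), c(0.5, 0.5))
  expect_error(markov_step(c(1, 0), rbind(c(0.5, 0.6), c(0, 1))),
               class = "rsbr_validation_error")
  set.seed(31)
  for (i in 1:20) {
    m <- random_stochastic(4)
    d <- rgamma(4, 1)
    expect_equal(sum(markov_step(d, m)), sum(d), tolerance = 1e-12)
  }
})

test_that("long-run distribution matches the stationary left eigenvector", {
  set.seed(32)
  m <- random_stochastic(5)
  d <- c(1, 0, 0, 0, 0)
  for (k in 1:1000) d <- markov_step(d, m)
  e <- eigen(t(m))
  i <- which.min(abs(e$values - 1))
  stat <- Re(e$vectors[, i])
  stat <- stat / sum(stat)
  expect_equal(d, stat, tolerance = 1e-8)
})

test_that("model invariants are validated", {
  st <- data.frame(id = c("a", "b"), dw = c(0.5, 0))
  expect_error(markov_model(st, rbind(c(0.9, 0.2), c(0, 1))),
               class = "rsbr_validation_error")  # row sum
  st2 <- data.frame(id = c("a", "b"), dw = c(0.5, 0),
                    absorbing = c(FALSE, TRUE))
  expect_error(markov_model(st2, rbind(c(0.5, 0.5), c(0.1, 0.9))),
               class = "rsbr_validation_error")  # absorbing self-transition
  expect_error(markov_model(data.frame(id = "a", dw = 1.5), matrix(1)),
               class = "rsbr_validation_error")  # dw range
  expect_error(markov_model(st, rbind(c(0.5, 0.5), c(0, 1)),
                            initial = c(0.6, 0.6)),
               class = "rsbr_validation_error")  # initial distribution
})

test_that("cohort runs conserve mass and match closed forms", {
  # zero disability -> zero YLD
  m0 <- markov_model(data.frame(id = c("a", "b"), dw = c(0, 0)),
                     rbind(c(0.5, 0.5), c(0, 1)), horizon_cycles = 8,
                     cohort = 100)
  expect_equal(run_cohort(m0)$yld, 0)

  # one state: n * dw * t
  m1 <- markov_model(data.frame(id = "sick", dw = 0.1), matrix(1),
                     cycle_length_years = 1, horizon_cycles = 5,
                     cohort = 1000)
  expect_equal(run_cohort(m1)$yld, 500)

  # two-state geometric decay: 100 * 0.2 * sum_{k=0..9} 0.8^k
  m2 <- markov_model(data.frame(id = c("sick", "well"), dw = c(0.2, 0)),
                     rbind(c(0.8, 0.2), c(0, 1)), horizon_cycles = 10,
                     cohort = 100)
  r2 <- run_cohort(m2)
  expect_equal(r2$yld, 20 * (1 - 0.8^10) / 0.2, tolerance = 1e-12)
  expect_equal(r2$yld, 89.2625817890, tolerance = 1e-9)
  # mass conserved at every cycle
  expect_equal(unname(rowSums(r2$trajectory)), rep(100, 11),
               tolerance = 1e-12)
  expect_true(all(r2$trajectory >= 0))

  # random geometric models against the analytic YLD
  set.seed(33)
  for (i in 1:50) {
    p <- runif(1, 0.05, 0.95)   # stay-sick probability
    dw <- runif(1)
    h <- sample(1:40, 1)
    cyc <- runif(1, 0.1, 2)
    m <- markov_model(data.frame(id = c("s", "w"), dw = c(dw, 0)),
                      rbind(c(p, 1 - p), c(0, 1)), cycle_length_years = cyc,
                      horizon_cycles = h, cohort = 1)
    analytic <- dw * cyc * sum(p^(0:(h - 1)))
    expect_equal(run_cohort(m)$yld, analytic, tolerance = 1e-10)
  }
})

test_that("YLL counts death-state entries times remaining life expectancy", {
  st <- data.frame(id = c("alive", "dead"), dw = c(0, 0),
                   absorbing = c(FALSE, TRUE), death = c(FALSE, TRUE))
  m <- markov_model(st, rbind(c(0.9, 0.1), c(0, 1)), horizon_cycles = 3,
                    cohort = 1000, life_expectancy = c(dead = 30))
  r <- run_cohort(m)
  dead_total <- 1000 * (1 - 0.9^3)
  expect_equal(r$yll, dead_total * 30, tolerance = 1e-10)
  expect_equal(r$daly, r$yld + r$yll)
  # default life expectancy is zero -> no YLL
  m0 <- markov_model(st, rbind(c(0.9, 0.1), c(0, 1)), horizon_cycles = 3,
                     cohort = 1000)
  expect_equal(run_cohort(m0)$yll, 0)
})

test_that("half-cycle correction halves the first and last accrual", {
  m <- markov_model(data.frame(id = c("s", "w"), dw = c(0.3, 0)),
                    rbind(c(0.7, 0.3), c(0, 1)), horizon_cycles = 6,
                    cohort = 10)
  occ <- 10 * 0.7^(0:5)
  expect_equal(run_cohort(m)$yld, 0.3 * sum(occ), tolerance = 1e-12)
  expect_equal(run_cohort(m, half_cycle = TRUE)$yld,
               0.3 * (sum(occ) - 0.5 * occ[1] - 0.5 * occ[6]),
               tolerance = 1e-12)
})

test_that("constant burden equals an identity-matrix cohort run", {
  expect_equal(constant_burden(0, 0.3, 10), 0)
  expect_equal(constant_burden(1000, 0.05, 5), 250)
  set.seed(34)
  for (i in 1:20) {
    cases <- runif(1, 1, 1e5)
    dw <- runif(1)
    years <- sample(1:20, 1)
    m <- markov_model(data.frame(id = "sick", dw = dw), matrix(1),
                      cycle_length_years = 1, horizon_cycles = years,
                      cohort = cases)
    expect_equal(constant_burden(cases, dw, years), run_cohort(m)$yld,
                 tolerance = 1e-12)
  }
})

test_that("disability and recovery shift YLD monotonically", {
  set.seed(35)
  base_states <- data.frame(id = c("sick", "well"), dw = c(0.4, 0.05))
  for (i in 1:20) {
    p_stay <- runif(1, 0.2, 0.9)
    m <- markov_model(base_states, rbind(c(p_stay, 1 - p_stay), c(0, 1)),
                      horizon_cycles = 12, cohort = 50)
    y <- run_cohort(m)$yld
    # higher disability weight never lowers YLD
    up <- base_states
    up$dw[1] <- min(up$dw[1] + runif(1, 0, 0.5), 1)
    m_up <- markov_model(up, m$transition, horizon_cycles = 12, cohort = 50)
    expect_gte(run_cohort(m_up)$yld, y)
  }
  # direct check: lowering stay-sick probability never raises YLD
  yld_at <- function(p) {
    m <- markov_model(base_states, rbind(c(p, 1 - p), c(0, 1)),
                      horizon_cycles = 12, cohort = 50)
    run_cohort(m)$yld
  }
  ps <- seq(0.1, 0.9, by = 0.1)
  ylds <- vapply(ps, yld_at, numeric(1))
  expect_true(all(diff(ylds) >= 0))
})

test_that("handprints from paired models are ordered and packaged correctly", {
  preset <- markov_preset("sth_toy")
  hp <- handprint_from_models(preset$treated, preset$untreated)
  expect_s3_class(hp$treatment, "handprint_estimate")
  # treatment recovers, comparator stays constant -> strictly lower burden
  expect_lt(hp$treatment$base, hp$comparator$base)
  expect_lte(hp$treatment$min, hp$treatment$base)
  expect_lte(hp$treatment$base, hp$treatment$max)

  # identical models -> zero benefit
  both <- handprint_from_models(preset$treated, preset$treated)
  expect_equal(both$treatment$base, both$comparator$base)

  # zero perturbation collapses bounds
  hp0 <- handprint_from_models(preset$treated, preset$untreated,
                               dw_perturbation = 0)
  expect_equal(hp0$treatment$min, hp0$treatment$base)

  # mismatched horizons are rejected
  short <- preset$treated
  short$horizon_cycles <- 4L
  expect_error(handprint_from_models(short, preset$untreated),
               class = "rsbr_validation_error")

  preset2 <- markov_preset("relapse_toy")
  hp2 <- handprint_from_models(preset2$treated, preset2$untreated)
  expect_lt(hp2$treatment$base, hp2$comparator$base)
})

test_that("model JSON specifications round-trip", {
  preset <- markov_preset("relapse_toy")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_markov_model(preset$treated, path)
  back <- read_markov_model(path)
  expect_equal(back$states$id, preset$treated$states$id)
  expect_equal(unname(back$transition), unname(preset$treated$transition))
  expect_equal(back$initial, preset$treated$initial)
  expect_equal(back$life_expectancy, preset$treated$life_expectancy)
  expect_equal(run_cohort(back)$daly, run_cohort(preset$treated)$daly)
})
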