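# Hierarchical sampling, Monte Carlo, enumeration, one-way sensitivity.

test_that("hierarchical draws hit the stated probabilities", {
  pools <- synthetic_pools(seed = 42)
  set.seed(101)
  n <- 100000
  # vector draws mirroring sample_iteration's hierarchy for speed
  mains <- names(pools$weighting_sets)[sample.int(3, n, replace = TRUE)]
  sizes <- lengths(pools$weighting_sets)
  sub <- integer(n)
  for (lbl in names(sizes)) {
    idx <- mains == lbl
    sub[idx] <- sample.int(sizes[[lbl]], sum(idx), replace = TRUE)
  }
  p_main <- mean(mains == "EI99") * 100
  expect_lt(abs(p_main - 100 / 3), 0.5)
  for (j in 1:4) {
    p_sub <- mean(mains == "EI99" & sub == j) * 100
    expect_lt(abs(p_sub - 100 / 12), 0.5)
  }
  for (j in 1:19) {
    p_itsubo <- mean(mains == "ITSUBO" & sub == j) * 100
    expect_lt(abs(p_itsubo - 100 / 57), 0.3)
  }
})

test_that("sample_iteration respects pool membership and hierarchy", {
  set.seed(7)
  pools <- small_pools(wf_sizes = c(EI99 = 2, ITSUBO = 5))
  set.seed(8)
  draws <- replicate(2000, sample_iteration(pools), simplify = FALSE)
  wf_ids <- vapply(draws, function(d) d$wf$id, character(1))
  mains <- vapply(draws, function(d) d$wf$main_set, character(1))
  expect_true(all(mains %in% c("EI99", "ITSUBO")))
  # family probability is uniform over families, not over sub-sets:
  # with groups of size 2 and 5 the family split stays near 50/50
  expect_lt(abs(mean(mains == "EI99") - 0.5), 0.04)
  # within a family each sub-set is equally likely
  ei99 <- table(wf_ids[mains == "EI99"])
  expect_equal(length(ei99), 2L)
  expect_lt(abs(ei99[1] / sum(ei99) - 0.5), 0.06)

  # singleton pools always return the only combination
  f <- reference_factors("sth_vietnam")
  single <- singleton_pools(f)
  d <- sample_iteration(single)
  expect_identical(d$nf$id, f$nf$id)
  expect_identical(d$wf$id, f$wf$id)
  expect_identical(d$variant, "base")
})

test_that("degenerate Monte Carlo equals the deterministic pipeline", {
  case <- builtin_case("sth_vietnam")
  f <- reference_factors("sth_vietnam")
  mc <- run_monte_carlo(case, singleton_pools(f), iterations = 50, seed = 1,
                        table_sign = TRUE)
  det <- compare_case(case, f$nf, f$hnf, f$wf, table_sign = TRUE)
  s <- mc$summary["combined_rsbr", ]
  expect_equal(unname(s[["median"]]), det$combined_rsbr, tolerance = 1e-12)
  expect_equal(unname(s[["min"]]), unname(s[["max"]]))
  expect_equal(unname(s[["min"]]), det$combined_rsbr, tolerance = 1e-12)
})

test_that("Monte Carlo is reproducible by seed and sensitive to it", {
  case <- generate_random_case(3)
  set.seed(21)
  pools <- small_pools(variants = c("base", "min", "max"))
  a <- run_monte_carlo(case, pools, iterations = 200, seed = 5)
  b <- run_monte_carlo(case, pools, iterations = 200, seed = 5)
  c0 <- run_monte_carlo(case, pools, iterations = 200, seed = 6)
  expect_identical(a$summary, b$summary)
  expect_identical(a$draws, b$draws)
  expect_false(identical(a$draws, c0$draws))
})

test_that("enumeration counts the Cartesian product and brackets sampling", {
  pools <- synthetic_pools(seed = 2)
  expect_identical(n_combinations(pools), 1248L * 1L)

  set.seed(22)
  small <- small_pools(n_fnf = 2, n_hnf = 3, wf_sizes = c(EI99 = 5),
                       variants = "base")
  expect_identical(n_combinations(small), 30L)
  case <- generate_random_case(4)
  tab <- enumerate_combinations(case, small)
  expect_identical(nrow(tab), 30L)
  expect_identical(attr(tab, "n_combinations"), 30L)

  mc <- run_monte_carlo(case, small, iterations = 500, seed = 9)
  vals <- tab$combined_rsbr
  # every sampled value occurs in the enumeration's value set
  expect_true(all(vapply(mc$draws$combined_rsbr, function(v) {
    any(abs(vals - v) < 1e-12)
  }, logical(1))))
  expect_gte(mc$summary["combined_rsbr", "min"], min(vals))
  expect_lte(mc$summary["combined_rsbr", "max"], max(vals))

  # degenerate pool: a single row
  f <- reference_factors("sth_vietnam")
  one <- enumerate_combinations(builtin_case("sth_vietnam"),
                                singleton_pools(f))
  expect_identical(nrow(one), 1L)
})

test_that("Monte Carlo median sits between adjacent enumeration order statistics", {
  set.seed(23)
  small <- small_pools(n_fnf = 2, n_hnf = 2, wf_sizes = c(EI99 = 3),
                       variants = "base")
  case <- generate_random_case(5)
  vals <- sort(enumerate_combinations(case, small)$combined_rsbr)
  mc <- run_monte_carlo(case, small, iterations = 10000, seed = 10)
  med <- mc$summary["combined_rsbr", "median"]
  n <- length(vals)
  lo <- vals[floor((n + 1) / 2) - 1]
  hi <- vals[ceiling((n + 1) / 2) + 1]
  expect_gte(med, lo)
  expect_lte(med, hi)
})

test_that("NA rates are excluded from percentiles but counted", {
  # comparator with zero footprint burden -> footprint RSBR undefined
  case <- case_study("na-case",
    scenario("t", impact_vector(1, 1, 1), handprint_estimate(5)),
    scenario("c", impact_vector(0, 0, 0), handprint_estimate(10)))
  set.seed(24)
  pools <- small_pools()
  mc <- run_monte_carlo(case, pools, iterations = 100, seed = 2)
  expect_identical(unname(mc$na_iterations[["footprint_rsbr"]]), 100L)
  expect_true(is.na(mc$summary["footprint_rsbr", "median"]))
  expect_identical(unname(mc$na_iterations[["combined_rsbr"]]), 0L)
})

test_that("one-way sensitivity attributes spread to the varied side", {
  f <- reference_factors("sth_vietnam")
  case <- builtin_case("sth_vietnam")

  # wildly differing WFs vs near-identical NFs: varying WF must dominate
  wfs <- list(EI99 = list(wf_of(0.98, 0.01, 0.01, "w-hh"),
                          wf_of(0.01, 0.98, 0.01, "w-eco"),
                          wf_of(0.01, 0.01, 0.98, "w-res"),
                          wf_of(1 / 3, 1 / 3, 1 / 3, "w-flat")))
  near_nf <- function(i, eps) {
    f0 <- f$nf$factors * (1 + eps)
    normalization_set(paste0("nf-near-", i), "test", 2000, f0[1], f0[2], f0[3])
  }
  pools <- factor_pools(
    list(near_nf(1, 0), near_nf(2, 1e-6)),
    list(f$hnf, hnf_of(f$hnf$factor * (1 + 1e-6), "hnf-near")),
    wfs, variants = "base")

  vary_wf <- one_way_sensitivity(case, pools, "FIX_NF_VARY_WF", f,
                                 iterations = 400, seed = 3)
  vary_nf <- one_way_sensitivity(case, pools, "FIX_WF_VARY_NF", f,
                                 iterations = 400, seed = 3)
  expect_gt(vary_wf$spread["treatment", "range"],
            vary_nf$spread["treatment", "range"])

  # single-element WF pool on the varied axis -> zero spread
  pools1 <- factor_pools(list(f$nf), list(f$hnf),
                         list(EI99 = list(f$wf)), variants = "base")
  flat <- one_way_sensitivity(case, pools1, "FIX_NF_VARY_WF", f,
                              iterations = 50, seed = 4)
  expect_equal(unname(flat$spread["treatment", "range"]), 0)

  # both sides singleton -> both axes deterministic and identical
  flat2 <- one_way_sensitivity(case, pools1, "FIX_WF_VARY_NF", f,
                               iterations = 50, seed = 4)
  expect_equal(flat$spread, flat2$spread)
})
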