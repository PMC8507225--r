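# Distribution specs, sampling, the PSA driver and the tornado DSA.

params <- default_parameter_set()
lt <- generate_life_table()

test_that("moment matching reproduces the published 10%-cv gamma specs", {
  s <- moments_to_spec(0.52, 0.1, "gamma")
  expect_equal(s$parameters$shape, 100, tolerance = 1e-9)
  expect_equal(s$parameters$scale, 0.0052, tolerance = 1e-9)
  s <- moments_to_spec(2.00, 0.1, "gamma")
  expect_equal(s$parameters$shape, 100, tolerance = 1e-9)
  expect_equal(s$parameters$scale, 0.02, tolerance = 1e-9)
  expect_equal(spec_mean(s), 2.00, tolerance = 1e-9)
  # beta method of moments hits the requested mean
  s <- moments_to_spec(0.5, 0.1, "beta")
  expect_equal(spec_mean(s), 0.5, tolerance = 1e-9)
  s <- moments_to_spec(0.867, 0.05, "beta")
  expect_equal(spec_mean(s), 0.867, tolerance = 1e-9)
  # literal variance-to-mean reading is available behind an option
  s <- moments_to_spec(0.52, 0.1, "gamma", interpretation = "variance_to_mean")
  expect_equal(s$parameters$shape * s$parameters$scale, 0.52, tolerance = 1e-9)
  expect_equal(s$parameters$shape * s$parameters$scale^2, 0.052, tolerance = 1e-9)
  expect_error(moments_to_spec(1.2, 0.1, "beta"), "beta mean")
  expect_error(moments_to_spec(0.5, 1.1, "beta"), "infeasible")
})

test_that("draws respect distribution supports", {
  set.seed(11)
  specs <- default_distribution_specs()
  for (i in 1:200) {
    sampled <- sample_parameter_set(params, specs)
    # type invariants hold for every draw (DSA ranges describe the base-case
    # analysis, so they are cleared before re-validating a sampled set)
    sampled$dsa_ranges <- list()
    expect_silent(validate_parameter_set(sampled))
    expect_gt(sampled$intervention$annual_severe_exac_rate, 0)
    expect_lt(sampled$intervention$annual_severe_exac_rate, 1)
    expect_lte(sampled$exac_types$SCS$disutility, 0)
    shares <- sampled$comparator$exac_type_shares
    expect_equal(sum(shares), 1, tolerance = 1e-12)
    expect_true(all(shares >= 0))
  }
})

test_that("sampled means recover analytic means within 3 standard errors", {
  n <- 10000
  check <- function(draw, mean_true, label) {
    se <- stats::sd(draw) / sqrt(n)
    expect_lt(abs(mean(draw) - mean_true), 3 * se + 1e-12, label = label)
  }
  set.seed(99)
  check(rbeta(n, 88.89, 719.20), 88.89 / (88.89 + 719.20), "intervention rate")
  expect_equal(88.89 / (88.89 + 719.20), 0.11, tolerance = 1e-4)
  check(rbeta(n, 87.88, 644.45), 0.12, "comparator rate")
  check(rbeta(n, 12.43, 1.91), 12.43 / 14.34, "utility")
  check(rgamma(n, 100, scale = 0.0052), 0.52, "inhalations/day")
  # the negated-disutility draws have the analytic beta mean
  spec <- distribution_spec("exac_types.SCS.disutility", "beta",
                            list(alpha = 110.1, beta = 1211.1), negate = TRUE)
  d <- replicate(2000, asthmaCE:::draw_from_spec(spec))
  expect_true(all(d < 0))
  expect_equal(mean(d), spec_mean(spec), tolerance = 5e-3)
})

test_that("fixed specs return the base set unchanged; shared targets share draws", {
  fixed_only <- list(
    distribution_spec("economics.nonexac_utility", "fixed"),
    distribution_spec("intervention.annual_severe_exac_rate", "fixed")
  )
  expect_equal(sample_parameter_set(params, fixed_only), params, tolerance = 0)
  # one draw lands in every path of a multi-target spec
  set.seed(5)
  shared <- list(distribution_spec(
    c("intervention.adverse_events.viral_urti.cost_per_event",
      "comparator.adverse_events.viral_urti.cost_per_event"),
    "gamma", list(shape = 100, scale = 79.09)))
  s <- sample_parameter_set(params, shared)
  expect_identical(s$intervention$adverse_events$viral_urti$cost_per_event,
                   s$comparator$adverse_events$viral_urti$cost_per_event)
  expect_false(identical(s$intervention$adverse_events$viral_urti$cost_per_event,
                         7909))
  # unknown path errors
  bad <- list(distribution_spec("intervention.not_a_field", "fixed"))
  expect_error(sample_parameter_set(params, bad), "unknown path")
})

test_that("drug acquisition prices are never sampled", {
  set.seed(21)
  for (i in 1:25) {
    s <- sample_parameter_set(params)
    expect_identical(s$intervention$regimens$budesonide_formoterol$cost_per_inhaler,
                     90.36)
    expect_identical(s$comparator$regimens$fluticasone$cost_per_inhaler, 43.00)
    expect_identical(s$comparator$regimens$salbutamol$cost_per_inhaler, 5.00)
  }
})

test_that("the PSA is reproducible and degenerates to the deterministic run", {
  cfg <- run_config(horizon_years = 2)
  p_fixed <- params
  p_fixed$distribution_specs <- list(
    distribution_spec("economics.nonexac_utility", "fixed"))
  psa1 <- run_psa(p_fixed, cfg, lt, n = 1, seed = 3)
  det <- run_base_case(p_fixed, cfg, lt)
  expect_equal(psa1$draws$delta_cost, det$incremental_cost, tolerance = 1e-12)
  expect_equal(psa1$draws$delta_qaly, det$incremental_qaly, tolerance = 1e-12)
  # same seed twice: identical results
  psa_a <- run_psa(params, cfg, lt, n = 8, seed = 42)
  psa_b <- run_psa(params, cfg, lt, n = 8, seed = 42)
  expect_identical(psa_a$draws, psa_b$draws)
  # different seeds differ
  psa_c <- run_psa(params, cfg, lt, n = 8, seed = 43)
  expect_false(identical(psa_a$draws, psa_c$draws))
  # summary means equal column means
  expect_equal(unname(psa_a$means["delta_cost"]),
               mean(psa_a$draws$delta_cost), tolerance = 1e-12)
  expect_error(run_psa(params, cfg, lt, n = 0), "n")
})

test_that("PSA draws feed a CEAC whose zero-threshold point counts savings", {
  cfg <- run_config(horizon_years = 2)
  psa <- run_psa(params, cfg, lt, n = 40, seed = 7)
  expect_identical(ceac_at(psa$ceac, 0), mean(psa$draws$delta_cost < 0))
  expect_true(all(psa$ceac$probability >= 0 & psa$ceac$probability <= 1))
  expect_true(all(c(50000, 100000) %in% psa$ceac$wtp))
})

test_that("tornado swings are zero for degenerate ranges and order-invariant", {
  cfg <- run_config(horizon_years = 2)
  rng <- list(
    "intervention.annual_severe_exac_rate" = c(0.088, 0.132),
    "economics.nonexac_utility" = c(0.867, 0.867),
    "config.discount_rate" = c(0, 0.03)
  )
  tor <- run_one_way_dsa(params, cfg, lt, ranges = rng)
  expect_s3_class(tor, "tornado_result")
  utility_row <- tor[tor$parameter == "economics.nonexac_utility", ]
  expect_equal(utility_row$cost_swing, 0)
  expect_equal(utility_row$nmb_swing, 0)
  # sorted by descending cost swing
  expect_true(!is.unsorted(rev(tor$cost_swing)))
  # permutation invariance
  tor2 <- run_one_way_dsa(params, cfg, lt, ranges = rev(rng))
  expect_equal(as.data.frame(tor2), as.data.frame(tor))
  # base case recovered at a degenerate range equal to the base value
  base <- attr(tor, "base")
  expect_equal(utility_row$inc_cost_low, base$incremental_cost,
               tolerance = 1e-12)
  expect_error(run_one_way_dsa(params, cfg, lt,
                               ranges = list("nope.x" = c(0, 1))),
               "unknown parameter path")
})

test_that("discount-rate DSA endpoints reproduce the scenario discount runs", {
  cfg <- run_config(horizon_years = 5)
  tor <- run_one_way_dsa(params, cfg, lt,
                         ranges = list("config.discount_rate" = c(0, 0.03)))
  sc1 <- build_scenario(1, params, cfg)
  sc2 <- build_scenario(2, params, cfg)
  r1 <- run_base_case(sc1$params, sc1$config, lt)
  r2 <- run_base_case(sc2$params, sc2$config, lt)
  expect_equal(tor$inc_cost_low[1], r1$incremental_cost, tolerance = 1e-12)
  expect_equal(tor$inc_cost_high[1], r2$incremental_cost, tolerance = 1e-12)
})
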