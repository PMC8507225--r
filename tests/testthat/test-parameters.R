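# Domain types, unit conversions, validation and the built-in input set.

test_that("per-day drug cost follows price / pack-size x daily use x utilization", {
  cases <- list(
    # price, inhalations/inhaler, inhalations/day, utilization, expected
    list(90.36, 120, 0.52, 1.0, 0.39156),
    list(43.00, 120, 2.00, 1.0, 43 / 120 * 2),
    list(5.00, 200, 0.49, 1.0, 5 / 200 * 0.49),
    list(77.70, 90, 0.00, 1.0, 0),
    list(43.00, 120, 2.00, 0.628, 43 / 120 * 2 * 0.628)
  )
  for (cs in cases) {
    reg <- drug_regimen("x", cs[[1]], cs[[2]], cs[[3]], cs[[4]])
    expect_equal(drug_cost_per_day(reg), cs[[5]], tolerance = 1e-12)
  }
  # display rounding to cents happens in reports only; raw values unrounded
  expect_equal(round(drug_cost_per_day(drug_regimen("a", 90.36, 120, 0.52)), 2), 0.39)
  expect_equal(round(drug_cost_per_day(drug_regimen("b", 43, 120, 2)), 2), 0.72)
})

test_that("drug cost is linear in daily use and in utilization fraction", {
  base <- drug_cost_per_day(drug_regimen("x", 50, 100, 1, 1))
  for (k in c(0.25, 0.5, 2, 3)) {
    expect_equal(drug_cost_per_day(drug_regimen("x", 50, 100, k, 1)),
                 k * base, tolerance = 1e-12)
  }
  for (u in c(0, 0.3, 0.628, 1)) {
    expect_equal(drug_cost_per_day(drug_regimen("x", 50, 100, 1, u)),
                 u * base, tolerance = 1e-12)
  }
  expect_error(drug_regimen("x", 50, 0, 1), "inhalations_per_inhaler")
})

test_that("annual rate converts to weekly probability via 1 - exp(-r/52)", {
  expect_equal(annual_rate_to_weekly_prob(0), 0)
  expect_equal(annual_rate_to_weekly_prob(0.11), 1 - exp(-0.11 / 52),
               tolerance = 1e-12)
  expect_equal(annual_rate_to_weekly_prob(0.11), 0.0021131, tolerance = 1e-4)
  expect_equal(annual_rate_to_weekly_prob(0.12), 0.0023050, tolerance = 1e-4)
  # always below the linear rate split, with equality only at zero
  for (r in c(1e-6, 0.05, 0.5, 2, 10))
    expect_lt(annual_rate_to_weekly_prob(r), r / 52)
  expect_error(annual_rate_to_weekly_prob(-0.1), "non-negative")
})

test_that("annual probability converts by compounding and round-trips", {
  expect_equal(annual_prob_to_weekly_prob(0), 0)
  expect_equal(annual_prob_to_weekly_prob(1), 1)
  expect_equal(annual_prob_to_weekly_prob(0.074), 1 - 0.926^(1 / 52),
               tolerance = 1e-12)
  # weekly-to-annual compounding inverts the conversion
  for (p in c(1e-8, 0.001, 0.074, 0.3, 0.9)) {
    pw <- annual_prob_to_weekly_prob(p)
    expect_lt(abs((1 - (1 - pw)^52) - p), 1e-12)
  }
  # monotone
  ps <- seq(0, 1, by = 0.05)
  expect_true(all(diff(annual_prob_to_weekly_prob(ps)) > 0))
  expect_error(annual_prob_to_weekly_prob(1.2), "\\[0, 1\\]")
})

test_that("share-weighted exacerbation cost and disutility are dot products", {
  types <- default_parameter_set()$exac_types
  expect_equal(weighted_exac_event_cost(types, c(1, 0, 0)), 155.14)
  expect_equal(weighted_exac_event_cost(types, c(0, 0, 1)), 9399.94)
  shares <- c(0.819, 0.102, 0.079)
  expect_equal(weighted_exac_event_cost(types, shares),
               0.819 * 155.14 + 0.102 * 490.81 + 0.079 * 9399.94,
               tolerance = 1e-12)
  expect_equal(weighted_exac_event_cost(types, shares), 919.72,
               tolerance = 1e-5)
  # monitoring cost added once per exacerbation cycle on request
  expect_equal(weighted_exac_event_cost(types, shares, nonexac_weekly_cost = 38.40 / 52),
               weighted_exac_event_cost(types, shares) + 38.40 / 52)
  expect_equal(weighted_exac_disutility(types, c(1, 0, 0)), -0.10)
  expect_equal(weighted_exac_disutility(types, c(0, 0, 1)), -0.20)
  expect_equal(weighted_exac_disutility(types, shares),
               -(0.819 * 0.10 + 0.102 * 0.15 + 0.079 * 0.20),
               tolerance = 1e-12)
  expect_error(weighted_exac_event_cost(types, c(0.5, 0.5, 0.5)), "summing to 1")
})

test_that("weighted event cost is bounded by the per-type extremes", {
  types <- default_parameter_set()$exac_types
  costs <- sapply(types, `[[`, "direct_cost_per_event")
  set.seed(42)
  for (i in 1:50) {
    s <- rgamma(3, 1); s <- s / sum(s)
    w <- weighted_exac_event_cost(types, s)
    expect_gte(w, min(costs)); expect_lte(w, max(costs))
  }
  # equal per-type costs collapse to that cost for any shares
  eq <- lapply(c("SCS", "ED_SCS", "INPATIENT"), exacerbation_type,
               direct_cost_per_event = 500, disutility = -0.1)
  names(eq) <- c("SCS", "ED_SCS", "INPATIENT")
  expect_equal(weighted_exac_event_cost(eq, c(1, 1, 1) / 3), 500)
})

test_that("validation reports every violated constraint, not just the first", {
  p <- default_parameter_set()
  expect_silent(validate_parameter_set(p))
  bad <- p
  bad$intervention$exac_type_shares <- c(SCS = 0.5, ED_SCS = 0.5, INPATIENT = 0.5)
  bad$comparator$regimens$fluticasone$cost_per_inhaler <- -1
  bad$economics$nonexac_utility <- 1.4
  err <- tryCatch(validate_parameter_set(bad), error = identity)
  expect_s3_class(err, "error")
  msg <- conditionMessage(err)
  expect_match(msg, "exac_type_shares.*summing to 1")
  expect_match(msg, "cost_per_inhaler: must be >= 0")
  expect_match(msg, "nonexac_utility: must be in \\[0, 1\\]")
})

test_that("the built-in input set carries the published base-case values", {
  p <- default_parameter_set()
  expect_equal(p$intervention$annual_severe_exac_rate, 0.11)
  expect_equal(p$comparator$annual_severe_exac_rate, 0.12)
  expect_equal(unname(p$intervention$exac_type_shares), c(0.819, 0.102, 0.079))
  expect_equal(unname(p$comparator$exac_type_shares), c(0.784, 0.152, 0.064))
  expect_equal(p$economics$nonexac_utility, 0.867)
  expect_equal(p$economics$nonexac_state_cost, 38.40)
  expect_equal(p$exac_types$INPATIENT$direct_cost_per_event, 9399.94)
  expect_equal(p$exac_types$ED_SCS$disutility, -0.15)
  expect_equal(p$intervention$adverse_events$influenza$annual_proportion, 0.016)
  expect_equal(p$intervention$adverse_events$influenza$cost_per_event, 6038)
  # combined comparator drug cost per day, unrounded
  expect_equal(arm_drug_cost_per_day(p$comparator), 43 / 120 * 2 + 5 / 200 * 0.49,
               tolerance = 1e-12)
  expect_identical(p$dsa_ranges[["intervention.annual_severe_exac_rate"]],
                   c(0.088, 0.132))
})

test_that("parameter files round-trip through YAML bit-identically", {
  p <- default_parameter_set()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, f)
  p2 <- read_parameters(f)
  expect_equal(p2, p, tolerance = 0)
  # and a second write is byte-stable
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("parameter paths address nested values for get and set", {
  p <- default_parameter_set()
  expect_equal(get_parameter(p, "exac_types.SCS.direct_cost_per_event"), 155.14)
  p2 <- set_parameter(p, "comparator.regimens.fluticasone.inhalations_per_day", 1.6)
  expect_equal(p2$comparator$regimens$fluticasone$inhalations_per_day, 1.6)
  # untouched elsewhere
  expect_equal(p2$intervention, p$intervention)
  expect_error(get_parameter(p, "comparator.no_such_field"), "unknown parameter path")
  expect_error(set_parameter(p, "intervention.nope.x", 1), "unknown parameter path")
})
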