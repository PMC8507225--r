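# Transition structure, cohort trace and accrual.

params <- default_parameter_set()
lt <- generate_life_table()

test_that("discount factor is exponential in elapsed cycles", {
  expect_equal(discount_factor(0, 0.015), 1)
  expect_equal(discount_factor(52, 0.015, 52), 1 / 1.015, tolerance = 1e-12)
  expect_equal(discount_factor(104, 0.015, 52), 1 / 1.015^2, tolerance = 1e-12)
  expect_equal(discount_factor(c(0, 7, 1000), 0, 52), rep(1, 3))
  expect_error(discount_factor(10, -1), "annual_rate")
})

test_that("weekly death probability adds asthma risk only in exacerbation states", {
  flt <- flat_life_table(0.074)
  w_bg <- annual_prob_to_weekly_prob(0.074)
  expect_equal(weekly_death_prob(50, 0.5, flt, "NONEXAC", params$exac_types),
               w_bg, tolerance = 1e-15)
  expect_equal(
    weekly_death_prob(50, 0.5, flt, "EXAC_INPATIENT", params$exac_types),
    w_bg + annual_prob_to_weekly_prob(0.05), tolerance = 1e-15)
  # sex-mix weighting
  mixed <- life_table(c(0:110, 0:110),
                      c(rep("F", 111), rep("M", 111)),
                      c(rep(0.01, 110), 1, rep(0.03, 110), 1))
  expect_equal(weekly_death_prob(40, 0.25, mixed, "NONEXAC", params$exac_types),
               0.25 * annual_prob_to_weekly_prob(0.01) +
                 0.75 * annual_prob_to_weekly_prob(0.03), tolerance = 1e-15)
  # clamped at 1
  certain <- params$exac_types
  certain$INPATIENT$annual_asthma_death_risk <- 1
  expect_equal(weekly_death_prob(50, 0.5, flt, "EXAC_INPATIENT", certain), 1)
})

test_that("ages beyond the life table use the terminal row with a warning", {
  short <- life_table(c(0:80, 0:80), c(rep("F", 81), rep("M", 81)),
                      c(rep(0.01, 80), 1, rep(0.01, 80), 1))
  lk <- asthmaCE:::lifetable_lookup(short)
  expect_warning(v <- lk(95, "F"), "beyond life-table range")
  expect_equal(v, 1)
})

test_that("the one-cycle transition matrix matches hand-computed rows", {
  cfg <- run_config()
  zero_lt <- flat_life_table(0)
  p0 <- zero_mortality_params(params)

  # no exacerbations, no mortality: identity on NONEXAC
  still <- p0
  still$intervention$annual_severe_exac_rate <- 0
  P <- build_cycle_transition(still$intervention, still, cfg, 41, zero_lt)
  expect_equal(P["NONEXAC", "NONEXAC"], 1)

  # published intervention rate and shares, zero mortality
  P <- build_cycle_transition(p0$intervention, p0, cfg, 41, zero_lt)
  pexac <- 1 - exp(-0.11 / 52)
  expect_equal(unname(P["NONEXAC", ]),
               c(1 - pexac, pexac * 0.819, pexac * 0.102, pexac * 0.079, 0),
               tolerance = 1e-12)
  expect_equal(unname(P["NONEXAC", ]),
               c(0.9978869, 0.0017306, 0.0002155, 0.0001669, 0),
               tolerance = 1e-3)
  expect_equal(sum(P["NONEXAC", ]), 1, tolerance = 1e-12)
  # death row is absorbing; exacerbation states return to NONEXAC
  expect_equal(unname(P["DEATH", ]), c(0, 0, 0, 0, 1))
  expect_equal(P["EXAC_SCS", "NONEXAC"], 1)
  # all rows stochastic with real mortality
  P <- build_cycle_transition(params$intervention, params, cfg, 80, lt)
  expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-12)
})

test_that("cohort trace equals the scalar brute-force oracle to 1e-12", {
  cfg <- run_config(horizon_years = 20 / 52, cycles_per_year = 52,
                    start_age = 64.6, sex_mix = 0.35)
  for (arm_name in c("intervention", "comparator")) {
    tr <- run_cohort(params[[arm_name]], params, cfg, lt)
    expect_equal(nrow(tr$occupancy), 20)
    oracle <- oracle_trace(params[[arm_name]], params, cfg, lt, 20)
    expect_equal(unname(tr$occupancy), unname(oracle), tolerance = 1e-12)
  }
  # and on a randomized parameter set
  rp <- generate_random_parameter_set(99)
  tr <- run_cohort(rp$intervention, rp, cfg, lt)
  expect_equal(unname(tr$occupancy),
               unname(oracle_trace(rp$intervention, rp, cfg, lt, 20)),
               tolerance = 1e-12)
})

test_that("occupancy rows are conserved and the cohort only shrinks", {
  cfg <- run_config()  # 50 years, 2600 cycles
  tr <- run_cohort(params$intervention, params, cfg, lt)
  expect_equal(nrow(tr$occupancy), 2600)
  expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-9))
  alive <- 1 - tr$occupancy[, "DEATH"]
  expect_true(all(diff(alive) < 0))  # strictly decreasing under mortality
  # zero rates and zero mortality: everyone stays in NONEXAC
  still <- zero_mortality_params(params)
  still$intervention$annual_severe_exac_rate <- 0
  tr0 <- run_cohort(still$intervention, still,
                    run_config(horizon_years = 2), flat_life_table(0))
  expect_equal(unname(tr0$occupancy[, "NONEXAC"]), rep(1, 104))
})

test_that("a full undiscounted year in perfect health accrues the state utility", {
  cfg <- run_config(horizon_years = 1, discount_rate_costs = 0,
                    discount_rate_outcomes = 0)
  still <- zero_mortality_params(params)
  still$intervention$annual_severe_exac_rate <- 0
  out <- run_arm(still$intervention, still, cfg, flat_life_table(0))
  expect_equal(out$total_qaly, 0.867, tolerance = 1e-12)
  expect_equal(out$life_years, 1, tolerance = 1e-12)
  # and the annual routine cost accrues exactly once
  expect_equal(out$cost_totals[["nonexac"]], 38.40, tolerance = 1e-12)
})

test_that("severe exacerbation costs match the closed-form rate x cost x time", {
  cfg <- run_config(discount_rate_costs = 0, discount_rate_outcomes = 0,
                    horizon_years = 5)
  p0 <- zero_mortality_params(params)
  out <- run_arm(p0$intervention, p0, cfg, flat_life_table(0))
  expected <- 0.11 * weighted_exac_event_cost(p0$exac_types,
                                              p0$intervention$exac_type_shares) * 5
  # occupancy-weighted weekly events differ from rate x time only through
  # the small exacerbation-state displacement
  expect_equal(out$cost_totals[["severe_exac"]], expected, tolerance = 5e-3)
})

test_that("zero discount rates make discounted totals equal plain sums", {
  cfg0 <- run_config(discount_rate_costs = 0, discount_rate_outcomes = 0,
                     horizon_years = 10)
  out <- run_arm(params$intervention, params, cfg0, lt)
  tr <- attr(out, "trace")
  occ <- tr$occupancy
  alive <- 1 - occ[, "DEATH"]
  plain_drugs <- sum(alive * arm_drug_cost_per_day(params$intervention) * 7)
  expect_equal(out$cost_totals[["drugs"]], plain_drugs, tolerance = 1e-9)
  plain_sev <- sum(occ[, c("EXAC_SCS", "EXAC_ED_SCS", "EXAC_INPATIENT")] %*%
                     c(155.14, 490.81, 9399.94))
  expect_equal(out$cost_totals[["severe_exac"]], plain_sev, tolerance = 1e-9)
})

test_that("totals over 2 years equal the first 104 cycles of a 50-year run", {
  cfg2 <- run_config(horizon_years = 2)
  cfg50 <- run_config(horizon_years = 50)
  out2 <- run_arm(params$comparator, params, cfg2, lt)
  out50 <- run_arm(params$comparator, params, cfg50, lt)
  for (cat in names(out2$cost_totals)) {
    expect_equal(out2$cost_totals[[cat]],
                 sum(out50$streams[[cat]][1:104]), tolerance = 1e-12)
  }
  expect_equal(out2$total_qaly, sum(out50$streams$qaly[1:104]),
               tolerance = 1e-12)
})

test_that("QALYs fall as disutilities or exacerbation rates grow", {
  cfg <- run_config(horizon_years = 10)
  q_of <- function(p) run_arm(p$intervention, p, cfg, lt)$total_qaly
  base_q <- q_of(params)
  worse <- set_parameter(params, "exac_types.INPATIENT.disutility", -0.4)
  expect_lt(q_of(worse), base_q)
  higher <- set_parameter(params, "intervention.annual_severe_exac_rate", 0.5)
  expect_lt(q_of(higher), base_q)
})

test_that("switching off adverse events zeroes that category exactly", {
  cfg <- run_config(include_AEs = FALSE, horizon_years = 5)
  out <- run_arm(params$intervention, params, cfg, lt)
  expect_identical(sum(out$streams$adverse_events), 0)
  expect_identical(out$cost_totals[["adverse_events"]], 0)
})

test_that("withdrawal variant: zero risk reproduces the base structure", {
  cfgw <- run_config(include_withdrawal = TRUE, horizon_years = 5)
  cfgb <- run_config(horizon_years = 5)
  none <- params
  none$intervention$annual_withdrawal_risk <- 0
  outw <- run_arm(none$intervention, none, cfgw, lt)
  outb <- run_arm(none$intervention, none, cfgb, lt)
  expect_equal(outw$total_cost, outb$total_cost, tolerance = 1e-12)
  expect_equal(outw$total_qaly, outb$total_qaly, tolerance = 1e-12)
  # with real risk, withdrawn patients accrue the step-up drug cost
  outr <- run_arm(params$intervention, params, cfgw, lt)
  expect_gt(outr$cost_totals[["withdrawal"]], 0)
  expect_lt(outr$cost_totals[["drugs"]], outb$cost_totals[["drugs"]])
  # enabling the variant without its parameter is a configuration error
  missing_risk <- params
  missing_risk$intervention$annual_withdrawal_risk <- NULL
  expect_error(run_arm(missing_risk$intervention, missing_risk, cfgw, lt),
               "withdrawal variant enabled")
})

test_that("moderate-exacerbation variant adds a one-cycle transient state", {
  cfgm <- run_config(include_moderate = TRUE, horizon_years = 5)
  expect_true("MODERATE_EXAC" %in% state_space(cfgm))
  out <- run_arm(params$intervention, params, cfgm, lt)
  expect_gt(out$cost_totals[["moderate_exac"]], 0)
  # default moderate disutility is half the SCS-only decrement
  expect_equal(params$economics$moderate_exac_disutility, -0.05)
  # QALYs fall relative to the base structure
  outb <- run_arm(params$intervention, params, run_config(horizon_years = 5), lt)
  expect_lt(out$total_qaly, outb$total_qaly)
})

test_that("half-cycle correction averages start- and end-of-cycle occupancy", {
  cfg <- run_config(horizon_years = 1, half_cycle_correction = TRUE,
                    discount_rate_costs = 0, discount_rate_outcomes = 0)
  still <- zero_mortality_params(params)
  still$intervention$annual_severe_exac_rate <- 0
  out <- run_arm(still$intervention, still, cfg, flat_life_table(0))
  expect_equal(out$total_qaly, 0.867, tolerance = 1e-12)  # flat trace unchanged
  # with mortality the corrected QALY exceeds the end-of-cycle accrual
  cfg2 <- run_config(horizon_years = 1, half_cycle_correction = TRUE)
  cfg3 <- run_config(horizon_years = 1)
  o2 <- run_arm(params$intervention, params, cfg2, lt)
  o3 <- run_arm(params$intervention, params, cfg3, lt)
  expect_gt(o2$total_qaly, o3$total_qaly)
})
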