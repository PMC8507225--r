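# Weekly-cycle Markov cohort engine: state space, transitions, trace,
# per-category discounted accrual.

#' Run configuration
#'
#' @param horizon_years Time horizon in years (default 50).
#' @param cycles_per_year Cycles per year (default 52, weekly).
#' @param discount_rate_costs,discount_rate_outcomes Annual discount rates
#'   (default 1.5% each).
#' @param start_age Cohort starting age in years (default 41).
#' @param sex_mix Proportion female in `[0, 1]` (default 0.5; the source
#'   trials report no sex split, see the methods vignette).
#' @param perspective `"public_payer"` (default) or `"societal"` (adds
#'   productivity costs).
#' @param include_AEs Accrue adverse-event costs/disutilities (default TRUE).
#' @param include_moderate Enable the transient moderate-exacerbation state
#'   (default FALSE).
#' @param include_withdrawal Enable the absorbing treatment-withdrawal state
#'   (default FALSE).
#' @param half_cycle_correction Average start- and end-of-cycle occupancy when
#'   accruing (default FALSE).
#' @return An object of class `run_config`.
#' @export
run_config <- function(horizon_years = 50, cycles_per_year = 52,
                       discount_rate_costs = 0.015,
                       discount_rate_outcomes = 0.015,
                       start_age = 41.0, sex_mix = 0.5,
                       perspective = c("public_payer", "societal"),
                       include_AEs = TRUE, include_moderate = FALSE,
                       include_withdrawal = FALSE,
                       half_cycle_correction = FALSE) {
  perspective <- match.arg(perspective)
  if (horizon_years <= 0 || cycles_per_year < 1)
    stop("horizon_years and cycles_per_year must be positive", call. = FALSE)
  if (discount_rate_costs < 0 || discount_rate_outcomes < 0)
    stop("discount rates must be >= 0", call. = FALSE)
  if (sex_mix < 0 || sex_mix > 1) stop("sex_mix must be in [0, 1]", call. = FALSE)
  structure(
    list(horizon_years = horizon_years, cycles_per_year = cycles_per_year,
         discount_rate_costs = discount_rate_costs,
         discount_rate_outcomes = discount_rate_outcomes,
         start_age = start_age, sex_mix = sex_mix, perspective = perspective,
         include_AEs = include_AEs, include_moderate = include_moderate,
         include_withdrawal = include_withdrawal,
         half_cycle_correction = half_cycle_correction),
    class = "run_config"
  )
}

#' State space implied by a run configuration
#'
#' Base states are non-exacerbation, three transient severe-exacerbation
#' sub-states (one per management type), and absorbing death. The
#' moderate-exacerbation and withdrawal variants add their states.
#'
#' @param config A [run_config()].
#' @return Character vector of ordered state names.
#' @export
state_space <- function(config) {
  states <- c("NONEXAC", paste0("EXAC_", exac_state_types()))
  if (isTRUE(config$include_moderate)) states <- c(states, "MODERATE_EXAC")
  if (isTRUE(config$include_withdrawal)) states <- c(states, "WITHDRAWN")
  c(states, "DEATH")
}

#' Discount factor for a cycle
#'
#' `(1 + annual_rate)^(-cycle_index / cycles_per_year)`; equals 1 at cycle 0.
#'
#' @param cycle_index Cycle index (0 = model start).
#' @param annual_rate Annual discount rate (> -1).
#' @param cycles_per_year Cycles per year.
#' @return Discount factor(s).
#' @export
discount_factor <- function(cycle_index, annual_rate, cycles_per_year = 52) {
  if (any(cycle_index < 0)) stop("cycle_index must be >= 0", call. = FALSE)
  if (annual_rate <= -1) stop("annual_rate must be > -1", call. = FALSE)
  (1 + annual_rate)^(-cycle_index / cycles_per_year)
}

#' Weekly probability of death by state
#'
#' The background component is the sex-mix-weighted weekly conversion of the
#' life-table annual probability at `floor(age)`. In a severe-exacerbation
#' state the weekly-converted annual asthma-related death risk of that
#' exacerbation type is added (asthma-related death can only occur from the
#' exacerbation states). The result is clamped to at most 1.
#'
#' @param age Age in years.
#' @param sex_mix Proportion female.
#' @param lt A `life_table` (or lookup closure).
#' @param state State name (see [state_space()]).
#' @param exac_types Named list of [exacerbation_type()] records.
#' @param cycles_per_year Cycles per year.
#' @return Weekly death probability.
#' @export
weekly_death_prob <- function(age, sex_mix, lt, state = "NONEXAC",
                              exac_types = NULL, cycles_per_year = 52) {
  p <- weekly_background_death_prob(age, sex_mix, lt, cycles_per_year)
  if (startsWith(state, "EXAC_")) {
    type <- sub("^EXAC_", "", state)
    risk <- exac_types[[type]]$annual_asthma_death_risk
    p <- p + annual_prob_to_weekly_prob(risk, cycles_per_year)
  }
  min(p, 1)
}

#' Build the one-cycle transition matrix
#'
#' From the non-exacerbation state the cohort moves to each severe
#' exacerbation sub-state with probability `p_exac * share_i` (where `p_exac`
#' is the weekly-converted annual severe exacerbation rate), to death with the
#' background weekly probability, to the optional moderate-exacerbation or
#' withdrawal states with their weekly-converted probabilities, and otherwise
#' stays. Exacerbation states last exactly one cycle: their only exits are
#' death (background plus asthma-related risk) and return to non-exacerbation.
#' The withdrawal state is absorbing except for death. The death row is the
#' identity.
#'
#' @param arm A [treatment_arm()].
#' @param params The enclosing `parameter_set` (for shared exacerbation
#'   types).
#' @param config A [run_config()].
#' @param age Current age in years.
#' @param lt A `life_table` (or lookup closure).
#' @return Row-stochastic matrix over [state_space()].
#' @export
build_cycle_transition <- function(arm, params, config, age, lt) {
  states <- state_space(config)
  cpy <- config$cycles_per_year
  n <- length(states)
  P <- matrix(0, n, n, dimnames = list(states, states))
  lookup <- if (is.function(lt)) lt else lifetable_lookup(lt)
  w_bg <- weekly_background_death_prob(age, config$sex_mix, lookup, cpy)

  p_exac <- annual_rate_to_weekly_prob(arm$annual_severe_exac_rate, cpy)
  exits <- p_exac * arm$exac_type_shares
  names(exits) <- paste0("EXAC_", exac_state_types())
  if (isTRUE(config$include_moderate)) {
    if (is.null(arm$annual_moderate_exac_rate))
      stop("moderate-exacerbation variant enabled but `annual_moderate_exac_rate` is missing for arm ",
           arm$name, call. = FALSE)
    exits <- c(exits, MODERATE_EXAC =
                 annual_rate_to_weekly_prob(arm$annual_moderate_exac_rate, cpy))
  }
  if (isTRUE(config$include_withdrawal)) {
    if (is.null(arm$annual_withdrawal_risk))
      stop("withdrawal variant enabled but `annual_withdrawal_risk` is missing for arm ",
           arm$name, call. = FALSE)
    exits <- c(exits, WITHDRAWN =
                 annual_prob_to_weekly_prob(arm$annual_withdrawal_risk, cpy))
  }
  # death takes priority near the terminal age (qx -> 1), where the additive
  # exit probabilities could otherwise exceed the available mass
  avail <- 1 - w_bg
  if (sum(exits) > avail) exits <- exits * (avail / sum(exits))
  P["NONEXAC", names(exits)] <- exits
  P["NONEXAC", "DEATH"] <- w_bg
  P["NONEXAC", "NONEXAC"] <- max(1 - sum(exits) - w_bg, 0)

  for (type in exac_state_types()) {
    st <- paste0("EXAC_", type)
    p_die <- weekly_death_prob(age, config$sex_mix, lookup, st,
                               params$exac_types, cpy)
    P[st, "DEATH"] <- p_die
    P[st, "NONEXAC"] <- 1 - p_die
  }
  if (isTRUE(config$include_moderate)) {
    P["MODERATE_EXAC", "DEATH"] <- w_bg
    P["MODERATE_EXAC", "NONEXAC"] <- 1 - w_bg
  }
  if (isTRUE(config$include_withdrawal)) {
    P["WITHDRAWN", "DEATH"] <- w_bg
    P["WITHDRAWN", "WITHDRAWN"] <- 1 - w_bg
  }
  P["DEATH", "DEATH"] <- 1

  bad <- which(abs(rowSums(P) - 1) > 1e-9)
  if (length(bad))
    stop("internal error: transition rows do not sum to 1: ",
         paste(states[bad], collapse = ", "), call. = FALSE)
  P
}

#' Run the cohort trace
#'
#' The whole cohort starts in the non-exacerbation state. Age advances by
#' `1/cycles_per_year` per cycle; the transition matrix is rebuilt whenever
#' the integer age increments. Row `t` of the occupancy matrix is the state
#' distribution at the end of cycle `t`.
#'
#' @inheritParams build_cycle_transition
#' @return A `cohort_trace`: list with `occupancy` (cycles x states matrix),
#'   `initial` (the starting distribution), `states`, `ages` (age during each
#'   cycle) and the arm name.
#' @export
run_cohort <- function(arm, params, config, lt) {
  states <- state_space(config)
  cpy <- config$cycles_per_year
  n_cycles <- round(config$horizon_years * cpy)
  lookup <- if (is.function(lt)) lt else lifetable_lookup(lt)

  occ <- matrix(0, n_cycles, length(states),
                dimnames = list(NULL, states))
  s <- stats::setNames(numeric(length(states)), states)
  s["NONEXAC"] <- 1
  initial <- s
  ages <- config$start_age + (seq_len(n_cycles) - 1) / cpy
  P <- NULL
  current_year <- -1L
  for (t in seq_len(n_cycles)) {
    yr <- floor(ages[t])
    if (yr != current_year) {
      P <- build_cycle_transition(arm, params, config, ages[t], lookup)
      current_year <- yr
    }
    s <- as.numeric(s %*% P)
    names(s) <- states
    occ[t, ] <- s
  }
  structure(list(occupancy = occ, initial = initial, states = states,
                 ages = ages, arm = arm$name),
            class = "cohort_trace")
}

#' Accrue discounted costs and QALYs from a trace
#'
#' Per cycle `t` with cost discount `v_t` and outcome discount `w_t`:
#' * `drugs`: on-treatment occupancy x daily drug cost x 7 x `v_t`;
#' * `nonexac`: alive occupancy x per-cycle routine cost x `v_t` (charged in
#'   exacerbation cycles too - routine monitoring continues during an
#'   exacerbation);
#' * `severe_exac`: occupancy of each exacerbation sub-state x its direct
#'   event cost x `v_t`;
#' * `adverse_events`: non-exacerbation occupancy x sum over events of weekly
#'   event probability x unit cost x `v_t` (adverse events apply to the
#'   non-exacerbation state only);
#' * `moderate_exac` / `withdrawal` / `societal`: variant and perspective
#'   streams;
#' * QALYs: state occupancy x (utility + state disutility) / cycles_per_year
#'   x `w_t`.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param arm The [treatment_arm()] that produced it.
#' @param params The `parameter_set`.
#' @param config The [run_config()].
#' @return An `arm_outcomes` object: per-cycle discounted streams
#'   (`streams`), per-category totals (`cost_totals`, `qaly_totals`),
#'   `total_cost`, `total_qaly`, and discounted life years.
#' @export
accrue_outcomes <- function(trace, arm, params, config) {
  occ <- trace$occupancy
  states <- trace$states
  n <- nrow(occ)
  cpy <- config$cycles_per_year
  if (isTRUE(config$half_cycle_correction)) {
    prev <- rbind(trace$initial, occ[-n, , drop = FALSE])
    occ <- (occ + prev) / 2
  }
  v_cost <- discount_factor(seq_len(n), config$discount_rate_costs, cpy)
  v_out <- discount_factor(seq_len(n), config$discount_rate_outcomes, cpy)

  exac_cols <- paste0("EXAC_", exac_state_types())
  occ_exac <- occ[, exac_cols, drop = FALSE]
  occ_non <- occ[, "NONEXAC"]
  occ_mod <- if ("MODERATE_EXAC" %in% states) occ[, "MODERATE_EXAC"] else 0
  occ_wd <- if ("WITHDRAWN" %in% states) occ[, "WITHDRAWN"] else 0
  alive <- 1 - occ[, "DEATH"]
  on_treatment <- alive - occ_wd

  eco <- params$economics
  cycle_monitor_cost <- switch(eco$nonexac_cost_basis,
    per_year = eco$nonexac_state_cost / cpy,
    per_week = eco$nonexac_state_cost * 52 / cpy)

  days_per_cycle <- 7 * 52 / cpy
  drug_day <- arm_drug_cost_per_day(arm)
  event_costs <- vapply(exac_state_types(),
                        function(nm) params$exac_types[[nm]]$direct_cost_per_event,
                        numeric(1))
  disutils <- vapply(exac_state_types(),
                     function(nm) params$exac_types[[nm]]$disutility, numeric(1))
  u <- eco$nonexac_utility

  streams <- list()
  streams$nonexac <- alive * cycle_monitor_cost * v_cost
  streams$severe_exac <- as.numeric(occ_exac %*% event_costs) * v_cost
  streams$drugs <- on_treatment * drug_day * days_per_cycle * v_cost

  ae_week_cost <- 0
  ae_week_disutil <- 0
  if (isTRUE(config$include_AEs) && length(arm$adverse_events)) {
    w_ae <- vapply(arm$adverse_events, function(e)
      annual_rate_to_weekly_prob(e$annual_proportion, cpy), numeric(1))
    ae_week_cost <- sum(w_ae * vapply(arm$adverse_events, `[[`, numeric(1),
                                      "cost_per_event"))
    ae_week_disutil <- sum(w_ae * vapply(arm$adverse_events, `[[`, numeric(1),
                                         "disutility"))
  }
  streams$adverse_events <- occ_non * ae_week_cost * v_cost

  streams$moderate_exac <- if (isTRUE(config$include_moderate)) {
    if (is.null(eco$moderate_exac_cost))
      stop("moderate-exacerbation variant enabled but `moderate_exac_cost` is missing",
           call. = FALSE)
    occ_mod * eco$moderate_exac_cost * v_cost
  } else numeric(n)

  streams$withdrawal <- if (isTRUE(config$include_withdrawal)) {
    if (is.null(eco$stepup_daily_drug_cost))
      stop("withdrawal variant enabled but `stepup_daily_drug_cost` is missing",
           call. = FALSE)
    occ_wd * eco$stepup_daily_drug_cost * days_per_cycle * v_cost
  } else numeric(n)

  streams$societal <- if (config$perspective == "societal") {
    alive * eco$productivity_days_lost_per_year * eco$daily_wage / cpy * v_cost
  } else numeric(n)

  d_mod <- if (is.null(eco$moderate_exac_disutility)) -0.05
           else eco$moderate_exac_disutility
  qaly_nonexac <- occ_non * (u + ae_week_disutil) / cpy * v_out
  qaly_severe <- as.numeric(occ_exac %*% (u + disutils)) / cpy * v_out
  qaly_other <- (occ_mod * (u + d_mod) + occ_wd * u) / cpy * v_out
  streams$qaly <- qaly_nonexac + qaly_severe + qaly_other

  cost_totals <- vapply(streams[setdiff(names(streams), "qaly")], sum,
                        numeric(1))
  qaly_totals <- c(nonexac = sum(qaly_nonexac), severe_exac = sum(qaly_severe),
                   other = sum(qaly_other))
  structure(
    list(arm = arm$name, streams = streams, cost_totals = cost_totals,
         total_cost = sum(cost_totals), qaly_totals = qaly_totals,
         total_qaly = sum(streams$qaly),
         life_years = sum(alive / cpy * v_out)),
    class = "arm_outcomes"
  )
}

#' Run one arm end-to-end
#'
#' Convenience wrapper: [run_cohort()] followed by [accrue_outcomes()].
#'
#' @inheritParams build_cycle_transition
#' @return An `arm_outcomes` object (with the trace attached as
#'   `attr(, "trace")`).
#' @export
run_arm <- function(arm, params, config, lt) {
  lookup <- if (is.function(lt)) lt else lifetable_lookup(lt)
  trace <- run_cohort(arm, params, config, lookup)
  out <- accrue_outcomes(trace, arm, params, config)
  attr(out, "trace") <- trace
  out
}

#' Export a cohort trace as delimited text
#'
#' One row per cycle: cycle index, age, state occupancies, then the
#' discounted accrual streams.
#'
#' @param trace A `cohort_trace`.
#' @param outcomes The matching `arm_outcomes` (optional; adds accrual
#'   columns).
#' @param path Output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, outcomes = NULL, path) {
  df <- data.frame(cycle = seq_len(nrow(trace$occupancy)), age = trace$ages)
  df <- cbind(df, as.data.frame(trace$occupancy))
  if (!is.null(outcomes))
    df <- cbind(df, as.data.frame(outcomes$streams))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
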