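#' @keywords internal
"_PACKAGE"

# ---- domain types -----------------------------------------------------------

#' Define a drug regimen
#'
#' A regimen is one inhaler product with its acquisition price, pack size and
#' mean daily use. The per-day acquisition cost is
#' `cost_per_inhaler / inhalations_per_inhaler * inhalations_per_day *
#' utilization_fraction` (see [drug_cost_per_day()]). `utilization_fraction`
#' scales acquisition cost for partial adherence (e.g. the 62.8% maintenance
#' ICS utilization scenario) without touching efficacy inputs.
#'
#' @param name Regimen label.
#' @param cost_per_inhaler Acquisition cost per inhaler, 2019 CAD.
#' @param inhalations_per_inhaler Doses per inhaler (>= 1).
#' @param inhalations_per_day Mean inhalations per day (>= 0).
#' @param utilization_fraction Fraction of acquisition cost actually incurred,
#'   in `[0, 1]`. Default 1 (full utilization).
#' @return An object of class `drug_regimen`.
#' @export
#' @examples
#' drug_cost_per_day(drug_regimen("budesonide-formoterol", 90.36, 120, 0.52))
drug_regimen <- function(name, cost_per_inhaler, inhalations_per_inhaler,
                         inhalations_per_day, utilization_fraction = 1.0) {
  x <- structure(
    list(
      name = as.character(name),
      cost_per_inhaler = as.numeric(cost_per_inhaler),
      inhalations_per_inhaler = as.numeric(inhalations_per_inhaler),
      inhalations_per_day = as.numeric(inhalations_per_day),
      utilization_fraction = as.numeric(utilization_fraction)
    ),
    class = "drug_regimen"
  )
  stop_on_issues(validate_drug_regimen(x, path = name))
  x
}

validate_drug_regimen <- function(x, path = "regimen") {
  issues <- character()
  if (!is.finite(x$cost_per_inhaler) || x$cost_per_inhaler < 0)
    issues <- c(issues, sprintf("%s.cost_per_inhaler: must be >= 0", path))
  if (!is.finite(x$inhalations_per_inhaler) || x$inhalations_per_inhaler < 1)
    issues <- c(issues, sprintf("%s.inhalations_per_inhaler: must be >= 1", path))
  if (!is.finite(x$inhalations_per_day) || x$inhalations_per_day < 0)
    issues <- c(issues, sprintf("%s.inhalations_per_day: must be >= 0", path))
  if (!is.finite(x$utilization_fraction) ||
      x$utilization_fraction < 0 || x$utilization_fraction > 1)
    issues <- c(issues, sprintf("%s.utilization_fraction: must be in [0, 1]", path))
  issues
}

#' Define a severe exacerbation type
#'
#' Severe exacerbations are split into three management types: systemic
#' corticosteroids only (`SCS`), emergency-department visit plus SCS
#' (`ED_SCS`), and inpatient hospitalization (`INPATIENT`). Each carries a
#' direct cost per event, a one-cycle utility decrement, and an annual risk of
#' asthma-related death applicable while in that exacerbation state.
#'
#' @param label One of `"SCS"`, `"ED_SCS"`, `"INPATIENT"`.
#' @param direct_cost_per_event Direct medical cost per event, 2019 CAD
#'   (excludes the weekly non-exacerbation monitoring cost, which the engine
#'   continues to charge during exacerbation cycles).
#' @param disutility Utility decrement in `[-1, 0]`, applied for the single
#'   cycle spent in the state.
#' @param annual_asthma_death_risk Annual probability of asthma-related death
#'   for patients in this exacerbation state, in `[0, 1]`.
#' @return An object of class `exacerbation_type`.
#' @export
exacerbation_type <- function(label, direct_cost_per_event, disutility,
                              annual_asthma_death_risk = 0) {
  label <- match.arg(label, c("SCS", "ED_SCS", "INPATIENT"))
  x <- structure(
    list(
      label = label,
      direct_cost_per_event = as.numeric(direct_cost_per_event),
      disutility = as.numeric(disutility),
      annual_asthma_death_risk = as.numeric(annual_asthma_death_risk)
    ),
    class = "exacerbation_type"
  )
  stop_on_issues(validate_exacerbation_type(x, path = label))
  x
}

validate_exacerbation_type <- function(x, path = "exac_type") {
  issues <- character()
  if (!is.finite(x$direct_cost_per_event) || x$direct_cost_per_event < 0)
    issues <- c(issues, sprintf("%s.direct_cost_per_event: must be >= 0", path))
  if (!is.finite(x$disutility) || x$disutility > 0 || x$disutility < -1)
    issues <- c(issues, sprintf("%s.disutility: must be in [-1, 0]", path))
  if (!is.finite(x$annual_asthma_death_risk) ||
      x$annual_asthma_death_risk < 0 || x$annual_asthma_death_risk > 1)
    issues <- c(issues, sprintf("%s.annual_asthma_death_risk: must be in [0, 1]", path))
  issues
}

#' Define an adverse-event input
#'
#' Adverse events apply to patients in the non-exacerbation state only (both
#' their costs and any disutility), to avoid double counting with
#' exacerbation inputs.
#'
#' @param name Event label (e.g. `"viral_urti"`).
#' @param annual_proportion Annual proportion of patients with the event, in
#'   `[0, 1]`; accrued as an annual event rate converted to a weekly
#'   probability.
#' @param cost_per_event Direct cost per event, 2019 CAD.
#' @param disutility Non-positive utility decrement per event-week; default 0.
#' @return An object of class `adverse_event`.
#' @export
adverse_event <- function(name, annual_proportion, cost_per_event,
                          disutility = 0) {
  x <- structure(
    list(
      name = as.character(name),
      annual_proportion = as.numeric(annual_proportion),
      cost_per_event = as.numeric(cost_per_event),
      disutility = as.numeric(disutility)
    ),
    class = "adverse_event"
  )
  stop_on_issues(validate_adverse_event(x, path = name))
  x
}

validate_adverse_event <- function(x, path = "adverse_event") {
  issues <- character()
  if (!is.finite(x$annual_proportion) ||
      x$annual_proportion < 0 || x$annual_proportion > 1)
    issues <- c(issues, sprintf("%s.annual_proportion: must be in [0, 1]", path))
  if (!is.finite(x$cost_per_event) || x$cost_per_event < 0)
    issues <- c(issues, sprintf("%s.cost_per_event: must be >= 0", path))
  if (!is.finite(x$disutility) || x$disutility > 0 || x$disutility < -1)
    issues <- c(issues, sprintf("%s.disutility: must be in [-1, 0]", path))
  issues
}

#' Define a treatment arm
#'
#' @param name Arm label.
#' @param regimens Named list of [drug_regimen()] objects; the arm's daily
#'   drug cost is the sum over regimens.
#' @param annual_severe_exac_rate Annual severe exacerbation rate
#'   (events/person-year).
#' @param exac_type_shares Named numeric vector of length 3
#'   (`SCS`, `ED_SCS`, `INPATIENT`) summing to 1: the time-constant split of
#'   severe exacerbations across management types.
#' @param adverse_events Named list of [adverse_event()] objects.
#' @param annual_moderate_exac_rate Optional annual moderate exacerbation rate
#'   (used only when the moderate-exacerbation variant is enabled).
#' @param annual_withdrawal_risk Optional annual probability of treatment
#'   withdrawal (used only when the withdrawal variant is enabled).
#' @return An object of class `treatment_arm`.
#' @export
treatment_arm <- function(name, regimens, annual_severe_exac_rate,
                          exac_type_shares, adverse_events = list(),
                          annual_moderate_exac_rate = NULL,
                          annual_withdrawal_risk = NULL) {
  shares <- as.numeric(exac_type_shares)
  names(shares) <- exac_state_types()
  x <- structure(
    list(
      name = as.character(name),
      regimens = regimens,
      annual_severe_exac_rate = as.numeric(annual_severe_exac_rate),
      exac_type_shares = shares,
      adverse_events = adverse_events,
      annual_moderate_exac_rate = if (is.null(annual_moderate_exac_rate)) NULL
        else as.numeric(annual_moderate_exac_rate),
      annual_withdrawal_risk = if (is.null(annual_withdrawal_risk)) NULL
        else as.numeric(annual_withdrawal_risk)
    ),
    class = "treatment_arm"
  )
  stop_on_issues(validate_treatment_arm(x, path = name))
  x
}

validate_treatment_arm <- function(x, path = "arm") {
  issues <- character()
  for (i in seq_along(x$regimens)) {
    nm <- names(x$regimens)[i]
    if (is.null(nm) || !nzchar(nm)) nm <- as.character(i)
    issues <- c(issues, validate_drug_regimen(
      x$regimens[[i]], path = paste0(path, ".regimens.", nm)))
  }
  if (!is.finite(x$annual_severe_exac_rate) || x$annual_severe_exac_rate < 0)
    issues <- c(issues, sprintf("%s.annual_severe_exac_rate: must be >= 0", path))
  s <- x$exac_type_shares
  if (length(s) != 3 || any(!is.finite(s)) || any(s < 0) ||
      abs(sum(s) - 1) > 1e-9)
    issues <- c(issues, sprintf(
      "%s.exac_type_shares: must be 3 non-negative shares summing to 1 (got sum %.12g)",
      path, sum(s)))
  for (i in seq_along(x$adverse_events)) {
    nm <- names(x$adverse_events)[i]
    if (is.null(nm) || !nzchar(nm)) nm <- as.character(i)
    issues <- c(issues, validate_adverse_event(
      x$adverse_events[[i]], path = paste0(path, ".adverse_events.", nm)))
  }
  if (!is.null(x$annual_moderate_exac_rate) &&
      (!is.finite(x$annual_moderate_exac_rate) || x$annual_moderate_exac_rate < 0))
    issues <- c(issues, sprintf("%s.annual_moderate_exac_rate: must be >= 0", path))
  if (!is.null(x$annual_withdrawal_risk) &&
      (!is.finite(x$annual_withdrawal_risk) ||
       x$annual_withdrawal_risk < 0 || x$annual_withdrawal_risk > 1))
    issues <- c(issues, sprintf("%s.annual_withdrawal_risk: must be in [0, 1]", path))
  issues
}

#' Define arm-independent economic inputs
#'
#' @param nonexac_state_cost Routine (monitoring) cost of the non-exacerbation
#'   state, 2019 CAD. Interpreted according to `nonexac_cost_basis`.
#' @param nonexac_cost_basis `"per_year"` (default: the cost is an annual
#'   amount accrued as `cost / cycles_per_year` each cycle) or `"per_week"`
#'   (the cost is charged in full every weekly cycle). See the methods
#'   vignette for why `per_year` is the default.
#' @param nonexac_utility Utility of the non-exacerbation state, in `[0, 1]`.
#' @param moderate_exac_cost Optional direct cost per moderate exacerbation
#'   (moderate-exacerbation variant only).
#' @param moderate_exac_disutility Optional non-positive utility decrement per
#'   moderate exacerbation cycle; default -0.05 when the variant is enabled.
#' @param productivity_days_lost_per_year Work days lost per patient-year
#'   (societal perspective only).
#' @param daily_wage Daily wage used to value lost productivity, 2019 CAD
#'   (societal perspective only).
#' @param stepup_daily_drug_cost Optional daily drug cost after treatment
#'   step-up (withdrawal variant only).
#' @return An object of class `economic_inputs`.
#' @export
economic_inputs <- function(nonexac_state_cost,
                            nonexac_cost_basis = c("per_year", "per_week"),
                            nonexac_utility,
                            moderate_exac_cost = NULL,
                            moderate_exac_disutility = NULL,
                            productivity_days_lost_per_year = 0,
                            daily_wage = 0,
                            stepup_daily_drug_cost = NULL) {
  x <- structure(
    list(
      nonexac_state_cost = as.numeric(nonexac_state_cost),
      nonexac_cost_basis = match.arg(nonexac_cost_basis),
      nonexac_utility = as.numeric(nonexac_utility),
      moderate_exac_cost = if (is.null(moderate_exac_cost)) NULL
        else as.numeric(moderate_exac_cost),
      moderate_exac_disutility = if (is.null(moderate_exac_disutility)) NULL
        else as.numeric(moderate_exac_disutility),
      productivity_days_lost_per_year = as.numeric(productivity_days_lost_per_year),
      daily_wage = as.numeric(daily_wage),
      stepup_daily_drug_cost = if (is.null(stepup_daily_drug_cost)) NULL
        else as.numeric(stepup_daily_drug_cost)
    ),
    class = "economic_inputs"
  )
  stop_on_issues(validate_economic_inputs(x, path = "economics"))
  x
}

validate_economic_inputs <- function(x, path = "economics") {
  issues <- character()
  if (!is.finite(x$nonexac_state_cost) || x$nonexac_state_cost < 0)
    issues <- c(issues, sprintf("%s.nonexac_state_cost: must be >= 0", path))
  if (!x$nonexac_cost_basis %in% c("per_year", "per_week"))
    issues <- c(issues, sprintf("%s.nonexac_cost_basis: must be per_year or per_week", path))
  if (!is.finite(x$nonexac_utility) ||
      x$nonexac_utility < 0 || x$nonexac_utility > 1)
    issues <- c(issues, sprintf("%s.nonexac_utility: must be in [0, 1]", path))
  if (!is.null(x$moderate_exac_cost) &&
      (!is.finite(x$moderate_exac_cost) || x$moderate_exac_cost < 0))
    issues <- c(issues, sprintf("%s.moderate_exac_cost: must be >= 0", path))
  if (!is.null(x$moderate_exac_disutility) &&
      (!is.finite(x$moderate_exac_disutility) || x$moderate_exac_disutility > 0 ||
       x$moderate_exac_disutility < -1))
    issues <- c(issues, sprintf("%s.moderate_exac_disutility: must be in [-1, 0]", path))
  if (!is.finite(x$productivity_days_lost_per_year) ||
      x$productivity_days_lost_per_year < 0)
    issues <- c(issues, sprintf("%s.productivity_days_lost_per_year: must be >= 0", path))
  if (!is.finite(x$daily_wage) || x$daily_wage < 0)
    issues <- c(issues, sprintf("%s.daily_wage: must be >= 0", path))
  if (!is.null(x$stepup_daily_drug_cost) &&
      (!is.finite(x$stepup_daily_drug_cost) || x$stepup_daily_drug_cost < 0))
    issues <- c(issues, sprintf("%s.stepup_daily_drug_cost: must be >= 0", path))
  issues
}

#' Assemble a complete parameter set
#'
#' Bundles both treatment arms, shared exacerbation-type definitions, economic
#' inputs, the probabilistic-sensitivity-analysis distribution specifications
#' and the one-way sensitivity ranges into a single validated object.
#'
#' @param intervention,comparator [treatment_arm()] objects.
#' @param economics An [economic_inputs()] object.
#' @param exac_types Named list of the three [exacerbation_type()] records
#'   (`SCS`, `ED_SCS`, `INPATIENT`), shared by both arms.
#' @param distribution_specs List of [distribution_spec()] objects for the PSA.
#' @param dsa_ranges Named list mapping parameter paths (see
#'   [get_parameter()]) to `c(lower, upper)` bounds for the one-way DSA.
#' @return An object of class `parameter_set`.
#' @seealso [default_parameter_set()], [validate_parameter_set()]
#' @export
parameter_set <- function(intervention, comparator, economics, exac_types,
                          distribution_specs = list(), dsa_ranges = list()) {
  x <- structure(
    list(
      intervention = intervention,
      comparator = comparator,
      economics = economics,
      exac_types = exac_types,
      distribution_specs = distribution_specs,
      dsa_ranges = dsa_ranges
    ),
    class = "parameter_set"
  )
  validate_parameter_set(x)
}

#' Validate a parameter set
#'
#' Checks every type invariant (non-negative costs and rates, probabilities in
#' `[0, 1]`, exacerbation-type shares summing to 1, disutilities in `[-1, 0]`,
#' DSA bounds bracketing the base value) and reports *all* violations at once.
#'
#' @param params A `parameter_set`.
#' @return `params`, invisibly unchanged, if valid; otherwise an error listing
#'   every violated constraint with its parameter path.
#' @export
validate_parameter_set <- function(params) {
  if (!inherits(params, "parameter_set"))
    stop("`params` must be a parameter_set object", call. = FALSE)
  issues <- character()
  issues <- c(issues, validate_treatment_arm(params$intervention, "intervention"))
  issues <- c(issues, validate_treatment_arm(params$comparator, "comparator"))
  issues <- c(issues, validate_economic_inputs(params$economics, "economics"))
  if (!setequal(names(params$exac_types), exac_state_types())) {
    issues <- c(issues,
      "exac_types: must be a named list with entries SCS, ED_SCS, INPATIENT")
  } else {
    for (nm in exac_state_types())
      issues <- c(issues, validate_exacerbation_type(
        params$exac_types[[nm]], path = paste0("exac_types.", nm)))
  }
  for (nm in names(params$dsa_ranges)) {
    rng <- params$dsa_ranges[[nm]]
    if (length(rng) != 2 || any(!is.finite(rng)) || rng[1] > rng[2]) {
      issues <- c(issues, sprintf("dsa_ranges.%s: must be finite c(lower, upper) with lower <= upper", nm))
      next
    }
    base <- tryCatch(get_parameter(params, nm), error = function(e) NULL)
    if (!is.null(base) && is.numeric(base) && length(base) == 1 &&
        (base < rng[1] - 1e-12 || base > rng[2] + 1e-12))
      issues <- c(issues, sprintf(
        "dsa_ranges.%s: base value %.6g outside [%.6g, %.6g]", nm, base, rng[1], rng[2]))
  }
  stop_on_issues(issues)
  invisible(params)
}

stop_on_issues <- function(issues) {
  issues <- issues[nzchar(issues)]
  if (length(issues))
    stop("invalid parameters:\n", paste0("  - ", issues, collapse = "\n"),
         call. = FALSE)
  invisible(NULL)
}

exac_state_types <- function() c("SCS", "ED_SCS", "INPATIENT")

# ---- unit conversions -------------------------------------------------------

#' Per-day drug acquisition cost of a regimen
#'
#' `cost_per_inhaler / inhalations_per_inhaler * inhalations_per_day *
#' utilization_fraction`, returned unrounded; rounding to cents happens only
#' in display tables.
#'
#' @param regimen A [drug_regimen()].
#' @return Cost per day in 2019 CAD.
#' @export
#' @examples
#' # Symbicort Turbuhaler, SYGMA 2 mean use
#' drug_cost_per_day(drug_regimen("bud-form", 90.36, 120, 0.52)) # 0.39156
drug_cost_per_day <- function(regimen) {
  stop_on_issues(validate_drug_regimen(regimen, path = regimen$name))
  regimen$cost_per_inhaler / regimen$inhalations_per_inhaler *
    regimen$inhalations_per_day * regimen$utilization_fraction
}

#' Daily drug cost of a whole arm
#'
#' @param arm A [treatment_arm()].
#' @return Sum of [drug_cost_per_day()] over the arm's regimens.
#' @export
arm_drug_cost_per_day <- function(arm) {
  sum(vapply(arm$regimens, drug_cost_per_day, numeric(1)))
}

#' Convert an annual event rate to a per-cycle probability
#'
#' Uses the exponential formula `p = 1 - exp(-r / cycles_per_year)`: the rate
#' is first rescaled to the cycle length, then converted to the probability of
#' at least one event in the cycle.
#'
#' @param rate Annual rate (events/person-year), >= 0.
#' @param cycles_per_year Number of cycles per year (default 52, weekly).
#' @return Probability in `[0, 1)`.
#' @export
annual_rate_to_weekly_prob <- function(rate, cycles_per_year = 52) {
  if (any(!is.finite(rate)) || any(rate < 0))
    stop("`rate` must be a non-negative finite number", call. = FALSE)
  1 - exp(-rate / cycles_per_year)
}

#' Convert an annual probability to a per-cycle probability
#'
#' Uses compounding: `p_cycle = 1 - (1 - p_annual)^(1 / cycles_per_year)`, so
#' that surviving all cycles of a year recovers the annual probability
#' exactly. Used for mortality and withdrawal risks, which are stated as
#' annual probabilities rather than rates.
#'
#' @param p_annual Annual probability in `[0, 1]`.
#' @param cycles_per_year Number of cycles per year (default 52).
#' @return Probability in `[0, 1]`; 0 maps to 0 and 1 maps to 1.
#' @export
annual_prob_to_weekly_prob <- function(p_annual, cycles_per_year = 52) {
  if (any(!is.finite(p_annual)) || any(p_annual < 0) || any(p_annual > 1))
    stop("`p_annual` must be in [0, 1]", call. = FALSE)
  1 - (1 - p_annual)^(1 / cycles_per_year)
}

#' Share-weighted severe exacerbation event cost
#'
#' The expected direct cost of one severe exacerbation given the split across
#' management types, optionally adding the per-cycle non-exacerbation
#' monitoring cost that continues to accrue during the exacerbation cycle.
#'
#' @param exac_types Named list of the three [exacerbation_type()] records.
#' @param shares Numeric vector of 3 shares over (`SCS`, `ED_SCS`,
#'   `INPATIENT`) summing to 1.
#' @param nonexac_weekly_cost Per-cycle monitoring cost added on top
#'   (default 0 returns the pure weighted event cost).
#' @return Expected cost per event, 2019 CAD.
#' @export
weighted_exac_event_cost <- function(exac_types, shares, nonexac_weekly_cost = 0) {
  shares <- check_shares(shares)
  costs <- vapply(exac_state_types(),
                  function(nm) exac_types[[nm]]$direct_cost_per_event, numeric(1))
  sum(shares * costs) + nonexac_weekly_cost
}

#' Share-weighted severe exacerbation disutility
#'
#' @inheritParams weighted_exac_event_cost
#' @return Expected one-cycle utility decrement (non-positive).
#' @export
weighted_exac_disutility <- function(exac_types, shares) {
  shares <- check_shares(shares)
  d <- vapply(exac_state_types(),
              function(nm) exac_types[[nm]]$disutility, numeric(1))
  sum(shares * d)
}

check_shares <- function(shares) {
  shares <- as.numeric(shares)
  if (length(shares) != 3 || any(!is.finite(shares)) || any(shares < 0) ||
      abs(sum(shares) - 1) > 1e-9)
    stop("`shares` must be 3 non-negative values summing to 1", call. = FALSE)
  shares
}

# ---- parameter paths --------------------------------------------------------

#' Get or set a parameter by path
#'
#' Parameters are addressed with dotted paths into the nested structure, e.g.
#' `"intervention.annual_severe_exac_rate"`,
#' `"comparator.regimens.fluticasone.inhalations_per_day"`,
#' `"exac_types.INPATIENT.direct_cost_per_event"` or
#' `"economics.nonexac_utility"`. These paths are the handles used by the PSA
#' distribution specifications and the one-way DSA ranges.
#'
#' @param params A `parameter_set`.
#' @param path Dotted path string.
#' @param value Replacement value (for `set_parameter`).
#' @return `get_parameter` returns the value at `path`; `set_parameter`
#'   returns a modified copy of `params`.
#' @export
get_parameter <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- params
  for (k in keys) {
    idx <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
    if (is.numeric(idx)) {
      if (idx > length(node)) stop("unknown parameter path: ", path, call. = FALSE)
    } else if (is.null(node[[idx]]) && !(is.list(node) && idx %in% names(node))) {
      stop("unknown parameter path: ", path, call. = FALSE)
    }
    node <- node[[idx]]
  }
  node
}

#' @rdname get_parameter
#' @export
set_parameter <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  # verify the path exists before assignment
  get_parameter(params, path)
  rec <- function(node, keys, value) {
    k <- keys[1]
    idx <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
    if (length(keys) == 1) node[[idx]] <- value
    else node[[idx]] <- rec(node[[idx]], keys[-1], value)
    node
  }
  rec(params, keys, value)
}

# ---- built-in inputs --------------------------------------------------------

#' Built-in model inputs
#'
#' The complete base-case input set for the comparison of as-needed
#' budesonide-formoterol (intervention) versus low-dose maintenance ICS plus
#' as-needed SABA (comparator): annual severe exacerbation rates 0.11 vs 0.12;
#' exacerbation-type splits (81.9/10.2/7.9)% vs (78.4/15.2/6.4)%; the seven
#' most common adverse events with their annual proportions and unit costs;
#' drug acquisition inputs (Symbicort 200-6; fluticasone 125 ug plus
#' salbutamol); severe exacerbation event costs $155.14 / $490.81 / $9399.94;
#' non-exacerbation routine cost $38.40; utility 0.867 with exacerbation
#' disutilities -0.10 / -0.15 / -0.20; the published PSA distribution
#' parameters; and the one-way DSA lower/upper bounds.
#'
#' The annual asthma-related death risks per exacerbation type are
#' study-assumption placeholders (the source values are not publicly
#' available): 0.5% (SCS), 2% (ED+SCS) and 5% (inpatient), ordered
#' inpatient >> ED+SCS >> SCS and documented in the methods vignette.
#'
#' @return A validated `parameter_set`.
#' @export
#' @examples
#' p <- default_parameter_set()
#' p$intervention$annual_severe_exac_rate # 0.11
default_parameter_set <- function() {
  exac_types <- list(
    SCS = exacerbation_type("SCS", 155.14, -0.10,
                            annual_asthma_death_risk = 0.005),
    ED_SCS = exacerbation_type("ED_SCS", 490.81, -0.15,
                               annual_asthma_death_risk = 0.02),
    INPATIENT = exacerbation_type("INPATIENT", 9399.94, -0.20,
                                  annual_asthma_death_risk = 0.05)
  )

  ae <- function(name, p_int, p_cmp, cost) list(
    intervention = adverse_event(name, p_int, cost),
    comparator = adverse_event(name, p_cmp, cost)
  )
  ae_defs <- list(
    viral_urti = ae("viral_urti", 0.074, 0.080, 7909.00),
    urti = ae("urti", 0.039, 0.043, 7909.00),
    bronchitis = ae("bronchitis", 0.031, 0.037, 157.00),
    pharyngitis = ae("pharyngitis", 0.024, 0.030, 157.00),
    headache = ae("headache", 0.025, 0.024, 157.00),
    allergic_rhinitis = ae("allergic_rhinitis", 0.024, 0.021, 157.00),
    influenza = ae("influenza", 0.016, 0.021, 6038.00)
  )

  intervention <- treatment_arm(
    name = "As-needed budesonide-formoterol",
    regimens = list(
      budesonide_formoterol = drug_regimen(
        "Symbicort Turbuhaler 200-6", 90.36, 120, 0.52)
    ),
    annual_severe_exac_rate = 0.11,
    exac_type_shares = c(SCS = 0.819, ED_SCS = 0.102, INPATIENT = 0.079),
    adverse_events = lapply(ae_defs, `[[`, "intervention"),
    annual_moderate_exac_rate = 0.07,
    annual_withdrawal_risk = 0.008
  )
  comparator <- treatment_arm(
    name = "Low-dose maintenance ICS + as-needed SABA",
    regimens = list(
      fluticasone = drug_regimen("Fluticasone 125 ug (Flovent)", 43.00, 120, 2),
      salbutamol = drug_regimen("Salbutamol 0.4 mg (Ventolin)", 5.00, 200, 0.49)
    ),
    annual_severe_exac_rate = 0.12,
    exac_type_shares = c(SCS = 0.784, ED_SCS = 0.152, INPATIENT = 0.064),
    adverse_events = lapply(ae_defs, `[[`, "comparator"),
    annual_moderate_exac_rate = 0.06,
    annual_withdrawal_risk = 0.012
  )

  economics <- economic_inputs(
    nonexac_state_cost = 38.40,
    nonexac_cost_basis = "per_year",
    nonexac_utility = 0.867,
    moderate_exac_cost = 77.57,       # half the SCS-only event cost, mirroring
                                      # the half-severity disutility assumption
    moderate_exac_disutility = -0.05,
    productivity_days_lost_per_year = 0.19,
    daily_wage = 166.9,               # calibrated; see methods vignette
    stepup_daily_drug_cost = 0.728917 # step-up to daily low-dose ICS + SABA
  )

  params <- parameter_set(
    intervention = intervention,
    comparator = comparator,
    economics = economics,
    exac_types = exac_types,
    distribution_specs = list(),
    dsa_ranges = default_dsa_ranges()
  )
  params$distribution_specs <- default_distribution_specs()
  params
}

#' Built-in one-way DSA ranges
#'
#' Lower/upper values for the one-way deterministic sensitivity analysis,
#' keyed by parameter path. Costs and disutilities vary by +/-20% around the
#' base case; rates by the bounds listed alongside each input; the discount
#' rate between 0% and 3%; starting age between 32.8 and 49.2 years.
#'
#' @return Named list of `c(lower, upper)` pairs.
#' @export
default_dsa_ranges <- function() {
  list(
    "config.start_age" = c(32.8, 49.2),
    "intervention.annual_severe_exac_rate" = c(0.088, 0.132),
    "comparator.annual_severe_exac_rate" = c(0.096, 0.144),
    "comparator.regimens.fluticasone.inhalations_per_day" = c(1.60, 2.40),
    "exac_types.SCS.direct_cost_per_event" = c(124.11, 186.16),
    "exac_types.ED_SCS.direct_cost_per_event" = c(392.64, 588.97),
    "exac_types.INPATIENT.direct_cost_per_event" = c(7519.95, 11279.92),
    "economics.nonexac_state_cost" = c(30.72, 46.08),
    "economics.nonexac_utility" = c(0.694, 1.000),
    "exac_types.SCS.disutility" = c(-0.12, -0.08),
    "exac_types.ED_SCS.disutility" = c(-0.18, -0.12),
    "exac_types.INPATIENT.disutility" = c(-0.24, -0.16),
    "config.discount_rate" = c(0.0, 0.03)
  )
}

# ---- serialization ----------------------------------------------------------

#' Read and write parameter files
#'
#' Parameter sets are stored as YAML whose keys mirror the input tables
#' (arms, regimens, exacerbation types, adverse events, economics, PSA
#' distribution specs, DSA ranges). Money fields are serialized with full
#' precision (15 significant digits) so a write/read round-trip reproduces the
#' in-memory values exactly.
#'
#' @param params A `parameter_set`.
#' @param path File path.
#' @return `write_parameters` returns `path` invisibly; `read_parameters`
#'   returns a validated `parameter_set`.
#' @export
write_parameters <- function(params, path) {
  validate_parameter_set(params)
  plain <- rapply(unclass_deep(params), identity, how = "replace")
  yaml::write_yaml(plain, path, precision = 15L)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  arm_from <- function(a) treatment_arm(
    name = a$name,
    regimens = lapply(a$regimens, function(r)
      drug_regimen(r$name, r$cost_per_inhaler, r$inhalations_per_inhaler,
                   r$inhalations_per_day, r$utilization_fraction)),
    annual_severe_exac_rate = a$annual_severe_exac_rate,
    exac_type_shares = unlist(a$exac_type_shares),
    adverse_events = lapply(a$adverse_events, function(e)
      adverse_event(e$name, e$annual_proportion, e$cost_per_event, e$disutility)),
    annual_moderate_exac_rate = a$annual_moderate_exac_rate,
    annual_withdrawal_risk = a$annual_withdrawal_risk
  )
  eco <- raw$economics
  parameter_set(
    intervention = arm_from(raw$intervention),
    comparator = arm_from(raw$comparator),
    economics = economic_inputs(
      nonexac_state_cost = eco$nonexac_state_cost,
      nonexac_cost_basis = eco$nonexac_cost_basis,
      nonexac_utility = eco$nonexac_utility,
      moderate_exac_cost = eco$moderate_exac_cost,
      moderate_exac_disutility = eco$moderate_exac_disutility,
      productivity_days_lost_per_year = eco$productivity_days_lost_per_year,
      daily_wage = eco$daily_wage,
      stepup_daily_drug_cost = eco$stepup_daily_drug_cost
    ),
    exac_types = lapply(raw$exac_types, function(e)
      exacerbation_type(e$label, e$direct_cost_per_event, e$disutility,
                        e$annual_asthma_death_risk)),
    distribution_specs = lapply(raw$distribution_specs, function(s)
      distribution_spec(unlist(s$target), s$family,
                        parameters = lapply(s$parameters, unlist),
                        negate = isTRUE(s$negate))),
    dsa_ranges = lapply(raw$dsa_ranges, unlist)
  )
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  for (arm in list(x$intervention, x$comparator)) {
    cat(sprintf("  %s:\n", arm$name))
    cat(sprintf("    annual severe exacerbation rate: %.3g; drug cost/day: $%.4f\n",
                arm$annual_severe_exac_rate, arm_drug_cost_per_day(arm)))
    cat(sprintf("    exacerbation-type shares: %s\n",
                paste(sprintf("%s %.1f%%", names(arm$exac_type_shares),
                              100 * arm$exac_type_shares), collapse = ", ")))
  }
  cat(sprintf("  non-exacerbation: $%.2f %s, utility %.3f\n",
              x$economics$nonexac_state_cost,
              sub("_", " ", x$economics$nonexac_cost_basis),
              x$economics$nonexac_utility))
  cat(sprintf("  %d PSA distribution specs, %d DSA ranges\n",
              length(x$distribution_specs), length(x$dsa_ranges)))
  invisible(x)
}
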