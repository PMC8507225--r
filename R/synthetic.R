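# Synthetic inputs: a calibrated Gompertz-Makeham life table standing in for
# national life tables, and randomized parameter sets for property testing.

#' Gompertz-Makeham mortality parameters
#'
#' Annual hazard at age `x` is `makeham + gompertz_a * exp(gompertz_b * x)`
#' for females; the male hazard is multiplied by `sex_ratio`. Annual death
#' probability is `1 - exp(-hazard)`.
#'
#' @param makeham Age-independent hazard component (>= 0).
#' @param gompertz_a Baseline senescent hazard (> 0).
#' @param gompertz_b Log-hazard slope per year of age (> 0).
#' @param sex_ratio Male/female hazard ratio (> 0).
#' @return An object of class `gompertz_makeham_params`.
#' @export
gompertz_makeham_params <- function(makeham = 4e-4,
                                    gompertz_a = 1.598213e-5,
                                    gompertz_b = 0.0955,
                                    sex_ratio = 1.5) {
  if (makeham < 0 || gompertz_a <= 0 || gompertz_b <= 0 || sex_ratio <= 0)
    stop("invalid Gompertz-Makeham parameters", call. = FALSE)
  structure(list(makeham = makeham, gompertz_a = gompertz_a,
                 gompertz_b = gompertz_b, sex_ratio = sex_ratio),
            class = "gompertz_makeham_params")
}

#' Generate a synthetic life table
#'
#' Builds an age x sex life table from a Gompertz-Makeham law. The terminal
#' age row is set to `qx = 1`. The packaged defaults are calibrated so that
#' discounted life expectancy from age 41 at 1.5%/year over a 50-year window
#' is approximately 29.9 years (see [calibrate_life_table()]).
#'
#' @param gm A [gompertz_makeham_params()] object.
#' @param max_age Terminal age (default 110).
#' @return A `life_table`.
#' @export
#' @examples
#' lt <- generate_life_table()
#' discounted_life_expectancy(lt)
generate_life_table <- function(gm = gompertz_makeham_params(), max_age = 110) {
  ages <- 0:max_age
  qx_for <- function(mult) {
    h <- (gm$makeham + gm$gompertz_a * exp(gm$gompertz_b * ages)) * mult
    qx <- pmin(1 - exp(-h), 1)
    qx[length(qx)] <- 1
    qx
  }
  qxF <- qx_for(1)
  qxM <- qx_for(gm$sex_ratio)
  if (any(qxF[ages < max_age] >= 1) || any(qxM[ages < max_age] >= 1))
    warning("hazard implies qx >= 1 before terminal age; clamping",
            call. = FALSE)
  life_table(
    age = c(ages, ages),
    sex = c(rep("F", length(ages)), rep("M", length(ages))),
    qx = c(qxF, qxM)
  )
}

#' Calibrate the synthetic life table to a discounted life expectancy
#'
#' Solves for `gompertz_a` (all other parameters held at the supplied
#' template) such that [discounted_life_expectancy()] of the generated table
#' hits the target within 0.5%. The search is deterministic bisection
#' (`uniroot`) over `log(gompertz_a)`.
#'
#' @param target_discounted_le Target discounted life expectancy in years.
#' @param start_age,discount,sex_mix,horizon_years As in
#'   [discounted_life_expectancy()].
#' @param template A [gompertz_makeham_params()] supplying the fixed
#'   parameters.
#' @param max_age Terminal age of the generated table.
#' @return A `gompertz_makeham_params` whose generated table meets the target.
#' @export
calibrate_life_table <- function(target_discounted_le, start_age = 41,
                                 discount = 0.015, sex_mix = 0.5,
                                 horizon_years = 50,
                                 template = gompertz_makeham_params(),
                                 max_age = 110) {
  le_for <- function(log_a) {
    gm <- template
    gm$gompertz_a <- exp(log_a)
    discounted_life_expectancy(generate_life_table(gm, max_age),
                               start_age = start_age, discount = discount,
                               sex_mix = sex_mix, horizon_years = horizon_years)
  }
  lo <- log(1e-8); hi <- log(2e-4)
  le_max <- le_for(lo)
  le_min <- le_for(hi)
  if (target_discounted_le > le_max || target_discounted_le < le_min)
    stop(sprintf(
      paste0("target discounted life expectancy %.3g is outside the achievable",
             " range [%.3f, %.3f] for these template parameters"),
      target_discounted_le, le_min, le_max), call. = FALSE)
  root <- stats::uniroot(function(x) le_for(x) - target_discounted_le,
                         lower = lo, upper = hi, tol = 1e-8)
  gm <- template
  gm$gompertz_a <- exp(root$root)
  achieved <- le_for(root$root)
  if (abs(achieved - target_discounted_le) / target_discounted_le > 0.005)
    stop(sprintf("calibration failed: achieved %.4f vs target %.4f",
                 achieved, target_discounted_le), call. = FALSE)
  gm
}

#' Generate a random valid parameter set
#'
#' Draws a structurally complete `parameter_set` with rates, shares, costs
#' and utilities in plausible ranges, for property-based testing of the
#' engine. Deterministic given `seed`; always passes
#' [validate_parameter_set()]. PSA specs and DSA ranges are left empty.
#'
#' @param seed Integer seed.
#' @return A validated `parameter_set`.
#' @export
generate_random_parameter_set <- function(seed) {
  set.seed(seed)
  runif1 <- function(lo, hi) stats::runif(1, lo, hi)
  random_arm <- function(nm) {
    shares <- stats::rgamma(3, shape = 2)
    shares <- shares / sum(shares)
    names(shares) <- exac_state_types()
    n_ae <- sample(0:4, 1)
    aes <- list()
    if (n_ae > 0) {
      aes <- lapply(seq_len(n_ae), function(i)
        adverse_event(paste0("ae_", i), runif1(0, 0.3),
                      runif1(10, 10000), -runif1(0, 0.02)))
      names(aes) <- paste0("ae_", seq_len(n_ae))
    }
    treatment_arm(
      name = nm,
      regimens = list(main = drug_regimen("main", runif1(1, 200),
                                          sample(60:240, 1), runif1(0, 4),
                                          runif1(0.3, 1))),
      annual_severe_exac_rate = runif1(0, 1),
      exac_type_shares = shares,
      adverse_events = aes,
      annual_moderate_exac_rate = runif1(0, 0.5),
      annual_withdrawal_risk = runif1(0, 0.05)
    )
  }
  parameter_set(
    intervention = random_arm("arm A"),
    comparator = random_arm("arm B"),
    economics = economic_inputs(
      nonexac_state_cost = runif1(0, 100),
      nonexac_cost_basis = sample(c("per_year", "per_week"), 1),
      nonexac_utility = runif1(0.3, 1),
      moderate_exac_cost = runif1(0, 500),
      moderate_exac_disutility = -runif1(0, 0.2),
      productivity_days_lost_per_year = runif1(0, 2),
      daily_wage = runif1(50, 400),
      stepup_daily_drug_cost = runif1(0, 3)
    ),
    exac_types = list(
      SCS = exacerbation_type("SCS", runif1(0, 500), -runif1(0, 0.3),
                              runif1(0, 0.02)),
      ED_SCS = exacerbation_type("ED_SCS", runif1(0, 2000), -runif1(0, 0.4),
                                 runif1(0, 0.05)),
      INPATIENT = exacerbation_type("INPATIENT", runif1(0, 20000),
                                    -runif1(0, 0.5), runif1(0, 0.1))
    )
  )
}
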