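# Parameter uncertainty: PSA distribution specs, sampling, the Monte Carlo
# driver, and one-way deterministic (tornado) sensitivity analysis.

#' Specify a sampling distribution for one parameter
#'
#' @param target Dotted parameter path (see [get_parameter()]) or a character
#'   vector of paths that share a single draw (used e.g. for unit costs common
#'   to both arms). Paths starting with `"config."` address the run
#'   configuration (e.g. `"config.start_age"`).
#' @param family `"beta"`, `"gamma"`, `"dirichlet"` or `"fixed"`.
#' @param parameters Family-specific list: beta `list(alpha, beta)`; gamma
#'   `list(shape, scale)`; dirichlet `list(concentration = <vector>)`; fixed
#'   `list(value)` (or empty to keep the base value).
#' @param negate If `TRUE`, the negative of the draw is used (disutilities
#'   are sampled from a beta and then negated).
#' @return An object of class `distribution_spec`.
#' @export
distribution_spec <- function(target,
                              family = c("beta", "gamma", "dirichlet", "fixed"),
                              parameters = list(), negate = FALSE) {
  family <- match.arg(family)
  if (family == "beta" &&
      (parameters$alpha <= 0 || parameters$beta <= 0))
    stop("beta parameters must be > 0", call. = FALSE)
  if (family == "gamma" &&
      (parameters$shape <= 0 || parameters$scale <= 0))
    stop("gamma parameters must be > 0", call. = FALSE)
  if (family == "dirichlet" && any(parameters$concentration <= 0))
    stop("dirichlet concentrations must be > 0", call. = FALSE)
  structure(list(target = as.character(target), family = family,
                 parameters = parameters, negate = isTRUE(negate)),
            class = "distribution_spec")
}

#' Analytic mean of a distribution spec
#'
#' @param spec A [distribution_spec()].
#' @return Mean of the sampling distribution (sign-adjusted for `negate`);
#'   a vector for dirichlet specs; `NA` for parameter-free `fixed` specs.
#' @export
spec_mean <- function(spec) {
  m <- switch(spec$family,
    beta = spec$parameters$alpha / (spec$parameters$alpha + spec$parameters$beta),
    gamma = spec$parameters$shape * spec$parameters$scale,
    dirichlet = spec$parameters$concentration / sum(spec$parameters$concentration),
    fixed = if (!is.null(spec$parameters$value)) spec$parameters$value else NA_real_
  )
  if (spec$negate) -m else m
}

#' Build a distribution spec from a mean and coefficient of variation
#'
#' The fallback used where no distribution parameters are published: the
#' spread is set by a coefficient of variation (standard deviation / mean),
#' 10% by default. For a gamma target, `shape = 1/cv^2` and
#' `scale = mean * cv^2` (so `cv = 0.1` gives `shape = 100`). For a beta
#' target, method-of-moments with `sd = cv * mean`. Setting
#' `interpretation = "variance_to_mean"` instead reads the ratio as
#' variance/mean.
#'
#' @param mean Target mean (> 0; < 1 for beta).
#' @param cv Coefficient of variation (or variance-to-mean ratio), default
#'   0.1.
#' @param family `"gamma"` or `"beta"`.
#' @param target Parameter path(s) for the resulting spec.
#' @param negate Passed through to [distribution_spec()].
#' @param interpretation `"cv"` (default) or `"variance_to_mean"`.
#' @return A [distribution_spec()] whose analytic mean equals `mean`.
#' @export
moments_to_spec <- function(mean, cv = 0.1, family = c("gamma", "beta"),
                            target = character(), negate = FALSE,
                            interpretation = c("cv", "variance_to_mean")) {
  family <- match.arg(family)
  interpretation <- match.arg(interpretation)
  if (mean <= 0) stop("`mean` must be > 0", call. = FALSE)
  var <- switch(interpretation,
                cv = (cv * mean)^2,
                variance_to_mean = cv * mean)
  if (family == "gamma") {
    spec <- distribution_spec(target, "gamma",
                              list(shape = mean^2 / var, scale = var / mean),
                              negate = negate)
  } else {
    if (mean >= 1) stop("beta mean must be < 1", call. = FALSE)
    if (var >= mean * (1 - mean))
      stop("infeasible beta variance for this mean", call. = FALSE)
    alpha <- mean * (mean * (1 - mean) / var - 1)
    beta <- alpha * (1 - mean) / mean
    spec <- distribution_spec(target, "beta",
                              list(alpha = alpha, beta = beta), negate = negate)
  }
  stopifnot(abs(abs(spec_mean(spec)) - mean) < 1e-9)
  spec
}

draw_from_spec <- function(spec) {
  d <- switch(spec$family,
    beta = stats::rbeta(1, spec$parameters$alpha, spec$parameters$beta),
    gamma = stats::rgamma(1, shape = spec$parameters$shape,
                          scale = spec$parameters$scale),
    dirichlet = {
      g <- stats::rgamma(length(spec$parameters$concentration),
                         shape = spec$parameters$concentration, scale = 1)
      g / sum(g)
    },
    fixed = spec$parameters$value   # NULL keeps the base value
  )
  if (!is.null(d) && spec$negate) d <- -d
  d
}

#' Published PSA distribution specifications
#'
#' The built-in sampling specifications: beta distributions for the annual
#' severe exacerbation rates, adverse-event proportions and the
#' non-exacerbation utility; negated betas for the exacerbation disutilities;
#' gamma distributions for inhalations/day and the starting age; dirichlet
#' for the exacerbation-type shares (concentration = shares x 100); and
#' 10%-coefficient-of-variation gamma fallbacks for unit costs with no
#' published parameters. Drug acquisition prices are fixed (not sampled);
#' adverse-event unit costs are sampled once and shared across arms.
#'
#' @return List of [distribution_spec()] objects.
#' @export
default_distribution_specs <- function() {
  both <- function(suffix) paste0(c("intervention.", "comparator."), suffix)
  ae_beta <- function(arm, name, alpha, beta) distribution_spec(
    sprintf("%s.adverse_events.%s.annual_proportion", arm, name),
    "beta", list(alpha = alpha, beta = beta))
  c(
    list(
      distribution_spec("config.start_age", "gamma",
                        list(shape = 100, scale = 0.41)),
      distribution_spec("intervention.annual_severe_exac_rate", "beta",
                        list(alpha = 88.89, beta = 719.20)),
      distribution_spec("comparator.annual_severe_exac_rate", "beta",
                        list(alpha = 87.88, beta = 644.45)),
      distribution_spec("intervention.exac_type_shares", "dirichlet",
                        list(concentration = c(81.9, 10.2, 7.9))),
      distribution_spec("comparator.exac_type_shares", "dirichlet",
                        list(concentration = c(78.4, 15.2, 6.4)))
    ),
    list(
      ae_beta("intervention", "viral_urti", 95.53, 1157.83),
      ae_beta("comparator", "viral_urti", 91.92, 1057.08),
      ae_beta("intervention", "urti", 96.06, 2367.04),
      ae_beta("comparator", "urti", 95.66, 2128.92),
      ae_beta("intervention", "bronchitis", 96.87, 3027.94),
      ae_beta("comparator", "bronchitis", 96.26, 2505.44),
      ae_beta("intervention", "pharyngitis", 97.58, 3968.09),
      ae_beta("comparator", "pharyngitis", 96.97, 3135.36),
      ae_beta("intervention", "headache", 97.48, 3801.53),
      ae_beta("comparator", "headache", 97.58, 3968.09),
      ae_beta("intervention", "allergic_rhinitis", 97.58, 3968.09),
      ae_beta("comparator", "allergic_rhinitis", 97.88, 4563.03),
      ae_beta("intervention", "influenza", 98.38, 6050.62),
      ae_beta("comparator", "influenza", 97.88, 4563.03)
    ),
    list(
      distribution_spec(
        "intervention.regimens.budesonide_formoterol.inhalations_per_day",
        "gamma", list(shape = 100, scale = 0.0052)),
      distribution_spec("comparator.regimens.fluticasone.inhalations_per_day",
                        "gamma", list(shape = 100, scale = 0.02)),
      distribution_spec("comparator.regimens.salbutamol.inhalations_per_day",
                        "gamma", list(shape = 100, scale = 0.0049)),
      distribution_spec("exac_types.SCS.direct_cost_per_event", "gamma",
                        list(shape = 100, scale = 1.5514)),
      distribution_spec("exac_types.ED_SCS.direct_cost_per_event", "gamma",
                        list(shape = 100, scale = 4.9081)),
      distribution_spec("exac_types.INPATIENT.direct_cost_per_event", "gamma",
                        list(shape = 100, scale = 93.9994)),
      distribution_spec("economics.nonexac_state_cost", "gamma",
                        list(shape = 100, scale = 0.384)),
      distribution_spec(both("adverse_events.viral_urti.cost_per_event"),
                        "gamma", list(shape = 100, scale = 79.09)),
      distribution_spec(both("adverse_events.urti.cost_per_event"),
                        "gamma", list(shape = 100, scale = 79.09)),
      distribution_spec(both("adverse_events.bronchitis.cost_per_event"),
                        "gamma", list(shape = 100, scale = 1.57)),
      distribution_spec(both("adverse_events.pharyngitis.cost_per_event"),
                        "gamma", list(shape = 100, scale = 1.57)),
      distribution_spec(both("adverse_events.headache.cost_per_event"),
                        "gamma", list(shape = 100, scale = 1.57)),
      distribution_spec(both("adverse_events.allergic_rhinitis.cost_per_event"),
                        "gamma", list(shape = 100, scale = 1.57)),
      distribution_spec(both("adverse_events.influenza.cost_per_event"),
                        "gamma", list(shape = 100, scale = 60.38)),
      distribution_spec("economics.nonexac_utility", "beta",
                        list(alpha = 12.43, beta = 1.91)),
      distribution_spec("exac_types.SCS.disutility", "beta",
                        list(alpha = 110.1, beta = 1211.1), negate = TRUE),
      distribution_spec("exac_types.ED_SCS.disutility", "beta",
                        list(alpha = 115.15, beta = 882.8), negate = TRUE),
      distribution_spec("exac_types.INPATIENT.disutility", "beta",
                        list(alpha = 120.2, beta = 721.2), negate = TRUE),
      distribution_spec("economics.moderate_exac_disutility", "beta",
                        list(alpha = 105.05, beta = 2206.05), negate = TRUE)
    )
  )
}

#' Draw one sampled parameter set
#'
#' Deep-copies `base` and replaces each targeted parameter with one draw from
#' its distribution (in the order the specs are listed; a spec with multiple
#' target paths assigns the same draw to each, and dirichlet draws replace
#' whole share vectors). Untargeted parameters - notably drug acquisition
#' prices, which are treated as known and fixed - are unchanged. Uses the
#' current R random-number stream; seed with `set.seed()` for
#' reproducibility.
#'
#' @param base A `parameter_set`.
#' @param specs List of [distribution_spec()] objects (default: those stored
#'   in `base`).
#' @param config Optional [run_config()]; when supplied, specs targeting
#'   `"config.*"` paths are applied to it and a list
#'   `list(params =, config =)` is returned. When `NULL` (default), config
#'   specs are ignored and only the sampled `parameter_set` is returned.
#' @return A sampled `parameter_set`, or `list(params, config)` when
#'   `config` is given.
#' @export
sample_parameter_set <- function(base, specs = base$distribution_specs,
                                 config = NULL) {
  params <- base
  for (spec in specs) {
    is_config <- startsWith(spec$target, "config.")
    if (any(is_config) && !all(is_config))
      stop("a spec cannot mix config and parameter targets", call. = FALSE)
    if (all(is_config) && is.null(config)) next
    # skip specs for optional parameters absent from this set
    current <- tryCatch(
      get_parameter(if (all(is_config)) list(config = config) else params,
                    spec$target[1]),
      error = function(e) stop("distribution spec targets unknown path: ",
                               spec$target[1], call. = FALSE))
    if (is.null(current)) next
    d <- draw_from_spec(spec)
    if (is.null(d)) next
    for (path in spec$target) {
      if (startsWith(path, "config.")) {
        config <- set_config_value(config, sub("^config\\.", "", path), d)
      } else {
        if (spec$family == "dirichlet") {
          old <- get_parameter(params, path)
          names(d) <- names(old)
        }
        params <- set_parameter(params, path, d)
      }
    }
  }
  if (is.null(config)) params else list(params = params, config = config)
}

set_config_value <- function(config, field, value) {
  if (field == "discount_rate") {
    config$discount_rate_costs <- value
    config$discount_rate_outcomes <- value
  } else if (field %in% names(config)) {
    config[[field]] <- value
  } else {
    stop("unknown config field: ", field, call. = FALSE)
  }
  config
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: `n` independent draws
#' from the distribution specs, each run deterministically through the Markov
#' engine for both arms. Each iteration uses its own random stream derived
#' from the master seed, so results are reproducible and extending the spec
#' list does not reshuffle other iterations' draws.
#'
#' @param params A `parameter_set` (with `distribution_specs`).
#' @param config A [run_config()].
#' @param lt A `life_table`.
#' @param n Number of iterations (default 1000).
#' @param seed Master seed.
#' @param wtp_grid Willingness-to-pay grid for the attached CEAC.
#' @return A `psa_result`: per-iteration draws (`draws` data frame with
#'   per-arm costs/QALYs and incrementals), summary means, the CEAC, and the
#'   seed.
#' @export
run_psa <- function(params, config = run_config(), lt, n = 1000, seed = 1L,
                    wtp_grid = default_wtp_grid()) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  validate_parameter_set(params)
  lookup <- lifetable_lookup(lt)
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max, n)
  cols <- c("cost_intervention", "cost_comparator",
            "qaly_intervention", "qaly_comparator")
  draws <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  for (i in seq_len(n)) {
    set.seed(iter_seeds[i])
    sampled <- sample_parameter_set(params, config = config)
    it_int <- run_arm(sampled$params$intervention, sampled$params,
                      sampled$config, lookup)
    it_cmp <- run_arm(sampled$params$comparator, sampled$params,
                      sampled$config, lookup)
    draws[i, ] <- c(it_int$total_cost, it_cmp$total_cost,
                    it_int$total_qaly, it_cmp$total_qaly)
  }
  draws <- as.data.frame(draws)
  draws$delta_cost <- draws$cost_intervention - draws$cost_comparator
  draws$delta_qaly <- draws$qaly_intervention - draws$qaly_comparator
  structure(
    list(n_iterations = n, seed = seed, draws = draws,
         means = colMeans(draws),
         ceac = ceac(draws$delta_cost, draws$delta_qaly, wtp_grid)),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations (seed %d)\n", x$n_iterations, x$seed))
  cat(sprintf("  mean incremental cost: $%.2f; mean incremental QALY: %.4f\n",
              x$means["delta_cost"], x$means["delta_qaly"]))
  cat(sprintf("  P(cost-effective) at $50,000/QALY: %.3f; at $100,000/QALY: %.3f\n",
              ceac_at(x$ceac, 50000), ceac_at(x$ceac, 100000)))
  invisible(x)
}

#' Export PSA draws as delimited text
#'
#' @param psa A `psa_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_psa_draws <- function(psa, path) {
  df <- cbind(iteration = seq_len(psa$n_iterations), psa$draws)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the deterministic model twice per parameter (at its lower and
#' upper bound, all else at base), recording incremental cost, incremental
#' QALYs and net monetary benefit at a reference willingness-to-pay. The
#' swing is the absolute difference between the high and low settings;
#' results are sorted by descending cost swing.
#'
#' @param params A `parameter_set`.
#' @param config A [run_config()].
#' @param lt A `life_table`.
#' @param ranges Named list of `c(lower, upper)` keyed by parameter path
#'   (default: `params$dsa_ranges`). Paths beginning `"config."` vary the
#'   run configuration (`"config.discount_rate"` moves both discount rates).
#' @param wtp Reference willingness-to-pay for the NMB swing (default
#'   $50,000/QALY).
#' @return A `tornado_result` data frame: one row per parameter with low/high
#'   incremental cost and QALYs, NMB at `wtp`, and swings; attribute `base`
#'   holds the base-case `ce_result`.
#' @export
run_one_way_dsa <- function(params, config = run_config(), lt,
                            ranges = params$dsa_ranges, wtp = 50000) {
  validate_parameter_set(params)
  lookup <- lifetable_lookup(lt)
  base <- run_base_case(params, config, lt)
  run_at <- function(path, value) {
    if (startsWith(path, "config.")) {
      cfg <- set_config_value(config, sub("^config\\.", "", path), value)
      run_base_case(params, cfg, lt)
    } else {
      run_base_case(set_parameter(params, path, value), config, lt)
    }
  }
  rows <- lapply(names(ranges), function(path) {
    rng <- ranges[[path]]
    lo <- run_at(path, rng[1]); hi <- run_at(path, rng[2])
    data.frame(
      parameter = path, lower = rng[1], upper = rng[2],
      inc_cost_low = lo$incremental_cost, inc_cost_high = hi$incremental_cost,
      inc_qaly_low = lo$incremental_qaly, inc_qaly_high = hi$incremental_qaly,
      nmb_low = net_monetary_benefit(lo$incremental_cost, lo$incremental_qaly, wtp),
      nmb_high = net_monetary_benefit(hi$incremental_cost, hi$incremental_qaly, wtp)
    )
  })
  out <- do.call(rbind, rows)
  out$cost_swing <- abs(out$inc_cost_high - out$inc_cost_low)
  out$nmb_swing <- abs(out$nmb_high - out$nmb_low)
  out <- out[order(-out$cost_swing, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado_result", "data.frame")
  attr(out, "base") <- base
  attr(out, "wtp") <- wtp
  out
}
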