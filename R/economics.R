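# Cost-effectiveness surface: incremental results, NMB, CEAC, CE plane.

#' Deterministic base-case analysis
#'
#' Runs both arms through the Markov engine and assembles the incremental
#' cost-utility result.
#'
#' @param params A `parameter_set`.
#' @param config A [run_config()].
#' @param lt A `life_table`.
#' @return A `ce_result` (see [incremental_result()]).
#' @export
#' @examples
#' \donttest{
#' res <- run_base_case(default_parameter_set(), run_config(),
#'                      generate_life_table())
#' print(res)
#' }
run_base_case <- function(params, config = run_config(), lt) {
  validate_parameter_set(params)
  lookup <- lifetable_lookup(lt)
  incremental_result(run_arm(params$intervention, params, config, lookup),
                     run_arm(params$comparator, params, config, lookup))
}

#' Incremental cost-utility result
#'
#' Computes incremental cost and QALYs (intervention minus comparator) and a
#' dominance verdict: `dominant` when the intervention is cheaper and more
#' effective, `dominated` when it is costlier and less effective, otherwise
#' the ICER. A QALY tie with a cost difference is reported as
#' `cost-difference-only` (no ICER).
#'
#' @param intervention,comparator `arm_outcomes` objects from [run_arm()],
#'   produced under the same run configuration.
#' @return A `ce_result` with per-arm category costs and QALYs, incrementals,
#'   `icer` (number or `NA`) and `verdict`.
#' @export
incremental_result <- function(intervention, comparator) {
  if (!identical(names(intervention$cost_totals), names(comparator$cost_totals)))
    stop("arm summaries have mismatched cost categories; were they run under the same configuration?",
         call. = FALSE)
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$total_qaly - comparator$total_qaly
  if (dq == 0 && dc == 0) {
    verdict <- "tie"; icer <- NA_real_
  } else if (dc < 0 && dq > 0) {
    verdict <- "dominant"; icer <- NA_real_
  } else if (dc > 0 && dq < 0) {
    verdict <- "dominated"; icer <- NA_real_
  } else if (dq == 0) {
    verdict <- "cost-difference-only"; icer <- NA_real_
  } else {
    verdict <- "ICER"; icer <- dc / dq
  }
  structure(
    list(
      arms = c(intervention = intervention$arm, comparator = comparator$arm),
      cost_categories = cbind(intervention = intervention$cost_totals,
                              comparator = comparator$cost_totals),
      qaly_categories = cbind(intervention = intervention$qaly_totals,
                              comparator = comparator$qaly_totals),
      total_cost = c(intervention = intervention$total_cost,
                     comparator = comparator$total_cost),
      total_qaly = c(intervention = intervention$total_qaly,
                     comparator = comparator$total_qaly),
      life_years = c(intervention = intervention$life_years,
                     comparator = comparator$life_years),
      incremental_cost = dc, incremental_qaly = dq,
      icer = icer, verdict = verdict
    ),
    class = "ce_result"
  )
}

#' Net monetary benefit
#'
#' `wtp * incremental_qaly - incremental_cost`.
#'
#' @param incremental_cost,incremental_qaly Incremental cost and QALYs.
#' @param wtp Willingness to pay per QALY (>= 0).
#' @return Net monetary benefit in currency units.
#' @export
net_monetary_benefit <- function(incremental_cost, incremental_qaly, wtp) {
  if (any(wtp < 0)) stop("`wtp` must be >= 0", call. = FALSE)
  wtp * incremental_qaly - incremental_cost
}

#' Default willingness-to-pay grid
#'
#' $0 to $200,000 per QALY in $1,000 steps (includes the commonly quoted
#' $50,000 and $100,000 thresholds).
#'
#' @return Ascending numeric vector.
#' @export
default_wtp_grid <- function() seq(0, 200000, by = 1000)

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with strictly
#' positive net monetary benefit (an NMB of exactly zero counts as not
#' cost-effective, a deterministic and conservative tie rule). At
#' `wtp = 0` this is exactly the fraction of draws with negative incremental
#' cost.
#'
#' @param delta_cost,delta_qaly Equal-length vectors of per-draw incremental
#'   costs and QALYs.
#' @param wtp_grid Strictly ascending willingness-to-pay values.
#' @return A `ceac_curve` data frame with columns `wtp` and `probability`,
#'   and attribute `n_iterations`.
#' @export
ceac <- function(delta_cost, delta_qaly, wtp_grid = default_wtp_grid()) {
  n <- length(delta_cost)
  if (n < 1) stop("at least one PSA draw is required", call. = FALSE)
  if (length(delta_qaly) != n)
    stop("`delta_cost` and `delta_qaly` must have equal length", call. = FALSE)
  if (is.unsorted(wtp_grid, strictly = TRUE))
    stop("`wtp_grid` must be strictly ascending", call. = FALSE)
  prob <- vapply(wtp_grid, function(l)
    mean(net_monetary_benefit(delta_cost, delta_qaly, l) > 0), numeric(1))
  out <- data.frame(wtp = wtp_grid, probability = prob)
  class(out) <- c("ceac_curve", "data.frame")
  attr(out, "n_iterations") <- n
  out
}

#' Probability of cost-effectiveness at a threshold
#'
#' @param curve A `ceac_curve`.
#' @param wtp A willingness-to-pay value present in the curve's grid.
#' @return Probability in `[0, 1]`.
#' @export
ceac_at <- function(curve, wtp) {
  i <- match(wtp, curve$wtp)
  if (is.na(i)) stop("wtp value ", wtp, " not on the CEAC grid", call. = FALSE)
  curve$probability[i]
}

#' Cost-effectiveness plane points
#'
#' Labels each PSA draw with its quadrant: `SE` (cheaper, more effective =
#' dominant), `NE` (costlier, more effective), `SW` (cheaper, less
#' effective), `NW` (costlier, less effective = dominated). Axis ties are
#' assigned to the more favourable quadrant boundary arbitrarily but
#' deterministically (ties on either axis go to `SE`/`NE`/`SW` in that
#' order of checks).
#'
#' @inheritParams ceac
#' @return Data frame with `delta_qaly`, `delta_cost`, `quadrant`.
#' @export
ce_plane_points <- function(delta_cost, delta_qaly) {
  if (length(delta_cost) < 1) stop("at least one draw is required", call. = FALSE)
  quadrant <- ifelse(delta_qaly >= 0,
                     ifelse(delta_cost <= 0, "SE", "NE"),
                     ifelse(delta_cost <= 0, "SW", "NW"))
  data.frame(delta_qaly = delta_qaly, delta_cost = delta_cost,
             quadrant = factor(quadrant, levels = c("SE", "NE", "SW", "NW")))
}

#' Tabulate a deterministic result in publication layout
#'
#' One row per cost category plus a total row; columns: per-arm costs,
#' incremental cost, per-arm QALYs, incremental QALYs.
#'
#' @param x A `ce_result`.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.ce_result <- function(x, ...) {
  cc <- x$cost_categories
  qal <- matrix(NA_real_, nrow(cc), 2,
                dimnames = list(rownames(cc), colnames(cc)))
  qc <- x$qaly_categories
  qal["nonexac", ] <- qc["nonexac", ]
  qal["severe_exac", ] <- qc["severe_exac", ]
  if ("adverse_events" %in% rownames(qal)) qal["adverse_events", ] <- 0
  keep <- rowSums(cc != 0) > 0 | rownames(cc) %in%
    c("nonexac", "severe_exac", "drugs", "adverse_events")
  cc <- cc[keep, , drop = FALSE]; qal <- qal[keep, , drop = FALSE]
  df <- data.frame(
    category = c(rownames(cc), "total"),
    cost_intervention = c(cc[, "intervention"], x$total_cost["intervention"]),
    cost_comparator = c(cc[, "comparator"], x$total_cost["comparator"]),
    incremental_cost = c(cc[, "intervention"] - cc[, "comparator"],
                         x$incremental_cost),
    qaly_intervention = c(qal[, "intervention"], x$total_qaly["intervention"]),
    qaly_comparator = c(qal[, "comparator"], x$total_qaly["comparator"]),
    row.names = NULL
  )
  df$incremental_qaly <- df$qaly_intervention - df$qaly_comparator
  df
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result>\n")
  cat(sprintf("  intervention: %s\n  comparator:   %s\n",
              x$arms["intervention"], x$arms["comparator"]))
  df <- as.data.frame(x)
  money <- c("cost_intervention", "cost_comparator", "incremental_cost")
  qaly <- c("qaly_intervention", "qaly_comparator", "incremental_qaly")
  shown <- df
  shown[money] <- lapply(shown[money], function(v) sprintf("%.2f", v))
  shown[qaly] <- lapply(shown[qaly], function(v)
    ifelse(is.na(v), "", sprintf("%.3f", v)))
  print(shown, row.names = FALSE)
  if (x$verdict == "ICER")
    cat(sprintf("  ICER: $%.0f per QALY\n", x$icer))
  else
    cat(sprintf("  verdict: %s%s\n", x$verdict,
                if (x$verdict == "dominant")
                  paste0(" (", x$arms["intervention"], ")") else ""))
  invisible(x)
}

#' Write a `ce_result` or CEAC to delimited text
#'
#' @param x A `ce_result` or `ceac_curve`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ce_table <- function(x, path) {
  df <- if (inherits(x, "ce_result")) as.data.frame(x) else as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
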