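# Publication-style outputs, plots, run manifests, and the functions behind
# the command-line interface.

#' Run manifest
#'
#' A small provenance record written next to every set of result files:
#' command, configuration snapshot, parameter-file hash, seed, package
#' version and timestamp.
#'
#' @param command Command name.
#' @param config A [run_config()].
#' @param param_file Path to the parameter file used (hashed with MD5), or
#'   `NULL`.
#' @param seed Seed used, or `NULL`.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(command, config, param_file = NULL, seed = NULL) {
  structure(list(
    command = command,
    config = unclass(config),
    param_file = param_file,
    param_file_md5 = if (!is.null(param_file) && file.exists(param_file))
      unname(tools::md5sum(param_file)) else NULL,
    seed = seed,
    package_version = as.character(utils::packageVersion("asthmaCE")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

resolve_inputs <- function(param_file = NULL, life_table_file = NULL) {
  params <- if (is.null(param_file)) default_parameter_set()
            else read_parameters(param_file)
  lt <- if (is.null(life_table_file)) generate_life_table()
        else read_life_table(life_table_file)
  list(params = params, lt = lt)
}

#' Base-case report
#'
#' Runs the deterministic base case and writes the category-by-arm cost/QALY
#' table, the per-cycle traces for both arms, and a run manifest to
#' `out_dir`.
#'
#' @param param_file Parameter YAML file (`NULL` uses
#'   [default_parameter_set()]).
#' @param life_table_file Life-table CSV (`NULL` uses the bundled synthetic
#'   [generate_life_table()]).
#' @param out_dir Output directory (created if missing).
#' @param config A [run_config()].
#' @return The `ce_result`, invisibly.
#' @export
command_base_case <- function(param_file = NULL, life_table_file = NULL,
                              out_dir = ".", config = run_config()) {
  inp <- resolve_inputs(param_file, life_table_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_base_case(inp$params, config, inp$lt)
  write_ce_table(res, file.path(out_dir, "base_case.csv"))
  for (role in c("intervention", "comparator")) {
    out <- run_arm(inp$params[[role]], inp$params, config,
                   lifetable_lookup(inp$lt))
    write_trace(attr(out, "trace"), out,
                file.path(out_dir, paste0("trace_", role, ".csv")))
  }
  write_manifest(run_manifest("base_case", config, param_file),
                 file.path(out_dir, "manifest.json"))
  message(sprintf("Incremental cost: $%.2f; incremental QALY: %.4f; verdict: %s",
                  res$incremental_cost, res$incremental_qaly, res$verdict))
  invisible(res)
}

#' PSA report
#'
#' Runs the probabilistic sensitivity analysis and writes the per-iteration
#' draws, the CEAC table (the $50,000 and $100,000 thresholds are always on
#' the grid), optional plots, and a run manifest.
#'
#' @inheritParams command_base_case
#' @param n Iterations.
#' @param seed Master seed.
#' @param plots Write CE-plane and CEAC plots (PNG)? Default `FALSE` so runs
#'   are clean on headless systems.
#' @return The `psa_result`, invisibly.
#' @export
command_psa <- function(param_file = NULL, life_table_file = NULL,
                        out_dir = ".", config = run_config(), n = 1000,
                        seed = 1L, plots = FALSE) {
  inp <- resolve_inputs(param_file, life_table_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  psa <- run_psa(inp$params, config, inp$lt, n = n, seed = seed)
  write_psa_draws(psa, file.path(out_dir, "psa_draws.csv"))
  write_ce_table(psa$ceac, file.path(out_dir, "ceac.csv"))
  if (plots) {
    ggplot2::ggsave(file.path(out_dir, "ce_plane.png"), plot_ce_plane(psa),
                    width = 6, height = 5, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "ceac.png"), plot_ceac(psa$ceac),
                    width = 6, height = 4, dpi = 150)
  }
  write_manifest(run_manifest("psa", config, param_file, seed),
                 file.path(out_dir, "manifest.json"))
  message(sprintf(
    "P(cost-effective): %.3f at $50,000/QALY; %.3f at $100,000/QALY (n = %d)",
    ceac_at(psa$ceac, 50000), ceac_at(psa$ceac, 100000), n))
  invisible(psa)
}

#' Tornado (one-way DSA) report
#'
#' @inheritParams command_psa
#' @param wtp Reference willingness-to-pay for NMB swings.
#' @return The `tornado_result`, invisibly.
#' @export
command_dsa <- function(param_file = NULL, life_table_file = NULL,
                        out_dir = ".", config = run_config(), wtp = 50000,
                        plots = FALSE) {
  inp <- resolve_inputs(param_file, life_table_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tor <- run_one_way_dsa(inp$params, config, inp$lt, wtp = wtp)
  utils::write.csv(as.data.frame(tor), file.path(out_dir, "tornado.csv"),
                   row.names = FALSE)
  if (plots)
    ggplot2::ggsave(file.path(out_dir, "tornado.png"), plot_tornado(tor),
                    width = 7, height = 5, dpi = 150)
  write_manifest(run_manifest("dsa", config, param_file),
                 file.path(out_dir, "manifest.json"))
  invisible(tor)
}

#' Scenario report
#'
#' @inheritParams command_psa
#' @param ids Scenario numbers (default all eight).
#' @param mode `"probabilistic"` or `"deterministic"`.
#' @return The `scenario_table`, invisibly.
#' @export
command_scenarios <- function(param_file = NULL, life_table_file = NULL,
                              out_dir = ".", config = run_config(),
                              ids = 1:8,
                              mode = c("probabilistic", "deterministic"),
                              n = 1000, seed = 1L) {
  mode <- match.arg(mode)
  inp <- resolve_inputs(param_file, life_table_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- run_scenarios(ids, inp$params, config, inp$lt, mode = mode,
                       n = n, seed = seed)
  write_scenario_table(tab, file.path(out_dir, "scenarios.csv"))
  write_manifest(run_manifest("scenarios", config, param_file, seed),
                 file.path(out_dir, "manifest.json"))
  invisible(tab)
}

# ---- plots ------------------------------------------------------------------

#' Plot the cost-effectiveness plane
#'
#' @param psa A `psa_result` (or anything accepted by [ce_plane_points()]
#'   when `delta_cost`/`delta_qaly` are passed directly).
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa) {
  pts <- ce_plane_points(psa$draws$delta_cost, psa$draws$delta_qaly)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (2019 CAD)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param curve A `ceac_curve`.
#' @param thresholds Vertical reference lines (default $50,000).
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve, thresholds = 50000) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = thresholds, linetype = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay per QALY (2019 CAD)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram
#'
#' @param tor A `tornado_result`.
#' @return A ggplot object of incremental-cost swings per parameter.
#' @export
plot_tornado <- function(tor) {
  base_dc <- attr(tor, "base")$incremental_cost
  df <- as.data.frame(tor)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$inc_cost_low,
                                       xend = .data$inc_cost_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_dc, linetype = 2) +
    ggplot2::labs(x = "Incremental cost (2019 CAD)", y = NULL,
                  title = "One-way sensitivity of incremental cost") +
    ggplot2::theme_minimal()
}
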