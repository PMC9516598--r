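## End-to-end pipeline: config -> fixture -> PSA -> cost-effectiveness ->
## value of information, with delimited-text outputs and a run manifest.

#' Run the full analysis pipeline from a config file
#'
#' Reads a YAML config, loads or generates the parameter fixture, runs the
#' PSA, computes cost-effectiveness outputs (summary table, incremental
#' points, quadrant shares, acceptability curves) and value-of-information
#' curves (EVPI plus EVPPI for the base-case uncertain parameters), and
#' writes everything as delimited text files plus a YAML run manifest.
#'
#' Config keys (all optional except `seed`): `fixture` (path to a fixture
#' YAML, or `"calibrated"`/`"synthetic"` to generate one), `seed`,
#' `n_teeth` (default 1000), `n_draws` (default 500), `horizon_years`
#' (default 66), `lambda_max` (default 100), `scenario` (named overrides as
#' in [sample_parameter_set()]), `voi_parameters` (default the three
#' base-case uncertain parameters), `voi_bootstrap` (default 200), `plots`
#' (default `FALSE`).
#'
#' @param config Path to the YAML config file, or an equivalent named list.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly; side effect: files `psa_results.csv`,
#'   `psa_draws.csv`, `cea_summary.csv`, `increments.csv`, `quadrants.csv`,
#'   `ceac.csv`, `voi.csv`, `manifest.yaml` (and PNG plots if requested).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config)
  } else config_path <- NULL
  bad <- validate_config(config)
  if (length(bad)) stop("invalid config:\n  ", paste(bad, collapse = "\n  "))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  n_teeth <- config$n_teeth %||% 1000L
  n_draws <- config$n_draws %||% 500L
  horizon <- config$horizon_years %||% 66L
  lambda_grid <- 0:(config$lambda_max %||% 100)

  fixture_spec <- config$fixture %||% "calibrated"
  fixture <- if (fixture_spec %in% c("calibrated", "synthetic"))
    make_fixture(seed = seed, variant = fixture_spec)
  else read_fixture(fixture_spec)

  cfg <- simulation_config(n_teeth = n_teeth, horizon_years = horizon,
                           seed = seed, n_psa_draws = n_draws)
  psa <- run_psa(fixture, cfg, scenario = config$scenario %||% list())

  cea <- summary(psa)
  inc <- psa_increments(psa)
  quad <- ce_plane_quadrant_shares(inc)
  ic <- icer(mean(inc$delta_cost), mean(inc$delta_effect))
  cea$icer_label <- ic$label
  cea$icer_value <- if (is.na(ic$value)) NA else ic$value
  ac <- ceac(psa, lambda_grid)

  voi_params <- config$voi_parameters %||%
    c("risk_profile", "training_fraction", "ai_cost")
  n_boot <- config$voi_bootstrap %||% 200
  voi <- rbind(
    voi_curve(psa, NULL, lambda_grid, n_boot = n_boot),
    do.call(rbind, lapply(voi_params, function(par)
      voi_curve(psa, par, lambda_grid, n_boot = n_boot)))
  )

  wr <- function(df, name) utils::write.csv(
    df, file.path(out_dir, name), row.names = FALSE)
  wr(psa$results, "psa_results.csv")
  wr(psa$draws, "psa_draws.csv")
  wr(cea, "cea_summary.csv")
  wr(inc, "increments.csv")
  wr(data.frame(quadrant = names(quad), share = as.numeric(quad)),
     "quadrants.csv")
  wr(as.data.frame(ac), "ceac.csv")
  wr(as.data.frame(voi), "voi.csv")

  if (isTRUE(config$plots)) {
    ggplot2::ggsave(file.path(out_dir, "ce_plane.png"), plot_ce_plane(psa),
                    width = 6, height = 5, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "ceac.png"), plot_ceac(ac),
                    width = 6, height = 4, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "voi.png"), plot_voi(voi),
                    width = 6, height = 4, dpi = 150)
  }

  manifest <- list(
    seed = seed,
    config_hash = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NA,
    package_version = as.character(utils::packageVersion("cariesim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_teeth = n_teeth, n_draws = n_draws, horizon_years = horizon,
    fixture = fixture_spec,
    files = c("psa_results.csv", "psa_draws.csv", "cea_summary.csv",
              "increments.csv", "quadrants.csv", "ceac.csv", "voi.csv")
  )
  writeLines(yaml::as.yaml(manifest), file.path(out_dir, "manifest.yaml"))
  message(sprintf("run complete: seed %d, %d draws x %d teeth -> %s",
                  seed, n_draws, n_teeth, out_dir))
  invisible(out_dir)
}

validate_config <- function(config) {
  v <- character(0)
  if (is.null(config$seed)) v <- c(v, "seed: required")
  else if (!is.numeric(config$seed)) v <- c(v, "seed: must be an integer")
  for (key in c("n_teeth", "n_draws", "horizon_years"))
    if (!is.null(config[[key]]) &&
        (!is.numeric(config[[key]]) || config[[key]] < 1))
      v <- c(v, sprintf("%s: must be a positive integer", key))
  fx <- config$fixture
  if (!is.null(fx) && !fx %in% c("calibrated", "synthetic") && !file.exists(fx))
    v <- c(v, sprintf("fixture: file not found: %s", fx))
  v
}

#' Summarize a pipeline results directory
#'
#' Reads the files written by [run_pipeline()] and prints a compact report:
#' per-strategy mean (2.5-97.5 percentile) cost and retention, the
#' incremental result with its ICER/dominance label, quadrant shares and
#' the value of information at the lowest and highest threshold.
#'
#' @param results_dir Directory written by [run_pipeline()].
#' @return The per-strategy summary data frame, invisibly.
#' @export
summarize_results <- function(results_dir) {
  manifest_path <- file.path(results_dir, "manifest.yaml")
  if (!file.exists(manifest_path))
    stop("no manifest.yaml in ", results_dir, "; not a pipeline results directory")
  manifest <- yaml::read_yaml(manifest_path)
  missing <- manifest$files[!file.exists(file.path(results_dir, manifest$files))]
  if (length(missing))
    stop("missing result files: ", paste(missing, collapse = ", "))

  cea <- utils::read.csv(file.path(results_dir, "cea_summary.csv"))
  quad <- utils::read.csv(file.path(results_dir, "quadrants.csv"))
  voi <- utils::read.csv(file.path(results_dir, "voi.csv"))

  cat(sprintf("Run: seed %s, %s draws x %s teeth, horizon %s y\n",
              manifest$seed, manifest$n_draws, manifest$n_teeth,
              manifest$horizon_years))
  cat("\nCost-effectiveness (mean, 2.5-97.5% across PSA draws):\n")
  for (i in seq_len(nrow(cea)))
    cat(sprintf("  %-16s %6.0f EUR (%.0f-%.0f)   %5.1f y (%.1f-%.1f)\n",
                cea$strategy[i], cea$mean_cost[i], cea$cost_lo[i],
                cea$cost_hi[i], cea$mean_retention[i], cea$retention_lo[i],
                cea$retention_hi[i]))
  cat(sprintf("  incremental result: %s%s\n", cea$icer_label[1],
              if (!is.na(cea$icer_value[1]))
                sprintf(" (%.1f EUR/y)", cea$icer_value[1]) else ""))
  cat("\nCE-plane quadrant shares:",
      paste(sprintf("%s=%.2f", quad$quadrant, quad$share), collapse = ", "), "\n")
  l0 <- min(voi$lambda); lmax <- max(voi$lambda)
  cat("\nValue of information (EUR per individual):\n")
  for (par in unique(voi$parameter)) {
    v <- voi[voi$parameter == par, ]
    cat(sprintf("  %-18s %6.2f at lambda=%d, %6.2f at lambda=%d\n",
                par, v$value[v$lambda == l0], l0,
                v$value[v$lambda == lmax], lmax))
  }
  invisible(cea)
}
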