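## Value-of-information analysis: net monetary benefit, EVPI, single-loop
## EVPPI by conditional grouping, and curves over the willingness-to-pay grid.

#' Net monetary benefit
#'
#' `NMB = lambda * effect - cost`. Applied per strategy with absolute
#' effectiveness and cost; differences of per-strategy NMBs give the
#' incremental form.
#'
#' @param lambda Willingness to pay, euros per retention year (vectorized).
#' @param effect Effectiveness in retention years.
#' @param cost Cost in euros.
#' @return Euros.
#' @export
nmb <- function(lambda, effect, cost) lambda * effect - cost

#' Expected value of perfect information
#'
#' The expected gain of deciding after all parameter uncertainty is
#' resolved: the mean over PSA draws of the per-draw best-strategy NMB,
#' minus the NMB of the strategy that is best on average. Nonnegative up to
#' Monte Carlo error; reported per individual (per-tooth-cohort scale).
#'
#' @param psa A `caries_psa`.
#' @param lambda Willingness to pay (scalar).
#' @return EVPI in euros.
#' @export
evpi <- function(psa, lambda) {
  parts <- nmb_matrix_parts(psa$results)
  if (ncol(parts$cost) < 2) stop("evpi requires at least two strategies")
  nmbm <- lambda * parts$effect - parts$cost
  mean(apply(nmbm, 1, max)) - max(colMeans(nmbm))
}

#' Expected value of partial perfect information for one parameter
#'
#' Single-loop conditional-mean estimator: draws are grouped by the sampled
#' value of the parameter (discrete parameters such as the risk profile or
#' training-data fraction group exactly; continuous parameters such as the
#' AI fee are quantile-binned). Within each group the strategy maximizing
#' the group-mean NMB is chosen; the frequency-weighted mean of these
#' conditional maxima minus the overall best mean NMB is the EVPPI.
#' Unbiased for discrete parameters; `0 <= EVPPI <= EVPI` up to Monte Carlo
#' error.
#'
#' @param psa A `caries_psa` whose `$draws` recorded the parameter.
#' @param parameter Column name in `psa$draws` (e.g. `"risk_profile"`,
#'   `"training_fraction"`, `"ai_cost"`).
#' @param lambda Willingness to pay (scalar).
#' @param n_bins Number of quantile bins for continuous parameters
#'   (default 10).
#' @return EVPPI in euros.
#' @export
evppi <- function(psa, parameter, lambda, n_bins = 10) {
  if (!parameter %in% names(psa$draws))
    stop("parameter not recorded in PSA draws: ", parameter)
  parts <- nmb_matrix_parts(psa$results)
  nmbm <- lambda * parts$effect - parts$cost
  val <- psa$draws[[parameter]][order(psa$draws$draw)]
  group <- if (is.numeric(val) && length(unique(val)) > n_bins) {
    cut(val, breaks = unique(stats::quantile(val, seq(0, 1, length.out = n_bins + 1))),
        include.lowest = TRUE)
  } else factor(val)
  group_max <- tapply(seq_along(group), group, function(idx) {
    max(colMeans(nmbm[idx, , drop = FALSE]))
  })
  freq <- as.numeric(table(group)) / length(group)
  sum(freq * group_max) - max(colMeans(nmbm))
}

#' EVPI or EVPPI over a willingness-to-pay grid
#'
#' Evaluates the value-of-information measure at each grid point and
#' attaches a nonparametric-bootstrap Monte Carlo standard error (resampling
#' PSA draws with replacement).
#'
#' @param psa A `caries_psa`.
#' @param parameter `NULL` for overall EVPI, otherwise a parameter name for
#'   EVPPI (see [evppi()]).
#' @param lambda_grid Willingness-to-pay grid (default 0 to 100 euros).
#' @param n_boot Bootstrap resamples for the standard error (default 200;
#'   0 disables).
#' @return A `caries_voi` data frame: `lambda`, `value`, `stderr`,
#'   `parameter` (`"all"` for EVPI).
#' @export
voi_curve <- function(psa, parameter = NULL, lambda_grid = 0:100, n_boot = 200) {
  measure <- if (is.null(parameter)) {
    function(p, l) evpi(p, l)
  } else {
    function(p, l) evppi(p, parameter, l)
  }
  value <- vapply(lambda_grid, function(l) measure(psa, l), numeric(1))
  stderr <- rep(NA_real_, length(lambda_grid))
  if (n_boot > 0) {
    n <- max(psa$results$draw)
    boot_vals <- matrix(NA_real_, n_boot, length(lambda_grid))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      bpsa <- resample_psa(psa, idx)
      boot_vals[b, ] <- vapply(lambda_grid, function(l) measure(bpsa, l),
                               numeric(1))
    }
    stderr <- apply(boot_vals, 2, stats::sd)
  }
  structure(
    data.frame(lambda = lambda_grid, value = value, stderr = stderr,
               parameter = if (is.null(parameter)) "all" else parameter),
    class = c("caries_voi", "data.frame")
  )
}

## Rebuild a caries_psa from a bootstrap index vector over draws.
resample_psa <- function(psa, idx) {
  res <- psa$results
  parts <- split(res, res$strategy)
  new_res <- do.call(rbind, lapply(parts, function(d) {
    d <- d[order(d$draw), ][idx, ]
    d$draw <- seq_along(idx)
    d
  }))
  draws <- psa$draws[order(psa$draws$draw), ][idx, , drop = FALSE]
  draws$draw <- seq_along(idx)
  structure(list(results = new_res, draws = draws,
                 strategies = psa$strategies, config = psa$config),
            class = "caries_psa")
}
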