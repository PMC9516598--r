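## Monte Carlo microsimulation: inner loop over teeth and annual cycles
## (Rcpp engine with a pure-R per-tooth reference), outer loop over PSA draws.

#' Simulation configuration
#'
#' @param n_teeth Teeth per cohort (default 1000).
#' @param horizon_years Lifetime horizon in annual cycles (default 66, the
#'   mean remaining lifetime of an initially 12-year-old individual).
#' @param seed Root RNG seed; every source of randomness in a run descends
#'   from it via deterministic sub-seeds.
#' @param n_psa_draws Number of PSA draws for [run_psa()] (default 500).
#' @param common_random_numbers Reuse the same cohort sub-seed for both
#'   strategies within a draw (variance reduction for incremental estimates;
#'   default `TRUE`).
#' @return A `caries_sim_config` object.
#' @export
simulation_config <- function(n_teeth = 1000L, horizon_years = 66L, seed = 1L,
                              n_psa_draws = 500L, common_random_numbers = TRUE) {
  stopifnot(n_teeth >= 1, horizon_years >= 1, n_psa_draws >= 1)
  structure(
    list(n_teeth = as.integer(n_teeth),
         horizon_years = as.integer(horizon_years),
         seed = as.integer(seed),
         n_psa_draws = as.integer(n_psa_draws),
         common_random_numbers = isTRUE(common_random_numbers)),
    class = "caries_sim_config"
  )
}

## Deterministic sub-seed derivation (Lehmer steps, safe in double precision).
derive_seed <- function(root, ...) {
  m <- 2147483647
  x <- (as.numeric(root) %% m) + 1
  for (k in c(...)) {
    x <- (x * 16807) %% m
    x <- (x + as.numeric(k) * 65537 + 1) %% m
  }
  as.integer((x * 16807) %% m)
}

#' Simulate one tooth over the lifetime horizon (reference implementation)
#'
#' Pure-R per-tooth walk through the annual cycles, applying the documented
#' within-cycle order: examination fees, examination and treatment decision,
#' natural progression, treated-state failures. [run_cohort()] uses a
#' compiled engine with identical logic; this function is the readable
#' reference and returns the full cost-event trace.
#'
#' @param strat A [strategy()].
#' @param p A `caries_parameter_set`.
#' @param cfg A [simulation_config()] (only `horizon_years` is used).
#' @param init Optional `caries_tooth` start state; drawn from the risk
#'   profile when `NULL`.
#' @return `list(retention_years, discounted_cost, events)` where `events`
#'   is a data frame of (label, euros, year) with undiscounted euros.
#' @export
simulate_tooth <- function(strat, p, cfg, init = NULL) {
  s <- if (is.null(init)) initial_state(p$risk) else init
  acc <- vector("list", 3L * cfg$horizon_years)
  n_acc <- 0L
  keep <- function(ev) if (nrow(ev)) { n_acc <<- n_acc + 1L; acc[[n_acc]] <<- ev }
  retention <- 0
  for (t in seq_len(cfg$horizon_years) - 1L) {
    if (!s$alive_tooth) break
    retention <- retention + 1
    keep(exam_costs(strat, p, t))
    out <- examine(s, strat, p, t)
    dt <- decide_and_treat(s, out, p$costs, year = t)
    s <- dt$state
    keep(dt$events)
    if (s$health %in% UNTREATED_STATES) {
      s <- natural_step(s, p$transitions, p$risk$progression_multiplier)
    } else if (s$health %in% TREATED_STATES) {
      ts <- treatment_step(s, p, year = t)
      s <- ts$state
      keep(ts$events)
    }
    s$age_years <- s$age_years + 1L
  }
  events <- if (n_acc) do.call(rbind, acc[seq_len(n_acc)]) else no_cost_events()
  disc_cost <- if (nrow(events)) {
    sum(events$euros * (1 + p$discount_rate)^(-events$year))
  } else 0
  list(retention_years = retention, discounted_cost = disc_cost,
       events = events, final_state = s)
}

#' Run a cohort of independent teeth under one strategy
#'
#' @param strat A [strategy()].
#' @param p A `caries_parameter_set`.
#' @param cfg A [simulation_config()]; `cfg$seed` fixes the cohort RNG.
#' @param engine `"cpp"` (compiled, default) or `"r"` (per-tooth reference
#'   loop; identical logic, used for cross-validation).
#' @return A `caries_cohort` object: per-tooth `retention_years` and
#'   `discounted_cost` vectors plus their means and 2.5/97.5 percentiles
#'   across teeth.
#' @export
run_cohort <- function(strat, p, cfg, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  set.seed(cfg$seed)
  if (engine == "cpp") {
    acc <- radiograph_accuracy(strat, p)
    res <- sim_cohort_cpp(
      n_teeth = cfg$n_teeth, horizon = cfg$horizon_years,
      init_prev = as.numeric(p$risk$prevalence),
      trans = as.numeric(p$transitions[TRANSITION_NAMES]),
      mult = p$risk$progression_multiplier,
      k_crown = p$restoration_failures_before_crown,
      p_repair = p$p_repair,
      rad_acc = c(acc$sensitivity[LESION_DEPTHS], acc$specificity),
      vt_acc = c(p$visual_tactile_accuracy$sensitivity[["D2D3"]],
                 p$visual_tactile_accuracy$specificity),
      fp_adv_share = p$fp_advanced_share,
      vt_every = p$schedule$visual_tactile_every_years,
      rad_every = p$schedule$radiograph_every_years,
      costs = as.numeric(p$costs[COST_NAMES]),
      use_ai = strat$uses_ai_cost,
      ai_teeth_per_app = p$ai_teeth_per_application,
      discount_rate = p$discount_rate
    )
    retention <- res$retention_years
    cost <- res$discounted_cost
  } else {
    sims <- lapply(seq_len(cfg$n_teeth), function(i) simulate_tooth(strat, p, cfg))
    retention <- vapply(sims, `[[`, numeric(1), "retention_years")
    cost <- vapply(sims, `[[`, numeric(1), "discounted_cost")
  }
  structure(
    list(
      strategy = strat$label,
      retention_years = retention,
      discounted_cost_euros = cost,
      mean_retention = mean(retention),
      mean_cost = mean(cost),
      retention_pct = stats::quantile(retention, c(0.025, 0.975), names = FALSE),
      cost_pct = stats::quantile(cost, c(0.025, 0.975), names = FALSE)
    ),
    class = "caries_cohort"
  )
}

#' @export
print.caries_cohort <- function(x, ...) {
  cat(sprintf("<caries_cohort: %s, %d teeth>\n", x$strategy,
              length(x$retention_years)))
  cat(sprintf("  retention %.1f y (2.5-97.5%%: %.1f-%.1f, across teeth)\n",
              x$mean_retention, x$retention_pct[1], x$retention_pct[2]))
  cat(sprintf("  cost      %.0f EUR (2.5-97.5%%: %.0f-%.0f, across teeth)\n",
              x$mean_cost, x$cost_pct[1], x$cost_pct[2]))
  invisible(x)
}

#' Probabilistic sensitivity analysis
#'
#' Outer Monte Carlo loop: for each draw one parameter set is sampled from
#' the fixture's uncertainty distributions and both strategies are evaluated
#' on a cohort of `cfg$n_teeth` teeth. With common random numbers (default)
#' both strategies within a draw share the cohort sub-seed.
#'
#' @param fixture A `caries_fixture` (see [make_fixture()]).
#' @param cfg A [simulation_config()].
#' @param strategies List of [strategy()] objects (default both comparators).
#' @param scenario Named list of scenario overrides passed to
#'   [sample_parameter_set()] (e.g. `list(risk = "low",
#'   training_fraction = 0.25, ai_cost = 8)`).
#' @param engine Cohort engine, see [run_cohort()].
#' @return A `caries_psa` object with `$results` (one row per draw and
#'   strategy: mean cost, mean retention) and `$draws` (the sampled values of
#'   the uncertain parameters per draw, for EVPPI grouping).
#' @export
run_psa <- function(fixture, cfg,
                    strategies = list(strategy("dentist_no_ai"),
                                      strategy("dentist_with_ai")),
                    scenario = list(), engine = "cpp") {
  n <- cfg$n_psa_draws
  labels <- vapply(strategies, `[[`, character(1), "label")
  rows <- vector("list", n * length(strategies))
  draws <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(cfg$seed, 1L, i))
    ps <- sample_parameter_set(fixture, scenario = scenario)
    draws[[i]] <- data.frame(draw = i, attr(ps, "sampled"))
    for (j in seq_along(strategies)) {
      sub <- if (cfg$common_random_numbers) derive_seed(cfg$seed, 2L, i)
             else derive_seed(cfg$seed, 2L, i, j)
      cohort <- run_cohort(strategies[[j]], ps,
                           simulation_config(cfg$n_teeth, cfg$horizon_years,
                                             seed = sub, n_psa_draws = 1L),
                           engine = engine)
      rows[[(i - 1) * length(strategies) + j]] <- data.frame(
        draw = i, strategy = labels[j],
        mean_cost = cohort$mean_cost, mean_retention = cohort$mean_retention
      )
    }
  }
  structure(
    list(results = do.call(rbind, rows), draws = do.call(rbind, draws),
         strategies = labels, config = cfg, scenario = scenario),
    class = "caries_psa"
  )
}

#' Summarize a PSA run as mean and 2.5-97.5 percentile per strategy
#'
#' Percentiles are across PSA draws of the per-draw cohort means (the
#' uncertainty interval of the expected outcome); within-cohort percentiles
#' across teeth are reported by [run_cohort()].
#'
#' @param object A `caries_psa`.
#' @param ... Unused.
#' @return Data frame with one row per strategy: mean cost and retention
#'   with their across-draw 2.5% and 97.5% percentiles.
#' @export
summary.caries_psa <- function(object, ...) {
  res <- object$results
  out <- do.call(rbind, lapply(split(res, res$strategy), function(d) {
    data.frame(
      strategy = d$strategy[1],
      mean_cost = mean(d$mean_cost),
      cost_lo = stats::quantile(d$mean_cost, 0.025, names = FALSE),
      cost_hi = stats::quantile(d$mean_cost, 0.975, names = FALSE),
      mean_retention = mean(d$mean_retention),
      retention_lo = stats::quantile(d$mean_retention, 0.025, names = FALSE),
      retention_hi = stats::quantile(d$mean_retention, 0.975, names = FALSE)
    )
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.caries_psa <- function(x, ...) {
  cat(sprintf("<caries_psa: %d draws x %d teeth, strategies: %s>\n",
              x$config$n_psa_draws, x$config$n_teeth,
              paste(x$strategies, collapse = ", ")))
  s <- summary(x)
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-16s %6.0f EUR (%.0f-%.0f)  %5.1f y (%.1f-%.1f)\n",
                s$strategy[i], s$mean_cost[i], s$cost_lo[i], s$cost_hi[i],
                s$mean_retention[i], s$retention_lo[i], s$retention_hi[i]))
  invisible(x)
}

## Per-draw incremental (cost, effect) points: intervention minus comparator.
psa_increments <- function(psa, intervention = "dentist_with_ai",
                           comparator = "dentist_no_ai") {
  res <- psa$results
  a <- res[res$strategy == intervention, ]
  b <- res[res$strategy == comparator, ]
  a <- a[order(a$draw), ]; b <- b[order(b$draw), ]
  data.frame(draw = a$draw,
             delta_cost = a$mean_cost - b$mean_cost,
             delta_effect = a$mean_retention - b$mean_retention)
}
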