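## Shared fixtures and independent brute-force oracles.

TN <- cariesim:::TRANSITION_NAMES

test_costs <- function() cost_table(
  radiograph_exam = 2, visual_tactile_exam = 1, ai_application = 8,
  infiltration = 70, restoration = 85, restoration_repair = 45,
  restoration_replacement = 85, crown = 340, crown_replacement = 340,
  root_canal = 280, retreat_nonsurgical = 330, retreat_surgical = 260,
  extraction = 80, implant_crown = 1000
)

## all-zero transition table with named overrides
zero_transitions <- function(...) {
  x <- stats::setNames(rep(0, length(TN)), TN)
  ov <- c(...)
  x[names(ov)] <- ov
  do.call(transition_table, as.list(x))
}

## deterministic-friendly parameter set for unit tests
test_params <- function(transitions = zero_transitions(),
                        dentist = accuracy_profile(1, 1, 1, 1),
                        ai = dentist,
                        vt = accuracy_profile(0, 0, 0, 1),
                        prevalence = c(sound = 1, E2 = 0, D1 = 0, D2D3 = 0),
                        mult = 1, risk_label = "low",
                        discount_rate = 0.03, k = 3, p_repair = 0.5,
                        fp_share = 0.2, teeth_per_app = 4,
                        sched = schedule()) {
  parameter_set(
    transitions = transitions, dentist_accuracy = dentist, ai_accuracy = ai,
    visual_tactile_accuracy = vt, costs = test_costs(),
    risk = risk_profile(risk_label, prevalence, mult),
    discount_rate = discount_rate, ai_training_fraction = 1.00,
    restoration_failures_before_crown = k, p_repair = p_repair,
    fp_advanced_share = fp_share, ai_teeth_per_application = teeth_per_app,
    schedule = sched
  )
}

## build a caries_psa from plain cost/effect matrices (draws x strategies)
make_psa_table <- function(cost, effect, draws = NULL,
                           strategies = paste0("s", seq_len(ncol(cost)))) {
  n <- nrow(cost)
  res <- do.call(rbind, lapply(seq_along(strategies), function(j) {
    data.frame(draw = seq_len(n), strategy = strategies[j],
               mean_cost = cost[, j], mean_retention = effect[, j])
  }))
  if (is.null(draws)) draws <- data.frame(draw = seq_len(n))
  structure(list(results = res, draws = draws, strategies = strategies,
                 config = simulation_config(1, 1, 1, n)),
            class = "caries_psa")
}

## brute-force VOI / CEAC oracles: explicit loops, no shared code with the
## implementation (which works on wide matrices via colMeans/apply).
bf_evpi <- function(cost, effect, lambda) {
  n <- nrow(cost); k <- ncol(cost)
  per_draw_best <- numeric(n)
  for (i in seq_len(n)) {
    best <- -Inf
    for (j in seq_len(k)) best <- max(best, lambda * effect[i, j] - cost[i, j])
    per_draw_best[i] <- best
  }
  best_mean <- -Inf
  for (j in seq_len(k)) {
    m <- 0
    for (i in seq_len(n)) m <- m + (lambda * effect[i, j] - cost[i, j]) / n
    best_mean <- max(best_mean, m)
  }
  mean(per_draw_best) - best_mean
}

bf_evppi <- function(cost, effect, group, lambda) {
  n <- nrow(cost); k <- ncol(cost)
  lv <- unique(group)
  acc <- 0
  for (g in lv) {
    idx <- which(group == g)
    best <- -Inf
    for (j in seq_len(k))
      best <- max(best, mean(lambda * effect[idx, j] - cost[idx, j]))
    acc <- acc + length(idx) / n * best
  }
  best_mean <- -Inf
  for (j in seq_len(k))
    best_mean <- max(best_mean, mean(lambda * effect[, j] - cost[, j]))
  acc - best_mean
}

bf_ceac <- function(cost, effect, lambda) {
  n <- nrow(cost); k <- ncol(cost)
  prob <- numeric(k)
  for (i in seq_len(n)) {
    nmbs <- lambda * effect[i, ] - cost[i, ]
    winners <- which(nmbs == max(nmbs))
    prob[winners] <- prob[winners] + 1 / (n * length(winners))
  }
  prob
}

## Exact expected retention for the collapsed D1 -> D2D3 -> cascade chain:
## D1 progresses with hazard h1 (end of cycle), the advanced lesion is then
## detected with per-cycle probability s, and forced endodontic/retreatment
## failures extract the tooth 4 cycles after detection. Retention is
## min(T1 + T2 + 5, H) with T1 ~ Geom0(h1), T2 ~ Geom0(s); the expectation
## is computed by exact tail summation.
chain_expected_retention <- function(h1, s, H) {
  ## pmf of T1 + T2 up to H (tail mass lumped; capped anyway)
  pmf1 <- h1 * (1 - h1)^(0:H)
  pmf2 <- s * (1 - s)^(0:H)
  pmf <- rep(0, 2 * H + 3)
  for (a in 0:H) for (b in 0:H) pmf[a + b + 1] <- pmf[a + b + 1] + pmf1[a + 1] * pmf2[b + 1]
  x <- 0
  for (k in 0:(H - 1)) {            # E[min(X,H)] = sum_k P(X > k), X = T1+T2+5
    p_gt <- if (k < 5) 1 else {
      idx <- 0:(k - 5)              # P(T1+T2 <= k-5)
      1 - sum(pmf[idx + 1])
    }
    x <- x + p_gt
  }
  x
}

## discounted fee stream of an exam charged every `every` years
fee_stream <- function(fee, every, horizon, rate = 0.03) {
  yrs <- seq(0, horizon - 1, by = every)
  sum(fee / (1 + rate)^yrs)
}

## convert every distribution in a fixture to its point mode
point_fixture <- function(fx) {
  fix <- function(x) {
    if (inherits(x, "caries_dist")) dist_point(x$mode)
    else if (is.list(x) && !inherits(x, c("caries_risk", "caries_schedule",
                                          "caries_learning_curve")))
      structure(lapply(x, fix), class = class(x))
    else x
  }
  fix(fx)
}
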