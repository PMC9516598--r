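no_ai <- strategy("dentist_no_ai")
with_ai <- strategy("dentist_with_ai")

test_that("a disease-free cohort retains all teeth and pays only exam fees", {
  p <- test_params()
  cfg <- simulation_config(50, horizon_years = 66, seed = 1)
  for (engine in c("cpp", "r")) {
    res <- run_cohort(no_ai, p, cfg, engine = engine)
    expect_equal(res$retention_years, rep(66, 50))
    fees <- fee_stream(1, 1, 66) + fee_stream(2, 2, 66)
    expect_equal(res$discounted_cost_euros, rep(fees, 50))
  }
})

test_that("a forced cascade reproduces the hand-computed trace", {
  p <- test_params(
    transitions = zero_transitions(p_restoration_failure = 1, p_crown_failure = 1,
                                   p_rootfill_failure = 1, p_retreat_failure = 1,
                                   p_surg_retreat_failure = 1),
    prevalence = c(sound = 0, E2 = 0, D1 = 0, D2D3 = 1),
    k = 3, p_repair = 1
  )
  cfg <- simulation_config(1, horizon_years = 66, seed = 4)
  set.seed(4)
  sim <- simulate_tooth(no_ai, p, cfg)

  # year 0: restored and first failure (repair); years 1-2 remaining failures
  # then crown; year 3 crown replaced; year 4 second crown failure -> root
  # canal; years 5-7 retreatments fail; extraction + implant in year 7
  expect_identical(sim$retention_years, 8)
  treatments <- sim$events$label[!grepl("exam$", sim$events$label)]
  expect_identical(treatments, c(
    "restoration", "restoration_repair", "restoration_repair", "crown",
    "crown_replacement", "root_canal", "retreat_nonsurgical",
    "retreat_surgical", "extraction", "implant_crown"))

  fees <- c(3, 1, 3, 1, 3, 1, 3, 1)                       # vt yearly + rad even years
  care <- c(85 + 45, 45, 340, 340, 280, 330, 260, 80 + 1000)
  hand <- sum((fees + care) / 1.03^(0:7))
  expect_equal(sim$discounted_cost, hand)

  res <- run_cohort(no_ai, p, cfg, engine = "cpp")
  expect_identical(res$retention_years, 8)
  expect_equal(res$discounted_cost_euros, hand)
})

test_that("cohorts and PSA runs are reproducible under a fixed seed", {
  fx <- make_fixture(1, "calibrated")
  cfg <- simulation_config(80, seed = 13, n_psa_draws = 6)
  a <- run_psa(fx, cfg)
  b <- run_psa(fx, cfg)
  expect_identical(a$results, b$results)
  expect_identical(a$draws, b$draws)
})

test_that("compiled and reference engines agree in distribution", {
  fx <- make_fixture(1, "calibrated")
  set.seed(2)
  p <- sample_parameter_set(fx, scenario = list(risk = "high"))
  a <- run_cohort(with_ai, p, simulation_config(1200, seed = 5), engine = "cpp")
  b <- run_cohort(with_ai, p, simulation_config(250, seed = 6), engine = "r")
  se_ret <- sqrt(sd(a$retention_years)^2 / 1200 + sd(b$retention_years)^2 / 250)
  se_cost <- sqrt(sd(a$discounted_cost_euros)^2 / 1200 +
                    sd(b$discounted_cost_euros)^2 / 250)
  expect_lt(abs(a$mean_retention - b$mean_retention), 4 * se_ret)
  expect_lt(abs(a$mean_cost - b$mean_cost), 4 * se_cost)
})

test_that("mean retention matches the collapsed-chain closed form", {
  h1 <- 0.15; s <- 0.3
  p <- test_params(
    transitions = zero_transitions(p_D1_to_D2D3 = h1, p_endo_complication = 1,
                                   p_rootfill_failure = 1, p_retreat_failure = 1,
                                   p_surg_retreat_failure = 1),
    dentist = accuracy_profile(0, 0, s, 1),
    prevalence = c(sound = 0, E2 = 0, D1 = 1, D2D3 = 0),
    sched = schedule(1, 1)
  )
  cfg <- simulation_config(1000, horizon_years = 66, seed = 23)
  res <- run_cohort(no_ai, p, cfg, engine = "cpp")
  expected <- chain_expected_retention(h1, s, 66)
  se <- sd(res$retention_years) / sqrt(1000)
  expect_lt(abs(res$mean_retention - expected), 3 * se)
})

test_that("retention is bounded by the horizon and costs are nonnegative", {
  fx <- make_fixture(1, "calibrated")
  set.seed(19)
  for (i in 1:5) {
    p <- sample_parameter_set(fx)
    res <- run_cohort(no_ai, p, simulation_config(500, seed = 100 + i))
    expect_true(all(res$retention_years >= 0 & res$retention_years <= 66))
    expect_true(all(res$discounted_cost_euros >= 0))
  }
})

test_that("discounting only reduces lifetime costs", {
  fx <- make_fixture(1, "calibrated")
  set.seed(4)
  p <- sample_parameter_set(fx, scenario = list(risk = "high"))
  p0 <- p; p0$discount_rate <- 0
  cfg <- simulation_config(400, seed = 77)
  disc <- run_cohort(no_ai, p, cfg)$discounted_cost_euros
  undisc <- run_cohort(no_ai, p0, cfg)$discounted_cost_euros
  expect_true(all(disc <= undisc + 1e-9))
})

test_that("doubling the cohort shrinks the standard error by about sqrt(2)", {
  fx <- make_fixture(1, "calibrated")
  set.seed(8)
  p <- sample_parameter_set(fx)
  means <- function(n, seeds) vapply(seeds, function(s)
    run_cohort(no_ai, p, simulation_config(n, seed = s))$mean_retention,
    numeric(1))
  m1 <- means(200, 1:30)
  m2 <- means(400, 31:60)
  ratio <- sd(m1) / sd(m2)
  expect_gt(ratio, 1.05)
  expect_lt(ratio, 1.95)
})

test_that("PSA summary intervals are across draws of per-draw means", {
  fx <- make_fixture(1, "calibrated")
  psa <- run_psa(fx, simulation_config(150, seed = 3, n_psa_draws = 30))
  s <- summary(psa)
  expect_identical(nrow(s), 2L)
  for (i in 1:2) {
    d <- psa$results[psa$results$strategy == s$strategy[i], ]
    expect_equal(s$mean_cost[i], mean(d$mean_cost))
    expect_true(s$cost_lo[i] <= s$mean_cost[i] && s$mean_cost[i] <= s$cost_hi[i])
  }
})
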