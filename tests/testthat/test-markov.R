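test_that("natural progression is inert when all probabilities are zero", {
  tr <- zero_transitions()
  for (h in c("SOUND", "E2", "D1", "D2D3", "ARRESTED")) {
    s <- tooth_state(h)
    expect_identical(natural_step(s, tr)$health, h)
  }
})

test_that("forced transitions follow the severity ladder one step at a time", {
  tr <- zero_transitions(p_sound_to_E2 = 1, p_E2_to_D1 = 1,
                         p_D1_to_D2D3 = 1, p_arrest_failure = 1)
  expect_identical(natural_step(tooth_state("SOUND"), tr)$health, "E2")
  expect_identical(natural_step(tooth_state("E2"), tr)$health, "D1")
  expect_identical(natural_step(tooth_state("D1"), tr)$health, "D2D3")
  expect_identical(natural_step(tooth_state("ARRESTED"), tr)$health, "D1")
  expect_identical(natural_step(tooth_state("D2D3"), tr)$health, "D2D3")
  expect_error(natural_step(tooth_state("EXTRACTED_IMPLANT"), tr), "absorbing")
})

test_that("incidence matches its binomial rate at scale", {
  tr <- zero_transitions(p_sound_to_E2 = 0.1)
  set.seed(21)
  moved <- sum(replicate(1e5, natural_step(tooth_state("SOUND"), tr)$health == "E2"))
  expect_lt(abs(moved / 1e5 - 0.1), 0.003)
})

test_that("progression multiplier scales incidence and caps at one", {
  tr <- zero_transitions(p_sound_to_E2 = 0.6)
  set.seed(2)
  expect_identical(natural_step(tooth_state("SOUND"), tr,
                                progression_multiplier = 2)$health, "E2")
})

test_that("restoration failures accumulate and the k-th places a crown", {
  p <- test_params(transitions = zero_transitions(p_restoration_failure = 1), k = 2)
  s <- tooth_state("RESTORED", restoration_failures = 1)
  out <- treatment_step(s, p, year = 4)
  expect_identical(out$state$health, "CROWNED")
  expect_identical(out$state$restoration_failures, 2L)
  expect_identical(out$events$label, "crown")
  expect_identical(out$events$year, 4L)
})

test_that("pre-crown failures resolve as repair or replacement", {
  p <- test_params(transitions = zero_transitions(p_restoration_failure = 1),
                   k = 3, p_repair = 1)
  out <- treatment_step(tooth_state("RESTORED"), p)
  expect_identical(out$state$health, "RESTORED")
  expect_identical(out$events$label, "restoration_repair")
  p$p_repair <- 0
  out <- treatment_step(tooth_state("RESTORED"), p)
  expect_identical(out$events$label, "restoration_replacement")
})

test_that("a crown is replaced once, then the cascade moves to root canal", {
  p <- test_params(transitions = zero_transitions(p_crown_failure = 1))
  out1 <- treatment_step(tooth_state("CROWNED"), p)
  expect_identical(out1$state$health, "CROWNED")
  expect_true(out1$state$crown_replaced)
  expect_identical(out1$events$label, "crown_replacement")
  out2 <- treatment_step(out1$state, p)
  expect_identical(out2$state$health, "ROOT_FILLED")
  expect_identical(out2$events$label, "root_canal")
})

test_that("endodontic complications preempt mechanical failure", {
  p <- test_params(transitions = zero_transitions(p_endo_complication = 1,
                                                  p_restoration_failure = 1))
  for (h in c("RESTORED", "CROWNED")) {
    out <- treatment_step(tooth_state(h), p)
    expect_identical(out$state$health, "ROOT_FILLED")
    expect_identical(out$events$label, "root_canal")
  }
})

test_that("exhausting the cascade extracts the tooth with implant costs", {
  p <- test_params(transitions = zero_transitions(p_surg_retreat_failure = 1))
  out <- treatment_step(tooth_state("RETREATED_SURG"), p, year = 30)
  expect_identical(out$state$health, "EXTRACTED_IMPLANT")
  expect_false(out$state$alive_tooth)
  expect_setequal(out$events$label, c("extraction", "implant_crown"))
  expect_error(treatment_step(out$state, p), "treated state")
})

test_that("quiet treated states emit no events", {
  p <- test_params()
  for (h in c("RESTORED", "CROWNED", "ROOT_FILLED",
              "RETREATED_NONSURG", "RETREATED_SURG")) {
    out <- treatment_step(tooth_state(h), p)
    expect_identical(out$state$health, h)
    expect_identical(nrow(out$events), 0L)
  }
})

test_that("initial states are drawn from the prevalence profile", {
  expect_identical(
    initial_state(risk_profile("low", c(sound = 1, E2 = 0, D1 = 0, D2D3 = 0)))$health,
    "SOUND")
  expect_identical(
    initial_state(risk_profile("high", c(sound = 0, E2 = 0, D1 = 0, D2D3 = 1)))$health,
    "D2D3")
  rp <- risk_profile("low", c(sound = 0.7, E2 = 0.3, D1 = 0, D2D3 = 0))
  set.seed(8)
  draws <- replicate(1e4, initial_state(rp)$health)
  expect_lt(abs(mean(draws == "SOUND") - 0.7), 0.015)
})

test_that("the state machine only moves along allowed edges", {
  allowed <- list(
    SOUND = c("SOUND", "E2"), E2 = c("E2", "D1"), D1 = c("D1", "D2D3"),
    D2D3 = "D2D3", ARRESTED = c("ARRESTED", "D1"),
    RESTORED = c("RESTORED", "CROWNED", "ROOT_FILLED"),
    CROWNED = c("CROWNED", "ROOT_FILLED"),
    ROOT_FILLED = c("ROOT_FILLED", "RETREATED_NONSURG"),
    RETREATED_NONSURG = c("RETREATED_NONSURG", "RETREATED_SURG"),
    RETREATED_SURG = c("RETREATED_SURG", "EXTRACTED_IMPLANT")
  )
  set.seed(33)
  for (rep in 1:150) {
    tr <- do.call(zero_transitions,
                  as.list(stats::setNames(runif(length(TN)), TN)))
    p <- test_params(transitions = tr)
    h <- sample(names(allowed), 1)
    s <- tooth_state(h, restoration_failures = sample(0:3, 1),
                     crown_replaced = sample(c(TRUE, FALSE), 1))
    s2 <- if (h %in% cariesim:::TREATED_STATES) treatment_step(s, p)$state
          else natural_step(s, tr)
    expect_true(s2$health %in% allowed[[h]])
  }
})
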