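no_ai <- strategy("dentist_no_ai")
with_ai <- strategy("dentist_with_ai")

test_that("perfect accuracy yields clean detection outcomes", {
  p <- test_params()
  expect_identical(examine(tooth_state("SOUND"), no_ai, p, cycle = 0), "TN")
  expect_identical(examine(tooth_state("D2D3"), no_ai, p, cycle = 0), "TP_advanced")
  expect_identical(examine(tooth_state("E2"), no_ai, p, cycle = 0), "TP_initial")
  expect_identical(examine(tooth_state("RESTORED"), no_ai, p, cycle = 0),
                   "not_examined")
})

test_that("initial lesions are only detectable on radiograph cycles", {
  # radiographs every 2 years: cycle 1 has only the visual-tactile exam,
  # which is blind to E2/D1
  p <- test_params()
  expect_identical(examine(tooth_state("E2"), no_ai, p, cycle = 1), "FN")
  expect_identical(examine(tooth_state("D1"), no_ai, p, cycle = 1), "FN")
})

test_that("visual-tactile detection of advanced lesions works off-radiograph", {
  p <- test_params(dentist = accuracy_profile(0, 0, 0, 1),
                   vt = accuracy_profile(0, 0, 1, 1))
  expect_identical(examine(tooth_state("D2D3"), no_ai, p, cycle = 1), "TP_advanced")
})

test_that("depth-specific sensitivity matches its binomial rate", {
  p <- test_params(dentist = accuracy_profile(0.6, 0, 0, 1))
  set.seed(14)
  hits <- sum(replicate(1e5, examine(tooth_state("E2"), no_ai, p, 0) == "TP_initial"))
  expect_lt(abs(hits / 1e5 - 0.6), 0.005)
})

test_that("false positives arise from sound and arrested surfaces only", {
  p <- test_params(dentist = accuracy_profile(1, 1, 1, 0), fp_share = 1)
  expect_identical(examine(tooth_state("SOUND"), no_ai, p, 0), "FP_advanced")
  expect_identical(examine(tooth_state("ARRESTED"), no_ai, p, 0), "FP_advanced")
  p$fp_advanced_share <- 0
  expect_identical(examine(tooth_state("SOUND"), no_ai, p, 0), "FP_initial")
})

test_that("raising sensitivity raises the detection rate", {
  set.seed(6)
  rate <- sapply(c(0.3, 0.6), function(s) {
    p <- test_params(dentist = accuracy_profile(s, 0, 0, 1))
    mean(replicate(5000, examine(tooth_state("E2"), no_ai, p, 0) == "TP_initial"))
  })
  expect_lt(rate[1], rate[2])
})

test_that("treatment decisions follow the detection outcome", {
  costs <- test_costs()
  out <- decide_and_treat(tooth_state("E2"), "TP_initial", costs, year = 2)
  expect_identical(out$state$health, "ARRESTED")
  expect_identical(out$events$label, "infiltration")

  out <- decide_and_treat(tooth_state("D2D3"), "TP_advanced", costs)
  expect_identical(out$state$health, "RESTORED")
  expect_identical(out$events$label, "restoration")

  out <- decide_and_treat(tooth_state("SOUND"), "TN", costs)
  expect_identical(out$state$health, "SOUND")
  expect_identical(nrow(out$events), 0L)

  # false positive staged as advanced drags a sound tooth into the cascade
  out <- decide_and_treat(tooth_state("SOUND"), "FP_advanced", costs)
  expect_identical(out$state$health, "RESTORED")
  expect_identical(out$events$label, "restoration")

  # false positive staged as initial: fee without a state change
  out <- decide_and_treat(tooth_state("SOUND"), "FP_initial", costs)
  expect_identical(out$state$health, "SOUND")
  expect_identical(out$events$label, "infiltration")
})

test_that("inconsistent outcome/state pairs violate the contract", {
  costs <- test_costs()
  expect_error(decide_and_treat(tooth_state("SOUND"), "TP_initial", costs),
               "contract violation")
  expect_error(decide_and_treat(tooth_state("E2"), "FP_initial", costs),
               "contract violation")
  expect_error(decide_and_treat(tooth_state("E2"), "TP_advanced", costs),
               "contract violation")
})

test_that("exam fees follow the schedule and the AI fee is per application", {
  p <- test_params()
  ev <- exam_costs(no_ai, p, cycle = 0)
  expect_setequal(ev$label, c("visual_tactile_exam", "radiograph_exam"))
  ev <- exam_costs(with_ai, p, cycle = 1)
  expect_identical(ev$label, "visual_tactile_exam")
  ev <- exam_costs(with_ai, p, cycle = 2)
  expect_setequal(ev$label, c("visual_tactile_exam", "radiograph_exam",
                              "ai_application"))
  # 8 EUR per application shared across 4 teeth
  expect_identical(ev$euros[ev$label == "ai_application"], 8 / 4)
})

test_that("identical accuracy and no AI fee make the strategies equivalent", {
  fx <- make_fixture(1, "calibrated")
  set.seed(2)
  p <- sample_parameter_set(fx)
  p$ai_accuracy <- p$dentist_accuracy
  p$costs[["ai_application"]] <- 0
  cfg <- simulation_config(400, seed = 31)
  a <- run_cohort(no_ai, p, cfg)
  b <- run_cohort(with_ai, p, cfg)
  expect_identical(a$retention_years, b$retention_years)
  expect_identical(a$discounted_cost_euros, b$discounted_cost_euros)
})

test_that("in an always-sound cohort the arms differ exactly by the AI fee stream", {
  p <- test_params()  # no disease, perfect specificity, no progression
  cfg <- simulation_config(100, horizon_years = 66, seed = 17)
  a <- run_cohort(no_ai, p, cfg)
  b <- run_cohort(with_ai, p, cfg)
  expect_equal(a$retention_years, rep(66, 100))
  stream <- fee_stream(8 / 4, every = 2, horizon = 66)
  expect_equal(b$discounted_cost_euros - a$discounted_cost_euros,
               rep(stream, 100))
})
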