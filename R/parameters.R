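## Parameter containers: one evaluation of the decision model consumes a
## fully point-valued parameter_set; uncertainty lives in the fixture
## (see synthetic_params.R) and is resolved by sample_parameter_set().

TRANSITION_NAMES <- c(
  "p_sound_to_E2", "p_E2_to_D1", "p_D1_to_D2D3", "p_arrest_failure",
  "p_restoration_failure", "p_crown_failure", "p_endo_complication",
  "p_rootfill_failure", "p_retreat_failure", "p_surg_retreat_failure"
)

COST_NAMES <- c(
  "radiograph_exam", "visual_tactile_exam", "ai_application", "infiltration",
  "restoration", "restoration_repair", "restoration_replacement", "crown",
  "crown_replacement", "root_canal", "retreat_nonsurgical", "retreat_surgical",
  "extraction", "implant_crown"
)

LESION_DEPTHS <- c("E2", "D1", "D2D3")
PREVALENCE_STATES <- c("sound", "E2", "D1", "D2D3")
TRAINING_FRACTIONS <- c(0.10, 0.25, 0.50, 1.00)

#' Lesion-depth-specific diagnostic accuracy
#'
#' Sensitivity is allowed to differ by lesion depth (E2: inner enamel half,
#' D1: outer dentin third, D2-D3: middle/inner dentin thirds); specificity is
#' a single probability for sound (and arrested) surfaces.
#'
#' @param sens_E2,sens_D1,sens_D2D3 Sensitivities per depth, in `[0, 1]`.
#' @param specificity Specificity in `[0, 1]`.
#' @return A `caries_accuracy` object.
#' @export
accuracy_profile <- function(sens_E2, sens_D1, sens_D2D3, specificity) {
  x <- structure(
    list(
      sensitivity = c(E2 = sens_E2, D1 = sens_D1, D2D3 = sens_D2D3),
      specificity = specificity
    ),
    class = "caries_accuracy"
  )
  bad <- c(x$sensitivity, x$specificity) < 0 | c(x$sensitivity, x$specificity) > 1
  if (any(bad)) stop("accuracy values must lie in [0, 1]")
  x
}

#' Cohort caries risk profile
#'
#' @param label `"low"` or `"high"`.
#' @param prevalence Named numeric over `sound`, `E2`, `D1`, `D2D3`; must sum
#'   to 1 (tolerance 1e-9). Initial state distribution of proximal surfaces.
#' @param progression_multiplier Positive multiplier applied to the natural
#'   incidence/progression probabilities (`p_sound_to_E2`, `p_E2_to_D1`,
#'   `p_D1_to_D2D3`), capped at 1 after multiplication.
#' @return A `caries_risk` object.
#' @export
risk_profile <- function(label, prevalence, progression_multiplier = 1) {
  label <- match.arg(label, c("low", "high"))
  prevalence <- prevalence[PREVALENCE_STATES]
  if (anyNA(prevalence)) stop("prevalence must name all of: ",
                              paste(PREVALENCE_STATES, collapse = ", "))
  if (abs(sum(prevalence) - 1) > 1e-9) stop("prevalence must sum to 1")
  if (any(prevalence < 0)) stop("prevalence values must be nonnegative")
  if (progression_multiplier <= 0) stop("progression_multiplier must be > 0")
  structure(
    list(label = label, prevalence = prevalence,
         progression_multiplier = progression_multiplier),
    class = "caries_risk"
  )
}

#' Per-event treatment and diagnostic costs (euros)
#'
#' @param ... Named costs; every name in the canonical set must be present
#'   (see `cariesim:::COST_NAMES`) and all costs must be nonnegative.
#' @return Named numeric vector of class `caries_costs`.
#' @export
cost_table <- function(...) {
  x <- c(...)
  missing <- setdiff(COST_NAMES, names(x))
  if (length(missing)) stop("missing costs: ", paste(missing, collapse = ", "))
  x <- x[COST_NAMES]
  if (any(x < 0)) stop("costs must be nonnegative")
  structure(x, class = "caries_costs")
}

#' Annual transition probabilities of the tooth state machine
#'
#' @param ... Named probabilities covering the canonical transition set
#'   (`cariesim:::TRANSITION_NAMES`), each in `[0, 1]`.
#' @return Named numeric vector of class `caries_transitions`.
#' @export
transition_table <- function(...) {
  x <- c(...)
  missing <- setdiff(TRANSITION_NAMES, names(x))
  if (length(missing)) stop("missing transitions: ", paste(missing, collapse = ", "))
  x <- x[TRANSITION_NAMES]
  if (any(x < 0 | x > 1)) stop("transition probabilities must lie in [0, 1]")
  structure(x, class = "caries_transitions")
}

#' Assemble a point-valued parameter set
#'
#' One `caries_parameter_set` holds everything a single model evaluation
#' needs: the transition table, accuracy of dentist / AI / visual-tactile
#' examination, the cost table, the cohort risk profile, discounting and the
#' screening schedule. Probabilistic sensitivity analysis repeatedly
#' constructs such sets via [sample_parameter_set()].
#'
#' @param transitions A [transition_table()].
#' @param dentist_accuracy,ai_accuracy Radiographic [accuracy_profile()]s.
#' @param visual_tactile_accuracy [accuracy_profile()] of the visual-tactile
#'   exam; its E2 and D1 sensitivities must be 0 (initial proximal lesions are
#'   detectable only radiographically).
#' @param costs A [cost_table()].
#' @param risk A [risk_profile()].
#' @param discount_rate Annual discount rate (`>= 0`), default 0.03.
#' @param ai_training_fraction Which AI training-data fraction this set's
#'   `ai_accuracy` corresponds to; one of 0.10, 0.25, 0.50, 1.00.
#' @param restoration_failures_before_crown Restoration failures tolerated
#'   before a crown is placed (default 3).
#' @param p_repair Probability that a non-terminal restoration failure is
#'   resolved by repair rather than replacement (default 0.5).
#' @param fp_advanced_share Probability that a false-positive radiographic
#'   call is staged as advanced and treated restoratively (default 0.2).
#' @param ai_teeth_per_application Number of teeth sharing one AI
#'   per-application fee (the fee is charged per bitewing application, not per
#'   tooth; default 6).
#' @param schedule A [schedule()].
#' @return A `caries_parameter_set` object.
#' @export
parameter_set <- function(transitions, dentist_accuracy, ai_accuracy,
                          visual_tactile_accuracy, costs, risk,
                          discount_rate = 0.03, ai_training_fraction = 1.00,
                          restoration_failures_before_crown = 3L,
                          p_repair = 0.5, fp_advanced_share = 0.2,
                          ai_teeth_per_application = 6,
                          schedule = cariesim::schedule()) {
  p <- structure(
    list(
      transitions = transitions,
      dentist_accuracy = dentist_accuracy,
      ai_accuracy = ai_accuracy,
      visual_tactile_accuracy = visual_tactile_accuracy,
      costs = costs,
      risk = risk,
      discount_rate = discount_rate,
      ai_training_fraction = ai_training_fraction,
      restoration_failures_before_crown = as.integer(restoration_failures_before_crown),
      p_repair = p_repair,
      fp_advanced_share = fp_advanced_share,
      ai_teeth_per_application = ai_teeth_per_application,
      schedule = schedule
    ),
    class = "caries_parameter_set"
  )
  v <- validate_parameter_set(p)
  if (length(v)) stop("invalid parameter set:\n  ", paste(v, collapse = "\n  "))
  p
}

#' Validate a parameter set
#'
#' Reporting counterpart of the constructor checks: returns a character
#' vector of violations (empty when the set is valid) instead of raising.
#'
#' @param p A `caries_parameter_set` (possibly hand-built or deserialized).
#' @return Character vector of human-readable violations; `character(0)` iff
#'   all invariants hold.
#' @export
validate_parameter_set <- function(p) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  tr <- p$transitions
  chk(all(TRANSITION_NAMES %in% names(tr)), "transitions: missing entries")
  if (all(TRANSITION_NAMES %in% names(tr)))
    for (nm in TRANSITION_NAMES)
      chk(tr[[nm]] >= 0 && tr[[nm]] <= 1,
          sprintf("transitions$%s: %g outside [0, 1]", nm, tr[[nm]]))
  for (acc_nm in c("dentist_accuracy", "ai_accuracy", "visual_tactile_accuracy")) {
    a <- p[[acc_nm]]
    vals <- c(a$sensitivity, specificity = a$specificity)
    for (i in seq_along(vals))
      chk(vals[[i]] >= 0 && vals[[i]] <= 1,
          sprintf("%s$%s: %g outside [0, 1]", acc_nm, names(vals)[i], vals[[i]]))
  }
  chk(p$visual_tactile_accuracy$sensitivity[["E2"]] == 0,
      "visual_tactile_accuracy: E2 sensitivity must be 0 (radiograph-only detection)")
  chk(p$visual_tactile_accuracy$sensitivity[["D1"]] == 0,
      "visual_tactile_accuracy: D1 sensitivity must be 0 (radiograph-only detection)")
  costs <- p$costs
  chk(all(COST_NAMES %in% names(costs)), "costs: missing entries")
  if (all(COST_NAMES %in% names(costs)))
    for (nm in COST_NAMES)
      chk(costs[[nm]] >= 0, sprintf("costs$%s: negative", nm))
  prev <- p$risk$prevalence
  chk(abs(sum(prev) - 1) <= 1e-9,
      sprintf("risk$prevalence: sums to %.6f, not 1", sum(prev)))
  chk(all(prev >= 0), "risk$prevalence: negative mass")
  chk(p$risk$progression_multiplier > 0, "risk$progression_multiplier: must be > 0")
  chk(p$discount_rate >= 0, "discount_rate: must be >= 0")
  chk(p$ai_training_fraction %in% TRAINING_FRACTIONS,
      "ai_training_fraction: must be one of 0.10, 0.25, 0.50, 1.00")
  chk(p$restoration_failures_before_crown >= 1,
      "restoration_failures_before_crown: must be >= 1")
  chk(p$p_repair >= 0 && p$p_repair <= 1, "p_repair: outside [0, 1]")
  chk(p$fp_advanced_share >= 0 && p$fp_advanced_share <= 1,
      "fp_advanced_share: outside [0, 1]")
  chk(p$ai_teeth_per_application > 0, "ai_teeth_per_application: must be > 0")
  chk(p$schedule$visual_tactile_every_years >= 1 &&
        p$schedule$radiograph_every_years >= 1,
      "schedule: exam intervals must be >= 1 year")
  v
}

#' @export
print.caries_parameter_set <- function(x, ...) {
  cat("<caries_parameter_set>\n")
  cat("  risk profile:      ", x$risk$label,
      sprintf(" (multiplier %.2f)\n", x$risk$progression_multiplier))
  cat("  training fraction: ", format(x$ai_training_fraction), "\n")
  cat("  discount rate:     ", format(x$discount_rate), "per annum\n")
  cat("  AI fee:            ", sprintf("%.2f EUR/application (%g teeth/application)\n",
      x$costs[["ai_application"]], x$ai_teeth_per_application))
  cat("  transitions:       ", paste(sprintf("%s=%.3f",
      sub("^p_", "", names(x$transitions)), x$transitions), collapse = ", "), "\n")
  invisible(x)
}
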