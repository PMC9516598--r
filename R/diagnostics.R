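## Screening schedule, comparator strategies, examination outcomes and the
## resulting treatment decisions.

#' Screening schedule
#'
#' Visual-tactile examination happens every `visual_tactile_every_years`
#' (default every annual cycle, the model's finest time step) and bitewing
#' radiographs every `radiograph_every_years` (default 2). Cycle 0 is always
#' an exam cycle for both modalities.
#'
#' @param visual_tactile_every_years,radiograph_every_years Positive integers.
#' @return A `caries_schedule` object.
#' @export
schedule <- function(visual_tactile_every_years = 1L, radiograph_every_years = 2L) {
  if (visual_tactile_every_years < 1 || radiograph_every_years < 1)
    stop("exam intervals must be >= 1 year")
  structure(
    list(visual_tactile_every_years = as.integer(visual_tactile_every_years),
         radiograph_every_years = as.integer(radiograph_every_years)),
    class = "caries_schedule"
  )
}

is_radiograph_cycle <- function(sched, cycle) cycle %% sched$radiograph_every_years == 0
is_vt_cycle <- function(sched, cycle) cycle %% sched$visual_tactile_every_years == 0

#' Comparator screening strategies
#'
#' Both comparators perform visual-tactile examination plus bitewing
#' radiographs; they differ in who reads the radiograph (dentist alone vs.
#' dentist supported by a CNN-based AI) and in whether an AI per-application
#' fee accrues on radiograph cycles.
#'
#' @param label `"dentist_no_ai"` or `"dentist_with_ai"`.
#' @return A `caries_strategy`; `uses_ai_cost` (and the AI accuracy profile)
#'   apply only to `"dentist_with_ai"`.
#' @export
strategy <- function(label = c("dentist_no_ai", "dentist_with_ai")) {
  label <- match.arg(label)
  structure(
    list(label = label, uses_ai_cost = label == "dentist_with_ai"),
    class = "caries_strategy"
  )
}

radiograph_accuracy <- function(strat, p) {
  if (strat$label == "dentist_with_ai") p$ai_accuracy else p$dentist_accuracy
}

DETECTION_OUTCOMES <- c("TP_initial", "TP_advanced", "FN", "TN",
                        "FP_initial", "FP_advanced", "not_examined")

#' Examine one tooth under a strategy's accuracy
#'
#' Combines the visual-tactile read (sensitive only to advanced, D2-D3,
#' lesions) with the radiographic read (depth-specific sensitivity; active
#' only on radiograph cycles) by logical OR. Sound and arrested surfaces can
#' be falsely flagged with probability one minus the respective specificity;
#' a false positive asserts an advanced stage with probability
#' `fp_advanced_share` and an initial stage otherwise. Treated states are not
#' re-screened.
#'
#' @param s A `caries_tooth`.
#' @param strat A [strategy()].
#' @param p A `caries_parameter_set` (accuracy profiles, `fp_advanced_share`,
#'   schedule).
#' @param cycle Cycle index (`>= 0`).
#' @return One of `"TP_initial"`, `"TP_advanced"`, `"FN"`, `"TN"`,
#'   `"FP_initial"`, `"FP_advanced"`, `"not_examined"`.
#' @export
examine <- function(s, strat, p, cycle) {
  stopifnot(cycle >= 0)
  sched <- p$schedule
  rad <- is_radiograph_cycle(sched, cycle)
  vt <- is_vt_cycle(sched, cycle)
  if (!rad && !vt) return("not_examined")
  if (!s$health %in% UNTREATED_STATES) return("not_examined")

  acc_rad <- radiograph_accuracy(strat, p)
  acc_vt <- p$visual_tactile_accuracy

  if (s$health %in% c("SOUND", "ARRESTED")) {
    p_fp_rad <- if (rad) 1 - acc_rad$specificity else 0
    p_fp_vt <- if (vt) 1 - acc_vt$specificity else 0
    p_fp <- 1 - (1 - p_fp_rad) * (1 - p_fp_vt)
    if (stats::runif(1) < p_fp) {
      if (stats::runif(1) < p$fp_advanced_share) "FP_advanced" else "FP_initial"
    } else "TN"
  } else {
    depth <- s$health
    p_det_rad <- if (rad) acc_rad$sensitivity[[depth]] else 0
    p_det_vt <- if (vt) acc_vt$sensitivity[[depth]] else 0
    p_det <- 1 - (1 - p_det_rad) * (1 - p_det_vt)
    if (stats::runif(1) < p_det) {
      if (depth == "D2D3") "TP_advanced" else "TP_initial"
    } else "FN"
  }
}

#' Translate a detection outcome into treatment
#'
#' True/false positives trigger treatment; negatives and unexamined teeth are
#' left alone. Initial-stage calls are managed microinvasively (caries
#' infiltration; a true positive arrests the lesion, a false positive incurs
#' the fee with the surface unchanged). Advanced-stage calls receive a
#' composite restoration — including false positives, which is the mechanism
#' by which imperfect specificity drags a sound tooth into the restorative
#' cascade.
#'
#' @param s A `caries_tooth`.
#' @param outcome A detection outcome from [examine()].
#' @param costs A [cost_table()].
#' @param year Cycle index recorded on cost events.
#' @return `list(state = <caries_tooth>, events = <data.frame>)`.
#' @export
decide_and_treat <- function(s, outcome, costs, year = s$age_years) {
  outcome <- match.arg(outcome, DETECTION_OUTCOMES)
  lesion <- s$health %in% c("E2", "D1", "D2D3")
  soundish <- s$health %in% c("SOUND", "ARRESTED")
  if (outcome %in% c("TP_initial", "TP_advanced") && !lesion)
    stop("contract violation: ", outcome, " on ", s$health)
  if (outcome %in% c("FP_initial", "FP_advanced") && !soundish)
    stop("contract violation: ", outcome, " on ", s$health)
  if (outcome == "TP_initial" && s$health == "D2D3")
    stop("contract violation: TP_initial on advanced lesion")
  if (outcome == "TP_advanced" && s$health != "D2D3")
    stop("contract violation: TP_advanced on ", s$health)

  ev <- no_cost_events()
  if (outcome == "TP_initial") {
    s$health <- "ARRESTED"
    ev <- cost_event("infiltration", costs[["infiltration"]], year)
  } else if (outcome == "TP_advanced") {
    s$health <- "RESTORED"
    ev <- cost_event("restoration", costs[["restoration"]], year)
  } else if (outcome == "FP_initial") {
    ev <- cost_event("infiltration", costs[["infiltration"]], year)
  } else if (outcome == "FP_advanced") {
    s$health <- "RESTORED"
    ev <- cost_event("restoration", costs[["restoration"]], year)
  }
  list(state = s, events = ev)
}

#' Examination fees for one cycle
#'
#' Visual-tactile exam fee on every visual-tactile cycle and radiograph fee
#' on radiograph cycles; the AI per-application fee (divided by
#' `ai_teeth_per_application`, since one application covers several teeth) is
#' added on radiograph cycles only for the AI strategy.
#'
#' @param strat A [strategy()].
#' @param p A `caries_parameter_set`.
#' @param cycle Cycle index.
#' @return Data frame of cost events (possibly empty).
#' @export
exam_costs <- function(strat, p, cycle) {
  ev <- no_cost_events()
  costs <- p$costs
  if (is_vt_cycle(p$schedule, cycle))
    ev <- rbind(ev, cost_event("visual_tactile_exam",
                               costs[["visual_tactile_exam"]], cycle))
  if (is_radiograph_cycle(p$schedule, cycle)) {
    ev <- rbind(ev, cost_event("radiograph_exam",
                               costs[["radiograph_exam"]], cycle))
    if (strat$uses_ai_cost)
      ev <- rbind(ev, cost_event("ai_application",
                                 costs[["ai_application"]] / p$ai_teeth_per_application,
                                 cycle))
  }
  ev
}
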