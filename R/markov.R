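## Tooth-level health-state machine. States form a severity ladder:
## natural progression SOUND -> E2 -> D1 -> D2D3 (one step per annual cycle,
## ARRESTED may relapse to D1), and a treatment cascade
## RESTORED (k failures) -> CROWNED (replaced once) -> ROOT_FILLED ->
## RETREATED_NONSURG -> RETREATED_SURG -> EXTRACTED_IMPLANT (absorbing),
## with endodontic complications jumping from RESTORED/CROWNED to ROOT_FILLED.

#' Health states of the tooth state machine
#'
#' Character vector of the eleven model states, ordered from sound through
#' the treatment cascade to the absorbing extracted/implant state.
#' @export
HEALTH_STATES <- c(
  "SOUND", "E2", "D1", "D2D3", "ARRESTED", "RESTORED", "CROWNED",
  "ROOT_FILLED", "RETREATED_NONSURG", "RETREATED_SURG", "EXTRACTED_IMPLANT"
)

UNTREATED_STATES <- c("SOUND", "E2", "D1", "D2D3", "ARRESTED")
TREATED_STATES <- c("RESTORED", "CROWNED", "ROOT_FILLED",
                    "RETREATED_NONSURG", "RETREATED_SURG")

#' Construct a tooth state
#'
#' @param health One of [HEALTH_STATES].
#' @param restoration_failures Accumulated restoration failures (only
#'   meaningful in `RESTORED`).
#' @param crown_replaced Has the crown already been replaced once?
#' @param age_years Tooth age in completed annual cycles.
#' @return A `caries_tooth` object; `alive_tooth` is `FALSE` exactly when the
#'   tooth is in the absorbing `EXTRACTED_IMPLANT` state.
#' @export
tooth_state <- function(health = "SOUND", restoration_failures = 0L,
                        crown_replaced = FALSE, age_years = 0L) {
  health <- match.arg(health, HEALTH_STATES)
  structure(
    list(
      health = health,
      restoration_failures = as.integer(restoration_failures),
      crown_replaced = isTRUE(crown_replaced),
      age_years = as.integer(age_years),
      alive_tooth = health != "EXTRACTED_IMPLANT"
    ),
    class = "caries_tooth"
  )
}

#' @export
print.caries_tooth <- function(x, ...) {
  cat(sprintf("<tooth: %s, age %d y, %d restoration failure(s)%s%s>\n",
              x$health, x$age_years, x$restoration_failures,
              if (x$crown_replaced) ", crown replaced" else "",
              if (!x$alive_tooth) ", extracted" else ""))
  invisible(x)
}

cost_event <- function(label, euros, year) {
  data.frame(label = label, euros = euros, year = as.integer(year))
}

no_cost_events <- function() {
  data.frame(label = character(0), euros = numeric(0), year = integer(0))
}

#' Draw the initial state of a tooth from a risk profile
#'
#' @param risk A [risk_profile()].
#' @return A fresh `caries_tooth` with health drawn from the profile's
#'   initial-state prevalence, age 0 and zeroed counters.
#' @export
initial_state <- function(risk) {
  health <- sample(c("SOUND", "E2", "D1", "D2D3"), 1, prob = risk$prevalence)
  tooth_state(health = health)
}

#' One annual cycle of natural caries progression
#'
#' Applies at most one disease transition: `SOUND -> E2`, `E2 -> D1`,
#' `D1 -> D2D3` (each probability multiplied by the risk profile's
#' progression multiplier, capped at 1), or the arrest-failure relapse
#' `ARRESTED -> D1`. Treated states are unaffected.
#'
#' @param s A `caries_tooth`, not in the absorbing state.
#' @param transitions A [transition_table()].
#' @param progression_multiplier Risk-profile multiplier (default 1).
#' @return Updated `caries_tooth`.
#' @export
natural_step <- function(s, transitions, progression_multiplier = 1) {
  if (s$health == "EXTRACTED_IMPLANT") stop("natural_step on absorbing state")
  mult <- progression_multiplier
  pr <- function(p) min(1, p * mult)
  moved <- switch(s$health,
    SOUND = if (stats::runif(1) < pr(transitions[["p_sound_to_E2"]])) "E2",
    E2 = if (stats::runif(1) < pr(transitions[["p_E2_to_D1"]])) "D1",
    D1 = if (stats::runif(1) < pr(transitions[["p_D1_to_D2D3"]])) "D2D3",
    ARRESTED = if (stats::runif(1) < transitions[["p_arrest_failure"]]) "D1",
    NULL
  )
  if (!is.null(moved)) s$health <- moved
  s
}

#' One annual cycle of treated-state failure and cascade progression
#'
#' For teeth in a treated state, draws this cycle's complication/failure
#' events and advances the cascade, emitting the cost events of any
#' re-intervention:
#' \itemize{
#'   \item `RESTORED`/`CROWNED`: an endodontic complication (probability
#'     `p_endo_complication`) leads to root canal treatment (`ROOT_FILLED`).
#'     Otherwise a mechanical failure may occur; restoration failures
#'     accumulate and are resolved by repair (probability `p_repair`) or
#'     replacement until the k-th failure places a crown; a failed crown is
#'     replaced once, its second failure moves to root canal treatment.
#'   \item `ROOT_FILLED` fails to nonsurgical retreatment, which fails to
#'     surgical retreatment, whose failure exhausts the cascade: extraction
#'     plus implant-supported crown, the absorbing state.
#' }
#'
#' @param s A `caries_tooth` in a treated state.
#' @param p A `caries_parameter_set` (transitions, cascade settings, costs).
#' @param year Cycle index recorded on emitted cost events.
#' @return `list(state = <caries_tooth>, events = <data.frame>)`.
#' @export
treatment_step <- function(s, p, year = s$age_years) {
  if (!s$health %in% TREATED_STATES)
    stop("treatment_step requires a treated state, got ", s$health)
  tr <- p$transitions
  costs <- p$costs
  ev <- no_cost_events()
  add <- function(label) ev <<- rbind(ev, cost_event(label, costs[[label]], year))

  if (s$health %in% c("RESTORED", "CROWNED") &&
      stats::runif(1) < tr[["p_endo_complication"]]) {
    s$health <- "ROOT_FILLED"
    add("root_canal")
  } else if (s$health == "RESTORED") {
    if (stats::runif(1) < tr[["p_restoration_failure"]]) {
      s$restoration_failures <- s$restoration_failures + 1L
      if (s$restoration_failures >= p$restoration_failures_before_crown) {
        s$health <- "CROWNED"
        add("crown")
      } else if (stats::runif(1) < p$p_repair) {
        add("restoration_repair")
      } else {
        add("restoration_replacement")
      }
    }
  } else if (s$health == "CROWNED") {
    if (stats::runif(1) < tr[["p_crown_failure"]]) {
      if (!s$crown_replaced) {
        s$crown_replaced <- TRUE
        add("crown_replacement")
      } else {
        s$health <- "ROOT_FILLED"
        add("root_canal")
      }
    }
  } else if (s$health == "ROOT_FILLED") {
    if (stats::runif(1) < tr[["p_rootfill_failure"]]) {
      s$health <- "RETREATED_NONSURG"
      add("retreat_nonsurgical")
    }
  } else if (s$health == "RETREATED_NONSURG") {
    if (stats::runif(1) < tr[["p_retreat_failure"]]) {
      s$health <- "RETREATED_SURG"
      add("retreat_surgical")
    }
  } else if (s$health == "RETREATED_SURG") {
    if (stats::runif(1) < tr[["p_surg_retreat_failure"]]) {
      s$health <- "EXTRACTED_IMPLANT"
      s$alive_tooth <- FALSE
      add("extraction")
      add("implant_crown")
    }
  }
  list(state = s, events = ev)
}
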