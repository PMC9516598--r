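## Cost-effectiveness outputs: discounting, ICER, cost-effectiveness plane
## quadrants, acceptability curves.

#' Discount a cost to present value
#'
#' Whole-year discounting: `cost / (1 + rate)^year`; year 0 is undiscounted.
#'
#' @param cost Cost in euros (vectorized).
#' @param year Nonnegative whole-year index of the cycle in which the cost
#'   occurs (vectorized).
#' @param rate Annual discount rate, `>= 0` (default 0.03).
#' @return Present-value euros.
#' @export
discount <- function(cost, year, rate = 0.03) {
  if (any(year < 0)) stop("year must be nonnegative")
  if (any(rate < 0)) stop("rate must be nonnegative")
  cost / (1 + rate)^year
}

#' Incremental cost-effectiveness ratio with dominance labels
#'
#' @param delta_cost Mean incremental cost (euros).
#' @param delta_effect Mean incremental effectiveness (years).
#' @return A list with `label` (`"dominant"`, `"dominated"`, `"icer"`,
#'   `"equivalent"`, or `"undefined"`) and `value` (euros per year when a
#'   ratio is meaningful, otherwise `NA`). `"dominant"` means cheaper and
#'   more effective (lower-right quadrant); `"dominated"` the reverse.
#' @export
icer <- function(delta_cost, delta_effect) {
  if (delta_cost == 0 && delta_effect == 0)
    return(list(label = "equivalent", value = NA_real_))
  if (delta_effect == 0)
    return(list(label = "undefined", value = NA_real_))
  if (delta_cost < 0 && delta_effect > 0)
    return(list(label = "dominant", value = NA_real_))
  if (delta_cost > 0 && delta_effect < 0)
    return(list(label = "dominated", value = NA_real_))
  list(label = "icer", value = delta_cost / delta_effect)
}

#' Quadrant shares of the incremental cost-effectiveness plane
#'
#' Shares of PSA draws falling in each quadrant of the (delta effect,
#' delta cost) plane. Boundary convention: points with `delta_effect == 0`
#' count toward the more-effective (right) side, points with
#' `delta_cost == 0` toward the less-costly (lower) side, so every point is
#' assigned to exactly one quadrant.
#'
#' @param points Data frame with columns `delta_cost` and `delta_effect`
#'   (one row per PSA draw), e.g. from `cariesim:::psa_increments()`.
#' @return Named numeric: `lower_right` (cheaper, more effective),
#'   `upper_right`, `lower_left`, `upper_left`; sums to 1.
#' @export
ce_plane_quadrant_shares <- function(points) {
  if (!nrow(points)) stop("no incremental points")
  de <- points$delta_effect >= 0
  dc <- points$delta_cost <= 0
  c(
    lower_right = mean(de & dc),
    upper_right = mean(de & !dc),
    lower_left = mean(!de & dc),
    upper_left = mean(!de & !dc)
  )
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the probability (fraction of PSA
#' draws) that a strategy attains the strictly highest net monetary benefit;
#' draws with tied maxima contribute equal fractional weight to each tied
#' strategy, so acceptabilities sum to 1 at every threshold.
#'
#' @param psa A `caries_psa` (or any object with a `$results` data frame of
#'   `draw`, `strategy`, `mean_cost`, `mean_retention`).
#' @param lambda_grid Willingness-to-pay grid in euros per retention year
#'   (default 0 to 100 in steps of 1).
#' @return A `caries_ceac`: data frame with columns `lambda`, `strategy`,
#'   `probability`.
#' @export
ceac <- function(psa, lambda_grid = 0:100) {
  res <- psa$results
  strategies <- sort(unique(res$strategy))
  if (length(strategies) < 2) stop("ceac requires at least two strategies")
  wide_c <- nmb_matrix_parts(res, strategies)
  out <- lapply(lambda_grid, function(l) {
    nmbm <- l * wide_c$effect - wide_c$cost        # draws x strategies
    best <- nmbm == apply(nmbm, 1, max)
    w <- best / rowSums(best)                      # tie-splitting
    data.frame(lambda = l, strategy = strategies,
               probability = colMeans(w), row.names = NULL)
  })
  structure(do.call(rbind, out), class = c("caries_ceac", "data.frame"))
}

## draws x strategies matrices of per-draw mean cost and effect,
## aligned by draw index.
nmb_matrix_parts <- function(res, strategies = sort(unique(res$strategy))) {
  res <- res[order(res$draw), ]
  cost <- sapply(strategies, function(s) res$mean_cost[res$strategy == s])
  effect <- sapply(strategies, function(s) res$mean_retention[res$strategy == s])
  list(cost = as.matrix(cost), effect = as.matrix(effect),
       strategies = strategies)
}
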