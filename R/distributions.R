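#' Uncertainty distributions for probabilistic sensitivity analysis
#'
#' Scalar model inputs carry one of three uncertainty shapes: a degenerate
#' point value, a uniform range, or a triangular distribution `(low, mode,
#' high)`. These are the two shapes used for parameter uncertainty in the
#' underlying decision model; the point form marks an input as fixed.
#'
#' @param value Point value (for `dist_point`).
#' @param low,high Lower and upper bounds.
#' @param mode Mode of the triangular distribution; must satisfy
#'   `low <= mode <= high`.
#' @return An object of class `caries_dist` with fields `kind`
#'   (`"point"`, `"uniform"` or `"triangular"`), `low`, `mode`, `high`.
#' @examples
#' dist_point(0.03)
#' dist_uniform(4, 12)          # AI fee per application, euros
#' dist_triangular(0.2, 0.3, 0.4)
#' @name distributions
NULL

new_dist <- function(kind, low, mode, high) {
  d <- structure(
    list(kind = kind, low = low, mode = mode, high = high),
    class = "caries_dist"
  )
  validate_dist(d)
  d
}

#' @rdname distributions
#' @export
dist_point <- function(value) new_dist("point", value, value, value)

#' @rdname distributions
#' @export
dist_uniform <- function(low, high) new_dist("uniform", low, (low + high) / 2, high)

#' @rdname distributions
#' @export
dist_triangular <- function(low, mode, high) new_dist("triangular", low, mode, high)

validate_dist <- function(d) {
  stopifnot(is.list(d), !is.null(d$kind))
  if (!d$kind %in% c("point", "uniform", "triangular"))
    stop("unknown distribution kind: ", d$kind)
  if (!is.finite(d$low) || !is.finite(d$high) || !is.finite(d$mode))
    stop("distribution bounds must be finite")
  if (d$low > d$high)
    stop("invalid distribution bounds: low (", d$low, ") > high (", d$high, ")")
  if (d$mode < d$low || d$mode > d$high)
    stop("triangular mode must satisfy low <= mode <= high")
  if (d$kind == "point" && d$low != d$high)
    stop("point distribution must have low == high")
  invisible(d)
}

#' @export
print.caries_dist <- function(x, ...) {
  cat(switch(x$kind,
    point = sprintf("point(%g)", x$low),
    uniform = sprintf("uniform(%g, %g)", x$low, x$high),
    triangular = sprintf("triangular(%g, %g, %g)", x$low, x$mode, x$high)
  ), "\n")
  invisible(x)
}

#' Draw from an uncertainty distribution
#'
#' Samples `n` values from a [distributions] object using R's global RNG
#' stream (so `set.seed()` governs reproducibility). Triangular variates are
#' generated by inverse-CDF transform.
#'
#' @param d A `caries_dist` object.
#' @param n Number of draws.
#' @return Numeric vector of length `n`, always within `[d$low, d$high]`.
#' @export
sample_distribution <- function(d, n = 1) {
  validate_dist(d)
  switch(d$kind,
    point = rep(d$low, n),
    uniform = stats::runif(n, d$low, d$high),
    triangular = {
      u <- stats::runif(n)
      a <- d$low; b <- d$high; m <- d$mode
      if (a == b) rep(a, n)
      else {
        fc <- (m - a) / (b - a)
        ifelse(u < fc,
          a + sqrt(u * (b - a) * (m - a)),
          b - sqrt((1 - u) * (b - a) * (b - m)))
      }
    }
  )
}

dist_mean <- function(d) {
  switch(d$kind,
    point = d$low,
    uniform = (d$low + d$high) / 2,
    triangular = (d$low + d$mode + d$high) / 3
  )
}

## serialization helpers (YAML round trip)
dist_to_list <- function(d) list(kind = d$kind, low = d$low, mode = d$mode, high = d$high)
dist_from_list <- function(x) new_dist(x$kind, x$low, x$mode, x$high)
is_dist <- function(x) inherits(x, "caries_dist")
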