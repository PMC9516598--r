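## YAML (de)serialization of fixtures. The parameter file mirrors the
## fixture structure; distributions are written as {kind, low, mode, high}
## mappings and risk profiles as plain mappings.

#' Write a fixture to a YAML parameter file
#'
#' @param fixture A `caries_fixture`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_fixture()]; the round trip is lossless.
#' @export
write_fixture <- function(fixture, path) {
  to_plain <- function(x) {
    if (is_dist(x)) dist_to_list(x)
    else if (inherits(x, "caries_risk"))
      list(label = x$label, prevalence = as.list(x$prevalence),
           progression_multiplier = x$progression_multiplier)
    else if (inherits(x, "caries_schedule") ||
             inherits(x, "caries_learning_curve")) unclass(x)
    else if (is.list(x)) lapply(x, to_plain)
    else if (is.numeric(x) && !is.null(names(x))) as.list(x)
    else x
  }
  # %.17g guarantees doubles survive the text round trip bit-exactly; a
  # trailing ".0" keeps integral doubles from being re-read as integers
  dbl <- function(v) {
    out <- sprintf("%.17g", v)
    plain <- !grepl("[.eE]", out)
    out[plain] <- paste0(out[plain], ".0")
    structure(out, class = "verbatim")
  }
  writeLines(yaml::as.yaml(to_plain(unclass(fixture)),
                           handlers = list(numeric = dbl)), path)
  invisible(path)
}

#' Read a fixture from a YAML parameter file
#'
#' @param path Path written by [write_fixture()].
#' @return A `caries_fixture` equal to the one written.
#' @export
read_fixture <- function(path) {
  raw <- yaml::read_yaml(path)
  as_dist_tree <- function(x) {
    if (is.list(x) && identical(sort(names(x)), sort(c("kind", "low", "mode", "high"))))
      dist_from_list(x)
    else if (is.list(x)) lapply(x, as_dist_tree)
    else x
  }
  f <- as_dist_tree(raw)
  f$risk_profiles <- lapply(f$risk_profiles, function(r)
    risk_profile(r$label, unlist(r$prevalence), r$progression_multiplier))
  f$schedule <- schedule(f$schedule$visual_tactile_every_years,
                         f$schedule$radiograph_every_years)
  f$learning_curves <- lapply(f$learning_curves, function(s)
    learning_curve_spec(s$floor, s$asymptote, s$rate, s$width0, s$width_decay))
  f$restoration_failures_before_crown <-
    as.integer(f$restoration_failures_before_crown)
  f$manifest$seed <- as.integer(f$manifest$seed)
  f$risk_weights <- unlist(f$risk_weights)
  f$training_fraction_weights <- unlist(f$training_fraction_weights)
  structure(f, class = "caries_fixture")
}
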