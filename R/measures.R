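# Measures of effect (causal, target-relative) and measures of association
# (factual and exposure-flipped) on the RD, RR and OR scales.

MEASURE_SCALES <- c("RD", "RR", "OR")
TARGETS <- c("total", "exposed", "unexposed")

invalid_target <- function(msg) {
  stop(errorCondition(msg, class = c("causalflip_invalid_target",
                                     "causalflip_error")))
}

#' Measure values
#'
#' A measure value couples a scale (`"RD"`, `"RR"` or `"OR"`) with an exact
#' rational value, or with the distinguished state *undefined* (a ratio whose
#' denominator risk is 0). Undefined is a first-class value so that condition
#' reports can render it rather than crash; the numeric accessors refuse it.
#'
#' @param scale one of `"RD"`, `"RR"`, `"OR"`.
#' @param value a scalar `rational`, or `NULL` for undefined.
#' @return An object of class `measure`.
#' @export
measure_value <- function(scale, value) {
  scale <- match.arg(scale, MEASURE_SCALES)
  if (!is.null(value)) {
    value <- as_rational(value)
    stopifnot(length(value) == 1L)
    if (scale == "RD" && (value < -1 || value > 1))
      invalid_input("an RD measure must lie in [-1, 1]")
    if (scale != "RD" && value < 0)
      invalid_input("RR/OR measures must be non-negative")
  }
  structure(list(scale = scale, value = value), class = "measure")
}

#' @rdname measure_value
#' @param x a `measure`.
#' @export
is_defined <- function(x) {
  stopifnot(inherits(x, "measure"))
  !is.null(x$value)
}

#' @rdname measure_value
#' @export
measure_rational <- function(x) {
  stopifnot(inherits(x, "measure"))
  if (is.null(x$value))
    stop("measure is undefined (zero denominator risk)", call. = FALSE)
  x$value
}

#' @export
format.measure <- function(x, ...) {
  if (is.null(x$value)) "undefined" else as.character(x$value)
}

#' @export
print.measure <- function(x, ...) {
  cat(sprintf("<measure %s> %s\n", x$scale, format(x)))
  invisible(x)
}

#' @export
as.numeric.measure <- function(x, ...) {
  if (is.null(x$value)) NA_real_ else as.numeric(x$value)
}

#' @export
as.double.measure <- as.numeric.measure

#' @export
`==.measure` <- function(e1, e2) {
  v2 <- if (inherits(e2, "measure")) e2$value else as_rational(e2)
  v1 <- e1$value
  if (is.null(v1) || is.null(v2)) return(NA)
  v1 == v2
}

ratio_measure <- function(scale, num, den) {
  if (den == 0) measure_value(scale, NULL) else measure_value(scale, num / den)
}

# risks of the chosen target population: list(exposed = risk-if-exposed,
# unexposed = risk-if-unexposed). The total target needs 0 < prevalence < 1.
target_risks <- function(pop, target) {
  target <- match.arg(target, TARGETS)
  r <- risks_of(pop)
  switch(target,
    exposed   = list(e = r$ap, u = r$bp),
    unexposed = list(e = r$aq, u = r$bq),
    total = {
      if (!has_interior_prevalence(pop))
        invalid_target(paste0(
          "the total target population requires 0 < Pr(E=1) < 1; ",
          "use target = \"exposed\" or \"unexposed\" at a degenerate prevalence"))
      pi <- r$pi
      list(e = pi * r$ap + (rational(1) - pi) * r$aq,
           u = pi * r$bp + (rational(1) - pi) * r$bq)
    })
}

#' Causal effect measures for a target population
#'
#' Causal contrasts of the risk the chosen target population would have if
#' everyone were exposed versus unexposed. For the total population these are
#' \eqn{(r_1+r_2) - (r_1+r_3)} (risk difference) and
#' \eqn{(r_1+r_2)/(r_1+r_3)} (risk ratio), with \eqn{r} the marginal
#' response-type distribution; for the exposed or unexposed target the
#' group's own distribution replaces \eqn{r}. The target must always be named:
#' causal estimands are target-relative, and the package never assumes one.
#'
#' `causal_or()` is the analogous odds-ratio contrast, provided as a
#' documented extension of the same four potential risks (the calculus itself
#' is usually stated for RD and RR).
#'
#' @param pop a [grouped_population()].
#' @param target `"total"`, `"exposed"` or `"unexposed"`. The total target
#'   requires an interior prevalence.
#' @return A [measure_value()] (ratio scales may be undefined).
#' @examples
#' s1 <- study_fixture("study1")
#' causal_rd(s1, "total")  # 1/5
#' causal_rr(s1, "total")  # 14/9
#' @export
causal_rd <- function(pop, target) {
  tr <- target_risks(pop, target)
  measure_value("RD", tr$e - tr$u)
}

#' @rdname causal_rd
#' @export
causal_rr <- function(pop, target) {
  tr <- target_risks(pop, target)
  ratio_measure("RR", tr$e, tr$u)
}

#' @rdname causal_rd
#' @export
causal_or <- function(pop, target) {
  tr <- target_risks(pop, target)
  ratio_measure("OR", tr$e * (1 - tr$u), (1 - tr$e) * tr$u)
}

#' Factual and counterfactual (exposure-flipped) association measures
#'
#' The factual associational measures contrast the observed group risks,
#' e.g. the factual associational risk difference
#' \eqn{(p_1+p_2) - (q_1+q_3)}. The counterfactual associational measures are
#' the same contrasts after flipping everyone's exposure, so the exposed are
#' compared at their risk under no exposure and the unexposed at their risk
#' under exposure: e.g. the counterfactual associational risk difference
#' \eqn{(q_1+q_2) - (p_1+p_3)}. Ratio scales are undefined when the
#' denominator risk is 0.
#'
#' @param pop a [grouped_population()].
#' @param scale `"RD"`, `"RR"` or `"OR"`.
#' @return A [measure_value()].
#' @examples
#' s1 <- study_fixture("study1")
#' factual_assoc(s1, "RD")         # 1/5
#' counterfactual_assoc(s1, "RD")  # 1/6
#' @export
factual_assoc <- function(pop, scale) {
  scale <- match.arg(scale, MEASURE_SCALES)
  r <- risks_of(pop)
  assoc_measure(scale, r$ap, r$bq)
}

#' @rdname factual_assoc
#' @export
counterfactual_assoc <- function(pop, scale) {
  scale <- match.arg(scale, MEASURE_SCALES)
  r <- risks_of(pop)
  assoc_measure(scale, r$aq, r$bp)
}

assoc_measure <- function(scale, r1, r0) {
  switch(scale,
    RD = measure_value("RD", r1 - r0),
    RR = ratio_measure("RR", r1, r0),
    OR = ratio_measure("OR", r1 * (1 - r0), (1 - r1) * r0))
}

#' Flip exposure status of a population
#'
#' Returns the population in which the exposed become the unexposed and vice
#' versa: the two group distributions swap and the prevalence becomes
#' \eqn{1 - \Pr(E=1)}. Flipping is an involution, and the factual association
#' measures of the flipped population equal the counterfactual association
#' measures of the original on every scale.
#'
#' @param pop a [grouped_population()].
#' @return A `grouped_population`.
#' @export
flip_exposure <- function(pop) {
  stopifnot(inherits(pop, "grouped_population"))
  grouped_population(exposed = pop$q, unexposed = pop$p,
                     prevalence = rational(1) - pop$prevalence)
}
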