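# The five no-confounding / exchangeability conditions, decided exactly.
#
# All verdicts are three-valued logicals: TRUE, FALSE, or NA ("not evaluable")
# when a ratio-scale condition involves a risk ratio with a zero denominator.
# Each condition that the theory states in several algebraically rearranged
# forms is evaluated in every form and the forms are asserted to agree; a
# disagreement would be an arithmetic bug, so it stops hard.

assert_forms_agree <- function(..., what) {
  v <- c(...)
  if (length(unique(v)) != 1L)
    stop("internal error: algebraic rearrangements of the ", what,
         " condition disagree", call. = FALSE)
  v[1]
}

#' No confounding in distribution
#'
#' Confounding *in distribution* is absent exactly when the exposed and
#' unexposed groups are representative of the total population's
#' potential-outcome distribution, i.e. when both groups share the same risk
#' under exposure and the same risk under no exposure:
#' \deqn{(p_1+p_2) = (q_1+q_2) \ \wedge\ (p_1+p_3) = (q_1+q_3),}
#' equivalently \eqn{D^e \perp\!\!\!\perp E}. For an interior prevalence this
#' is also evaluated in its marginal form
#' \eqn{(r_1+r_2)=(p_1+p_2) \wedge (r_1+r_3)=(q_1+q_3)} and the two forms are
#' asserted to agree. The condition is scale-independent and is stronger than
#' no confounding in any measure.
#'
#' @param pop a [grouped_population()].
#' @return `TRUE` or `FALSE`.
#' @examples
#' no_confounding_in_distribution(study_fixture("study1"))  # FALSE
#' @export
no_confounding_in_distribution <- function(pop) {
  r <- risks_of(pop)
  direct <- (r$ap == r$aq) && (r$bp == r$bq)
  if (!has_interior_prevalence(pop)) return(direct)
  pi <- r$pi
  re <- pi * r$ap + (rational(1) - pi) * r$aq
  ru <- pi * r$bp + (rational(1) - pi) * r$bq
  marginal <- (re == r$ap) && (ru == r$bq)
  assert_forms_agree(direct, marginal, what = "no-confounding-in-distribution")
}

#' No confounding in measure (risk difference scale)
#'
#' Confounding *in measure* is scale-specific. On the risk-difference scale it
#' is absent exactly when the causal risk difference in the target population
#' equals the factual associational risk difference:
#' \deqn{(r_1+r_2)-(r_1+r_3) = (p_1+p_2)-(q_1+q_3).}
#' The equivalent prevalence-weighted rearrangement
#' \deqn{(p_1+p_3)\pi + (p_1+p_2)(1-\pi) = (q_1+q_3)\pi + (q_1+q_2)(1-\pi)}
#' (with \eqn{\pi = \Pr(E=1)}) is evaluated as well and asserted to agree; it
#' makes visible that, with the total population as target, confounding in
#' measure depends on the exposure prevalence. At a degenerate prevalence
#' (exactly 0 or 1) the condition specialises to the corresponding
#' single-group target.
#'
#' @param pop a [grouped_population()].
#' @return `TRUE` or `FALSE`.
#' @examples
#' no_confounding_in_rd(study_fixture("study1"))  # TRUE
#' @export
no_confounding_in_rd <- function(pop) {
  r <- risks_of(pop)
  ard <- r$ap - r$bq
  if (!has_interior_prevalence(pop)) {
    target <- if (pop$prevalence == 1) "exposed" else "unexposed"
    return(measure_rational(causal_rd(pop, target)) == ard)
  }
  pi <- r$pi
  omp <- rational(1) - pi
  crd <- (pi * r$ap + omp * r$aq) - (pi * r$bp + omp * r$bq)
  direct <- crd == ard
  weighted <- (r$bp * pi + r$ap * omp) == (r$bq * pi + r$aq * omp)
  assert_forms_agree(direct, weighted, what = "no-confounding-in-RD")
}

#' No confounding in measure (risk ratio scale)
#'
#' On the risk-ratio scale confounding is absent exactly when the causal risk
#' ratio in the target population equals the factual associational risk
#' ratio:
#' \deqn{\frac{r_1+r_2}{r_1+r_3} = \frac{p_1+p_2}{q_1+q_3}.}
#' The cross-multiplied product form
#' \deqn{(p_1+p_2)\{(p_1+p_3)-(q_1+q_3)\}\pi =
#'       (q_1+q_3)\{(q_1+q_2)-(p_1+p_2)\}(1-\pi)}
#' is evaluated as well and asserted to agree. Both ratios must be defined;
#' if a denominator risk is 0 the verdict is `NA` ("not evaluable"), which is
#' deliberately distinct from `FALSE`. Degenerate prevalences specialise to
#' the single-group target as in [no_confounding_in_rd()].
#'
#' @param pop a [grouped_population()].
#' @return `TRUE`, `FALSE`, or `NA` when a ratio is undefined.
#' @examples
#' no_confounding_in_rr(study_fixture("study1"))  # FALSE
#' @export
no_confounding_in_rr <- function(pop) {
  r <- risks_of(pop)
  if (!has_interior_prevalence(pop)) {
    target <- if (pop$prevalence == 1) "exposed" else "unexposed"
    crr <- causal_rr(pop, target)
    if (r$bq == 0 || !is_defined(crr)) return(NA)
    return(measure_rational(crr) == r$ap / r$bq)
  }
  pi <- r$pi
  omp <- rational(1) - pi
  ru <- pi * r$bp + omp * r$bq   # total-population risk when unexposed
  if (ru == 0 || r$bq == 0) return(NA)
  direct <- (pi * r$ap + omp * r$aq) / ru == r$ap / r$bq
  product <- (r$ap * (r$bp - r$bq) * pi) == (r$bq * (r$aq - r$ap) * omp)
  assert_forms_agree(direct, product, what = "no-confounding-in-RR")
}

#' Exchangeability of association measures under exposure flipping
#'
#' `exchangeable_assoc_rd()` decides whether the factual associational risk
#' difference equals its counterfactual (exposure-flipped) version:
#' \deqn{(p_1+p_2)-(q_1+q_3) = (q_1+q_2)-(p_1+p_3).}
#' Equality holds exactly when a single shift constant
#' \eqn{\alpha \in [-1, 1]} satisfies
#' \eqn{(q_1+q_2)=(p_1+p_2)+\alpha} and \eqn{(p_1+p_3)=(q_1+q_3)+\alpha};
#' when the verdict is `TRUE` that \eqn{\alpha} is extracted and the paired
#' characterisation verified. \eqn{\alpha = 0} recovers no confounding in
#' distribution.
#'
#' `exchangeable_assoc_rr()` is the risk-ratio analogue:
#' \deqn{\frac{p_1+p_2}{q_1+q_3} = \frac{q_1+q_2}{p_1+p_3},}
#' characterised by a positive scale constant \eqn{\beta} with
#' \eqn{(q_1+q_2)=(p_1+p_2)\beta} and \eqn{(p_1+p_3)=(q_1+q_3)\beta};
#' \eqn{\beta = 1} recovers no confounding in distribution. The verdict is
#' `NA` when either denominator risk is 0, and \eqn{\beta} is extracted only
#' when the verdict is `TRUE` and the risks are positive.
#'
#' Non-exchangeability on either scale is *sufficient* for confounding in
#' distribution, but exchangeability guarantees nothing: confounding in
#' distribution and in measure can both be present while these conditions
#' hold.
#'
#' The always-computable differences \eqn{(q_1+q_2)-(p_1+p_2)} and
#' \eqn{(p_1+p_3)-(q_1+q_3)} are returned as diagnostics whatever the
#' verdict; the shift constant itself exists only under equality.
#'
#' @param pop a [grouped_population()].
#' @return An object of class `exchangeability`: a list with elements
#'   `exchangeable` (`TRUE`/`FALSE`/`NA`), `scale`, `constant` (the rational
#'   \eqn{\alpha} or \eqn{\beta}, or `NULL` when absent) and `diagnostics`.
#' @examples
#' exchangeable_assoc_rr(study_fixture("study1"))  # TRUE, beta = 5/6
#' @export
exchangeable_assoc_rd <- function(pop) {
  r <- risks_of(pop)
  verdict <- (r$ap - r$bq) == (r$aq - r$bp)
  alpha <- NULL
  if (verdict) {
    alpha <- r$aq - r$ap
    stopifnot(alpha >= -1, alpha <= 1,
              r$aq == r$ap + alpha, r$bp == r$bq + alpha)
  }
  new_exchangeability("RD", verdict, alpha, r)
}

#' @rdname exchangeable_assoc_rd
#' @export
exchangeable_assoc_rr <- function(pop) {
  r <- risks_of(pop)
  if (r$bq == 0 || r$bp == 0)
    return(new_exchangeability("RR", NA, NULL, r))
  verdict <- (r$ap * r$bp) == (r$aq * r$bq)  # ap/bq = aq/bp, cross-multiplied
  beta <- NULL
  if (verdict && r$ap > 0) {
    beta <- r$aq / r$ap
    stopifnot(beta > 0, r$aq == r$ap * beta, r$bp == r$bq * beta)
  }
  new_exchangeability("RR", verdict, beta, r)
}

new_exchangeability <- function(scale, verdict, constant, r) {
  structure(list(
    scale = scale,
    exchangeable = verdict,
    constant = constant,
    diagnostics = list(shift_when_exposed = r$aq - r$ap,
                       shift_when_unexposed = r$bp - r$bq)
  ), class = "exchangeability")
}

#' @export
print.exchangeability <- function(x, ...) {
  v <- if (is.na(x$exchangeable)) "not evaluable" else x$exchangeable
  cat(sprintf("Exchangeability of associational %s under exposure flip: %s\n",
              x$scale, v))
  if (!is.null(x$constant)) {
    lab <- if (x$scale == "RD") "shift constant alpha" else "scale constant beta"
    cat(sprintf("  %s = %s\n", lab, as.character(x$constant)))
  }
  invisible(x)
}

#' Exchangeability of background risks
#'
#' Decides whether the risk of the outcome under *no* exposure -- one reading
#' of the "background risk", the risk not caused by the exposure -- is the
#' same in both groups: \eqn{\Pr(D^0=1 \mid E=1) = \Pr(D^0=1 \mid E=0)}, i.e.
#' \eqn{(p_1+p_3) = (q_1+q_3)}. This is the second conjunct of no confounding
#' in distribution, so it is necessary but not sufficient for it; it is
#' neither necessary nor sufficient for no confounding in measure. The
#' operationalisation is provisional: "background risk" admits other readings
#' (see the methods vignette).
#'
#' @param pop a [grouped_population()].
#' @return `TRUE` or `FALSE`.
#' @export
background_risk_exchangeable <- function(pop) {
  r <- risks_of(pop)
  r$bp == r$bq
}

#' Full condition report for a population
#'
#' Evaluates all condition verdicts -- no confounding in distribution, no
#' confounding in measure on the RD and RR scales, exchangeability of the
#' associational RD and RR under exposure flipping, and background-risk
#' exchangeability -- and collects them with the extracted shift constant
#' \eqn{\alpha} and scale constant \eqn{\beta} into a single report, the
#' machine-readable form of a study-summary grid.
#'
#' @param pop a [grouped_population()].
#' @param label optional study label carried into the report.
#' @return An object of class `condition_report` with logical (possibly `NA`)
#'   elements `no_confounding_distribution`, `no_confounding_rd`,
#'   `no_confounding_rr`, `exchangeable_rd`, `exchangeable_rr`,
#'   `background_exchangeable`, and rational-or-`NULL` elements `alpha`,
#'   `beta`.
#' @examples
#' condition_summary(study_fixture("study3"))
#' @export
condition_summary <- function(pop, label = NULL) {
  xrd <- exchangeable_assoc_rd(pop)
  xrr <- exchangeable_assoc_rr(pop)
  structure(list(
    label = label,
    no_confounding_distribution = no_confounding_in_distribution(pop),
    no_confounding_rd = no_confounding_in_rd(pop),
    no_confounding_rr = no_confounding_in_rr(pop),
    exchangeable_rd = xrd$exchangeable,
    exchangeable_rr = xrr$exchangeable,
    background_exchangeable = background_risk_exchangeable(pop),
    alpha = xrd$constant,
    beta = xrr$constant
  ), class = "condition_report")
}

verdict_word <- function(v) {
  if (is.na(v)) "n/e" else if (v) "True" else "False"
}

#' @export
print.condition_report <- function(x, ...) {
  if (!is.null(x$label)) cat("Study:", x$label, "\n")
  rows <- c(
    "No confounding in distribution"                 = "no_confounding_distribution",
    "No confounding in risk difference"              = "no_confounding_rd",
    "No confounding in risk ratio"                   = "no_confounding_rr",
    "Exchangeability of associational risk difference" = "exchangeable_rd",
    "Exchangeability of associational risk ratio"    = "exchangeable_rr",
    "Exchangeability of background risks"            = "background_exchangeable"
  )
  w <- max(nchar(names(rows)))
  for (i in seq_along(rows)) {
    cat(sprintf("  %-*s  %s\n", w, names(rows)[i],
                verdict_word(x[[rows[i]]])))
  }
  if (!is.null(x$alpha))
    cat(sprintf("  alpha (RD shift) = %s\n", as.character(x$alpha)))
  if (!is.null(x$beta))
    cat(sprintf("  beta (RR scale)  = %s\n", as.character(x$beta)))
  invisible(x)
}

# Vectorised condition verdicts on parallel rational risk vectors; used by the
# property suite so that 10^4 populations cost a handful of C++ calls, not
# 10^4 R round-trips. Prevalences must be interior.
conditions_vectorized <- function(ap, bp, aq, bq, pi) {
  one <- rational(1)
  omp <- one - pi
  re <- pi * ap + omp * aq
  ru <- pi * bp + omp * bq
  rr_def <- (ru > 0) & (bq > 0)
  xr_def <- (bq > 0) & (bp > 0)
  rr_measure <- (re * bq) == (ap * ru)
  rr_measure[!rr_def] <- NA
  rr_exch <- (ap * bp) == (aq * bq)
  rr_exch[!xr_def] <- NA
  list(
    distribution = (ap == aq) & (bp == bq),
    rd_measure   = (re - ru) == (ap - bq),
    rr_measure   = rr_measure,
    rd_exchangeable = (ap - bq) == (aq - bp),
    rr_exchangeable = rr_exch,
    background   = bp == bq
  )
}
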