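# Seeded property suite: verifies the logical relationships between the
# conditions on thousands of random and constructed populations.

#' Run the property suite
#'
#' Checks, on `n_draws` seeded random populations (plus constructed ones
#' where a premise would otherwise almost never occur), the logical
#' relationships that the confounding calculus asserts:
#'
#' * **implication** -- no confounding in distribution implies no confounding
#'   in either measure and exchangeability of both association measures, with
#'   shift constant `alpha = 0` and scale constant `beta = 1`; conversely
#'   `alpha = 0` (or `beta = 1`) under exchangeability implies no confounding
#'   in distribution.
#' * **half_prevalence** -- at prevalence 1/2, no confounding in the RD (RR)
#'   measure is equivalent to exchangeability of the associational RD (RR).
#' * **contrapositive** -- non-exchangeability of either association measure
#'   implies confounding in distribution.
#' * **flip_duality** -- factual association measures of the flipped
#'   population equal counterfactual measures of the original on every scale.
#' * **null_special_case** -- when the exposed factual risk equals the
#'   unexposed one with the counterfactual risks swapped, both association
#'   measures are null and exchangeable at every prevalence.
#' * **form_agreement** -- the algebraically rearranged forms of each
#'   condition agree as Boolean predicates (evaluated inside the scalar
#'   condition functions, exercised here on random draws).
#' * **or_witness** -- the frozen witness population shows that at prevalence
#'   1/2 the measure/exchangeability equivalence does *not* extend to the
#'   odds-ratio scale.
#'
#' @param n_draws number of random populations (at least 1).
#' @param seed integer seed (mandatory: the suite is reproducible by
#'   construction).
#' @param denominator lattice denominator for the samplers.
#' @return An object of class `property_suite`: a list with `pass` (logical),
#'   `n_draws`, per-property verdicts in `results`, and `failures`, a list of
#'   offending populations (risk quadruples and prevalence) for any violated
#'   property.
#' @examples
#' run_property_suite(200, seed = 1)$pass
#' @export
run_property_suite <- function(n_draws, seed, denominator = 10000L) {
  if (!is.finite(n_draws) || n_draws < 1)
    invalid_input("n_draws must be at least 1")
  n_draws <- as.integer(n_draws)
  set.seed(as.integer(seed))
  results <- list()
  failures <- list()
  note_failure <- function(property, risks, idx) {
    bad <- which(idx)[seq_len(min(3L, sum(idx)))]
    failures[[property]] <<- lapply(bad, function(i) list(
      when_exposed_in_exposed    = as.character(risks$ap[i]),
      when_unexposed_in_exposed  = as.character(risks$bp[i]),
      when_exposed_in_unexposed  = as.character(risks$aq[i]),
      when_unexposed_in_unexposed = as.character(risks$bq[i]),
      prevalence = as.character(risks$pi[i])))
  }

  # -- general random draws ---------------------------------------------
  g <- sample_risks(n_draws, denominator = denominator)
  cg <- conditions_vectorized(g$ap, g$bp, g$aq, g$bq, g$pi)

  # contrapositive: any non-exchangeable measure forces confounding in
  # distribution
  viol <- (!isTRUE_vec(cg$rd_exchangeable) | !isTRUE_vec(cg$rr_exchangeable)) &
          cg$distribution
  results$contrapositive <- !any(viol)
  if (any(viol)) note_failure("contrapositive", g, viol)

  # implication on draws *constructed* to have no confounding in
  # distribution (same risks in both groups)
  d <- g
  d$aq <- d$ap
  d$bq <- d$bp
  cd <- conditions_vectorized(d$ap, d$bp, d$aq, d$bq, d$pi)
  alpha0 <- (d$aq - d$ap) == 0
  beta1 <- ifelse(as.numeric(d$ap) > 0 & as.numeric(d$bp) > 0,
                  (d$aq * d$bq) == (d$ap * d$bp), TRUE)
  ok <- cd$distribution & cd$rd_measure &
        isTRUE_or_na(cd$rr_measure) & cd$rd_exchangeable &
        isTRUE_or_na(cd$rr_exchangeable) & alpha0 & beta1
  results$implication <- all(ok)
  if (!all(ok)) note_failure("implication", d, !ok)

  # alpha = 0 under RD-exchangeability is equivalent to no confounding in
  # distribution (and beta = 1 likewise), checked on the general draws
  zero_shift <- cg$rd_exchangeable & ((g$aq - g$ap) == 0)
  viol <- xor(zero_shift, cg$distribution)
  results$zero_shift_equivalence <- !any(viol)
  if (any(viol)) note_failure("zero_shift_equivalence", g, viol)
  unit_scale <- isTRUE_vec(cg$rr_exchangeable) & (g$ap > 0) & (g$aq == g$ap) &
    (g$bp == g$bq)
  both_pos <- (g$ap > 0) & (g$bp > 0) & (g$bq > 0)
  viol <- both_pos & xor(unit_scale, cg$distribution)
  results$unit_scale_equivalence <- !any(viol)
  if (any(viol)) note_failure("unit_scale_equivalence", g, viol)

  # -- prevalence fixed at 1/2 ------------------------------------------
  h <- sample_risks(n_draws, denominator = denominator,
                    prevalence = rational(1, 2))
  ch <- conditions_vectorized(h$ap, h$bp, h$aq, h$bq, h$pi)
  viol_rd <- xor(ch$rd_measure, ch$rd_exchangeable)
  both_eval <- !is.na(ch$rr_measure) & !is.na(ch$rr_exchangeable)
  viol_rr <- both_eval & xor(ch$rr_measure, ch$rr_exchangeable)
  results$half_prevalence <- !any(viol_rd) && !any(viol_rr)
  if (any(viol_rd | viol_rr)) note_failure("half_prevalence", h,
                                           viol_rd | viol_rr)

  # -- null special case at random prevalences --------------------------
  s <- g
  s$aq <- s$bp
  s$bq <- s$ap
  cs <- conditions_vectorized(s$ap, s$bp, s$aq, s$bq, s$pi)
  null_rd <- (s$ap - s$bq) == 0
  ok <- cs$rd_exchangeable & isTRUE_or_na(cs$rr_exchangeable) & null_rd
  results$null_special_case <- all(ok)
  if (!all(ok)) note_failure("null_special_case", s, !ok)

  # -- flip duality through the actual measure functions ----------------
  m <- min(n_draws, 200L)
  dual_ok <- vapply(seq_len(m), function(i) {
    pop <- grouped_population(
      exposed    = lift_risks(g$ap[i], g$bp[i]),
      unexposed  = lift_risks(g$aq[i], g$bq[i]),
      prevalence = g$pi[i])
    flipped <- flip_exposure(pop)
    all(vapply(MEASURE_SCALES, function(sc) {
      a <- factual_assoc(flipped, sc)
      b <- counterfactual_assoc(pop, sc)
      if (!is_defined(a) || !is_defined(b)) !is_defined(a) && !is_defined(b)
      else isTRUE(measure_rational(a) == measure_rational(b))
    }, logical(1)))
  }, logical(1))
  results$flip_duality <- all(dual_ok)
  if (!all(dual_ok))
    note_failure("flip_duality", g, c(!dual_ok, rep(FALSE, n_draws - m)))

  # -- rearranged-form agreement through the scalar functions -----------
  # (the scalar condition functions stop() if their algebraic forms ever
  # disagree, so evaluating them is the check)
  form_ok <- vapply(seq_len(m), function(i) {
    pop <- grouped_population(
      exposed    = lift_risks(g$ap[i], g$bp[i]),
      unexposed  = lift_risks(g$aq[i], g$bq[i]),
      prevalence = g$pi[i])
    summ <- condition_summary(pop)
    identical(summ$no_confounding_distribution, cg$distribution[i]) &&
      identical(summ$no_confounding_rd, cg$rd_measure[i]) &&
      identical(summ$no_confounding_rr, cg$rr_measure[i]) &&
      identical(summ$exchangeable_rd, cg$rd_exchangeable[i]) &&
      identical(summ$exchangeable_rr, cg$rr_exchangeable[i])
  }, logical(1))
  results$form_agreement <- all(form_ok)
  if (!all(form_ok))
    note_failure("form_agreement", g, c(!form_ok, rep(FALSE, n_draws - m)))

  # -- frozen odds-ratio witness ----------------------------------------
  w <- or_witness()
  xrr_or <- {
    f <- factual_assoc(w, "OR")
    cfa <- counterfactual_assoc(w, "OR")
    is_defined(f) && is_defined(cfa) &&
      measure_rational(f) == measure_rational(cfa)
  }
  meas_or <- {
    co <- causal_or(w, "total")
    f <- factual_assoc(w, "OR")
    is_defined(co) && is_defined(f) &&
      measure_rational(co) == measure_rational(f)
  }
  results$or_witness <- (w$prevalence == rational(1, 2)) && xrr_or && !meas_or

  structure(list(pass = all(unlist(results)), n_draws = n_draws,
                 seed = as.integer(seed), results = results,
                 failures = failures),
            class = "property_suite")
}

isTRUE_vec <- function(x) !is.na(x) & x
isTRUE_or_na <- function(x) is.na(x) | x

#' Odds-ratio witness population
#'
#' A frozen synthetic population with prevalence 1/2 whose associational odds
#' ratio is exchangeable under exposure flipping (both equal 2) while
#' confounding in the odds-ratio measure is present (causal OR 13/7 in the
#' total population). It witnesses that the prevalence-1/2 equivalence
#' between exchangeability and no confounding in measure holds for RD and RR
#' but not for the OR scale.
#'
#' @return A [grouped_population()].
#' @export
or_witness <- function() {
  grouped_population(
    exposed    = lift_risks("1/2", "2/3"),
    unexposed  = lift_risks("4/5", "1/3"),
    prevalence = "1/2")
}

#' @export
print.property_suite <- function(x, ...) {
  cat(sprintf("Property suite: %s (%d random draws, seed %d)\n",
              if (x$pass) "PASS" else "FAIL", x$n_draws, x$seed))
  for (nm in names(x$results))
    cat(sprintf("  %-24s %s\n", nm, if (x$results[[nm]]) "ok" else "VIOLATED"))
  invisible(x)
}
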