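# Population generators: the three pinned study fixtures, seeded random
# simplex sampling, and constructive samplers for populations satisfying a
# requested condition.

infeasible <- function(msg, ...) {
  stop(errorCondition(msg, ..., class = c("causalflip_infeasible",
                                          "causalflip_error")))
}

#' Pinned study populations
#'
#' Three hypothetical cohort studies used throughout the documentation and
#' tests (the target population is the total population in all of them):
#'
#' * `study1` -- exposed response-type counts (160, 200, 40, 200), unexposed
#'   (160, 40, 0, 200); exposure prevalence 3/5. Confounded in distribution,
#'   not in the RD measure, confounded in the RR measure; the associational
#'   RD is not exchangeable under flipping but the associational RR is, with
#'   scale constant beta = 5/6.
#' * `study2` -- the same two groups at prevalence 1/2, where exchangeability
#'   of an association measure coincides with no confounding in the same
#'   measure.
#' * `study3` -- study1's exposed group, with the unexposed group's factual
#'   outcome counts flipped so that its potential risks become 1/3 (when
#'   exposed) and 3/5 (when unexposed), realised canonically as the
#'   response-type distribution (1/3, 0, 4/15, 2/5). Both association
#'   measures are null and exchangeable (alpha = -4/15, beta = 5/9) although
#'   confounding is present in distribution and in both measures.
#'
#' @param id `"study1"`, `"study2"` or `"study3"`.
#' @return A [grouped_population()].
#' @examples
#' condition_summary(study_fixture("study1"))
#' @export
study_fixture <- function(id) {
  id <- match.arg(id, c("study1", "study2", "study3"))
  study1 <- from_response_type_counts(c(160, 200, 40, 200),
                                      c(160, 40, 0, 200))
  switch(id,
    study1 = study1,
    study2 = set_prevalence(study1, rational(1, 2)),
    study3 = grouped_population(
      exposed    = study1$p,
      unexposed  = response_type_distribution("1/3", "0", "4/15", "2/5"),
      prevalence = study1$prevalence
    ))
}

#' Replace the exposure prevalence
#'
#' Returns the population with the same two group compositions and a new
#' exposure prevalence. Factual and counterfactual association measures
#' depend only on the group compositions, so they are unchanged; only
#' total-target causal measures move.
#'
#' @param pop a [grouped_population()].
#' @param new_prevalence a proportion in `[0, 1]`.
#' @return A `grouped_population`.
#' @examples
#' s2 <- set_prevalence(study_fixture("study1"), "1/2")
#' causal_rd(s2, "total")  # 11/60
#' @export
set_prevalence <- function(pop, new_prevalence) {
  stopifnot(inherits(pop, "grouped_population"))
  grouped_population(pop$p, pop$q, as_rational(new_prevalence))
}

#' Lift a pair of potential risks to a response-type distribution
#'
#' A pair (risk when exposed, risk when unexposed) = (t1 + t2, t1 + t3)
#' determines a response-type distribution only up to one degree of freedom:
#' the doomed proportion t1 can be anything in
#' `[max(0, a + b - 1), min(a, b)]`. Every measure and condition in the
#' package depends on the risks alone, so the choice is observationally
#' irrelevant; the canonical default takes the maximal doomed proportion
#' `t1 = min(a, b)` (equivalently, zero preventive or zero causal types),
#' which keeps constructed fixtures reproducible.
#'
#' @param when_exposed,when_unexposed risks in `[0, 1]` (rationals or
#'   strings).
#' @param doomed optional override for t1 within the feasible interval.
#' @return A [response_type_distribution()].
#' @examples
#' lift_risks("1/2", "2/5")  # (2/5, 1/10, 0, 1/2)
#' @export
lift_risks <- function(when_exposed, when_unexposed, doomed = NULL) {
  a <- as_rational(when_exposed)
  b <- as_rational(when_unexposed)
  if (a < 0 || a > 1 || b < 0 || b > 1)
    invalid_input("risks must lie in [0, 1]")
  lo <- if (a + b > 1) a + b - 1 else rational(0)
  hi <- if (a <= b) a else b
  t1 <- if (is.null(doomed)) hi else as_rational(doomed)
  if (t1 < lo || t1 > hi)
    invalid_input(paste0("doomed proportion must lie in [",
                         as.character(lo), ", ", as.character(hi), "]"))
  response_type_distribution(t1, a - t1, b - t1, 1 - a - b + t1)
}

# largest-remainder rounding of a non-negative vector onto the lattice
# {k/D : sum k = D}; deterministic (ties broken by index order)
lattice_round <- function(x, D) {
  scaled <- x / sum(x) * D
  k <- floor(scaled)
  deficit <- round(D - sum(k))
  if (deficit > 0) {
    idx <- order(scaled - k, seq_along(x), decreasing = c(TRUE, FALSE),
                 method = "radix")[seq_len(deficit)]
    k[idx] <- k[idx] + 1
  }
  k
}

sample_simplex_counts <- function(n, concentration, D) {
  g <- matrix(rgamma(4L * n, shape = rep(concentration, each = n)), nrow = n)
  t(apply(g, 1L, lattice_round, D = D))
}

sample_prevalence_lattice <- function(n, D) {
  k <- pmin(pmax(round(runif(n) * D), 1), D - 1)  # interior: 0 < pi < 1
  rational(k, D)
}

#' Sample a random grouped population
#'
#' Draws the exposed- and unexposed-group response-type distributions
#' independently from a Dirichlet law with the given concentration, then
#' rounds each onto the exact lattice of fractions with the common
#' denominator `denominator` (largest-remainder method, so the four
#' proportions still sum to 1 exactly). The prevalence is either fixed or
#' drawn uniformly and rounded to the same lattice, clamped to the interior
#' so the total target population is always admissible. With a fixed seed the
#' output is reproducible.
#'
#' @param concentration positive length-4 Dirichlet concentration; the
#'   default `c(1, 1, 1, 1)` is uniform on the simplex.
#' @param prevalence `"uniform"` (default) or a fixed proportion.
#' @param denominator lattice denominator for the exact rounding (default
#'   `1e4`).
#' @param seed optional integer seed.
#' @return A [grouped_population()].
#' @examples
#' sample_population(seed = 1)
#' @export
sample_population <- function(concentration = c(1, 1, 1, 1),
                              prevalence = "uniform",
                              denominator = 10000L, seed = NULL) {
  stopifnot(length(concentration) == 4L, all(concentration > 0),
            denominator >= 4, denominator == floor(denominator))
  if (!is.null(seed)) set.seed(seed)
  kp <- sample_simplex_counts(1L, concentration, denominator)[1L, ]
  kq <- sample_simplex_counts(1L, concentration, denominator)[1L, ]
  pi <- if (identical(prevalence, "uniform"))
    sample_prevalence_lattice(1L, denominator)
  else as_rational(prevalence)
  grouped_population(
    exposed    = response_type_distribution(rational(kp, denominator)),
    unexposed  = response_type_distribution(rational(kq, denominator)),
    prevalence = pi
  )
}

# vectorised risk-space sampler used by the property suite: returns parallel
# scalar-rational vectors of the four potential risks and the prevalence
sample_risks <- function(n, concentration = c(1, 1, 1, 1),
                         denominator = 10000L, prevalence = NULL) {
  kp <- sample_simplex_counts(n, concentration, denominator)
  kq <- sample_simplex_counts(n, concentration, denominator)
  pi <- if (is.null(prevalence)) sample_prevalence_lattice(n, denominator)
        else rep(as_rational(prevalence), n)
  list(ap = rational(kp[, 1] + kp[, 2], denominator),
       bp = rational(kp[, 1] + kp[, 3], denominator),
       aq = rational(kq[, 1] + kq[, 2], denominator),
       bq = rational(kq[, 1] + kq[, 3], denominator),
       pi = pi)
}

#' Sample a population constructed to satisfy a condition
#'
#' Draws a random exposed-group distribution (or takes the one from `from`),
#' then *constructs* the unexposed group so that the requested condition
#' holds exactly, using the characterisations of the conditions in risk
#' space:
#'
#' * `"distribution"` -- the unexposed group gets the same pair of potential
#'   risks as the exposed group (no confounding in distribution).
#' * `"rd_shift"` -- the risks are shifted by `alpha`:
#'   risk-when-exposed + `alpha` for the unexposed group, and conversely, so
#'   the associational RD is exchangeable with shift constant `alpha`.
#' * `"rr_scale"` -- the risks are scaled by `beta`, making the associational
#'   RR exchangeable with scale constant `beta`.
#' * `"null_association"` -- the unexposed risks are the exposed risks
#'   swapped, the special case in which both association measures are null
#'   and exchangeable at every prevalence.
#'
#' The unexposed distribution is realised from its constructed risk pair via
#' [lift_risks()]. If the construction leaves a risk outside `[0, 1]` the
#' sampler redraws (up to `max_tries` times) and then signals an
#' infeasibility error; an `alpha` outside `[-1, 1]` or non-positive `beta`
#' is rejected immediately.
#'
#' @param condition one of `"distribution"`, `"rd_shift"`, `"rr_scale"`,
#'   `"null_association"`.
#' @param alpha shift constant in `[-1, 1]` (for `"rd_shift"`).
#' @param beta positive scale constant (for `"rr_scale"`).
#' @param from optional [grouped_population()] whose exposed group and
#'   prevalence are reused instead of sampling.
#' @param max_tries redraw budget before declaring infeasibility.
#' @inheritParams sample_population
#' @return A [grouped_population()] that verifiably satisfies the condition.
#' @examples
#' pop <- sample_satisfying("rd_shift", alpha = "1/10", seed = 7)
#' exchangeable_assoc_rd(pop)$constant  # 1/10
#' @export
sample_satisfying <- function(condition, alpha = NULL, beta = NULL,
                              from = NULL,
                              concentration = c(1, 1, 1, 1),
                              prevalence = "uniform",
                              denominator = 10000L, seed = NULL,
                              max_tries = 1000L) {
  condition <- match.arg(condition, c("distribution", "rd_shift", "rr_scale",
                                      "null_association"))
  if (condition == "rd_shift") {
    if (is.null(alpha)) invalid_input("rd_shift requires alpha")
    alpha <- as_rational(alpha)
    if (alpha < -1 || alpha > 1)
      infeasible("alpha must lie in [-1, 1]")
  }
  if (condition == "rr_scale") {
    if (is.null(beta)) invalid_input("rr_scale requires beta")
    beta <- as_rational(beta)
    if (!(beta > 0)) infeasible("beta must be positive")
  }
  if (!is.null(seed)) set.seed(seed)

  for (i in seq_len(max_tries)) {
    if (!is.null(from)) {
      base <- from
    } else {
      base <- sample_population(concentration, prevalence, denominator)
    }
    r <- risks_of(base)
    target <- switch(condition,
      distribution     = list(a = r$ap, b = r$bp),
      rd_shift         = list(a = r$ap + alpha, b = r$bp - alpha),
      rr_scale         = list(a = r$ap * beta, b = r$bp / beta),
      null_association = list(a = r$bp, b = r$ap))
    feasible <- target$a >= 0 && target$a <= 1 &&
                target$b >= 0 && target$b <= 1
    if (feasible) {
      return(grouped_population(
        exposed    = base$p,
        unexposed  = lift_risks(target$a, target$b),
        prevalence = base$prevalence))
    }
    if (!is.null(from)) break  # a fixed base either works or never will
  }
  infeasible(paste0("could not realise condition '", condition,
                    "': constructed unexposed risks fall outside [0, 1]"))
}
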