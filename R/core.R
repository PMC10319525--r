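# Core containers: response-type distributions, grouped populations with an
# exposure prevalence, potential risks, and factual 2x2 tables.

invalid_input <- function(msg, ...) {
  stop(errorCondition(msg, ..., class = c("causalflip_invalid_input", "causalflip_error")))
}

RESPONSE_TYPES <- c("doomed", "causal", "preventive", "immune")

#' Response-type distribution
#'
#' In the potential-outcomes framework each individual has a pair of potential
#' outcomes \eqn{(D^1, D^0)}: the outcome if exposed and if unexposed. The four
#' possible pairs define the classical response types: *doomed* (1,1),
#' *causal* (1,0), *preventive* (0,1) and *immune* (0,0). A
#' `response_type_distribution` is a point on the 4-simplex giving the exact
#' proportion of each type in some group; the four proportions must be
#' non-negative and sum to 1 exactly.
#'
#' @param doomed,causal,preventive,immune proportions of each type, given as
#'   `rational` values or strings such as `"4/15"` (see [as_rational()]).
#'   Alternatively pass a single length-4 `rational` vector as `doomed`.
#' @return An object of class `response_types`: a named length-4 `rational`
#'   vector wrapper.
#' @examples
#' response_type_distribution("4/15", "5/15", "1/15", "5/15")
#' @export
response_type_distribution <- function(doomed, causal = NULL, preventive = NULL,
                                       immune = NULL) {
  if (is.null(causal) && length(doomed) == 4L) {
    t <- as_rational(doomed)
  } else {
    t <- c(as_rational(doomed), as_rational(causal),
           as_rational(preventive), as_rational(immune))
  }
  if (length(t) != 4L)
    invalid_input("a response-type distribution needs exactly 4 proportions")
  names(t) <- RESPONSE_TYPES
  if (any(t < 0))
    invalid_input("response-type proportions must be non-negative")
  if (!(sum(t) == 1))
    invalid_input(paste0("response-type proportions must sum to 1 exactly; got ",
                         as.character(sum(t))))
  structure(list(t = t), class = "response_types")
}

#' @export
print.response_types <- function(x, ...) {
  cat("Response-type distribution (doomed, causal, preventive, immune):\n  ",
      paste(as.character(x$t), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
`==.response_types` <- function(e1, e2) all(e1$t == e2$t)

as_response_types <- function(x) {
  if (inherits(x, "response_types")) return(x)
  response_type_distribution(x)
}

#' Grouped population
#'
#' The full data object of the calculus: a response-type distribution for the
#' exposed group, one for the unexposed group, and the exposure prevalence
#' Pr(E = 1). Analyses that take the *total* population as the target
#' additionally require an interior prevalence (0 < Pr(E = 1) < 1); a
#' degenerate prevalence of exactly 0 or 1 is allowed here but flagged with an
#' attribute, and condition/measure functions specialise to the corresponding
#' single-group target.
#'
#' @param exposed,unexposed response-type distributions (see
#'   [response_type_distribution()]), or anything coercible to one.
#' @param prevalence exposure prevalence Pr(E = 1) in `[0, 1]`, as a rational
#'   or string.
#' @return An object of class `grouped_population` with elements `p`
#'   (exposed-group distribution), `q` (unexposed-group distribution) and
#'   `prevalence`.
#' @examples
#' grouped_population(
#'   exposed   = response_type_distribution("4/15", "5/15", "1/15", "5/15"),
#'   unexposed = response_type_distribution("4/10", "1/10", "0", "5/10"),
#'   prevalence = "3/5"
#' )
#' @export
grouped_population <- function(exposed, unexposed, prevalence) {
  p <- as_response_types(exposed)
  q <- as_response_types(unexposed)
  pi <- as_rational(prevalence)
  if (length(pi) != 1L || pi < 0 || pi > 1)
    invalid_input("prevalence must be a single proportion in [0, 1]")
  structure(list(p = p, q = q, prevalence = pi), class = "grouped_population")
}

#' @export
print.grouped_population <- function(x, ...) {
  cat("Grouped population, Pr(E = 1) =", as.character(x$prevalence), "\n")
  cat("  exposed   (p):", paste(as.character(x$p$t), collapse = ", "), "\n")
  cat("  unexposed (q):", paste(as.character(x$q$t), collapse = ", "), "\n")
  invisible(x)
}

has_interior_prevalence <- function(pop) {
  pop$prevalence > 0 && pop$prevalence < 1
}

#' Marginal (total-population) response-type distribution
#'
#' Mixes the exposed- and unexposed-group distributions by the exposure
#' prevalence: \eqn{r_i = p_i \Pr(E=1) + q_i \Pr(E=0)}. The result is the
#' response-type distribution of the total population and sums to 1 exactly.
#'
#' @param p,q response-type distributions of the exposed and unexposed groups,
#'   or a single `grouped_population` as `p`.
#' @param prevalence exposure prevalence (ignored when `p` is a population).
#' @return A `response_types` object.
#' @export
marginal_distribution <- function(p, q = NULL, prevalence = NULL) {
  if (inherits(p, "grouped_population")) {
    prevalence <- p$prevalence
    q <- p$q
    p <- p$p
  }
  p <- as_response_types(p)
  q <- as_response_types(q)
  pi <- as_rational(prevalence)
  r <- p$t * pi + q$t * (rational(1) - pi)
  response_type_distribution(r)
}

#' Potential risks of a grouped population
#'
#' The four identifying quantities of the calculus: the risk each group would
#' have under exposure and under no exposure,
#' \deqn{\Pr(D^1=1 \mid E=1) = p_1+p_2, \quad \Pr(D^0=1 \mid E=1) = p_1+p_3,}
#' \deqn{\Pr(D^1=1 \mid E=0) = q_1+q_2, \quad \Pr(D^0=1 \mid E=0) = q_1+q_3.}
#' Under consistency the factual group risks are
#' \eqn{\Pr(D=1|E=1) = p_1+p_2} and \eqn{\Pr(D=1|E=0) = q_1+q_3}. Every
#' measure and condition in the package is a function of these four risks
#' alone.
#'
#' @param pop a `grouped_population`.
#' @return A `potential_risks` object: a named length-4 `rational` vector with
#'   names `exposed.when_exposed`, `exposed.when_unexposed`,
#'   `unexposed.when_exposed`, `unexposed.when_unexposed`.
#' @export
potential_risks <- function(pop) {
  r <- risks_of(pop)
  out <- c(r$ap, r$bp, r$aq, r$bq)
  names(out) <- c("exposed.when_exposed", "exposed.when_unexposed",
                  "unexposed.when_exposed", "unexposed.when_unexposed")
  structure(list(r = out), class = "potential_risks")
}

#' @export
print.potential_risks <- function(x, ...) {
  v <- as.character(x$r)
  cat("Potential risks Pr(D^e = 1 | E = e'):\n")
  cat(sprintf("  exposed group   (E=1): when exposed %s, when unexposed %s\n",
              v[1], v[2]))
  cat(sprintf("  unexposed group (E=0): when exposed %s, when unexposed %s\n",
              v[3], v[4]))
  invisible(x)
}

# internal: the four risk sums as scalar rationals
# ap = Pr(D^1=1|E=1), bp = Pr(D^0=1|E=1), aq = Pr(D^1=1|E=0), bq = Pr(D^0=1|E=0)
risks_of <- function(pop) {
  stopifnot(inherits(pop, "grouped_population"))
  p <- pop$p$t
  q <- pop$q$t
  list(ap = p[1] + p[2], bp = p[1] + p[3],
       aq = q[1] + q[2], bq = q[1] + q[3],
       pi = pop$prevalence)
}

#' Build a population from response-type counts
#'
#' Converts per-group counts of the four response types (the unobservable
#' individual-level table) into exact group proportions and an exposure
#' prevalence equal to the exposed share of the grand total.
#'
#' @param exposed_counts,unexposed_counts non-negative integer vectors of
#'   length 4, ordered doomed, causal, preventive, immune.
#' @return A `grouped_population`.
#' @examples
#' from_response_type_counts(c(160, 200, 40, 200), c(160, 40, 0, 200))
#' @export
from_response_type_counts <- function(exposed_counts, unexposed_counts) {
  check_counts <- function(x, lab) {
    if (length(x) != 4L || any(!is.finite(x)) || any(x < 0) || any(x != floor(x)))
      invalid_input(paste0(lab, " must be 4 non-negative integers"))
    if (sum(x) == 0)
      invalid_input(paste0(lab, " has zero total"))
  }
  check_counts(exposed_counts, "exposed_counts")
  check_counts(unexposed_counts, "unexposed_counts")
  ne <- sum(exposed_counts)
  nu <- sum(unexposed_counts)
  grouped_population(
    exposed    = response_type_distribution(rational(exposed_counts, ne)),
    unexposed  = response_type_distribution(rational(unexposed_counts, nu)),
    prevalence = rational(ne, ne + nu)
  )
}

#' Observed 2x2 exposure-outcome table
#'
#' The factual, association-only view of a cohort: counts of exposed/unexposed
#' individuals with and without the outcome. Carries no counterfactual
#' information, so only associational measures are identified from it.
#'
#' @param a exposed with outcome; @param b unexposed with outcome;
#' @param c exposed without outcome; @param d unexposed without outcome.
#' @return An `observed_table` object.
#' @examples
#' observed_table(a = 360, b = 160, c = 240, d = 240)
#' @export
observed_table <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(x)) || any(x < 0) || any(x != floor(x)))
    invalid_input("table counts must be non-negative integers")
  structure(as.list(x), class = "observed_table")
}

#' @export
print.observed_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), nrow = 2, byrow = TRUE,
              dimnames = list(c("D = 1", "D = 0"),
                              c("Exposed (E=1)", "Unexposed (E=0)")))
  print(m)
  invisible(x)
}

#' Observed group risks from a 2x2 table
#'
#' @param table an [observed_table()].
#' @return A named length-2 `rational` vector: risk in the exposed group
#'   `a/(a+c)` and in the unexposed group `b/(b+d)`.
#' @export
observed_risks <- function(table) {
  stopifnot(inherits(table, "observed_table"))
  if (table$a + table$c == 0)
    invalid_input("exposed group is empty; its risk is undefined")
  if (table$b + table$d == 0)
    invalid_input("unexposed group is empty; its risk is undefined")
  out <- c(rational(table$a, table$a + table$c),
           rational(table$b, table$b + table$d))
  names(out) <- c("exposed", "unexposed")
  out
}

#' Factual 2x2 table implied by a population
#'
#' Collapses a grouped population to the observed exposure-outcome counts it
#' would produce at a given total size: under consistency the exposed show the
#' outcome with probability \eqn{p_1+p_2} and the unexposed with probability
#' \eqn{q_1+q_3}. All four counts must come out as exact integers; otherwise
#' the error reports the smallest total that works.
#'
#' @param pop a `grouped_population`.
#' @param total total number of individuals.
#' @return An [observed_table()].
#' @examples
#' s1 <- study_fixture("study1")
#' observed_table_of(s1, 1000)  # 360 / 160 / 240 / 240
#' @export
observed_table_of <- function(pop, total) {
  stopifnot(inherits(pop, "grouped_population"))
  if (!is.finite(total) || total <= 0 || total != floor(total))
    invalid_input("total must be a positive integer")
  r <- risks_of(pop)
  pi <- r$pi
  cells <- c(pi * r$ap, (rational(1) - pi) * r$bq,
             pi * (1 - r$ap), (rational(1) - pi) * (1 - r$bq))
  minimal <- Reduce(lcm_num, denominator(cells))
  counts <- as_rational(total) * cells
  if (any(denominator(counts) != 1))
    invalid_input(
      paste0("population does not yield integer counts at total = ", total,
             "; smallest valid total is ", minimal),
      minimal_total = minimal)
  k <- numerator(counts)
  observed_table(a = k[1], b = k[2], c = k[3], d = k[4])
}

lcm_num <- function(a, b) {
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  a / g(a, b) * b
}
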