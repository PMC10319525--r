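---
title: "Confounding and exchangeability of association measures: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confounding and exchangeability of association measures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalflip)
```

## The model

causalflip works in the potential-outcomes (counterfactual) model of a
cohort with a binary exposure $E$ and binary outcome $D$. Each individual
carries two potential outcomes $D^1$ and $D^0$ — the outcome that would
occur under exposure and under no exposure — and is therefore one of four
*response types*:

| type | $D^1$ | $D^0$ | |
|---|---|---|---|
| 1 | 1 | 1 | doomed |
| 2 | 1 | 0 | causal |
| 3 | 0 | 1 | preventive |
| 4 | 0 | 0 | immune |

A population is described by the exact proportions of the four types in the
exposed group ($p_1,\dots,p_4$), in the unexposed group ($q_1,\dots,q_4$),
and by the exposure prevalence $\pi = \Pr(E=1)$. The marginal
(total-population) composition is the mixture
$r_i = p_i\,\pi + q_i\,(1-\pi)$. Everything the package computes is a
function of four *potential risks*:

$$a_p = \Pr(D^1{=}1\mid E{=}1) = p_1+p_2,\qquad b_p = \Pr(D^0{=}1\mid E{=}1) = p_1+p_3,$$
$$a_q = \Pr(D^1{=}1\mid E{=}0) = q_1+q_2,\qquad b_q = \Pr(D^0{=}1\mid E{=}0) = q_1+q_3.$$

Under consistency the factual group risks are $a_p$ (exposed) and $b_q$
(unexposed); $b_p$ and $a_q$ are counterfactual and unobservable, which is
precisely why confounding cannot be diagnosed from a 2×2 table alone
(`analyze()` on an `observed_table` therefore reports causal and
counterfactual quantities as *not identified*).

The model deliberately describes **expected data only**: proportions are
exact, there is no sampling variability, no loss to follow-up and no
measurement error. Consequently the package decides conditions by exact
equality, and the distinction between confounding in expectation and
realized confounding never arises — it is out of scope by construction.

## Estimands and conditions

Causal measures are target-relative. For a target population with risk pair
$(R^1, R^0)$ — $(a_p,b_p)$ for the exposed target, $(a_q,b_q)$ for the
unexposed, the $\pi$-mixture for the total population — the package computes
$\mathrm{cRD} = R^1 - R^0$, $\mathrm{cRR} = R^1/R^0$ and an odds-ratio
analogue. The target argument is mandatory everywhere: a causal estimand
without a stated target is not a number.

The association measures come in a factual and an exposure-flipped
(counterfactual) version:

$$\mathrm{aRD}_{\text{fact}} = a_p - b_q, \qquad
  \mathrm{aRD}_{\text{flip}} = a_q - b_p,$$

and analogously for ratios. Flipping the population (`flip_exposure()`)
swaps the groups and complements the prevalence; the factual measures of the
flipped population are exactly the counterfactual measures of the original,
and this duality is verified on random draws in the test suite.

Six conditions are decided exactly:

1. **No confounding in distribution**: $a_p = a_q$ and $b_p = b_q$
   (equivalently $D^e \perp E$). Scale-independent, and the strongest of the
   conditions.
2. **No confounding in the RD measure**: $\mathrm{cRD}_{\text{total}} =
   \mathrm{aRD}_{\text{fact}}$, equivalently
   $b_p\pi + a_p(1-\pi) = b_q\pi + a_q(1-\pi)$ — visibly
   prevalence-dependent.
3. **No confounding in the RR measure**: $\mathrm{cRR}_{\text{total}} =
   \mathrm{aRR}_{\text{fact}}$, equivalently
   $a_p(b_p-b_q)\pi = b_q(a_q-a_p)(1-\pi)$.
4. **Exchangeability of the associational RD**:
   $a_p - b_q = a_q - b_p$, equivalently a single shift constant
   $\alpha \in [-1,1]$ with $a_q = a_p + \alpha$ and $b_p = b_q + \alpha$.
5. **Exchangeability of the associational RR**:
   $a_p/b_q = a_q/b_p$, equivalently a scale constant $\beta > 0$ with
   $a_q = a_p\beta$ and $b_p = b_q\beta$.
6. **Exchangeability of background risks**: $b_p = b_q$.

Their logical geometry — the reason the package exists — is:

* condition 1 implies all the others, with $\alpha = 0$ and $\beta = 1$;
  conversely $\alpha = 0$ (or $\beta = 1$) under exchangeability brings
  condition 1 back.
* non-exchangeability on either scale is *sufficient* for confounding in
  distribution, but exchangeability certifies nothing: in the `study3`
  fixture both association measures are null and exchangeable while
  confounding is present in distribution and in both measures (the "null
  special case" $a_p = b_q$, $b_p = a_q$, which forces conditions 4–5 at
  every prevalence).
* conditions 2 and 4 (and 3 and 5) are logically incomparable in general —
  `study1` witnesses both directions of failure — but coincide when
  $\pi = 1/2$. That equivalence is specific to the difference and ratio
  scales: the shipped `or_witness()` population (prevalence 1/2,
  associational OR exchangeable at 2, causal OR 13/7) shows it fails for
  odds ratios.

All of these are verified by `run_property_suite()` on seeded random
populations, plus constructed ones where a premise (such as condition 1)
would almost surely never occur in a random draw.

Every multi-form condition is evaluated in each algebraic form and the forms
are asserted to agree at run time; a disagreement is treated as an internal
arithmetic error, not a verdict.

### Three-valued verdicts

Ratio-scale conditions are undefined when a denominator risk is 0. The
package returns `NA` ("not evaluable", rendered `n/e`) in that case rather
than `FALSE` or an error: a condition that cannot be stated is different
from one that fails. The constants are extracted only when they exist:
$\alpha$ requires condition 4 to hold; $\beta$ additionally requires
positive risks (an all-immune pair of groups is exchangeable but
scale-free). The always-computable differences $a_q - a_p$ and $b_p - b_q$
are exposed as diagnostics instead of an "$\alpha$" that the theory does not
define. The bounds on $\alpha$ are enforced as the closed interval
$[-1, 1]$; both endpoints are attainable (an all-preventive exposed group
against an all-causal unexposed group realises $\alpha = 1$).

### Degenerate prevalence

A prevalence of exactly 0 or 1 is legal in the data object but makes the
total target population ill-defined. Measure functions refuse
`target = "total"` there, and conditions 2–3 specialise to the
corresponding single-group target (at $\pi = 1$ the RD condition reduces to
$b_p = b_q$, at $\pi = 0$ to $a_p = a_q$). Condition 1 always compares the
two groups directly.

### Background risks

Condition 6 operationalises the "background risk" as the risk under no
exposure, so its exchangeability is $b_p = b_q$ — one conjunct of condition
1, hence necessary but not sufficient for it, and neither necessary nor
sufficient for no confounding in measure. This reading (risk not caused by
the exposure) is provisional: the term is used loosely in the literature,
and other formalisations exist. The verdict is reported separately from the
five main conditions so users can ignore it.

## Exact arithmetic

The acceptance surface of this calculus is printed fractions (1/5, 14/9,
5/6, −4/15, …), and its conditions are *equalities*. Floating point would
force tolerances and make "True/False" verdicts tolerance-dependent, so the
canonical number type is an exact rational vector class backed by a small
C++ kernel:

* numerators and denominators are 53-bit integers stored in doubles;
  every operation reduces to lowest terms with a positive denominator;
* intermediates (cross-products, sums) are taken in 128-bit integers, so no
  operation on in-range operands can overflow silently;
* a *reduced* result that no longer fits in 53 bits raises an error —
  exactness is never traded for range without telling the user.

Inputs are interpreted exactly: `"3/5"` as a fraction, `"0.35"` as the
decimal literal 35/100, and JSON numbers through their decimal printing —
never through the binary double. Arithmetic between rationals and plain R
numerics is allowed only for integer-valued numerics; `r == 0.1` is an
error, because the double `0.1` is not the number the user wrote. Users who
want approximate comparisons can drop to `as.numeric()` and use an explicit
tolerance (1e-9 is ample for anything this package produces).

## The population generator

`sample_population()` draws each group's composition from a Dirichlet law
(default concentration $(1,1,1,1)$, i.e. uniform on the simplex) and then
rounds it onto the lattice of fractions with a **common denominator**
(default $10^4$) by the largest-remainder method, so the four proportions
still sum to 1 exactly. The prevalence is drawn uniformly and rounded to the
same lattice, clamped to the open interval so the total target is always
admissible.

The common-denominator lattice is a deliberate design choice: rationalising
each proportion separately (e.g. by continued fractions) yields
incommensurable denominators whose least common multiples explode past the
exact range once sums, mixtures and cross-products are taken, while a
common lattice keeps every quantity the condition predicates need —
risk sums, prevalence mixtures, products of three factors — well inside
53 bits. A denominator of $10^4$ makes ties and boundary cases (risks
exactly 0, 1, or equal) reachable with small probability while approximating
the continuous Dirichlet closely; the empirical per-type mean over $10^4$
draws is within 0.01 of the theoretical 1/4 under the uniform concentration.

`sample_satisfying()` constructs, rather than rejects into, populations
satisfying a requested condition: it draws the exposed group, builds the
unexposed group's risk pair from the condition's characterisation
($\alpha$-shift, $\beta$-scale, equality, or swap), and realises that pair
as a composition via `lift_risks()`. A constructed risk outside $[0,1]$
triggers a redraw and eventually an explicit infeasibility error.

### Lifting risks to compositions

A risk pair $(a, b) = (t_1+t_2,\, t_1+t_3)$ under-determines the
composition by one degree of freedom, $t_1 \in [\max(0, a+b-1),
\min(a,b)]$. Since every measure and condition depends on $(a,b)$ alone,
the choice is observationally irrelevant; the package fixes the canonical
lift $t_1 = \min(a,b)$ (maximal doomed proportion, so the smaller of the
causal/preventive proportions is zero) to keep constructed fixtures
byte-reproducible, and exposes the `doomed` argument for any other choice.
The `study3` fixture is pinned this way: its defining inputs are the flip
construction's risk pair (1/3, 3/5) for the unexposed group, and the
canonical lift gives the composition (1/3, 0, 4/15, 2/5); any other lift
yields identical measures and verdicts.

## Problem sizes

The shipped test suite decides the three study fixtures exactly, runs the
property suite at 1 000 draws for fast feedback, and the acceptance checks
at 10 000 draws (a few seconds of CPU: the property predicates are evaluated
on vectorised rational arithmetic, so $10^4$ populations cost a few hundred
C++ calls). Per-draw duality and cross-form agreement, which go through the
scalar user-facing functions, use a 200-draw subsample.

## What passing tests do and do not show

The generator emulates the calculus's own universe — exact expected-data
populations on a fine lattice — and the property suite therefore verifies
*logical* claims: implications, equivalences and witnesses among the
conditions. It says nothing about finite-sample behaviour on real cohorts:
there is no binomial noise, no confidence statement, and a real study's
verdicts would be estimates, not decisions. The package diagnoses
confounding given counterfactual knowledge; it does not adjust for it,
select confounders, or standardise beyond the three internal target
populations, and the odds-ratio scale is provided as an extension of the
same four risks rather than as part of the core calculus.
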