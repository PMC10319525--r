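# causalflip

Exact counterfactual arithmetic for confounding and for the exchangeability
of association measures under exposure flipping.

## The problem

In the potential-outcomes model of a cohort with binary exposure *E* and
binary outcome *D*, every individual has a pair of potential outcomes
(*D*¹, *D*⁰) and is one of four response types — doomed (1,1), causal
(1,0), preventive (0,1), immune (0,0). A population is a pair of
response-type distributions, *p* for the exposed group and *q* for the
unexposed, plus the exposure prevalence π = Pr(*E* = 1). Four potential
risks determine everything:

    a_p = p1 + p2 = Pr(D¹=1 | E=1)      b_p = p1 + p3 = Pr(D⁰=1 | E=1)
    a_q = q1 + q2 = Pr(D¹=1 | E=0)      b_q = q1 + q3 = Pr(D⁰=1 | E=0)

From these the package computes causal risk differences/ratios for an
explicit target population (total, exposed, or unexposed), the factual
association measures (a_p vs b_q) and their counterfactual versions after
*flipping* everyone's exposure (a_q vs b_p), and decides — by exact
rational arithmetic, with no floating-point tolerance — the conditions of

* **no confounding in distribution**: a_p = a_q and b_p = b_q;
* **no confounding in measure** on the RD scale
  (cRD_total = aRD_factual) and on the RR scale (cRR_total = aRR_factual);
* **exchangeability of association measures** under flipping:
  aRD_factual = aRD_flipped, characterised by a shift constant
  α ∈ [−1, 1] (a_q = a_p + α, b_p = b_q + α), and
  aRR_factual = aRR_flipped, characterised by a scale constant β > 0
  (a_q = a_p·β, b_p = b_q·β);
* **exchangeability of background risks**: b_p = b_q.

The point of the calculus is the logical geometry of these conditions:
no confounding in distribution implies all the others (with α = 0, β = 1);
non-exchangeability implies confounding in distribution, but
exchangeability certifies nothing; measure-confounding and exchangeability
are incomparable in general yet equivalent at prevalence 1/2 on the RD and
RR scales — and provably *not* on the OR scale. A seeded simulator and
property suite verify all of this on tens of thousands of exact random
populations. It is a diagnostic and teaching tool for epidemiologists and
biostatisticians; it does not adjust for confounding.

## Worked example

Three hypothetical cohort studies ship as fixtures. Study 1 has exposed
response-type counts (160, 200, 40, 200), unexposed (160, 40, 0, 200), so
π = 3/5:

```r
library(causalflip)
s1 <- study_fixture("study1")
analyze(s1, label = "study1")
```

```
Analysis: study1
Exposure prevalence Pr(E = 1) = 3/5

Potential risks:
  exposed.when_exposed         3/5
  exposed.when_unexposed       1/3
  unexposed.when_exposed       1/2
  unexposed.when_unexposed     2/5

Measures of effect (causal), by target population:
  total      cRD = 1/5, cRR = 14/9, cOR = 224/99
  exposed    cRD = 4/15, cRR = 9/5, cOR = 3
  unexposed  cRD = 1/10, cRR = 5/4, cOR = 3/2

Measures of association:
  factual         aRD = 1/5, aRR = 3/2, aOR = 9/4
  counterfactual  aRD = 1/6, aRR = 3/2, aOR = 2

Conditions:
Study: study1 
  No confounding in distribution                    False
  No confounding in risk difference                 True
  No confounding in risk ratio                      False
  Exchangeability of associational risk difference  False
  Exchangeability of associational risk ratio       True
  Exchangeability of background risks               False
  beta (RR scale)  = 5/6
```

Reading the output: the observed contrast aRD = 1/5 happens to equal the
causal cRD in the total population (no confounding in the RD *measure*),
yet the groups are not exchangeable in distribution, and flipping exposure
changes the associational RD to 1/6 — so RD-exchangeability fails. On the
ratio scale the pattern reverses: the causal cRR 14/9 differs from the
associational 3/2 (confounding in the RR measure) while the factual and
flipped aRR are both 3/2, exchangeable with β = 5/6. Scale matters, and
neither notion of confounding is captured by flipping alone.

Other entry points: `from_response_type_counts()`, `read_population()`
(JSON schema under `inst/extdata/`), `observed_table()` /
`read_observed_table()` for association-only 2×2 data,
`sample_population()` / `sample_satisfying()` for seeded simulation,
`run_property_suite()` for the logical checks, and a thin command-line
front end at `inst/cli/causalflip.R` (`analyze`, `summarize`, `fixture`,
`simulate`, `transform`, `check`).

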