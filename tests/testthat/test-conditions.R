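studies <- lapply(setNames(c("study1", "study2", "study3"),
                           c("study1", "study2", "study3")), study_fixture)

test_that("no confounding in distribution is decided from the risk pairs", {
  expect_false(no_confounding_in_distribution(studies$study1))
  u <- response_type_distribution("1/4", "1/4", "1/4", "1/4")
  expect_true(no_confounding_in_distribution(grouped_population(u, u, "1/3")))
  # constructed so both risk pairs agree while the compositions differ:
  # q has q1+q2 = 9/15 = p1+p2 and q1+q3 = 5/15 = p1+p3
  p <- response_type_distribution("4/15", "5/15", "1/15", "5/15")
  q <- response_type_distribution("5/15", "4/15", "0", "6/15")
  mixed <- grouped_population(p, q, "1/2")
  expect_false(all(p$t == q$t))
  expect_true(no_confounding_in_distribution(mixed))
})

test_that("confounding in measure is scale- and prevalence-dependent", {
  expect_true(no_confounding_in_rd(studies$study1))
  expect_false(no_confounding_in_rr(studies$study1))
  # same groups, prevalence moved to 1/2: the verdicts swap
  expect_false(no_confounding_in_rd(studies$study2))
  expect_true(no_confounding_in_rr(studies$study2))
  u <- response_type_distribution("1/4", "1/4", "1/4", "1/4")
  both <- grouped_population(u, u, "1/3")
  expect_true(no_confounding_in_rd(both))
  expect_true(no_confounding_in_rr(both))
})

test_that("ratio conditions report not-evaluable on zero denominators", {
  immune <- response_type_distribution(0, 0, 0, 1)
  doomed <- response_type_distribution(1, 0, 0, 0)
  pop <- grouped_population(doomed, immune, "1/2")  # q1+q3 = 0
  expect_true(is.na(no_confounding_in_rr(pop)))
  expect_true(is.na(exchangeable_assoc_rr(pop)$exchangeable))
  # NA is distinct from FALSE in the report rendering
  out <- capture.output(print(condition_summary(pop)))
  expect_true(any(grepl("n/e", out)))
})

test_that("degenerate prevalence specialises measure conditions to one group", {
  s1 <- study_fixture("study1")
  all_exposed <- set_prevalence(s1, 1)
  # with target = exposed both contrasts use the same factual risk ap, so
  # RD-confounding reduces to bp == bq
  expect_false(no_confounding_in_rd(all_exposed))  # 1/3 != 2/5
  eq <- grouped_population(s1$p, lift_risks("1/2", "1/3"), 1)
  expect_true(no_confounding_in_rd(eq))
  expect_true(no_confounding_in_rr(eq))
  # distribution condition still compares p and q directly
  expect_false(no_confounding_in_distribution(eq))
})

test_that("RD exchangeability extracts the shift constant alpha", {
  x1 <- exchangeable_assoc_rd(studies$study1)
  expect_false(x1$exchangeable)
  expect_null(x1$constant)
  # diagnostics are computable regardless of the verdict
  expect_exact(x1$diagnostics$shift_when_exposed, "-1/10")
  expect_exact(x1$diagnostics$shift_when_unexposed, "-1/15")
  x3 <- exchangeable_assoc_rd(studies$study3)
  expect_true(x3$exchangeable)
  expect_exact(x3$constant, "-4/15")
  # null association both ways: alpha = 0
  sym <- response_type_distribution("1/8", "2/8", "2/8", "3/8")  # t2 = t3
  x0 <- exchangeable_assoc_rd(grouped_population(sym, sym, "1/3"))
  expect_true(x0$exchangeable)
  expect_exact(x0$constant, "0")
})

test_that("RR exchangeability extracts the scale constant beta", {
  x1 <- exchangeable_assoc_rr(studies$study1)
  expect_true(x1$exchangeable)
  expect_exact(x1$constant, "5/6")
  x3 <- exchangeable_assoc_rr(studies$study3)
  expect_true(x3$exchangeable)
  expect_exact(x3$constant, "5/9")
  sym <- response_type_distribution("1/8", "2/8", "2/8", "3/8")
  x0 <- exchangeable_assoc_rr(grouped_population(sym, sym, "1/3"))
  expect_true(x0$exchangeable)
  expect_exact(x0$constant, "1")
  # beta needs positive risks: all-immune groups are exchangeable but scale-free
  immune <- response_type_distribution(0, 0, 0, 1)
  degen <- grouped_population(
    response_type_distribution("1/2", 0, 0, "1/2"), immune, "1/2")
  expect_true(is.na(exchangeable_assoc_rr(degen)$exchangeable))
})

test_that("background-risk exchangeability is the unexposed-risk equality", {
  expect_false(background_risk_exchangeable(studies$study1))  # 1/3 vs 2/5
  u <- response_type_distribution("1/4", "1/4", "1/4", "1/4")
  expect_true(background_risk_exchangeable(grouped_population(u, u, "1/3")))
  # implied by no confounding in distribution
  p <- response_type_distribution("4/15", "5/15", "1/15", "5/15")
  q <- response_type_distribution("5/15", "4/15", "0", "6/15")
  pop <- grouped_population(p, q, "1/2")
  expect_true(no_confounding_in_distribution(pop))
  expect_true(background_risk_exchangeable(pop))
  # ...but does not imply it: exchangeable background with confounding present
  pop2 <- grouped_population(lift_risks("2/3", "1/3"), lift_risks("1/4", "1/3"),
                             "1/2")
  expect_true(background_risk_exchangeable(pop2))
  expect_false(no_confounding_in_distribution(pop2))
})

test_that("condition summaries reproduce the three-study verdict grid", {
  grid <- list(
    study1 = c(FALSE, TRUE, FALSE, FALSE, TRUE),
    study2 = c(FALSE, FALSE, TRUE, FALSE, TRUE),
    study3 = c(FALSE, FALSE, FALSE, TRUE, TRUE))
  for (id in names(grid)) {
    s <- condition_summary(studies[[id]], label = id)
    expect_equal(c(s$no_confounding_distribution, s$no_confounding_rd,
                   s$no_confounding_rr, s$exchangeable_rd, s$exchangeable_rr),
                 grid[[id]], info = id)
  }
  s1 <- condition_summary(studies$study1)
  expect_null(s1$alpha)
  expect_exact(s1$beta, "5/6")
  s3 <- condition_summary(studies$study3)
  expect_exact(s3$alpha, "-4/15")
  expect_exact(s3$beta, "5/9")
  out <- capture.output(print(condition_summary(studies$study1, label = "study1")))
  expect_true(any(grepl("No confounding in risk difference\\s+True", out)))
  expect_true(any(grepl("beta.*5/6", out)))
})
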