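test_that("study fixtures are pinned to their published summaries", {
  s1 <- study_fixture("study1")
  s2 <- study_fixture("study2")
  s3 <- study_fixture("study3")
  expect_exact(s1$prevalence, "3/5")
  expect_exact(s2$prevalence, "1/2")
  expect_true(all(s2$p$t == s1$p$t) && all(s2$q$t == s1$q$t))
  # study2 keeps the association measures of study1, moves the causal RD
  expect_exact(factual_assoc(s2, "RD"), "1/5")
  expect_exact(counterfactual_assoc(s2, "RD"), "1/6")
  expect_exact(causal_rd(s2, "total"), "11/60")
  expect_exact(causal_rr(s2, "total"), "3/2")
  expect_exact(factual_assoc(s2, "RR"), "3/2")
  expect_exact(counterfactual_assoc(s2, "RR"), "3/2")
  # study3: flipped unexposed outcomes -> null associations both ways
  expect_exact(factual_assoc(s3, "RD"), "0")
  expect_exact(counterfactual_assoc(s3, "RD"), "0")
  expect_exact(factual_assoc(s3, "RR"), "1")
  expect_true(all(s3$q$t == as_rational(c("1/3", "0", "4/15", "2/5"))))
  expect_exact(exchangeable_assoc_rd(s3)$constant, "-4/15")
  expect_exact(exchangeable_assoc_rr(s3)$constant, "5/9")
})

test_that("set_prevalence moves only the total-target causal measures", {
  set.seed(31)
  for (i in 1:10) {
    pop <- sample_population(denominator = 400)
    moved <- set_prevalence(pop, "1/3")
    expect_true(all(moved$p$t == pop$p$t) && all(moved$q$t == pop$q$t))
    for (sc in c("RD", "RR", "OR")) {
      f1 <- factual_assoc(pop, sc); f2 <- factual_assoc(moved, sc)
      expect_identical(is_defined(f1), is_defined(f2))
      if (is_defined(f1))
        expect_true(measure_rational(f1) == measure_rational(f2))
    }
  }
  s1 <- study_fixture("study1")
  expect_true(set_prevalence(s1, "3/5")$prevalence == s1$prevalence)
  at1 <- set_prevalence(s1, 1)
  expect_true(causal_rd(at1, "exposed") == causal_rd(s1, "exposed"))
})

test_that("lift_risks inverts the risk pair with a canonical doomed choice", {
  d <- lift_risks("1/2", "2/5")
  expect_true(all(d$t == as_rational(c("2/5", "1/10", "0", "1/2"))))
  # high risks force doomed overlap: a + b - 1 lower bound binds
  h <- lift_risks("9/10", "4/5", doomed = "7/10")
  expect_true(h$t[1] + h$t[2] == as_rational("9/10"))
  expect_true(h$t[1] + h$t[3] == as_rational("4/5"))
  expect_error(lift_risks("9/10", "4/5", doomed = "1/2"), "doomed")
  expect_error(lift_risks("3/2", "1/2"), class = "causalflip_invalid_input")
  set.seed(17)
  for (i in 1:20) {
    a <- rational(sample(0:60, 1), 60); b <- rational(sample(0:60, 1), 60)
    d <- lift_risks(a, b)
    expect_true(d$t[1] + d$t[2] == a && d$t[1] + d$t[3] == b)
    expect_true(d$t[3] == 0 || d$t[2] == 0)  # maximal-doomed lift
  }
})

test_that("sampling is deterministic under a seed and lands on the lattice", {
  a <- sample_population(seed = 123)
  b <- sample_population(seed = 123)
  expect_true(all(a$p$t == b$p$t) && all(a$q$t == b$q$t) &&
                a$prevalence == b$prevalence)
  expect_true(all(denominator(a$p$t) <= 10000))
  expect_true(sum(a$p$t) == 1 && sum(a$q$t) == 1)
  expect_true(a$prevalence > 0 && a$prevalence < 1)
})

test_that("symmetric Dirichlet draws have mean 1/4 per type", {
  set.seed(99)
  n <- 4000
  counts <- causalflip:::sample_simplex_counts(n, c(1, 1, 1, 1), 10000L)
  means <- colMeans(counts / 10000)
  expect_true(all(abs(means - 0.25) < 0.01))
})

test_that("constrained samplers verifiably satisfy their conditions", {
  pop <- sample_satisfying("distribution", seed = 3)
  s <- condition_summary(pop)
  expect_true(s$no_confounding_distribution && s$no_confounding_rd &&
                isTRUE(s$exchangeable_rd))
  pop <- sample_satisfying("rd_shift", alpha = "1/10", seed = 4)
  x <- exchangeable_assoc_rd(pop)
  expect_true(x$exchangeable)
  expect_exact(x$constant, "1/10")
  pop <- sample_satisfying("rr_scale", beta = "6/5", seed = 5)
  x <- exchangeable_assoc_rr(pop)
  expect_true(x$exchangeable)
  expect_exact(x$constant, "6/5")
  pop <- sample_satisfying("null_association", seed = 6)
  expect_exact(factual_assoc(pop, "RD"), "0")
  expect_exact(counterfactual_assoc(pop, "RD"), "0")
  expect_true(exchangeable_assoc_rd(pop)$exchangeable)
})

test_that("constrained sampling from a fixed base reproduces the study-1 geometry", {
  s1 <- study_fixture("study1")
  pop <- sample_satisfying("rr_scale", beta = "5/6", from = s1)
  r <- potential_risks(pop)$r
  expect_true(r["unexposed.when_exposed"] == as_rational("1/2"))
  expect_true(r["unexposed.when_unexposed"] == as_rational("2/5"))
  expect_true(factual_assoc(pop, "RR") == counterfactual_assoc(pop, "RR"))
  # boundary shift alpha = 1: an all-preventive exposed group (risks 0 and 1)
  # forces an all-causal unexposed group (risks 1 and 0)
  preventive <- response_type_distribution(0, 0, 1, 0)
  base <- grouped_population(preventive, preventive, "1/2")
  pop <- sample_satisfying("rd_shift", alpha = 1, from = base)
  r <- potential_risks(pop)$r
  expect_true(r["unexposed.when_exposed"] == 1)
  expect_true(r["unexposed.when_unexposed"] == 0)
  x <- exchangeable_assoc_rd(pop)
  expect_true(x$exchangeable)
  expect_exact(x$constant, "1")
})

test_that("infeasible constructions are reported as such", {
  expect_error(sample_satisfying("rd_shift", alpha = "3/2"),
               class = "causalflip_infeasible")
  expect_error(sample_satisfying("rr_scale", beta = "0"),
               class = "causalflip_infeasible")
  doomed <- response_type_distribution(1, 0, 0, 0)
  base <- grouped_population(doomed, doomed, "1/2")
  expect_error(sample_satisfying("rd_shift", alpha = "1/2", from = base),
               class = "causalflip_infeasible")
})
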