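test_that("response-type distributions enforce the simplex exactly", {
  d <- response_type_distribution("4/15", "5/15", "1/15", "5/15")
  expect_true(sum(d$t) == 1)
  expect_error(response_type_distribution("1/2", "1/2", "1/10", "0"),
               "sum to 1")
  expect_error(response_type_distribution("1/2", "3/4", "-1/4", "0"),
               "non-negative")
})

test_that("counts convert to exact proportions and prevalence", {
  pop <- from_response_type_counts(c(160, 200, 40, 200), c(160, 40, 0, 200))
  expect_true(all(pop$p$t == as_rational(c("4/15", "5/15", "1/15", "5/15"))))
  expect_true(all(pop$q$t == as_rational(c("4/10", "1/10", "0", "5/10"))))
  expect_exact(pop$prevalence, "3/5")
  # scaling all counts leaves the population unchanged
  for (k in c(2, 7)) {
    scaled <- from_response_type_counts(k * c(160, 200, 40, 200),
                                        k * c(160, 40, 0, 200))
    expect_true(all(scaled$p$t == pop$p$t) && all(scaled$q$t == pop$q$t) &&
                  scaled$prevalence == pop$prevalence)
  }
  expect_true(all(from_response_type_counts(c(2, 2, 2, 2), c(1, 1, 1, 1))$p$t ==
                    rational(1, 4)))
  expect_error(from_response_type_counts(c(0, 0, 0, 0), c(1, 1, 1, 1)),
               "zero total")
})

test_that("marginal distribution mixes groups by prevalence", {
  s1 <- study_fixture("study1")
  r <- marginal_distribution(s1)
  expect_true(all(r$t == as_rational(c("8/25", "6/25", "1/25", "10/25"))))
  # oracle cross-check
  o <- as.numeric(s1$p$t) * 0.6 + as.numeric(s1$q$t) * 0.4
  expect_equal(as.numeric(r$t), o, ignore_attr = TRUE, tolerance = 1e-12)
  # exact rational average at prevalence 1/2 (hand-derived)
  half <- marginal_distribution(s1$p, s1$q, "1/2")
  expect_true(all(half$t == as_rational(c("1/3", "13/60", "1/30", "5/12"))))
  # identity when groups coincide; boundary prevalences pick one group
  u <- response_type_distribution("1/4", "1/4", "1/4", "1/4")
  expect_true(all(marginal_distribution(u, u, "2/7")$t == rational(1, 4)))
  expect_true(all(marginal_distribution(s1$p, s1$q, 1)$t == s1$p$t))
  expect_true(all(marginal_distribution(s1$p, s1$q, 0)$t == s1$q$t))
})

test_that("marginal distribution stays on the simplex for random inputs", {
  set.seed(11)
  for (i in 1:25) {
    pop <- sample_population(denominator = 360)
    expect_true(sum(marginal_distribution(pop)$t) == 1)
  }
})

test_that("potential risks are the four response-type sums", {
  s1 <- study_fixture("study1")
  pr <- potential_risks(s1)$r
  expect_true(all(pr == as_rational(c("9/15", "5/15", "5/10", "4/10"))))
  allimmune <- response_type_distribution(0, 0, 0, 1)
  pop0 <- grouped_population(allimmune, allimmune, "1/2")
  expect_true(all(potential_risks(pop0)$r == 0))
  extreme <- grouped_population(response_type_distribution(1, 0, 0, 0),
                                allimmune, "1/2")
  expect_true(all(potential_risks(extreme)$r == as_rational(c(1, 1, 0, 0))))
})

test_that("observed tables give exact group risks", {
  tab <- observed_table(a = 360, b = 160, c = 240, d = 240)
  r <- observed_risks(tab)
  expect_exact(r["exposed"], "3/5")
  expect_exact(r["unexposed"], "2/5")
  expect_true(all(observed_risks(observed_table(1, 1, 0, 0)) == 1))
  expect_true(all(observed_risks(observed_table(0, 0, 5, 7)) == 0))
  expect_error(observed_risks(observed_table(0, 1, 0, 1)), "exposed group")
})

test_that("populations collapse to factual 2x2 tables and round-trip", {
  s1 <- study_fixture("study1")
  tab <- observed_table_of(s1, 1000)
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 360, b = 160, c = 240, d = 240))
  r <- observed_risks(tab)
  risks <- potential_risks(s1)$r
  expect_true(r["exposed"] == risks["exposed.when_exposed"])
  expect_true(r["unexposed"] == risks["unexposed.when_unexposed"])
  err <- tryCatch(observed_table_of(s1, 10), condition = identity)
  expect_s3_class(err, "causalflip_invalid_input")
  expect_equal(err$minimal_total, 25)
  # degenerate tiny case: everyone doomed, half exposed
  doomed <- response_type_distribution(1, 0, 0, 0)
  tab4 <- observed_table_of(grouped_population(doomed, doomed, "1/2"), 4)
  expect_equal(unlist(tab4[c("a", "b", "c", "d")]), c(a = 2, b = 2, c = 0, d = 0))
})

test_that("round-trip observed_risks(observed_table_of()) on random populations", {
  set.seed(23)
  for (i in 1:20) {
    pop <- sample_population(denominator = 60)
    tab <- observed_table_of(pop, 3600)  # 3600 is divisible by every cell
    r <- observed_risks(tab)
    risks <- potential_risks(pop)$r
    expect_true(r["exposed"] == risks["exposed.when_exposed"])
    expect_true(r["unexposed"] == risks["unexposed.when_unexposed"])
  }
})
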