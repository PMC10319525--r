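# Independent double-precision oracle: recomputes risks and measures with
# plain floating-point arithmetic straight from the group proportions, never
# touching the package's rational kernel. Exact assertions are checked
# against frozen fractions; the oracle guards them numerically.

oracle_risks <- function(exposed, unexposed, prevalence) {
  p <- as.numeric(exposed)
  q <- as.numeric(unexposed)
  list(ap = p[1] + p[2], bp = p[1] + p[3],
       aq = q[1] + q[2], bq = q[1] + q[3], pi = as.numeric(prevalence))
}

oracle_measures <- function(r) {
  ra <- r$pi * r$ap + (1 - r$pi) * r$aq
  rb <- r$pi * r$bp + (1 - r$pi) * r$bq
  list(crd_total = ra - rb, crr_total = ra / rb,
       crd_exposed = r$ap - r$bp, crr_exposed = r$ap / r$bp,
       crd_unexposed = r$aq - r$bq, crr_unexposed = r$aq / r$bq,
       ard = r$ap - r$bq, arr = r$ap / r$bq,
       aor = (r$ap / (1 - r$ap)) / (r$bq / (1 - r$bq)),
       cf_ard = r$aq - r$bp, cf_arr = r$aq / r$bp)
}

# fraction equality helper: rational/measure against a frozen "a/b" string
expect_exact <- function(object, fraction) {
  value <- if (inherits(object, "measure")) measure_rational(object) else object
  expect_true(value == as_rational(fraction),
              label = paste0(as.character(value), " == ", fraction))
}

study1_raw <- list(exposed = c(4, 5, 1, 5) / 15, unexposed = c(4, 1, 0, 5) / 10)
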