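# Assembled analysis reports and their text / markdown / JSON renderings.

measure_string <- function(m) format(m)

#' Analyse a population or an observed table
#'
#' Builds the full report for its input: the potential (or observed) risks,
#' the causal effect measures for every admissible target population, the
#' factual and counterfactual association measures on the RD, RR and OR
#' scales, and the condition summary with the extracted constants. An
#' observed 2x2 table carries no counterfactual information, so for it only
#' the factual association measures are computed and every causal or
#' counterfactual quantity is reported as *not identified*.
#'
#' @param x a [grouped_population()] or an [observed_table()].
#' @param label optional label carried into the report.
#' @return An object of class `analysis_report`; render it with `format()`
#'   (text), [report_markdown()], or serialise with [report_json()].
#' @examples
#' analyze(study_fixture("study1"))
#' @export
analyze <- function(x, label = NULL) UseMethod("analyze")

#' @export
analyze.grouped_population <- function(x, label = NULL) {
  targets <- c(if (has_interior_prevalence(x)) "total", "exposed", "unexposed")
  effects <- lapply(setNames(targets, targets), function(tg) list(
    RD = measure_string(causal_rd(x, tg)),
    RR = measure_string(causal_rr(x, tg)),
    OR = measure_string(causal_or(x, tg))))
  assoc <- list(
    factual = lapply(setNames(MEASURE_SCALES, MEASURE_SCALES), function(sc)
      measure_string(factual_assoc(x, sc))),
    counterfactual = lapply(setNames(MEASURE_SCALES, MEASURE_SCALES),
                            function(sc)
      measure_string(counterfactual_assoc(x, sc))))
  structure(list(
    kind = "population", label = label,
    prevalence = as.character(x$prevalence),
    risks = as.list(as.character(potential_risks(x)$r)),
    effects = effects,
    association = assoc,
    conditions = condition_summary(x, label = label)
  ), class = "analysis_report")
}

#' @export
analyze.observed_table <- function(x, label = NULL) {
  r <- observed_risks(x)
  rd <- r[1] - r[2]
  rr <- if (r[2] == 0) NULL else r[1] / r[2]
  or_den <- (1 - r[1]) * r[2]
  orv <- if (or_den == 0) NULL else (r[1] * (1 - r[2])) / or_den
  fr <- function(v) if (is.null(v)) "undefined" else as.character(v)
  n <- x$a + x$b + x$c + x$d
  structure(list(
    kind = "observed", label = label,
    prevalence = as.character(rational(x$a + x$c, n)),
    risks = list(exposed = as.character(r[1]), unexposed = as.character(r[2])),
    effects = "not identified",
    association = list(
      factual = list(RD = fr(rd), RR = fr(rr), OR = fr(orv)),
      counterfactual = "not identified"),
    conditions = "not identified"
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.analysis_report <- function(x, ...) {
  out <- character()
  add <- function(...) out <<- c(out, paste0(...))
  if (!is.null(x$label)) add("Analysis: ", x$label)
  add("Exposure prevalence Pr(E = 1) = ", x$prevalence)
  add("")
  if (x$kind == "population") {
    add("Potential risks:")
    for (nm in names(x$risks)) add(sprintf("  %-28s %s", nm, x$risks[[nm]]))
    add("")
    add("Measures of effect (causal), by target population:")
    for (tg in names(x$effects)) {
      e <- x$effects[[tg]]
      add(sprintf("  %-10s cRD = %s, cRR = %s, cOR = %s",
                  tg, e$RD, e$RR, e$OR))
    }
  } else {
    add("Observed risks:")
    add("  exposed   ", x$risks$exposed)
    add("  unexposed ", x$risks$unexposed)
    add("")
    add("Measures of effect (causal): not identified from an observed table")
  }
  add("")
  add("Measures of association:")
  fa <- x$association$factual
  add(sprintf("  factual         aRD = %s, aRR = %s, aOR = %s",
              fa$RD, fa$RR, fa$OR))
  if (identical(x$association$counterfactual, "not identified")) {
    add("  counterfactual  not identified from an observed table")
  } else {
    cf <- x$association$counterfactual
    add(sprintf("  counterfactual  aRD = %s, aRR = %s, aOR = %s",
                cf$RD, cf$RR, cf$OR))
  }
  add("")
  if (identical(x$conditions, "not identified")) {
    add("Conditions: not identified from an observed table")
  } else {
    add("Conditions:")
    con <- utils::capture.output(print(x$conditions))
    out <- c(out, con)
  }
  out
}

report_conditions_list <- function(con) {
  if (identical(con, "not identified")) return("not identified")
  verdict_json <- function(v) if (is.na(v)) "n/e" else v
  list(
    no_confounding_distribution = verdict_json(con$no_confounding_distribution),
    no_confounding_rd = verdict_json(con$no_confounding_rd),
    no_confounding_rr = verdict_json(con$no_confounding_rr),
    exchangeable_rd = verdict_json(con$exchangeable_rd),
    exchangeable_rr = verdict_json(con$exchangeable_rr),
    background_exchangeable = verdict_json(con$background_exchangeable),
    alpha = if (is.null(con$alpha)) NULL else as.character(con$alpha),
    beta = if (is.null(con$beta)) NULL else as.character(con$beta)
  )
}

#' Serialise or render a report
#'
#' `report_json()` writes (or returns) the schema-stable JSON form of an
#' [analyze()] report, with every exact value as a fraction string and
#' non-evaluable verdicts as `"n/e"`. `report_markdown()` renders the
#' condition grid and measure panels as markdown tables.
#'
#' @param report an `analysis_report`.
#' @param path optional output path; when omitted the JSON string / markdown
#'   lines are returned.
#' @return A JSON string (or `path`, invisibly) / a character vector of
#'   markdown lines.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  obj <- report[c("kind", "label", "prevalence", "risks", "effects",
                  "association")]
  obj$conditions <- report_conditions_list(report$conditions)
  if (is.null(obj$label)) obj$label <- NULL
  if (is.null(path))
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                         null = "null", pretty = TRUE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname report_json
#' @export
report_markdown <- function(report) {
  stopifnot(inherits(report, "analysis_report"))
  out <- character()
  add <- function(...) out <<- c(out, paste0(...))
  add("## Analysis", if (!is.null(report$label)) paste0(": ", report$label))
  add("")
  add("Exposure prevalence Pr(E = 1): `", report$prevalence, "`")
  add("")
  fa <- report$association$factual
  add("| Measure | RD | RR | OR |")
  add("|---|---|---|---|")
  add("| Factual association | ", fa$RD, " | ", fa$RR, " | ", fa$OR, " |")
  if (!identical(report$association$counterfactual, "not identified")) {
    cf <- report$association$counterfactual
    add("| Counterfactual association | ", cf$RD, " | ", cf$RR, " | ",
        cf$OR, " |")
  }
  if (!identical(report$effects, "not identified")) {
    for (tg in names(report$effects)) {
      e <- report$effects[[tg]]
      add("| Causal (", tg, " target) | ", e$RD, " | ", e$RR, " | ",
          e$OR, " |")
    }
  }
  add("")
  if (!identical(report$conditions, "not identified")) {
    con <- report_conditions_list(report$conditions)
    word <- function(v) if (identical(v, "n/e")) "n/e" else
      if (isTRUE(v)) "True" else "False"
    add("| Condition | Verdict |")
    add("|---|---|")
    add("| No confounding in distribution | ",
        word(con$no_confounding_distribution), " |")
    add("| No confounding in risk difference | ",
        word(con$no_confounding_rd), " |")
    add("| No confounding in risk ratio | ",
        word(con$no_confounding_rr), " |")
    add("| Exchangeability of associational risk difference | ",
        word(con$exchangeable_rd), " |")
    add("| Exchangeability of associational risk ratio | ",
        word(con$exchangeable_rr), " |")
    add("| Exchangeability of background risks | ",
        word(con$background_exchangeable), " |")
    if (!is.null(con$alpha)) add("", "alpha = `", con$alpha, "`")
    if (!is.null(con$beta)) add("", "beta = `", con$beta, "`")
  }
  out
}
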