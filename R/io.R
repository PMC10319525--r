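# File interfaces: JSON populations, CSV count tables, and rendered reports.

value_to_rational <- function(v, field) {
  out <- tryCatch({
    if (is.character(v)) as_rational(v)
    else if (is.numeric(v)) {
      # JSON numbers arrive as doubles; interpret their decimal literal
      # exactly (0.6 -> 6/10), never the binary float
      as_rational(format(v, digits = 15, scientific = FALSE))
    } else stop("not a number or string")
  }, error = function(e) NULL)
  if (is.null(out) || length(out) != 1L)
    invalid_input(paste0("field '", field, "': cannot interpret ",
                         deparse(v), " as an exact proportion"))
  out
}

schema_group <- function(obj, group) {
  if (is.null(obj[[group]]) || !is.list(obj[[group]]))
    invalid_input(paste0("missing or malformed group object '", group, "'"))
  vals <- lapply(RESPONSE_TYPES, function(ty) {
    v <- obj[[group]][[ty]]
    if (is.null(v))
      invalid_input(paste0("group '", group, "' is missing response type '",
                           ty, "'"))
    value_to_rational(v, paste0(group, ".", ty))
  })
  extra <- setdiff(names(obj[[group]]), RESPONSE_TYPES)
  if (length(extra))
    invalid_input(paste0("group '", group, "' has unknown response-type ",
                         "label(s): ", paste(extra, collapse = ", ")))
  tryCatch(response_type_distribution(do.call(c, vals)),
           causalflip_invalid_input = function(e)
             invalid_input(paste0("group '", group, "': ",
                                  conditionMessage(e))))
}

#' Read and write populations as JSON
#'
#' The population schema is a JSON object with keys `exposed`, `unexposed`
#' (each an object with keys `doomed`, `causal`, `preventive`, `immune`) and
#' `prevalence`. Proportions may be fraction strings (`"4/15"`), decimal
#' strings (`"0.35"`) or JSON numbers; all are interpreted exactly as decimal
#' or fraction literals. Validation errors name the offending field.
#' Fractions are written back as strings so exactness survives the format.
#'
#' @param path file path.
#' @return `read_population()` returns a [grouped_population()];
#'   `write_population()` invisibly returns `path`.
#' @examples
#' path <- system.file("extdata", "study1.json", package = "causalflip")
#' read_population(path)
#' @export
read_population <- function(path) {
  if (!file.exists(path)) invalid_input(paste0("no such file: ", path))
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e)
                    invalid_input(paste0("malformed JSON in ", path, ": ",
                                         conditionMessage(e))))
  p <- schema_group(obj, "exposed")
  q <- schema_group(obj, "unexposed")
  if (is.null(obj$prevalence))
    invalid_input("missing field 'prevalence'")
  pi <- value_to_rational(obj$prevalence, "prevalence")
  if (pi < 0 || pi > 1)
    invalid_input("field 'prevalence': must lie in [0, 1]")
  grouped_population(p, q, pi)
}

#' @rdname read_population
#' @param pop a [grouped_population()].
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "grouped_population"))
  as_named <- function(d) as.list(setNames(as.character(d$t), RESPONSE_TYPES))
  obj <- list(exposed = as_named(pop$p), unexposed = as_named(pop$q),
              prevalence = as.character(pop$prevalence))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

read_count_csv <- function(path, key_col, key_values, what) {
  if (!file.exists(path)) invalid_input(paste0("no such file: ", path))
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   invalid_input(paste0("malformed CSV in ", path, ": ",
                                        conditionMessage(e))))
  need <- c("group", key_col, "count")
  if (!all(need %in% names(df)))
    invalid_input(paste0(what, " CSV must have columns ",
                         paste(need, collapse = ", ")))
  df$group <- tolower(trimws(as.character(df$group)))
  bad <- !df$group %in% c("exposed", "unexposed")
  if (any(bad))
    invalid_input(paste0("unknown group label(s) at data row(s) ",
                         paste(which(bad), collapse = ", "), ": ",
                         paste(unique(df$group[bad]), collapse = ", ")))
  df$key <- trimws(as.character(df[[key_col]]))
  bad <- !df$key %in% key_values
  if (any(bad))
    invalid_input(paste0("unknown ", key_col, " label(s) at data row(s) ",
                         paste(which(bad), collapse = ", "), ": ",
                         paste(unique(df$key[bad]), collapse = ", ")))
  if (any(!is.finite(df$count) | df$count < 0 | df$count != floor(df$count)))
    invalid_input("counts must be non-negative integers")
  df
}

#' Read an observed 2x2 exposure-outcome table from CSV
#'
#' Expects columns `group` (`exposed`/`unexposed`), `outcome` (`1`/`0`) and
#' `count`; duplicate rows for a cell are summed.
#'
#' @param path file path.
#' @return An [observed_table()].
#' @export
read_observed_table <- function(path) {
  df <- read_count_csv(path, "outcome", c("1", "0"), "observed 2x2")
  cell <- function(g, o) sum(df$count[df$group == g & df$key == o])
  observed_table(a = cell("exposed", "1"), b = cell("unexposed", "1"),
                 c = cell("exposed", "0"), d = cell("unexposed", "0"))
}

#' Read response-type counts from CSV
#'
#' Expects columns `group` (`exposed`/`unexposed`), `type` (`doomed`,
#' `causal`, `preventive`, `immune`) and `count`; duplicate rows are summed.
#'
#' @param path file path.
#' @return A [grouped_population()] (prevalence = exposed share of the grand
#'   total, as in [from_response_type_counts()]).
#' @export
read_response_counts <- function(path) {
  df <- read_count_csv(path, "type", RESPONSE_TYPES, "response-type count")
  cell <- function(g, ty) sum(df$count[df$group == g & df$key == ty])
  from_response_type_counts(
    vapply(RESPONSE_TYPES, cell, numeric(1), g = "exposed"),
    vapply(RESPONSE_TYPES, cell, numeric(1), g = "unexposed"))
}
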