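#' Exact rational vectors
#'
#' `rational()` builds a vector of exact rational numbers from integer
#' numerators and denominators. All arithmetic (`+`, `-`, `*`, `/`),
#' comparisons, `sum()` and `abs()` are exact: results are always reduced to
#' lowest terms with a positive denominator, and an operation whose reduced
#' result cannot be represented exactly raises an error instead of rounding.
#' This is the canonical number type of the package; every risk, measure and
#' condition verdict is computed on it, so equality tests carry no
#' floating-point tolerance.
#'
#' @param num integer-valued numerator(s).
#' @param den integer-valued denominator(s), recycled against `num`.
#'
#' @return An object of class `rational`.
#' @examples
#' rational(1, 3) + rational(1, 6)    # 1/2, exactly
#' sum(rational(rep(1, 3), 3)) == 1   # TRUE
#' @seealso [as_rational()] for parsing `"3/5"` or `"0.6"`.
#' @export
rational <- function(num, den = 1) {
  n <- max(length(num), length(den))
  if (length(num) == 0L || length(den) == 0L) n <- 0L
  z <- .rat_norm(rep_len(as.numeric(num), n), rep_len(as.numeric(den), n))
  new_rational(z$num, z$den, names = names(num))
}

new_rational <- function(num, den, names = NULL) {
  structure(list(num = num, den = den, names = names), class = "rational")
}

#' Coerce to an exact rational
#'
#' Character input is interpreted exactly: `"3/5"` as the fraction 3/5 and a
#' decimal literal such as `"0.35"` as 35/100 (then reduced) -- never through
#' binary floating point. Numeric input must be integer-valued; fractional
#' doubles are rejected so that, e.g., the double `0.1` is never silently
#' reinterpreted as 1/10. Write `as_rational("0.1")` to say what you mean.
#'
#' @param x a rational, integer-valued numeric, or character vector of
#'   fractions/decimal literals.
#' @return A `rational` vector.
#' @examples
#' as_rational("3/5")
#' as_rational(c("0.35", "2", "-1/4"))
#' @export
as_rational <- function(x) UseMethod("as_rational")

#' @export
as_rational.rational <- function(x) x

#' @export
as_rational.numeric <- function(x) {
  if (any(!is.finite(x) | x != floor(x)))
    stop("numeric input to as_rational() must be integer-valued; ",
         "pass fractions or decimals as strings (e.g. \"1/10\")", call. = FALSE)
  rational(x, 1)
}

#' @export
as_rational.integer <- function(x) rational(as.numeric(x), 1)

#' @export
as_rational.character <- function(x) {
  nums <- numeric(length(x))
  dens <- numeric(length(x))
  for (i in seq_along(x)) {
    s <- gsub("[[:space:]]", "", x[[i]])
    if (grepl("^[+-]?[0-9]+/[0-9]+$", s)) {
      parts <- strsplit(s, "/", fixed = TRUE)[[1]]
      nums[i] <- as.numeric(parts[1])
      dens[i] <- as.numeric(parts[2])
    } else if (grepl("^[+-]?[0-9]+$", s)) {
      nums[i] <- as.numeric(s)
      dens[i] <- 1
    } else if (grepl("^[+-]?[0-9]*\\.[0-9]+$", s)) {
      frac <- sub("^[+-]?[0-9]*\\.", "", s)
      if (nchar(frac) > 15)
        stop("decimal literal has more than 15 fractional digits: ", x[[i]],
             call. = FALSE)
      sgn <- if (startsWith(s, "-")) -1 else 1
      whole <- sub("\\..*$", "", sub("^[+-]", "", s))
      if (whole == "") whole <- "0"
      den <- 10^nchar(frac)
      nums[i] <- sgn * (as.numeric(whole) * den + as.numeric(frac))
      dens[i] <- den
    } else {
      stop("cannot parse '", x[[i]], "' as a fraction or decimal literal",
           call. = FALSE)
    }
  }
  out <- rational(nums, dens)
  out$names <- names(x)
  out
}

#' Test for the rational class
#' @param x an object.
#' @return `TRUE` if `x` is a `rational` vector.
#' @export
is_rational <- function(x) inherits(x, "rational")

coerce_operand <- function(x) {
  if (is_rational(x)) return(x)
  as_rational(x)
}

#' @export
length.rational <- function(x) length(x$num)

#' @export
names.rational <- function(x) x$names

#' @export
`names<-.rational` <- function(x, value) {
  x$names <- value
  x
}

#' @export
`[.rational` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$names)
  new_rational(x$num[i], x$den[i],
               names = if (!is.null(x$names)) x$names[i])
}

#' @export
c.rational <- function(...) {
  parts <- lapply(list(...), coerce_operand)
  nms <- lapply(parts, function(p) if (is.null(p$names)) rep("", length(p)) else p$names)
  nms <- unlist(nms)
  if (all(nms == "")) nms <- NULL
  new_rational(unlist(lapply(parts, `[[`, "num")),
               unlist(lapply(parts, `[[`, "den")), names = nms)
}

#' @export
rep.rational <- function(x, ...) {
  idx <- rep(seq_along(x$num), ...)
  x[idx]
}

#' @export
Ops.rational <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") return(rational(0) - e1)
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for rational vectors")
  }
  a <- coerce_operand(e1)
  b <- coerce_operand(e2)
  n <- max(length(a), length(b))
  if (length(a) != n) a <- a[rep_len(seq_along(a$num), n)]
  if (length(b) != n) b <- b[rep_len(seq_along(b$num), n)]
  op <- match(.Generic, c("+", "-", "*", "/"))
  if (!is.na(op)) {
    z <- .rat_arith(a$num, a$den, b$num, b$den, op)
    return(new_rational(z$num, z$den))
  }
  cmp <- .rat_cmp(a$num, a$den, b$num, b$den)
  switch(.Generic,
    "==" = cmp == 0L,
    "!=" = cmp != 0L,
    "<"  = cmp < 0L,
    "<=" = cmp <= 0L,
    ">"  = cmp > 0L,
    ">=" = cmp >= 0L,
    stop("operation ", .Generic, " not defined for rational vectors")
  )
}

#' @export
sum.rational <- function(..., na.rm = FALSE) {
  x <- c.rational(...)
  z <- .rat_sum(x$num, x$den)
  new_rational(z$num, z$den)
}

#' @export
abs.rational <- function(x) new_rational(abs(x$num), x$den, names = x$names)

#' @export
as.numeric.rational <- function(x, ...) setNames(x$num / x$den, x$names)

#' @export
as.double.rational <- function(x, ...) as.numeric.rational(x)

#' @export
as.character.rational <- function(x, ...) {
  out <- ifelse(x$den == 1,
                formatC(x$num, format = "d", big.mark = ""),
                paste0(formatC(x$num, format = "d"), "/",
                       formatC(x$den, format = "d")))
  setNames(out, x$names)
}

#' @export
format.rational <- function(x, ...) format(as.character(x), ...)

#' @export
print.rational <- function(x, ...) {
  cat("<rational>", paste(as.character(x), collapse = " "), "\n")
  invisible(x)
}

#' Numerator and denominator accessors
#'
#' Return the reduced numerators/denominators of a rational vector as plain
#' numeric (integer-valued) vectors.
#' @param x a `rational` vector.
#' @return An integer-valued numeric vector.
#' @export
numerator <- function(x) {
  stopifnot(is_rational(x))
  setNames(x$num, x$names)
}

#' @rdname numerator
#' @export
denominator <- function(x) {
  stopifnot(is_rational(x))
  setNames(x$den, x$names)
}
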