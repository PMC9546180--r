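#' Calendar month indices
#'
#' The study's time axis is the calendar month. A `month_index` is stored as
#' an integer month code (`year * 12 + month - 1`) so that consecutive months
#' differ by exactly 1 and ordering, gaps and year rollover need no special
#' handling. Construct from `(year, month)` pairs or parse from ISO
#' `"YYYY-MM"` strings.
#'
#' @param year integer calendar year(s).
#' @param month integer calendar month(s), 1--12.
#' @return A `month_index` vector.
#' @examples
#' m <- month_index(2011, 7)
#' format(m + 1) # "2011-08"
#' @export
month_index <- function(year, month) {
  year <- as.integer(year)
  month <- as.integer(month)
  if (any(is.na(year)) || any(is.na(month))) {
    stop("year and month must be non-missing integers", call. = FALSE)
  }
  if (any(month < 1L | month > 12L)) {
    stop("month must be in 1..12", call. = FALSE)
  }
  new_month_index(year * 12L + (month - 1L))
}

new_month_index <- function(code) {
  structure(as.integer(code), class = "month_index")
}

#' Parse ISO "YYYY-MM" month strings
#'
#' @param x character vector of months in ISO `"YYYY-MM"` form.
#' @return A `month_index` vector.
#' @examples
#' parse_month("2011-07")
#' @export
parse_month <- function(x) {
  if (inherits(x, "month_index")) return(x)
  x <- as.character(x)
  ok <- grepl("^[0-9]{4}-(0[1-9]|1[0-2])$", x)
  if (!all(ok)) {
    stop("invalid month string(s): ", paste(utils::head(x[!ok], 3), collapse = ", "),
         " (expected ISO \"YYYY-MM\")", call. = FALSE)
  }
  month_index(as.integer(substr(x, 1, 4)), as.integer(substr(x, 6, 7)))
}

#' @export
format.month_index <- function(x, ...) {
  sprintf("%04d-%02d", unclass(x) %/% 12L, unclass(x) %% 12L + 1L)
}

#' @export
print.month_index <- function(x, ...) {
  print(format(x))
  invisible(x)
}

#' @export
`[.month_index` <- function(x, i) new_month_index(unclass(x)[i])

#' @export
c.month_index <- function(...) {
  new_month_index(unlist(lapply(list(...), unclass)))
}

#' Calendar components of a month index
#' @param x a `month_index` vector.
#' @return Integer vector of years (`month_year`) or months 1--12
#'   (`month_of_year`).
#' @export
month_year <- function(x) unclass(x) %/% 12L

#' @rdname month_year
#' @export
month_of_year <- function(x) unclass(x) %% 12L + 1L

#' Shift a month index by whole months
#' @param m a `month_index` vector.
#' @param k integer number of months (may be negative).
#' @return A `month_index` vector.
#' @export
month_add <- function(m, k) new_month_index(unclass(m) + as.integer(k))

#' Consecutive sequence of months
#' @param from starting `month_index` (or ISO string).
#' @param length_out number of consecutive months.
#' @return A `month_index` vector of length `length_out`.
#' @export
month_seq <- function(from, length_out) {
  from <- parse_month(from)
  new_month_index(unclass(from)[1] + seq_len(length_out) - 1L)
}

month_code <- function(x) unclass(parse_month(x))
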