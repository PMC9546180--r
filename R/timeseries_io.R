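#' Monthly prescribing series for one group
#'
#' A `prescription_series` holds a strictly consecutive monthly sequence of
#' prescription counts, population denominators and rates per 100 000
#' population for one analysis group (e.g. one jurisdiction x sex x age-band
#' combination). Rates are derived from counts and populations whenever both
#' are available; alternatively a series may carry pre-computed rates only
#' (the usual situation when counts were aggregated upstream).
#'
#' @param group_id named character vector of group labels (e.g.
#'   `c(country = "AU", sex = "M")`), or a single unnamed label.
#' @param months `month_index` vector (or ISO "YYYY-MM" strings), strictly
#'   consecutive.
#' @param counts non-negative integer prescription counts per month, or `NA`.
#' @param populations positive population denominators per month.
#' @param rates rates per 100 000 population; computed from
#'   `counts`/`populations` when omitted.
#' @return An object of class `prescription_series`.
#' @examples
#' s <- prescription_series("AU", month_seq("2009-07", 36),
#'                          counts = rep(1690, 36),
#'                          populations = rep(1e6, 36))
#' s$rates[1] # 169
#' @export
prescription_series <- function(group_id, months, counts = NULL,
                                populations = NULL, rates = NULL) {
  months <- parse_month(months)
  n <- length(months)
  if (n == 0) stop("series must contain at least one month", call. = FALSE)
  code <- unclass(months)
  if (anyDuplicated(code)) stop("duplicate months in series", call. = FALSE)
  o <- order(code)
  months <- months[o]
  code <- code[o]
  gaps <- which(diff(code) != 1L)
  if (length(gaps)) {
    stop("months are not consecutive: missing ",
         format(new_month_index(code[gaps[1]] + 1L)), call. = FALSE)
  }
  reorder <- function(v) if (is.null(v)) NULL else {
    if (length(v) == 1 && n > 1) v <- rep(v, n)
    if (length(v) != n) stop("field length does not match number of months",
                             call. = FALSE)
    v[o]
  }
  counts <- reorder(counts)
  populations <- reorder(populations)
  rates <- reorder(rates)
  if (!is.null(populations) && any(populations <= 0, na.rm = TRUE)) {
    stop("populations must be positive", call. = FALSE)
  }
  if (!is.null(counts) && any(counts < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  have_cp <- !is.null(counts) && !is.null(populations) && !all(is.na(counts))
  if (is.null(rates)) {
    if (!have_cp) {
      stop("either rates or both counts and populations are required",
           call. = FALSE)
    }
    rates <- compute_rates(counts, populations)
  } else if (have_cp) {
    implied <- compute_rates(counts, populations)
    ok <- is.na(implied) | abs(rates - implied) <= 1e-9 * pmax(1, abs(implied))
    if (!all(ok)) {
      stop("supplied rates disagree with counts/populations at ",
           format(months[which(!ok)[1]]), call. = FALSE)
    }
  }
  if (any(rates < 0, na.rm = TRUE)) stop("rates must be non-negative", call. = FALSE)
  if (is.null(names(group_id)) && length(group_id) == 1) {
    group_id <- c(group = unname(group_id))
  }
  structure(
    list(group_id = group_id,
         months = months,
         counts = if (is.null(counts)) rep(NA_real_, n) else as.numeric(counts),
         populations = if (is.null(populations)) rep(NA_real_, n) else as.numeric(populations),
         rates = as.numeric(rates)),
    class = "prescription_series")
}

#' @export
print.prescription_series <- function(x, ...) {
  cat("<prescription_series> ", series_label(x), "\n",
      "  ", length(x$months), " months: ", format(x$months[1]), " .. ",
      format(x$months[length(x$months)]), "\n",
      "  rate per 100 000: median ", signif(stats::median(x$rates), 4),
      " [", signif(min(x$rates), 4), ", ", signif(max(x$rates), 4), "]\n",
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.prescription_series <- function(x, ...) {
  df <- data.frame(month = format(x$months),
                   prescriptions = x$counts,
                   population = x$populations,
                   rate = x$rates)
  for (nm in rev(names(x$group_id))) df <- cbind(stats::setNames(
    data.frame(unname(x$group_id[[nm]]), stringsAsFactors = FALSE), nm), df)
  df
}

#' @export
length.prescription_series <- function(x) length(x$months)

series_label <- function(s) paste(s$group_id, collapse = "/")

#' Prescribing rate per 100 000 population
#'
#' @param counts non-negative prescription counts.
#' @param populations positive population denominators, same length.
#' @return Numeric rates `counts / populations * 100000`.
#' @examples
#' compute_rates(169, 100000) # 169
#' @export
compute_rates <- function(counts, populations) {
  if (length(counts) != length(populations)) {
    stop("counts and populations must have equal length", call. = FALSE)
  }
  if (any(populations <= 0, na.rm = TRUE)) {
    stop("populations must be strictly positive", call. = FALSE)
  }
  as.numeric(counts) / as.numeric(populations) * 1e5
}

default_schema <- function() {
  list(month = "month", count = "prescriptions", population = "population",
       rate = "rate", group = "group")
}

#' Read a monthly prescribing panel
#'
#' Reads a comma-delimited panel with one row per (group, month) and splits it
#' into one [prescription_series] per distinct combination of group labels.
#' Either prescription counts and population denominators, or pre-computed
#' rates per 100 000, must be present; when counts and populations are both
#' given, rates are (re)derived from them.
#'
#' @param path CSV file with a header row.
#' @param schema column-name mapping: a list with entries `month`, `group`
#'   (character vector of group-label columns), and `count`/`population`
#'   and/or `rate`. Defaults to `month`, `group`, `prescriptions`,
#'   `population`, `rate`.
#' @return A named list of [prescription_series], keyed by the group labels
#'   joined with `/`.
#' @export
read_panel <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sch <- utils::modifyList(default_schema(), schema)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!(sch$month %in% names(df))) {
    stop("schema error: required month column '", sch$month, "' not found",
         call. = FALSE)
  }
  group_cols <- intersect(sch$group, names(df))
  if (length(sch$group) && !length(group_cols)) {
    stop("schema error: no group column of ",
         paste(sch$group, collapse = ", "), " found", call. = FALSE)
  }
  have_cp <- all(c(sch$count, sch$population) %in% names(df))
  have_rate <- sch$rate %in% names(df)
  if (!have_cp && !have_rate) {
    stop("schema error: need either columns (", sch$count, ", ",
         sch$population, ") or column ", sch$rate, call. = FALSE)
  }
  known <- c(sch$month, group_cols, sch$count, sch$population, sch$rate)
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    warning("ignoring unmapped column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  key <- if (length(group_cols)) {
    interaction(df[group_cols], drop = TRUE, sep = "/", lex.order = TRUE)
  } else factor(rep("all", nrow(df)))
  out <- lapply(split(df, key), function(d) {
    m <- parse_month(d[[sch$month]])
    if (anyDuplicated(unclass(m))) {
      stop("data error: duplicate (group, month) rows at ",
           format(m[duplicated(unclass(m))][1]), " in group ",
           paste(unlist(d[1, group_cols, drop = FALSE]), collapse = "/"),
           call. = FALSE)
    }
    gid <- if (length(group_cols)) {
      stats::setNames(as.character(unlist(d[1, group_cols, drop = FALSE])),
                      group_cols)
    } else c(group = "all")
    counts <- if (have_cp) d[[sch$count]] else NULL
    all_na_counts <- !is.null(counts) && all(is.na(counts))
    prescription_series(
      group_id = gid,
      months = m,
      counts = if (all_na_counts) NULL else counts,
      populations = if (have_cp) d[[sch$population]] else NULL,
      rates = if (have_rate) d[[sch$rate]] else NULL)
  })
  out[order(names(out))]
}

#' Write a prescribing panel to CSV
#'
#' Inverse of [read_panel()]: writes one row per (group, month) with columns
#' for the group labels, `month` (ISO "YYYY-MM"), `prescriptions`,
#' `population` and `rate`.
#'
#' @param series a [prescription_series] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(series, path) {
  if (inherits(series, "prescription_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, as.data.frame))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Coefficient table for one or more fitted models
#'
#' Arranges fit results as one row per (group, term) with the estimate,
#' standard error and p-value, mirroring the usual reporting layout for
#' segmented-regression coefficients (series level at start, pre-intervention
#' monthly change, level change at the intervention, post-intervention
#' monthly change, followed by seasonal terms if requested).
#'
#' @param fits an `its_fit` or named list of them (names used as group labels).
#' @param seasonal include the seasonal dummy coefficients? Default `FALSE`,
#'   matching the usual reporting which shows the four structural terms.
#' @return A `data.frame` with columns `group`, `term`, `estimate`, `se`,
#'   `p_value`, `r2_total`.
#' @export
fit_table <- function(fits, seasonal = FALSE) {
  if (inherits(fits, "its_fit")) fits <- list(all = fits)
  out <- do.call(rbind, lapply(names(fits), function(g) {
    f <- fits[[g]]
    keep <- if (seasonal) seq_along(f$beta) else seq_len(4L)
    data.frame(group = g,
               term = names(f$beta)[keep],
               estimate = unname(f$beta[keep]),
               se = unname(f$se[keep]),
               p_value = unname(f$p_values[keep]),
               r2_total = f$r2_total,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
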