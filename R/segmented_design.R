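#' Interrupted time series study design
#'
#' Describes the analysis window around a single intervention (here a drug
#' safety advisory): the intervention month, the number of pre- and
#' post-intervention months modelled, the transition month(s) excluded from
#' fitting because exposure within them is mixed, and whether month-of-year
#' seasonal dummies are included.
#'
#' The modelled window spans `n_pre` months strictly before the advisory
#' month, the advisory month itself (excluded by default as the transition
#' month) and `n_post` months strictly after it.
#'
#' @param advisory_month the intervention month (`month_index` or ISO
#'   "YYYY-MM").
#' @param n_pre months before the advisory included in the model (>= 3).
#' @param n_post months after the advisory included in the model (>= 3).
#' @param transition_months months excluded from fitting; defaults to the
#'   advisory month itself.
#' @param seasonal include 11 month-of-year dummies?
#' @param season_ref calendar month (1--12) used as the omitted seasonal
#'   reference; default January. Predictions are invariant to this choice.
#' @param post_trend_start value of the post-intervention trend term in the
#'   first post-advisory modelled month: 1 (default) or 0. With the default,
#'   the level-change coefficient is the displacement at the first post month
#'   net of one month of the new slope.
#' @return An object of class `study_design`.
#' @examples
#' study_design("2011-07") # 24 pre months, 11 post, July 2011 transitional
#' @export
study_design <- function(advisory_month, n_pre = 24L, n_post = 11L,
                         transition_months = advisory_month,
                         seasonal = TRUE, season_ref = 1L,
                         post_trend_start = 1L) {
  advisory_month <- parse_month(advisory_month)
  stopifnot(length(advisory_month) == 1)
  n_pre <- as.integer(n_pre)
  n_post <- as.integer(n_post)
  if (n_pre < 3L || n_post < 3L) {
    stop("n_pre and n_post must each be >= 3 for the segment slopes to be ",
         "identified", call. = FALSE)
  }
  transition_months <- parse_month(transition_months)
  adv <- unclass(advisory_month)
  tcode <- unclass(transition_months)
  if (any(tcode < adv - n_pre | tcode > adv + n_post)) {
    stop("transition months must lie inside the study window", call. = FALSE)
  }
  season_ref <- as.integer(season_ref)
  if (season_ref < 1L || season_ref > 12L) stop("season_ref must be in 1..12",
                                               call. = FALSE)
  if (!post_trend_start %in% c(0L, 1L)) {
    stop("post_trend_start must be 0 or 1", call. = FALSE)
  }
  structure(
    list(advisory_month = advisory_month, n_pre = n_pre, n_post = n_post,
         transition_months = transition_months, seasonal = isTRUE(seasonal),
         season_ref = season_ref, post_trend_start = as.integer(post_trend_start)),
    class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design> advisory ", format(x$advisory_month),
      "; ", x$n_pre, " pre + ", x$n_post, " post months",
      "; transition {", paste(format(x$transition_months), collapse = ", "),
      "}; seasonal ", if (x$seasonal) "on" else "off", "\n", sep = "")
  invisible(x)
}

#' Segmented-regression design matrix for an interrupted time series
#'
#' Builds the design matrix of the segmented model
#' \deqn{y_t = \beta_0 + \beta_1 \cdot time_t + \beta_2 \cdot step_t +
#'       \beta_3 \cdot ptrend_t + \sum_m \gamma_m \cdot I(month_t = m) + e_t}
#' where `time` counts calendar months since the first included month
#' (so the intercept is the modelled level at the series start), `step`
#' indicates the post-advisory period, and `ptrend` counts months elapsed in
#' the post period (starting at `post_trend_start` in the first post month).
#' Transition months are dropped as rows but calendar spacing in the time
#' codes is preserved: an exclusion removes an observation, not a time
#' increment.
#'
#' @param series a [prescription_series] covering at least the study window.
#' @param design a [study_design].
#' @return An object of class `segmented_design`: list with the model matrix
#'   `x`, response `y` (rate per 100 000), `months`, logical `is_post`, and
#'   the originating `design` and `group_id`.
#' @export
build_design <- function(series, design) {
  stopifnot(inherits(series, "prescription_series"),
            inherits(design, "study_design"))
  adv <- unclass(design$advisory_month)
  window <- seq.int(adv - design$n_pre, adv + design$n_post)
  scode <- unclass(series$months)
  if (window[1] < scode[1] || window[length(window)] > scode[length(scode)]) {
    stop("coverage error: series ", format(series$months[1]), "..",
         format(series$months[length(scode)]), " does not cover the window ",
         format(new_month_index(window[1])), "..",
         format(new_month_index(window[length(window)])), call. = FALSE)
  }
  keep <- !(window %in% unclass(design$transition_months))
  inc <- window[keep]
  is_post <- inc > adv
  if (!any(is_post) || all(is_post)) {
    stop("identifiability error: included window must contain both pre- and ",
         "post-advisory months", call. = FALSE)
  }
  time <- inc - window[1]
  step <- as.numeric(is_post)
  ptrend <- ifelse(is_post, inc - adv - 1L + design$post_trend_start, 0)
  x <- cbind(intercept = 1, time = time, step = step, post_trend = ptrend)
  if (design$seasonal) {
    moy <- inc %% 12L + 1L
    lev <- setdiff(1:12, design$season_ref)
    dummies <- vapply(lev, function(m) as.numeric(moy == m), numeric(length(inc)))
    colnames(dummies) <- paste0("month_", month.abb[lev])
    x <- cbind(x, dummies)
  }
  y <- series$rates[match(inc, scode)]
  if (anyNA(y)) stop("series has missing rates inside the study window",
                     call. = FALSE)
  structure(
    list(x = x, y = y, months = new_month_index(inc), is_post = is_post,
         time = time, design = design, group_id = series$group_id),
    class = "segmented_design")
}

#' @export
print.segmented_design <- function(x, ...) {
  cat("<segmented_design> ", nrow(x$x), " rows (", sum(!x$is_post), " pre, ",
      sum(x$is_post), " post), ", ncol(x$x), " columns: ",
      paste(colnames(x$x)[1:min(4, ncol(x$x))], collapse = ", "),
      if (ncol(x$x) > 4) ", + seasonal dummies", "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.segmented_design <- function(x, ...) {
  data.frame(month = format(x$months), x$x, rate = x$y, check.names = FALSE)
}

#' Export a design matrix for audit
#' @param design a `segmented_design`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
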