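# Hour / weekday / daypart extraction and temporal aggregation.

DAYPARTS <- c("morning", "afternoon", "evening", "night")
WEEKDAYS <- c("Monday", "Tuesday", "Wednesday", "Thursday",
              "Friday", "Saturday", "Sunday")

#' Map an hour of day to its daypart
#'
#' Half-open six-hour bands: morning \[6, 12), afternoon \[12, 18), evening
#' \[18, 24), night \[0, 6). The left-closed convention fixes the ambiguous
#' boundaries: a post at exactly 12:00 is afternoon, at 0:00 night.
#'
#' @param hour Integer vector in 0..23.
#' @return Factor with levels morning, afternoon, evening, night.
#' @export
daypart <- function(hour) {
  if (any(is.na(hour) | hour < 0 | hour > 23 | hour != floor(hour))) {
    stop("hour must be an integer in 0..23", call. = FALSE)
  }
  out <- dplyr::case_when(hour >= 6 & hour < 12 ~ "morning",
                          hour >= 12 & hour < 18 ~ "afternoon",
                          hour >= 18 ~ "evening",
                          TRUE ~ "night")
  factor(out, levels = DAYPARTS)
}

#' Posting hour and weekday of each post
#'
#' Derived in the timezone the timestamps carry (set when the table was
#' read; diurnal analysis is meaningless without a fixed zone).
#'
#' @param posts Canonical post tibble.
#' @return `post_hour()`: integer vector in 0..23. `post_weekday()`: factor
#'   with levels Monday..Sunday.
#' @export
post_hour <- function(posts) lubridate::hour(posts$created)

#' @rdname post_hour
#' @export
post_weekday <- function(posts) {
  factor(WEEKDAYS[lubridate::wday(posts$created, week_start = 1)],
         levels = WEEKDAYS)
}

#' Aggregate a per-post metric over a temporal (or type) key
#'
#' @param posts Canonical post tibble.
#' @param metric Numeric vector aligned with `posts` (e.g. engagement or
#'   polarity), or `NULL` to aggregate post frequency only.
#' @param by One of `"hour"`, `"weekday"`, `"daypart"`, `"post_type"`.
#' @param metric_name Label recorded in the output.
#' @return Tibble `(key, n, mean)` with one row per key level — empty
#'   levels are kept with `n = 0` and `mean = NA` so the key set is always
#'   exhaustive — plus attribute `metric` with the label. `sum(n)` equals
#'   `nrow(posts)`.
#' @export
aggregate_metric <- function(posts, metric = NULL,
                             by = c("hour", "weekday", "daypart", "post_type"),
                             metric_name = deparse(substitute(metric))) {
  by <- match.arg(by)
  if (is.null(metric)) {
    metric <- rep(NA_real_, nrow(posts))
    metric_name <- "none"
  }
  stopifnot(length(metric) == nrow(posts))
  key <- switch(by,
    hour = factor(post_hour(posts), levels = 0:23),
    weekday = post_weekday(posts),
    daypart = daypart(post_hour(posts)),
    post_type = factor(posts$post_type, levels = POST_TYPES))
  out <- tibble::tibble(key = key, value = metric) |>
    dplyr::group_by(key, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = if (dplyr::n() > 0) mean(value) else NA_real_,
                     .groups = "drop")
  attr(out, "metric") <- metric_name
  out
}

#' Classical one-way analysis of variance
#'
#' Equal-variance one-way ANOVA of a metric across groups (e.g. polarity
#' across the 24 hours of the day), returning the F statistic and its
#' upper-tail p-value. The all-identical degenerate case is defined as
#' (F = 0, p = 1): no variance to apportion means no evidence of group
#' differences.
#'
#' @param values Numeric observations.
#' @param groups Group labels aligned with `values` (coerced to factor;
#'   empty levels dropped).
#' @return List with `statistic` (F), `p_value`, and `df` (numerator,
#'   denominator degrees of freedom).
#' @export
one_way_anova <- function(values, groups) {
  groups <- droplevels(factor(groups))
  stopifnot(length(values) == length(groups))
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (n - k < 1) stop("no residual degrees of freedom", call. = FALSE)
  if (max(table(groups)) < 2) {
    stop("at least one group needs 2 or more observations", call. = FALSE)
  }
  if (length(unique(values)) == 1) {
    return(list(statistic = 0, p_value = 1, df = c(k - 1, n - k)))
  }
  # anova(lm(...)) rather than oneway.test: the latter refuses singleton
  # groups, which hour-of-day factors routinely contain
  tab <- stats::anova(stats::lm(values ~ groups))
  list(statistic = tab[["F value"]][1],
       p_value = tab[["Pr(>F)"]][1],
       df = c(tab$Df[1], tab$Df[2]))
}
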