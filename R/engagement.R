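# Engagement metric and tertile stratification.

#' Per-post engagement
#'
#' Engagement is the sum of comments, shares and reactions. Likes are NOT
#' added on top: a like is one of the six reaction types and is already
#' inside the reaction count, so adding it separately would double-count.
#'
#' @param posts Canonical post tibble (or any data frame with `comments`,
#'   `shares`, `reactions` columns).
#' @return Numeric vector of engagement values, one per post.
#' @export
engagement <- function(posts) {
  posts$comments + posts$shares + posts$reactions
}

#' Split posts into low/medium/high engagement tertiles
#'
#' Thresholds are nearest-rank order statistics of the engagement values at
#' the exact tertile fractions 1/3 and 2/3: `q_low` is the `ceiling(n/3)`-th
#' and `q_high` the `ceiling(2n/3)`-th sorted value. A post is `low` if its
#' engagement is `<= q_low`, `high` if `> q_high`, else `medium`; with
#' heavily tied count data this sends all boundary ties to the lower group,
#' deterministically. In the degenerate case `q_low == q_high` (e.g. all
#' engagements equal) no post is separable from the middle of the
#' distribution and every post is assigned `medium`.
#'
#' @param posts Canonical post tibble with at least 3 rows.
#' @return An object of class `pm_tertiles`: list with `q_low`, `q_high`
#'   and `assignment`, a tibble `(post_id, engagement, group)` in input
#'   order with `group` a factor with levels `low < medium < high`.
#' @export
tertile_split <- function(posts) {
  n <- nrow(posts)
  if (is.null(n) || n < 3) {
    stop("tertile split needs at least 3 posts, got ", n, call. = FALSE)
  }
  e <- engagement(posts)
  s <- sort(e)
  q_low <- s[ceiling(n / 3)]
  q_high <- s[ceiling(2 * n / 3)]
  group <- if (q_low == q_high) {
    rep("medium", n)
  } else {
    ifelse(e <= q_low, "low", ifelse(e > q_high, "high", "medium"))
  }
  structure(list(
    q_low = q_low, q_high = q_high,
    assignment = tibble::tibble(
      post_id = posts$post_id,
      engagement = e,
      group = factor(group, levels = c("low", "medium", "high")))
  ), class = "pm_tertiles")
}

#' @export
print.pm_tertiles <- function(x, ...) {
  cat(sprintf("<pm_tertiles> thresholds: low <= %g < medium <= %g < high\n",
              x$q_low, x$q_high))
  print(table(x$assignment$group))
  invisible(x)
}
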