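# Spearman correlation screen between sentiment scores and interaction
# counts, with the |rho| >= 0.10 highlighting convention.

#' Spearman rank correlation with tie-aware ranks
#'
#' Rho uses average ranks for ties (interaction counts are heavily tied);
#' the p-value comes from the t approximation on n - 2 degrees of freedom,
#' appropriate at the sample sizes of whole-group post collections.
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#' @return List with `rho` and `p_value`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Correlation grid: sentiment vs. interaction attributes
#'
#' The 2 x 5 Spearman screen of polarity and subjectivity against likes,
#' comments, reactions, shares and engagement, with cells flagged when
#' `|rho| >= 0.10` — the conventional "worth a look" threshold for weak
#' monotone association in large social-media samples.
#'
#' @param sentiments Tibble from [score_posts()], aligned with `posts` by
#'   `post_id`.
#' @param posts Canonical post tibble.
#' @return Tibble `(row_var, col_var, rho, p_value, highlighted)` with 10
#'   rows.
#' @export
correlation_matrix <- function(sentiments, posts) {
  stopifnot(nrow(sentiments) == nrow(posts))
  s <- sentiments[match(posts$post_id, sentiments$post_id), ]
  if (anyNA(s$post_id)) stop("sentiment table does not align with posts", call. = FALSE)
  left <- list(polarity = s$polarity, subjectivity = s$subjectivity)
  right <- list(likes = posts$likes, comments = posts$comments,
                reactions = posts$reactions, shares = posts$shares,
                engagement = engagement(posts))
  grid <- expand.grid(row_var = names(left), col_var = names(right),
                      stringsAsFactors = FALSE)
  res <- purrr::pmap(grid, function(row_var, col_var) {
    spearman(left[[row_var]], right[[col_var]])
  })
  tibble::tibble(
    row_var = grid$row_var,
    col_var = grid$col_var,
    rho = vapply(res, `[[`, numeric(1), "rho"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    highlighted = abs(vapply(res, `[[`, numeric(1), "rho")) >= 0.10
  )
}
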