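# Small deterministic post fixtures built in code.

make_posts <- function(n = 5, post_type = "status", likes = 1L,
                       comments = 1L, shares = 0L, reactions = 2L,
                       message = "hola grupo", hour = 12L,
                       tz = "Europe/Madrid") {
  tibble::tibble(
    post_id = sprintf("x%03d", seq_len(n)),
    post_type = rep_len(post_type, n),
    message = rep_len(message, n),
    created = lubridate::make_datetime(2017, 3, 1 + (seq_len(n) - 1) %% 28,
                                       hour = rep_len(hour, n),
                                       min = seq_len(n) %% 60, tz = tz),
    likes = as.integer(rep_len(likes, n)),
    comments = as.integer(rep_len(comments, n)),
    shares = as.integer(rep_len(shares, n)),
    reactions = as.integer(rep_len(reactions, n))
  )
}

# Posts whose engagement values are exactly `e` (comments carry the value).
posts_with_engagement <- function(e) {
  p <- make_posts(length(e), comments = 0L, shares = 0L, reactions = 0L,
                  likes = 0L)
  p$comments <- as.integer(e)
  p
}
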