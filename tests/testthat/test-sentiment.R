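mini_lexicon <- function() {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(c("term,polarity,subjectivity,role,factor",
               "good,0.7,0.6,term,",
               "great,0.8,0.9,term,",
               "bad,-0.7,0.7,term,",
               "not,,,negator,",
               "very,1.3,,intensifier,1.3"), path)
  read_lexicon(path)
}

test_that("scoring follows the documented lexicon-average rules", {
  lex <- mini_lexicon()
  expect_equal(score_text("", lex), list(polarity = 0, subjectivity = 0,
                                         matched_terms = 0L))
  expect_equal(score_text("nothing matches here", lex)$polarity, 0)

  one <- score_text("a great idea", lex)
  expect_equal(one$polarity, 0.8)
  expect_equal(one$subjectivity, 0.9)
  expect_equal(one$matched_terms, 1L)

  neg <- score_text("not good", lex)
  expect_equal(neg$polarity, -0.35)   # 0.7 * -0.5
  expect_equal(neg$subjectivity, 0.6) # subjectivity unmodified

  intens <- score_text("very good", lex)
  expect_equal(intens$polarity, 0.7 * 1.3)

  # negation window is 3 tokens: too-distant negators do nothing
  far <- score_text("not at all that good", lex)
  expect_equal(far$polarity, 0.7)

  two <- score_text("good and bad", lex)
  expect_equal(two$polarity, 0)
  expect_equal(two$subjectivity, mean(c(0.6, 0.7)))
})

test_that("scores stay in range and clamp extreme modifications", {
  lex <- mini_lexicon()
  # stacked intensifiers push past 1 before clamping
  expect_equal(score_text("very very great", lex)$polarity, 1)

  set.seed(4)
  words <- c("good", "great", "bad", "not", "very", "otra", "cosa")
  for (i in 1:50) {
    s <- score_text(paste(sample(words, 8, TRUE), collapse = " "), lex)
    expect_true(s$polarity >= -1 && s$polarity <= 1)
    expect_true(s$subjectivity >= 0 && s$subjectivity <= 1)
  }
})

test_that("adding a positive term never lowers polarity absent modifiers", {
  lex <- mini_lexicon()
  base <- c("bad cosa", "good cosa", "cosa neutra")
  for (txt in base) {
    expect_gte(score_text(paste(txt, "great"), lex)$polarity,
               score_text(txt, lex)$polarity)
  }
})

test_that("bundled-lexicon polarity signs match the published example texts", {
  lex <- read_lexicon()
  ex <- example_scored_texts()
  got <- vapply(ex$text, function(t) score_text(t, lex)$polarity, numeric(1))
  expect_equal(unname(sign(got)), sign(ex$reference_polarity))
})

test_that("score_posts aligns by post and is order-independent", {
  posts <- generate_posts(generator_config(n_posts = 40, seed = 2))
  s1 <- score_posts(posts)
  expect_equal(s1$post_id, posts$post_id)
  shuffled <- posts[rev(seq_len(nrow(posts))), ]
  s2 <- score_posts(shuffled)
  m <- merge(s1, s2, by = "post_id")
  expect_equal(m$polarity.x, m$polarity.y)

  empty <- make_posts(3, message = "")
  s <- score_posts(empty)
  expect_true(all(s$polarity == 0 & s$subjectivity == 0))
})
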