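test_that("tokenize folds case, strips punctuation and applies stopwords", {
  expect_equal(tokenize("Ayuda, AYUDA!"), c("ayuda", "ayuda"))
  expect_equal(tokenize(""), character())
  cfg <- token_config(stopwords = c("el", "de"))
  expect_equal(tokenize("el síndrome de Marfan", cfg), c("síndrome", "marfan"))
  # URLs and handles stripped, digits dropped, accents kept
  expect_equal(tokenize("ver https://spam.example/x @user después 123"),
               c("ver", "después"))
})

test_that("build_corpus counts match a brute-force flat count", {
  expect_equal(build_corpus(c("ayuda ayuda", "vida"))$term_counts,
               c(ayuda = 2L, vida = 1L))
  expect_equal(build_corpus(character())$total_tokens, 0)

  cfg <- token_config(stopwords = spanish_stopwords())
  msgs <- generate_posts(generator_config(n_posts = 200, seed = 5))$message
  corpus <- build_corpus(msgs, cfg)
  flat <- table(tokenize(msgs, cfg))
  expect_equal(corpus$total_tokens, length(tokenize(msgs, cfg)))
  expect_equal(corpus$term_counts[names(flat)],
               stats::setNames(as.integer(flat), names(flat)))
  expect_equal(sum(corpus$term_counts), corpus$total_tokens)
})

test_that("tf-idf zeroes ubiquitous terms and follows tf * ln(3/df)", {
  low <- build_corpus(c("comun unico", "comun"))
  med <- build_corpus("comun medio")
  high <- build_corpus("comun raro")
  tbl <- tfidf_by_group(low, med, high)

  comun <- tbl[tbl$term == "comun", ]
  expect_equal(nrow(comun), 3)
  expect_equal(comun$weight, rep(0, 3))  # present in all three groups

  raro <- tbl[tbl$term == "raro", ]
  expect_equal(raro$group, "high")
  expect_equal(raro$weight, (1 / high$total_tokens) * log(3))

  unico <- tbl[tbl$term == "unico", ]
  expect_equal(unico$weight, (1 / 3) * log(3))

  # weight 0 iff absent from group or present in all three
  expect_true(all((tbl$weight == 0) == (tbl$term == "comun")))
  expect_true(all(is.finite(tbl$weight)) && all(tbl$weight >= 0))
})

test_that("tf-idf handles empty groups", {
  empty <- build_corpus(character())
  expect_equal(nrow(tfidf_by_group(empty, empty, empty)), 0)
  one <- build_corpus("palabra")
  tbl <- tfidf_by_group(one, empty, empty)
  expect_equal(tbl$weight, log(3))
})

test_that("top_terms ranks deterministically with lexicographic ties", {
  expect_equal(top_terms(c(a = 3, b = 1), 1),
               tibble::tibble(term = "a", weight = 3))
  tied <- c(zeta = 2, alfa = 2, beta = 2)
  expect_equal(top_terms(tied, 3)$term, c("alfa", "beta", "zeta"))
  # permutation-stable prefix
  expect_equal(top_terms(rev(tied), 2), top_terms(tied, 2))
  # fewer than k terms returns all
  expect_equal(nrow(top_terms(c(x = 1), 10)), 1)
  # corpus method ranks by raw count
  corp <- build_corpus("vida vida ayuda")
  expect_equal(top_terms(corp, 1)$term, "vida")
})
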