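test_that("expected counts split a+b by corpus size", {
  e <- expected_counts(32, 9, 9665, 335)
  expect_equal(e$E1, 39.63, tolerance = 0.01 / 39.63)
  expect_equal(e$E2, 1.37, tolerance = 0.01 / 1.37)
  expect_equal(e$E1 + e$E2, 41)
  # equal corpora split evenly; E depends on a+b only
  expect_equal(expected_counts(7, 3, 200, 200), expected_counts(0, 10, 200, 200))
  expect_equal(expected_counts(0, 5, 100, 100)$E1, 2.5)
  expect_error(expected_counts(1, 1, 0, 0), "positive")
  expect_error(expected_counts(5, 0, 3, 10), "0 <= a <= c")
})

test_that("log-likelihood is zero exactly at equal relative frequencies", {
  r <- log_likelihood(97, 3, 9700, 300)
  expect_equal(r$ll, 0)
  expect_equal(r$direction, "balanced")
  # and positive off balance, with direction from relative frequency
  up <- log_likelihood(98, 2, 9700, 300)
  expect_gt(up$ll, 0)
  expect_equal(up$direction, "A-enriched")
  expect_equal(log_likelihood(2, 98, 300, 9700)$direction, "B-enriched")
})

test_that("zero-count convention gives single-corpus terms a finite score", {
  r <- log_likelihood(10, 0, 100, 100)
  expect_equal(r$ll, 20 * log(2))
  expect_equal(r$direction, "A-enriched")
  expect_error(log_likelihood(0, 0, 100, 100), "at least 1")
})

test_that("ll grows as the observed split moves away from the expected one", {
  # c = d, a + b = 40 fixed: balanced at a = 20, rising towards the edges
  ll <- vapply(0:40, function(a) log_likelihood(a, 40 - a, 500, 500)$ll,
               numeric(1))
  expect_equal(ll[21], 0)
  expect_true(all(diff(ll[21:41]) > 0))
  expect_true(all(diff(ll[1:21]) < 0))
})

test_that("rank_keywords equals a brute-force per-term evaluation", {
  set.seed(8)
  terms <- replicate(80, paste(sample(letters, 6, TRUE), collapse = ""))
  texts_a <- replicate(40, paste(sample(terms, 15, TRUE, prob = runif(80)),
                                 collapse = " "))
  texts_b <- replicate(10, paste(sample(terms, 12, TRUE, prob = runif(80)),
                                 collapse = " "))
  ca <- build_corpus(texts_a)
  cb <- build_corpus(texts_b)
  ranked <- rank_keywords(ca, cb)

  vocab <- sort(union(names(ca$term_counts), names(cb$term_counts)))
  brute <- vapply(vocab, function(t) {
    a <- if (t %in% names(ca$term_counts)) ca$term_counts[[t]] else 0
    b <- if (t %in% names(cb$term_counts)) cb$term_counts[[t]] else 0
    E1 <- ca$total_tokens * (a + b) / (ca$total_tokens + cb$total_tokens)
    E2 <- cb$total_tokens * (a + b) / (ca$total_tokens + cb$total_tokens)
    2 * ((if (a > 0) a * log(a / E1) else 0) +
           (if (b > 0) b * log(b / E2) else 0))
  }, numeric(1))
  brute_order <- vocab[order(-brute, vocab, method = "radix")]

  expect_equal(ranked$term, brute_order)
  expect_equal(ranked$ll, unname(brute[ranked$term]), tolerance = 1e-12)

  # min_count filters the union vocabulary
  ranked2 <- rank_keywords(ca, cb, min_count = 5)
  expect_true(all(ranked2$a + ranked2$b >= 5))
})

test_that("a planted 10x reference-enriched term ranks near the top", {
  vocab <- tibble::tibble(term = c(paste0("base", 1:30), "planta"),
                          freq_posts = 1, freq_reference = 1)
  cfg <- generator_config(
    n_posts = 400, seed = 21, vocabulary = vocab,
    planted_keywords = tibble::tibble(term = "planta", factor = 10,
                                      corpus = "reference"))
  posts <- generate_posts(cfg)
  doc <- generate_reference_document(cfg, 4000)
  ranked <- rank_keywords(build_corpus(posts$message), build_corpus(doc))
  hit <- match("planta", ranked$term)
  expect_lte(hit, 3)
  expect_equal(ranked$direction[hit], "B-enriched")
})

test_that("calibrate_ratio recovers a known corpus-size ratio", {
  a <- c(30, 100, 50, 12, 80, 200)
  b <- c(5, 3, 10, 6, 1, 4)
  rows <- tibble::tibble(a = a, b = b, ll = postmine:::ll_at_ratio(a, b, 0.9))
  cal <- calibrate_ratio(rows)
  expect_equal(cal$p_hat, 0.9, tolerance = 0.005 / 0.9)
  expect_true(max(abs(cal$residuals)) < 1e-6)
  expect_error(calibrate_ratio(tibble::tibble(a = 1, b = 1, ll = 0)),
               "positive ll")
})

test_that("a single row with a printed score is reproduced after calibration", {
  cal <- calibrate_ratio(tibble::tibble(a = 53, b = 9, ll = 13.4))
  expect_equal(postmine:::ll_at_ratio(53, 9, cal$p_hat), 13.4,
               tolerance = 0.05 / 13.4)
})
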