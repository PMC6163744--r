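test_that("generation is deterministic for a fixed seed", {
  cfg <- generator_config(n_posts = 100, seed = 77)
  expect_identical(generate_posts(cfg), generate_posts(cfg))
  expect_identical(generate_reference_document(cfg, 500),
                   generate_reference_document(cfg, 500))
  # a different seed changes the draw
  cfg2 <- generator_config(n_posts = 100, seed = 78)
  expect_false(identical(generate_posts(cfg), generate_posts(cfg2)))
})

test_that("generated posts satisfy every post invariant by construction", {
  posts <- generate_posts(generator_config(n_posts = 800, seed = 14))
  expect_silent(validate_posts(posts))
  expect_true(all(posts$reactions >= posts$likes))
  expect_equal(lubridate::tz(posts$created), "Europe/Madrid")
})

test_that("hourly intensity controls the timestamp support", {
  intensity <- rep(0, 24)
  intensity[c(14, 15)] <- 1  # hours 13 and 14
  cfg <- generator_config(n_posts = 200, seed = 5,
                          hourly_intensity = intensity)
  posts <- generate_posts(cfg)
  expect_true(all(lubridate::hour(posts$created) %in% c(13, 14)))
})

test_that("empirical type frequencies track the configured probabilities", {
  cfg <- generator_config(n_posts = 20000, seed = 31)
  posts <- generate_posts(cfg)
  freq <- table(factor(posts$post_type, levels = names(cfg$type_probs))) / 20000
  expect_true(all(abs(freq - cfg$type_probs) < 0.02))
})

test_that("reference document reflects planted enrichment", {
  cfg <- generator_config(n_posts = 1000, seed = 19)
  doc <- generate_reference_document(cfg, 6000)
  doc_tokens <- tokenize(doc)
  posts <- generate_posts(cfg)
  post_tokens <- tokenize(posts$message)
  rel <- function(tokens, term) mean(tokens == term)
  # 10x reference-enriched term: at least 5x the post-corpus frequency
  expect_gte(rel(doc_tokens, "discapacidad") / rel(post_tokens, "discapacidad"), 5)
  # 10x post-enriched term goes the other way
  expect_gte(rel(post_tokens, "ayuda") / rel(doc_tokens, "ayuda"), 5)
})

test_that("without planted keywords no vocabulary term is strongly enriched", {
  cfg <- generator_config(
    n_posts = 2000, seed = 23,
    planted_keywords = default_planted_keywords()[0, ])
  doc_tokens <- tokenize(generate_reference_document(cfg, 20000))
  post_tokens <- tokenize(generate_posts(cfg)$message)
  post_tokens <- post_tokens[post_tokens %in% cfg$vocabulary$term]
  # frequency ratios are only estimable for terms actually observed a
  # reasonable number of times; the long-tail terms are too rare to test
  counts <- table(c(doc_tokens, post_tokens))
  common <- names(counts)[counts >= 30]
  expect_gt(length(common), 40)
  ratios <- vapply(common, function(t) {
    mean(doc_tokens == t) / mean(post_tokens == t)
  }, numeric(1))
  expect_true(all(ratios < 3 & ratios > 1 / 3))
})

test_that("invalid generator configs are rejected", {
  expect_error(generator_config(n_posts = 0), "n_posts")
  expect_error(generator_config(type_probs = c(status = 1)), "type_probs")
  expect_error(generator_config(hourly_intensity = rep(0, 24)),
               "hourly_intensity")
  expect_error(generator_config(
    planted_keywords = tibble::tibble(term = "ayuda", factor = -1,
                                      corpus = "posts")), "factors")
})
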