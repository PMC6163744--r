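test_that("a well-formed file round-trips through write_posts/read_posts", {
  posts <- generate_posts(generator_config(n_posts = 50, seed = 11))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_posts(posts, path)
  back <- read_posts(path)
  expect_equal(nrow(back), 50)
  expect_equal(back$post_id, posts$post_id)
  expect_equal(back$post_type, posts$post_type)
  expect_equal(back$message, posts$message)
  expect_equal(back$likes, posts$likes)
  expect_equal(back$comments, posts$comments)
  expect_equal(back$shares, posts$shares)
  expect_equal(back$reactions, posts$reactions)
  # same instants, to the second
  expect_true(all(abs(difftime(back$created, posts$created, units = "secs")) < 1))
})

test_that("validation enforces the post invariants", {
  good <- make_posts(5)
  expect_silent(validate_posts(good))

  bad <- good
  bad$reactions[3] <- 3L; bad$likes[3] <- 5L
  expect_error(validate_posts(bad), "row 3.*reactions \\(3\\) < likes \\(5\\)")
  expect_warning(out <- validate_posts(bad, strict = FALSE), "1 invalid")
  expect_equal(nrow(out), 4)

  bad <- good; bad$post_type[1] <- "poll"
  expect_error(validate_posts(bad), "unknown post_type 'poll'")
  bad <- good; bad$likes[2] <- -1L
  expect_error(validate_posts(bad), "negative or non-integer")
})

test_that("read_posts reports missing columns and honours column remapping", {
  posts <- make_posts(4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_posts(posts, path)

  renamed <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  names(renamed)[names(renamed) == "created"] <- "post_time"
  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(renamed, path2)

  expect_error(read_posts(path2), "missing required column.*created")
  remapped <- read_posts(path2, col_map = c(created = "post_time"))
  expect_equal(remapped$post_id, posts$post_id)
  expect_error(read_posts(path2, col_map = c(created = "nope")),
               "configuration error.*nope")
})

test_that("zoneless timestamps are read in the configured timezone", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(postmine:::POST_COLUMNS, collapse = "\t"),
               "p1\tstatus\thola\t2017-06-01 13:30:00\t1\t1\t0\t2"), path)
  posts <- read_posts(path, tz = "Europe/Madrid")
  expect_equal(lubridate::hour(posts$created), 13)
  expect_equal(lubridate::tz(posts$created), "Europe/Madrid")
})

test_that("read_reference_document returns text verbatim", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("línea uno", "línea dos", "atención sanitaria"), path)
  txt <- read_reference_document(path)
  expect_equal(length(strsplit(txt, "\n")[[1]]), 3)
  expect_match(txt, "atención", fixed = TRUE)  # accents preserved

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines("", empty)
  expect_error(read_reference_document(empty), "empty")
})

test_that("anonymize masks identifiers, is idempotent and touches only messages", {
  posts <- make_posts(3)
  posts$message <- c("write to ana@example.org", "sin identificadores",
                     "Ana Garcia y ana@example.org")
  out <- anonymize(posts, names = "Ana Garcia")
  expect_equal(out$message[1], "write to <EMAIL>")
  expect_equal(out$message[2], "sin identificadores")
  expect_equal(out$message[3], "<NAME> y <EMAIL>")
  expect_identical(out[setdiff(names(out), "message")],
                   posts[setdiff(names(posts), "message")])

  # idempotence on random generated fixtures
  gen <- generate_posts(generator_config(n_posts = 30, seed = 3))
  gen$message[1:5] <- paste(gen$message[1:5], "maria@test.es")
  once <- anonymize(gen, names = "sindrome")
  expect_identical(anonymize(once, names = "sindrome"), once)
})
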