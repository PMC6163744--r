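# Tokenization, bag-of-words corpora and tf-idf across engagement groups.

#' Tokenization configuration
#'
#' @param min_length Minimum token length in characters (default 2, so
#'   stranded single letters from elisions and initials drop out).
#' @param strip_digits Drop tokens made of digits (default `TRUE`).
#' @param strip_urls Remove URLs and user handles before tokenizing
#'   (default `TRUE`); low-engagement spam is dominated by them.
#' @param stopwords Character vector of terms to exclude after case folding;
#'   default empty. See [spanish_stopwords()] for the bundled list.
#' @return A list of class `token_config`.
#' @export
token_config <- function(min_length = 2L, strip_digits = TRUE,
                         strip_urls = TRUE, stopwords = character()) {
  structure(list(min_length = as.integer(min_length),
                 strip_digits = isTRUE(strip_digits),
                 strip_urls = isTRUE(strip_urls),
                 stopwords = tolower(stopwords)),
            class = "token_config")
}

#' Bundled Spanish stopword list
#'
#' A compact function-word list (articles, prepositions, pronouns, common
#' auxiliaries) for Spanish-language post corpora. Supply your own list to
#' [token_config()] for other languages.
#'
#' @return Character vector of lowercase stopwords.
#' @export
spanish_stopwords <- function() {
  readLines(system.file("extdata", "stopwords_es.txt", package = "postmine"),
            encoding = "UTF-8")
}

#' Tokenize text into lowercase word tokens
#'
#' Tokens are maximal runs of Unicode letters (accents preserved — accented
#' Spanish forms are meaningful vocabulary, not noise), lowercased, filtered
#' by length, digit and stopword rules from the config.
#'
#' @param text Character vector; each element is tokenized independently and
#'   the results concatenated in order.
#' @param config A [token_config()].
#' @return Character vector of tokens (empty for empty input).
#' @export
tokenize <- function(text, config = token_config()) {
  stopifnot(inherits(config, "token_config"))
  text <- text[!is.na(text)]
  if (length(text) == 0) return(character())
  txt <- tolower(text)
  if (config$strip_urls) {
    txt <- stringr::str_replace_all(txt, "(https?://|www\\.)\\S+", " ")
    txt <- stringr::str_replace_all(txt, "@\\w+", " ")
  }
  keep <- if (config$strip_digits) "\\p{L}+" else "[\\p{L}\\p{N}]+"
  tokens <- unlist(stringr::str_extract_all(txt, keep), use.names = FALSE)
  tokens <- tokens[nchar(tokens) >= config$min_length]
  if (length(config$stopwords) > 0) {
    tokens <- tokens[!tokens %in% config$stopwords]
  }
  tokens
}

#' Build a bag-of-words corpus from a text collection
#'
#' @param texts Character vector of documents (post messages, reference
#'   document lines, ...).
#' @param config A [token_config()].
#' @return An object of class `pm_corpus`: a list with `term_counts` (named
#'   integer vector, terms sorted lexicographically) and `total_tokens`
#'   (their sum — the corpus-size margin of the keyness contingency table).
#' @export
build_corpus <- function(texts, config = token_config()) {
  tokens <- tokenize(texts, config)
  if (length(tokens) == 0) {
    return(structure(list(term_counts = stats::setNames(integer(), character()),
                          total_tokens = 0L),
                     class = "pm_corpus"))
  }
  counts <- table(tokens)
  term_counts <- stats::setNames(as.integer(counts), names(counts))
  term_counts <- term_counts[order(names(term_counts), method = "radix")]
  structure(list(term_counts = term_counts,
                 total_tokens = sum(term_counts)),
            class = "pm_corpus")
}

#' @export
print.pm_corpus <- function(x, ...) {
  cat(sprintf("<pm_corpus> %d distinct terms, %d tokens\n",
              length(x$term_counts), x$total_tokens))
  invisible(x)
}

term_count <- function(corpus, terms) {
  out <- corpus$term_counts[terms]
  out[is.na(out)] <- 0L
  stats::setNames(as.integer(out), terms)
}

#' Tf-idf weights across the three engagement groups
#'
#' Treats the concatenated low/medium/high-engagement corpora as a
#' three-document collection: `tf(term, g)` is the term's relative frequency
#' in group `g` and `idf(term) = ln(3 / groups containing term)`. A term
#' present in all three groups therefore gets idf 0, i.e. weight exactly 0
#' everywhere — which is the point of the scheme here: vocabulary shared by
#' every engagement level is discarded, leaving each group's distinctive
#' terms.
#'
#' @param low,medium,high `pm_corpus` objects for the three engagement
#'   groups (any may be empty; an empty group contributes tf = 0).
#' @return A tibble with columns `term`, `group` (`low`/`medium`/`high`) and
#'   `weight`, one row per (term, group) with the term present in the group.
#' @export
tfidf_by_group <- function(low, medium, high) {
  groups <- list(low = low, medium = medium, high = high)
  stopifnot(all(vapply(groups, inherits, logical(1), "pm_corpus")))
  vocab <- sort(unique(unlist(lapply(groups, function(g) names(g$term_counts)))))
  if (length(vocab) == 0) {
    return(tibble::tibble(term = character(), group = character(),
                          weight = numeric()))
  }
  counts <- vapply(groups, term_count, integer(length(vocab)), terms = vocab)
  counts <- matrix(counts, nrow = length(vocab),
                   dimnames = list(vocab, names(groups)))
  totals <- vapply(groups, function(g) g$total_tokens, numeric(1))
  tf <- sweep(counts, 2, pmax(totals, 1), "/")
  tf[, totals == 0] <- 0
  df <- rowSums(counts > 0)
  idf <- log(3 / df)
  w <- tf * idf

  out <- tibble::tibble(
    term = rep(vocab, times = 3),
    group = rep(names(groups), each = length(vocab)),
    weight = as.vector(w)
  )
  present <- as.vector(counts > 0)
  out[present, ]
}

#' Highest-weight terms of a corpus or weight table
#'
#' @param x A `pm_corpus` (ranked by raw count — the convention used for a
#'   single reference document), a named numeric vector of weights, or a
#'   data frame with `term` and `weight` columns (one group of a
#'   [tfidf_by_group()] table).
#' @param k Number of terms to return (all terms if fewer exist).
#' @return Tibble `(term, weight)` sorted by decreasing weight, ties broken
#'   lexicographically so the ranking is deterministic.
#' @export
top_terms <- function(x, k) {
  stopifnot(k >= 1)
  if (inherits(x, "pm_corpus")) {
    tbl <- tibble::tibble(term = names(x$term_counts),
                          weight = as.numeric(x$term_counts))
  } else if (is.data.frame(x)) {
    stopifnot(all(c("term", "weight") %in% names(x)))
    tbl <- tibble::tibble(term = x$term, weight = x$weight)
  } else {
    tbl <- tibble::tibble(term = names(x), weight = as.numeric(x))
  }
  tbl <- tbl[order(-tbl$weight, tbl$term, method = "radix"), ]
  utils::head(tbl, k)
}
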