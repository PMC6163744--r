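# Lexicon-based polarity / subjectivity scoring.
#
# The scorer is a transparent lexicon average with the conventional range
# semantics: polarity in [-1, 1] (negative .. positive), subjectivity in
# [0, 1] (objective .. opinionated). Black-box trained lexicons are not
# reproduced; any lexicon in the documented CSV format can be plugged in,
# and a small bundled Spanish + English lexicon drives the defaults.

#' Load a sentiment lexicon
#'
#' The file format is CSV with columns `term`, `polarity` (in \[-1, 1\]),
#' `subjectivity` (in \[0, 1\]), `role` (one of `term`, `negator`,
#' `intensifier`) and `factor` (multiplier for intensifiers; ignored
#' otherwise).
#'
#' @param path Path to a lexicon CSV; default the bundled lexicon.
#' @return Object of class `pm_lexicon`: list with `entries` (tibble of
#'   scored terms), `negators` (character vector) and `intensifiers`
#'   (named numeric vector of multipliers).
#' @export
read_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sentiment_lexicon.csv", package = "postmine")
  }
  raw <- readr::read_csv(path, col_types = "cddcd", progress = FALSE)
  stopifnot(all(c("term", "polarity", "subjectivity", "role", "factor") %in% names(raw)))
  raw$term <- tolower(raw$term)
  entries <- raw[raw$role == "term", c("term", "polarity", "subjectivity")]
  if (any(abs(entries$polarity) > 1) || any(entries$subjectivity < 0 |
                                            entries$subjectivity > 1)) {
    stop("lexicon weights out of range: polarity must be in [-1,1], ",
         "subjectivity in [0,1]", call. = FALSE)
  }
  intens <- raw[raw$role == "intensifier", ]
  if (any(intens$factor <= 0)) stop("intensifier factors must be > 0", call. = FALSE)
  structure(list(
    entries = entries,
    negators = raw$term[raw$role == "negator"],
    intensifiers = stats::setNames(intens$factor, intens$term)
  ), class = "pm_lexicon")
}

#' Score one text for polarity and subjectivity
#'
#' Matching is token-based against the lexicon after the same tokenization
#' the rest of the pipeline uses (stopwords are NOT removed here — negators
#' are function words). Polarity is the mean of the matched terms' polarity
#' weights, each first modified by its context: a negator among the 3
#' tokens preceding the match multiplies its polarity by -0.5 (negation
#' flips and dampens, "not good" being milder than "bad"), and every
#' intensifier in that window multiplies it by the intensifier's factor.
#' Subjectivity is the unmodified mean of matched subjectivity weights.
#' Both means are clamped to their declared ranges; a text with no matches
#' scores (0, 0).
#'
#' @param text A single character string.
#' @param lexicon A `pm_lexicon` from [read_lexicon()].
#' @return List with `polarity` in \[-1, 1\], `subjectivity` in \[0, 1\]
#'   and `matched_terms` (count of lexicon matches).
#' @export
score_text <- function(text, lexicon) {
  stopifnot(inherits(lexicon, "pm_lexicon"))
  tokens <- tokenize(text, token_config(stopwords = character()))
  if (length(tokens) == 0) {
    return(list(polarity = 0, subjectivity = 0, matched_terms = 0L))
  }
  idx <- match(tokens, lexicon$entries$term)
  hits <- which(!is.na(idx))
  if (length(hits) == 0) {
    return(list(polarity = 0, subjectivity = 0, matched_terms = 0L))
  }
  pol <- vapply(hits, function(i) {
    p <- lexicon$entries$polarity[idx[i]]
    window <- if (i > 1) tokens[max(1, i - 3):(i - 1)] else character()
    if (any(window %in% lexicon$negators)) p <- p * -0.5
    for (w in window) {
      if (w %in% names(lexicon$intensifiers)) p <- p * lexicon$intensifiers[[w]]
    }
    p
  }, numeric(1))
  subj <- lexicon$entries$subjectivity[idx[hits]]
  list(polarity = clamp(mean(pol), -1, 1),
       subjectivity = clamp(mean(subj), 0, 1),
       matched_terms = length(hits))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Score every post in a collection
#'
#' @param posts Canonical post tibble.
#' @param lexicon A `pm_lexicon`; default the bundled lexicon.
#' @return Tibble `(post_id, polarity, subjectivity, matched_terms)` aligned
#'   with the input rows.
#' @export
score_posts <- function(posts, lexicon = read_lexicon()) {
  scores <- lapply(posts$message, score_text, lexicon = lexicon)
  tibble::tibble(
    post_id = posts$post_id,
    polarity = vapply(scores, `[[`, numeric(1), "polarity"),
    subjectivity = vapply(scores, `[[`, numeric(1), "subjectivity"),
    matched_terms = vapply(scores, `[[`, integer(1), "matched_terms")
  )
}

#' Example messages with published sentiment scores
#'
#' Four English-language example messages from a published rare-disease
#' group analysis together with the polarity and subjectivity their
#' original (trained-lexicon) toolkit assigned. Absolute magnitudes are
#' toolkit-specific; across scorers only the polarity signs are
#' comparable, which is how these examples are used in the test suite.
#'
#' @return Tibble `(text, reference_polarity, reference_subjectivity)`.
#' @export
example_scored_texts <- function() {
  path <- system.file("extdata", "example_posts_polarity.csv",
                      package = "postmine")
  readr::read_csv(path, col_types = "cdd", progress = FALSE)
}
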