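# Log-likelihood keyness: contingency-table comparison of two corpora.
#
# For a term occurring a times in corpus A (c tokens total) and b times in
# corpus B (d tokens total), the expected counts under a common rate are
#
#   E1 = c (a + b) / (c + d),   E2 = d (a + b) / (c + d)
#
# and the keyness score is the two-term log-likelihood ratio
#
#   LL = 2 ( a ln(a / E1) + b ln(b / E2) ),  with 0 ln(0/E) := 0.
#
# LL is 0 exactly when the relative frequencies a/c and b/d coincide and
# grows as the term's use diverges between the corpora. Because E1 and E2
# depend on (c, d) only through the ratio p = c / (c + d), LL for fixed
# (a, b) is a one-parameter function of p — which is what makes the ratio
# recoverable from a published score table whose corpus totals were never
# printed (see calibrate_ratio()).

check_rows <- function(a, b, c, d) {
  if (any(c + d <= 0)) stop("corpus totals c + d must be positive", call. = FALSE)
  if (any(a < 0 | b < 0 | a > c | b > d)) {
    stop("counts must satisfy 0 <= a <= c and 0 <= b <= d", call. = FALSE)
  }
}

#' Expected term counts under a common rate
#'
#' @param a,b Observed term counts in corpus A and corpus B.
#' @param c,d Total token counts of corpus A and corpus B.
#' @return Tibble with columns `E1`, `E2`; `E1 + E2 = a + b` exactly.
#' @export
expected_counts <- function(a, b, c, d) {
  check_rows(a, b, c, d)
  n <- a + b
  tibble::tibble(E1 = c * n / (c + d), E2 = d * n / (c + d))
}

# 0 * ln(0 / E) := 0, so single-corpus terms get a finite score.
xlogx_ratio <- function(x, e) ifelse(x == 0, 0, x * log(x / e))

#' Log-likelihood keyness score
#'
#' Computes the two-term log-likelihood ratio for each term row of a
#' two-corpus contingency table, with the enrichment direction given by the
#' relative-frequency comparison (`a/c` vs `b/d`) — the score alone says how
#' strongly a term separates the corpora, not in which one it is
#' over-represented.
#'
#' @inheritParams expected_counts
#' @param term Optional term labels carried through to the output.
#' @return Tibble with columns `term` (if given), `a`, `b`, `E1`, `E2`,
#'   `ll` (>= 0) and `direction` (`"A-enriched"`, `"B-enriched"` or
#'   `"balanced"`).
#' @export
log_likelihood <- function(a, b, c, d, term = NULL) {
  check_rows(a, b, c, d)
  if (any(a + b == 0)) stop("a + b must be at least 1", call. = FALSE)
  ec <- expected_counts(a, b, c, d)
  ll <- 2 * (xlogx_ratio(a, ec$E1) + xlogx_ratio(b, ec$E2))
  ll <- pmax(ll, 0)  # guard against -1e-16 from rounding at the balanced point
  rel_a <- a / c
  rel_b <- b / d
  direction <- dplyr::case_when(rel_a > rel_b ~ "A-enriched",
                                rel_a < rel_b ~ "B-enriched",
                                TRUE ~ "balanced")
  out <- tibble::tibble(a = a, b = b, E1 = ec$E1, E2 = ec$E2,
                        ll = ll, direction = direction)
  if (!is.null(term)) out <- dplyr::bind_cols(tibble::tibble(term = term), out)
  out
}

#' Rank the union vocabulary of two corpora by keyness
#'
#' Builds one contingency row per term of the union vocabulary (corpus
#' totals taken from the corpora themselves), scores each with
#' [log_likelihood()], and sorts by decreasing score with a lexicographic
#' tie-break.
#'
#' @param corpus_a,corpus_b `pm_corpus` objects (e.g. the post corpus and
#'   the reference-document corpus).
#' @param min_count Keep only terms with combined count `a + b >=
#'   min_count` (default 1, i.e. the full union vocabulary).
#' @return Tibble `(term, a, b, E1, E2, ll, direction)` sorted by `ll`
#'   descending.
#' @export
rank_keywords <- function(corpus_a, corpus_b, min_count = 1) {
  stopifnot(inherits(corpus_a, "pm_corpus"), inherits(corpus_b, "pm_corpus"))
  if (corpus_a$total_tokens == 0 || corpus_b$total_tokens == 0) {
    stop("both corpora must be non-empty", call. = FALSE)
  }
  vocab <- sort(unique(c(names(corpus_a$term_counts), names(corpus_b$term_counts))))
  a <- term_count(corpus_a, vocab)
  b <- term_count(corpus_b, vocab)
  keep <- (a + b) >= min_count
  vocab <- vocab[keep]; a <- a[keep]; b <- b[keep]
  if (length(vocab) == 0) {
    return(log_likelihood(1, 1, 2, 2, term = "x")[0, ])
  }
  res <- log_likelihood(unname(a), unname(b),
                        corpus_a$total_tokens, corpus_b$total_tokens,
                        term = vocab)
  res[order(-res$ll, res$term, method = "radix"), ]
}

# LL as a function of (a, b) and the corpus-size ratio p = c / (c + d):
# E1 = (a + b) p, E2 = (a + b)(1 - p).
ll_at_ratio <- function(a, b, p) {
  n <- a + b
  2 * (xlogx_ratio(a, n * p) + xlogx_ratio(b, n * (1 - p)))
}

#' Recover the corpus-size ratio behind a published keyness table
#'
#' A published keyness table often prints, per term, the score and the two
#' observed counts but not the corpus totals. Since the two-term LL depends
#' on the totals only through `p = c / (c + d)`, that single unknown can be
#' recovered: `calibrate_ratio()` finds the `p` in (0, 1) minimizing the
#' summed squared difference between `ll_at_ratio(a, b, p)` and the printed
#' scores (one-dimensional bounded minimization via [stats::optimize()]).
#' A small maximum residual across rows is then strong evidence that the
#' table was produced by exactly this two-term formula with one common pair
#' of corpus totals. The recovered `p_hat` is an estimate, not a published
#' value.
#'
#' @param rows Data frame with columns `a`, `b` (printed term counts) and
#'   `ll` (printed scores); at least one row must have `ll > 0`.
#' @return Object of class `pm_calibration`: list with `p_hat`, `fitted`
#'   (LL recomputed at `p_hat`) and `residuals` (`fitted - ll`).
#' @export
calibrate_ratio <- function(rows) {
  stopifnot(all(c("a", "b", "ll") %in% names(rows)))
  if (nrow(rows) < 1 || all(rows$ll <= 0)) {
    stop("calibration needs at least one row with positive ll", call. = FALSE)
  }
  obj <- function(p) sum((ll_at_ratio(rows$a, rows$b, p) - rows$ll)^2)
  opt <- stats::optimize(obj, interval = c(1e-9, 1 - 1e-9), tol = 1e-12)
  eps <- 1e-6
  if (opt$minimum < eps || opt$minimum > 1 - eps) {
    stop("calibration failed: no interior ratio improves on the endpoints",
         call. = FALSE)
  }
  fitted <- ll_at_ratio(rows$a, rows$b, opt$minimum)
  structure(list(p_hat = opt$minimum, fitted = fitted,
                 residuals = fitted - rows$ll),
            class = "pm_calibration")
}

#' @export
print.pm_calibration <- function(x, ...) {
  cat(sprintf("<pm_calibration> p_hat = %.5f, max |residual| = %.4f over %d rows\n",
              x$p_hat, max(abs(x$residuals)), length(x$residuals)))
  invisible(x)
}

#' Published keyness rows: rare-disease posts vs. priority decalogue
#'
#' The printed rows of a published keyness comparison between a Spanish
#' rare-disease Facebook post corpus and the FEDER priority decalogue: per
#' term, the log-likelihood score, the count in the post corpus (`a`) and
#' the count in the decalogue (`b`). `"top"` returns the twelve
#' highest-scoring terms, `"low"` the ten lowest. The corpus totals were not
#' published; [calibrate_ratio()] recovers their ratio from these rows.
#'
#' @param which `"top"` (default) or `"low"`.
#' @return Tibble with columns `term`, `gloss` (English gloss), `ll`, `a`,
#'   `b`.
#' @export
decalogue_keyness_rows <- function(which = c("top", "low")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("decalogue_keyness_", which, ".csv"),
                      package = "postmine")
  readr::read_csv(path, col_types = "ccdii", progress = FALSE)
}
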