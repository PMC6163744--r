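# Dataset characterization and the end-to-end pipeline driver.

ATTRIBUTES <- c("likes", "comments", "reactions", "shares", "engagement")

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Characterize a post collection by type
#'
#' Per observed post type plus a `total` row: the number of posts and the
#' mean and population standard deviation of likes, comments, reactions,
#' shares and engagement. This is the standard first-look table for a
#' post corpus; engagement being a sum of components, its mean equals the
#' sum of the component means (comments + shares + reactions) on every row.
#'
#' @param posts Canonical post tibble (non-empty).
#' @return Tibble with columns `post_type`, `n`, and `{attribute}_mean`,
#'   `{attribute}_sd` for the five attributes; `n` sums to `2 * nrow(posts)`
#'   counting the total row once more.
#' @export
characterize <- function(posts) {
  if (nrow(posts) == 0) stop("posts must be non-empty", call. = FALSE)
  dat <- tibble::as_tibble(posts[c("post_type", COUNT_COLUMNS)])
  dat$engagement <- engagement(posts)
  one <- function(d, label) {
    row <- tibble::tibble(post_type = label, n = nrow(d))
    for (attr in ATTRIBUTES) {
      row[[paste0(attr, "_mean")]] <- mean(d[[attr]])
      row[[paste0(attr, "_sd")]] <- pop_sd(d[[attr]])
    }
    row
  }
  types <- sort(unique(dat$post_type))
  dplyr::bind_rows(
    purrr::map(types, function(tp) one(dat[dat$post_type == tp, ], tp)),
    one(dat, "total")
  )
}

#' Pipeline run configuration
#'
#' @param posts_path Path to the post table ([read_posts()] dialect).
#' @param reference_path Path to the reference document (plain text).
#' @param out_dir Output directory (created if missing).
#' @param lexicon_path Sentiment lexicon CSV; `NULL` for the bundled one.
#' @param stopwords Character vector of stopwords; default the bundled
#'   Spanish list.
#' @param name_list Personal names to mask during anonymization.
#' @param tz Timezone for timestamps and hour/weekday extraction.
#' @param delim Post-table delimiter.
#' @param min_count Keyness minimum combined term count.
#' @param k_terms How many terms to keep per ranked output table.
#' @return List of class `pm_runconfig`.
#' @export
run_config <- function(posts_path, reference_path, out_dir,
                       lexicon_path = NULL, stopwords = spanish_stopwords(),
                       name_list = character(), tz = "Europe/Madrid",
                       delim = "\t", min_count = 1, k_terms = 25) {
  for (p in c(posts_path, reference_path, lexicon_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("configuration error: input file not found: ", p, call. = FALSE)
    }
  }
  structure(list(posts_path = posts_path, reference_path = reference_path,
                 out_dir = out_dir, lexicon_path = lexicon_path,
                 stopwords = stopwords, name_list = name_list, tz = tz,
                 delim = delim, min_count = min_count, k_terms = k_terms),
            class = "pm_runconfig")
}

stage <- function(name, log, expr) {
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  log(sprintf("stage %-16s ok", name))
  res
}

#' Run the full content-based and temporal analysis
#'
#' Orchestrates every module over one post table and one reference
#' document: anonymization, dataset characterization, engagement tertiles,
#' tf-idf term tables per engagement group, keyness ranking of the post
#' corpus against the reference document, per-post sentiment, temporal
#' aggregates (hour, weekday, daypart) with ANOVA screens, and the
#' sentiment-interaction correlation grid. All tables are written as CSV
#' under `config$out_dir` (LL scores and means rounded to one decimal in
#' the CSVs), together with a full-precision `summary.json` and a
#' `pipeline.log`. The run is a pure function of the inputs and config:
#' identical inputs give byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of the computed tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pm_runconfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  tok <- token_config(stopwords = config$stopwords)

  posts <- stage("read_posts", log,
                 read_posts(config$posts_path, delim = config$delim,
                            tz = config$tz))
  log(sprintf("  %d posts read", nrow(posts)))
  reference <- stage("read_reference", log,
                     read_reference_document(config$reference_path))
  lexicon <- stage("read_lexicon", log, read_lexicon(config$lexicon_path))

  posts <- stage("anonymize", log, anonymize(posts, names = config$name_list))

  char_tbl <- stage("characterize", log, characterize(posts))

  tertiles <- stage("tertiles", log, tertile_split(posts))
  groups <- split(posts$message, tertiles$assignment$group)

  tfidf_tbl <- stage("tfidf", log, {
    corp <- lapply(c(low = "low", medium = "medium", high = "high"),
                   function(g) build_corpus(groups[[g]], tok))
    w <- tfidf_by_group(corp$low, corp$medium, corp$high)
    dplyr::bind_rows(lapply(split(w, w$group), top_terms, k = config$k_terms),
                     .id = "group")
  })

  keyness_tbl <- stage("keyness", log, {
    corpus_a <- build_corpus(posts$message, tok)
    corpus_b <- build_corpus(reference, tok)
    utils::head(rank_keywords(corpus_a, corpus_b, min_count = config$min_count),
                config$k_terms)
  })

  sentiments <- stage("sentiment", log, score_posts(posts, lexicon))

  eng <- engagement(posts)
  temporal_tbls <- stage("temporal", log, list(
    hour_freq = aggregate_metric(posts, eng, by = "hour",
                                 metric_name = "engagement"),
    hour_polarity = aggregate_metric(posts, sentiments$polarity, by = "hour",
                                     metric_name = "polarity"),
    weekday = aggregate_metric(posts, eng, by = "weekday",
                               metric_name = "engagement"),
    daypart = aggregate_metric(posts, sentiments$polarity, by = "daypart",
                               metric_name = "polarity")
  ))
  anova_res <- stage("anova", log, list(
    polarity_hour = one_way_anova(sentiments$polarity, post_hour(posts)),
    polarity_weekday = one_way_anova(sentiments$polarity, post_weekday(posts)),
    engagement_hour = one_way_anova(eng, post_hour(posts)),
    engagement_weekday = one_way_anova(eng, post_weekday(posts))
  ))

  corr_tbl <- stage("correlations", log, correlation_matrix(sentiments, posts))

  stage("write_outputs", log, {
    out <- function(name) file.path(config$out_dir, name)
    readr::write_csv(round_cols(char_tbl, 1), out("characterization.csv"))
    readr::write_csv(tertiles$assignment, out("engagement_groups.csv"))
    readr::write_csv(tfidf_tbl, out("tfidf_terms.csv"))
    k <- keyness_tbl
    k$ll <- round(k$ll, 1)
    readr::write_csv(k[c("term", "ll", "a", "b", "direction")], out("keyness.csv"))
    readr::write_csv(sentiments, out("sentiment.csv"))
    readr::write_csv(round_cols(temporal_tbls$hour_freq, 1), out("temporal_hour.csv"))
    readr::write_csv(round_cols(temporal_tbls$weekday, 1), out("temporal_weekday.csv"))
    readr::write_csv(round_cols(temporal_tbls$daypart, 3), out("temporal_daypart.csv"))
    readr::write_csv(corr_tbl, out("correlations.csv"))
    jsonlite::write_json(list(
      n_posts = nrow(posts),
      tertile_thresholds = list(q_low = tertiles$q_low, q_high = tertiles$q_high),
      anova = anova_res,
      top_keyness = utils::head(keyness_tbl, 12),
      correlations = corr_tbl
    ), out("summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, out("pipeline.log"))
  })

  invisible(list(posts = posts, characterization = char_tbl,
                 tertiles = tertiles, tfidf = tfidf_tbl,
                 keyness = keyness_tbl, sentiments = sentiments,
                 temporal = temporal_tbls, anova = anova_res,
                 correlations = corr_tbl))
}

round_cols <- function(tbl, digits) {
  num <- vapply(tbl, is.numeric, logical(1)) & !(names(tbl) %in% c("n"))
  tbl[num] <- lapply(tbl[num], round, digits = digits)
  tbl
}
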