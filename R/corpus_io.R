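# Reading, writing, validating and anonymizing post tables.

POST_TYPES <- c("event", "link", "note", "photo", "status", "video")

POST_COLUMNS <- c("post_id", "post_type", "message", "created",
                  "likes", "comments", "shares", "reactions")

COUNT_COLUMNS <- c("likes", "comments", "shares", "reactions")

#' Validate a post table
#'
#' Checks the structural invariants every downstream step relies on: all
#' required columns present, interaction counts non-negative integers,
#' `reactions >= likes` (a like is one of the six Facebook reactions, so the
#' reaction total can never fall below the like count), `post_type` one of
#' the six export types, and timestamps timezone-aware.
#'
#' @param posts A data frame of posts (see [read_posts()] for the schema).
#' @param strict If `TRUE` (default) any invalid row aborts with an error
#'   naming the first offending row; if `FALSE`, invalid rows are dropped
#'   with a warning listing how many were skipped.
#' @return The validated (possibly filtered) post tibble, invisibly ordered
#'   as given.
#' @export
validate_posts <- function(posts, strict = TRUE) {
  missing <- setdiff(POST_COLUMNS, names(posts))
  if (length(missing) > 0) {
    stop("post table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  posts <- tibble::as_tibble(posts)
  if (!inherits(posts$created, "POSIXct")) {
    stop("'created' must be a POSIXct timestamp column", call. = FALSE)
  }

  counts <- as.matrix(posts[COUNT_COLUMNS])
  bad <- is.na(posts$created) |
    apply(counts, 1, function(x) anyNA(x) || any(x < 0) || any(x != floor(x))) |
    posts$reactions < posts$likes |
    !(posts$post_type %in% POST_TYPES)

  if (any(bad)) {
    if (strict) {
      i <- which(bad)[1]
      stop(sprintf("invalid post at row %d: %s", i, describe_violation(posts[i, ])),
           call. = FALSE)
    }
    warning(sprintf("skipping %d invalid post row(s)", sum(bad)), call. = FALSE)
    posts <- posts[!bad, ]
  }
  posts
}

describe_violation <- function(row) {
  if (!(row$post_type %in% POST_TYPES)) {
    return(sprintf("unknown post_type '%s'", row$post_type))
  }
  if (is.na(row$created)) return("unparseable timestamp")
  cnt <- unlist(row[COUNT_COLUMNS])
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != floor(cnt))) {
    return("negative or non-integer interaction count")
  }
  if (row$reactions < row$likes) {
    return(sprintf("reactions (%d) < likes (%d)", row$reactions, row$likes))
  }
  "invariant violation"
}

#' Read a post table from a Netvizz-style export
#'
#' Parses a delimited post export (one row per post) into the canonical post
#' tibble. The expected dialect is tab-separated UTF-8 with a single header
#' row and ISO-8601 timestamps; both the delimiter and the column names can
#' be remapped because export dialects varied across tool versions.
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter, default tab.
#' @param col_map Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(post_id = "id", created = "post_time")`.
#'   Canonical columns are `post_id`, `post_type`, `message`, `created`,
#'   `likes`, `comments`, `shares`, `reactions`.
#' @param tz Timezone applied to timestamps that carry no zone designator
#'   (default `"Europe/Madrid"`); timestamps with an explicit offset are
#'   converted into this zone.
#' @param strict Passed to [validate_posts()]: fail on the first invalid row
#'   (default) or skip invalid rows with a warning.
#' @return A tibble with the canonical post columns, one row per data row of
#'   the file, in file order.
#' @export
read_posts <- function(path, delim = "\t", col_map = NULL,
                       tz = "Europe/Madrid", strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, trim_ws = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      file_col <- col_map[[canon]]
      if (!file_col %in% names(raw)) {
        stop(sprintf("configuration error: mapped column '%s' (for '%s') not in file",
                     file_col, canon), call. = FALSE)
      }
      names(raw)[names(raw) == file_col] <- canon
    }
  }
  missing <- setdiff(POST_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stop("configuration error: header is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  posts <- tibble::tibble(
    post_id   = raw$post_id,
    post_type = raw$post_type,
    message   = dplyr::coalesce(raw$message, ""),
    created   = parse_timestamps(raw$created, tz),
    likes     = suppressWarnings(as.numeric(raw$likes)),
    comments  = suppressWarnings(as.numeric(raw$comments)),
    shares    = suppressWarnings(as.numeric(raw$shares)),
    reactions = suppressWarnings(as.numeric(raw$reactions))
  )
  posts <- validate_posts(posts, strict = strict)
  posts[COUNT_COLUMNS] <- lapply(posts[COUNT_COLUMNS], as.integer)
  posts
}

# ISO-8601, with or without zone offset; zoneless values are interpreted in
# `tz`, offset-carrying values converted into it.
parse_timestamps <- function(x, tz) {
  has_offset <- stringr::str_detect(x, "(Z|[+-]\\d{2}:?\\d{2})$")
  out <- rep(lubridate::as_datetime(NA), length(x))
  if (any(has_offset, na.rm = TRUE)) {
    i <- which(has_offset)
    out[i] <- lubridate::with_tz(
      lubridate::ymd_hms(x[i], quiet = TRUE), tzone = tz)
  }
  i <- which(!has_offset | is.na(has_offset))
  if (length(i) > 0) {
    out[i] <- lubridate::ymd_hms(x[i], tz = tz, quiet = TRUE)
  }
  lubridate::with_tz(out, tzone = tz)
}

#' Write a post table in the same dialect `read_posts()` accepts
#'
#' Timestamps are serialized as ISO-8601 with an explicit UTC offset so the
#' file round-trips losslessly through [read_posts()].
#'
#' @param posts Canonical post tibble.
#' @param path Output path.
#' @param delim Field delimiter, default tab.
#' @return `path`, invisibly.
#' @export
write_posts <- function(posts, path, delim = "\t") {
  out <- posts
  out$created <- strftime(posts$created, "%Y-%m-%dT%H:%M:%S%z",
                          tz = lubridate::tz(posts$created))
  readr::write_delim(out[POST_COLUMNS], path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Read a reference document as raw text
#'
#' Reads a plain-text priority document (for example a federation's decalogue
#' of priorities) verbatim; all normalization happens later in tokenization.
#'
#' @param path Path to a UTF-8 text file.
#' @return The full file contents as a single string.
#' @export
read_reference_document <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- readr::read_file(path)
  if (nchar(trimws(txt)) == 0) {
    stop("reference document is empty: ", path, call. = FALSE)
  }
  txt
}

#' Mask personal identifiers in post messages
#'
#' Replaces email-shaped substrings and any terms from an explicit name list
#' with placeholder tokens. Only `message` is touched; identifiers are
#' matched deterministically (a regular expression for emails, literal
#' case-insensitive whole-word matches for names) so the operation is
#' idempotent and fully testable. No named-entity recognition is attempted.
#'
#' @param posts Canonical post tibble.
#' @param names Character vector of personal names to mask (default none).
#' @param email_token,name_token Replacement placeholders.
#' @return The post tibble with masked messages; all other fields unchanged.
#' @export
anonymize <- function(posts, names = character(),
                      email_token = "<EMAIL>", name_token = "<NAME>") {
  msg <- posts$message
  msg <- stringr::str_replace_all(
    msg, "[[:alnum:]._%+-]+@[[:alnum:].-]+\\.[[:alpha:]]{2,}", email_token)
  for (nm in names) {
    msg <- stringr::str_replace_all(
      msg,
      stringr::regex(paste0("\\b", escape_regex(nm), "\\b"), ignore_case = TRUE),
      name_token)
  }
  posts$message <- msg
  posts
}

escape_regex <- function(x) stringr::str_replace_all(x, "([.^$*+?()\\[\\]{}|\\\\])", "\\\\\\1")
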