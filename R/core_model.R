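STRATA <- c("zero_dose", "under_vaccinated", "unknown")
ORIGINS <- c("original_option", "added_category")

RESPONSE_COLS <- c("response_id", "survey_round", "text", "translated_text",
                   "weight", "stratum", "admin_unit")

#' Normalize free-text for comparison and deduplication
#'
#' Applies Unicode NFC normalization and trims surrounding whitespace
#' (`"exact"`), optionally case-folding as well (`"trim_casefold"`). All
#' string comparison in the package goes through this function so that
#' French diacritics compare consistently across platforms.
#'
#' @param x Character vector.
#' @param normalization `"exact"` (NFC + trim) or `"trim_casefold"`
#'   (NFC + trim + lower case).
#' @return Character vector of the same length.
#' @export
normalize_text <- function(x, normalization = c("exact", "trim_casefold")) {
  normalization <- match.arg(normalization)
  out <- stringi::stri_trans_nfc(as.character(x))
  out <- stringi::stri_trim_both(out)
  if (normalization == "trim_casefold") out <- stringi::stri_trans_tolower(out)
  out
}

#' Construct and validate a table of survey responses
#'
#' A survey-response table is a `data.frame` with one row per free-text
#' answer and the columns `response_id`, `survey_round`, `text`,
#' `translated_text`, `weight`, `stratum`, `admin_unit`. Missing optional
#' columns are filled with defaults: weight 1, stratum `"unknown"`,
#' `translated_text`/`admin_unit` `NA`.
#'
#' @param df A data.frame with at least `response_id`, `survey_round`
#'   and `text`.
#' @return The validated data.frame with class `survey_responses`.
#' @export
survey_responses <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("response_id", "survey_round", "text")
  for (col in required) {
    if (!col %in% names(df)) {
      stop("schema error: required field '", col, "' is missing", call. = FALSE)
    }
  }
  if (!"translated_text" %in% names(df)) df$translated_text <- NA_character_
  if (!"weight" %in% names(df)) df$weight <- 1
  if (!"stratum" %in% names(df)) df$stratum <- "unknown"
  if (!"admin_unit" %in% names(df)) df$admin_unit <- NA_character_

  df$response_id <- as.character(df$response_id)
  df$survey_round <- as.integer(df$survey_round)
  df$text <- as.character(df$text)
  df$translated_text <- as.character(df$translated_text)
  df$weight <- as.numeric(df$weight)
  df$weight[is.na(df$weight)] <- 1
  df$stratum <- as.character(df$stratum)
  df$stratum[is.na(df$stratum) | df$stratum == ""] <- "unknown"
  df$admin_unit <- as.character(df$admin_unit)

  dup <- duplicated(df$response_id)
  if (any(dup)) {
    stop("schema error: duplicate response_id '", df$response_id[which(dup)[1]],
         "' at record ", which(dup)[1], call. = FALSE)
  }
  empty <- !nzchar(trimws(df$text)) | is.na(df$text)
  if (any(empty)) {
    stop("schema error: empty text at record ", which(empty)[1], call. = FALSE)
  }
  bad_w <- is.na(df$weight) | df$weight < 0
  if (any(bad_w)) {
    stop("schema error: negative or missing weight at record ",
         which(bad_w)[1], call. = FALSE)
  }
  bad_s <- !df$stratum %in% STRATA
  if (any(bad_s)) {
    stop("schema error: unknown stratum '", df$stratum[which(bad_s)[1]],
         "' at record ", which(bad_s)[1], " (expected one of ",
         paste(STRATA, collapse = ", "), ")", call. = FALSE)
  }
  df <- df[RESPONSE_COLS]
  rownames(df) <- NULL
  class(df) <- c("survey_responses", "data.frame")
  df
}

#' Read survey responses from a delimited or JSON-lines file
#'
#' @param path File path. UTF-8 encoding is assumed.
#' @param format `"auto"` (by extension: `.jsonl`/`.ndjson` are JSON-lines,
#'   anything else delimited), `"delimited"` (comma-separated with header)
#'   or `"json_lines"` (one JSON object per line).
#' @return A [survey_responses()] data.frame.
#' @export
read_responses <- function(path, format = c("auto", "delimited", "json_lines")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE))
      "json_lines" else "delimited"
  }
  if (format == "delimited") {
    df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                   colClasses = "character", na.strings = "")
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) stop("empty input: ", path, call. = FALSE)
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) stop("schema error: record ", i,
                                               " is not valid JSON", call. = FALSE))
      as.data.frame(lapply(rec, function(v) if (is.null(v)) NA else v),
                    stringsAsFactors = FALSE)
    })
    all_cols <- unique(unlist(lapply(recs, names)))
    recs <- lapply(recs, function(r) {
      for (col in setdiff(all_cols, names(r))) r[[col]] <- NA
      r[all_cols]
    })
    df <- do.call(rbind, recs)
  }
  if (nrow(df) == 0) stop("empty input: ", path, call. = FALSE)
  survey_responses(df)
}

#' Write survey responses to a delimited or JSON-lines file
#'
#' Writing then reading back reproduces the table field-for-field.
#'
#' @param responses A [survey_responses()] data.frame.
#' @param path Output path.
#' @inheritParams read_responses
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path,
                            format = c("auto", "delimited", "json_lines")) {
  format <- match.arg(format)
  responses <- survey_responses(as.data.frame(responses))
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE))
      "json_lines" else "delimited"
  }
  if (format == "delimited") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    write.csv(as.data.frame(responses), con, row.names = FALSE, na = "")
  } else {
    lines <- vapply(seq_len(nrow(responses)), function(i) {
      rec <- as.list(responses[i, , drop = FALSE])
      rec <- rec[!vapply(rec, function(v) is.na(v) && !is.numeric(v), logical(1))]
      jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null")
    }, character(1))
    writeLines(lines, path, useBytes = FALSE)
  }
  invisible(path)
}

#' Construct and validate a closed category scheme
#'
#' A category scheme is the ordered, numbered list of candidate reason
#' categories an assignment must come from: the original questionnaire
#' options plus any researcher-added categories. Indices are 1-based
#' because prompts ask the model to return "the number associated with the
#' chosen label".
#'
#' @param df Data.frame with columns `index`, `label` and optionally
#'   `domain_tag`, `origin` (`"original_option"` or `"added_category"`).
#' @param name,version Scheme identification strings.
#' @return A `category_scheme` data.frame with attributes `name`, `version`.
#' @export
category_scheme <- function(df, name = "scheme", version = "1") {
  stopifnot(is.data.frame(df))
  for (col in c("index", "label")) {
    if (!col %in% names(df)) {
      stop("validation error: scheme is missing column '", col, "'",
           call. = FALSE)
    }
  }
  if (!"domain_tag" %in% names(df)) df$domain_tag <- NA_character_
  if (!"origin" %in% names(df)) df$origin <- "original_option"
  df$index <- as.integer(df$index)
  df$label <- as.character(df$label)
  df$domain_tag <- as.character(df$domain_tag)
  df$origin <- as.character(df$origin)
  df$origin[is.na(df$origin) | df$origin == ""] <- "original_option"

  if (nrow(df) < 2) {
    stop("validation error: scheme needs at least 2 categories", call. = FALSE)
  }
  df <- df[order(df$index), , drop = FALSE]
  if (anyDuplicated(df$index)) {
    stop("validation error: duplicate category index ",
         df$index[duplicated(df$index)][1], call. = FALSE)
  }
  if (!identical(df$index, seq_len(nrow(df)))) {
    stop("validation error: category indices must be contiguous from 1 (got ",
         paste(df$index, collapse = ","), ")", call. = FALSE)
  }
  if (any(!nzchar(trimws(df$label)) | is.na(df$label))) {
    stop("validation error: empty category label at index ",
         df$index[which(!nzchar(trimws(df$label)))[1]], call. = FALSE)
  }
  if (anyDuplicated(df$label)) {
    stop("validation error: duplicate category label '",
         df$label[duplicated(df$label)][1], "'", call. = FALSE)
  }
  bad <- !df$origin %in% ORIGINS
  if (any(bad)) {
    stop("validation error: unknown origin '", df$origin[which(bad)[1]],
         "'", call. = FALSE)
  }
  df <- df[c("index", "label", "domain_tag", "origin")]
  rownames(df) <- NULL
  attr(df, "name") <- name
  attr(df, "version") <- version
  class(df) <- c("category_scheme", "data.frame")
  df
}

#' Read a category scheme from a delimited or JSON file
#'
#' Delimited files carry columns `index,label[,domain_tag,origin]`; JSON
#' files carry either an array of category objects or an object with keys
#' `name`, `version`, `categories`.
#'
#' @param path File path.
#' @return A [category_scheme()].
#' @export
read_category_scheme <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    if (is.data.frame(obj)) {
      return(category_scheme(obj))
    }
    category_scheme(as.data.frame(obj$categories),
                    name = obj$name %||% "scheme",
                    version = as.character(obj$version %||% "1"))
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                   na.strings = "")
    category_scheme(df)
  }
}

#' Write a category scheme
#'
#' @param scheme A [category_scheme()].
#' @param path Output path; `.json` writes JSON, anything else delimited.
#' @return `path`, invisibly.
#' @export
write_category_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "category_scheme"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(name = attr(scheme, "name"), version = attr(scheme, "version"),
                categories = as.data.frame(scheme))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, dataframe = "rows",
                         na = "null")
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    write.csv(as.data.frame(scheme), con, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' The default vaccination-barrier category scheme
#'
#' A best-effort 43-category scheme for caregiver-reported reasons a child
#' missed vaccination, as used in DRC vaccination-coverage survey analysis:
#' indices 1-22 are original questionnaire options, 23-43 are
#' researcher-added categories discovered in the free-text channel. The
#' exact label strings are configuration, not ground truth; supply your own
#' scheme file for a different questionnaire.
#'
#' @return A [category_scheme()] with 43 categories.
#' @export
default_scheme <- function() {
  path <- system.file("extdata", "default_scheme.csv", package = "survcat")
  sc <- read_category_scheme(path)
  attr(sc, "name") <- "vaccination-barriers-drc"
  attr(sc, "version") <- "1"
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deduplicate responses to unique strings
#'
#' Free-text survey answers repeat heavily (common answers like "Travel" or
#' "Health worker strike" recur hundreds of times), so each distinct string
#' is categorized once and the label propagated to all duplicates. Returns
#' a dedup table: the unique normalized texts in first-appearance order,
#' their multiplicities, one representative `response_id` each, and the
#' response-to-unique-text mapping.
#'
#' @param responses A [survey_responses()] data.frame.
#' @inheritParams normalize_text
#' @return A `dedup_table` list with elements `unique_texts`,
#'   `multiplicity`, `representative`, `key_by_id`, `normalization`.
#' @export
deduplicate <- function(responses, normalization = c("exact", "trim_casefold")) {
  normalization <- match.arg(normalization)
  responses <- survey_responses(as.data.frame(responses))
  if (nrow(responses) == 0) stop("empty input: no responses", call. = FALSE)
  keys <- normalize_text(responses$text, normalization)
  first <- !duplicated(keys)
  unique_texts <- keys[first]
  multiplicity <- table(factor(keys, levels = unique_texts))
  multiplicity <- setNames(as.integer(multiplicity), unique_texts)
  representative <- setNames(responses$response_id[first], unique_texts)
  key_by_id <- setNames(keys, responses$response_id)
  out <- list(unique_texts = unique_texts,
              multiplicity = multiplicity,
              representative = representative,
              key_by_id = key_by_id,
              normalization = normalization)
  class(out) <- "dedup_table"
  out
}

#' @export
print.dedup_table <- function(x, ...) {
  cat("<dedup_table> ", length(x$key_by_id), " responses -> ",
      length(x$unique_texts), " unique strings (",
      x$normalization, " normalization)\n", sep = "")
  mult <- sort(x$multiplicity, decreasing = TRUE)
  show <- head(mult, 5)
  for (i in seq_along(show)) {
    cat("  ", names(show)[i], " (N=", show[i], ")\n", sep = "")
  }
  invisible(x)
}

#' Expand unique-string assignments back to all responses
#'
#' Inverse of [deduplicate()]: copies each unique string's category
#' assignment to every response that deduplicated to it, so that
#' categorize-then-expand over unique strings equals categorizing every raw
#' response directly (for any categorizer that depends only on the text).
#'
#' @param table A `dedup_table` from [deduplicate()].
#' @param unique_assignments A [category_assignments()] data.frame whose
#'   `response_id` column holds the unique normalized texts (as produced by
#'   running a strategy over [unique_responses()]).
#' @return A [category_assignments()] data.frame with one row per original
#'   response, in the original response order.
#' @export
expand_assignments <- function(table, unique_assignments) {
  stopifnot(inherits(table, "dedup_table"))
  ua <- as.data.frame(unique_assignments)
  key_col <- if ("text" %in% names(ua)) "text" else "response_id"
  idx <- match(table$key_by_id, ua[[key_col]])
  if (anyNA(idx)) {
    missing <- unique(table$key_by_id[is.na(idx)])
    stop("incomplete assignment: no assignment for unique text '",
         missing[1], "' (", length(missing), " missing)", call. = FALSE)
  }
  out <- data.frame(response_id = names(table$key_by_id),
                    category_index = ua$category_index[idx],
                    method = ua$method[idx],
                    raw_output = ua$raw_output[idx],
                    parse_status = ua$parse_status[idx],
                    stringsAsFactors = FALSE)
  category_assignments(out)
}

#' Present the unique strings of a dedup table as a response table
#'
#' Convenience for the categorize-once workflow: each unique text becomes a
#' pseudo-response whose `response_id` is the normalized text itself, so
#' strategy output keys directly into [expand_assignments()].
#'
#' @param table A `dedup_table`.
#' @return A [survey_responses()] data.frame with one row per unique text.
#' @export
unique_responses <- function(table) {
  stopifnot(inherits(table, "dedup_table"))
  survey_responses(data.frame(response_id = table$unique_texts,
                              survey_round = NA_integer_,
                              text = table$unique_texts,
                              stringsAsFactors = FALSE))
}

#' Construct and validate a table of category assignments
#'
#' One row per categorized response: the chosen category index (`NA` when
#' parsing failed), the strategy that produced it, the raw model output and
#' a parse status (`ok`, `fallback` when the backend declared it used its
#' fallback category, `failed`).
#'
#' @param df Data.frame with columns `response_id`, `category_index`,
#'   `method`, `raw_output`, `parse_status`.
#' @param scheme Optional [category_scheme()]; when given, `ok` rows must
#'   hold an index within the scheme.
#' @return The validated data.frame with class `category_assignments`.
#' @export
category_assignments <- function(df, scheme = NULL) {
  stopifnot(is.data.frame(df))
  for (col in c("response_id", "category_index", "method", "raw_output",
                "parse_status")) {
    if (!col %in% names(df)) {
      stop("validation error: assignments missing column '", col, "'",
           call. = FALSE)
    }
  }
  df$response_id <- as.character(df$response_id)
  df$category_index <- as.integer(df$category_index)
  df$method <- as.character(df$method)
  df$raw_output <- as.character(df$raw_output)
  df$parse_status <- as.character(df$parse_status)
  bad <- !df$parse_status %in% c("ok", "fallback", "failed")
  if (any(bad)) {
    stop("validation error: unknown parse_status '",
         df$parse_status[which(bad)[1]], "'", call. = FALSE)
  }
  ok <- df$parse_status %in% c("ok", "fallback")
  if (any(ok & is.na(df$category_index))) {
    stop("validation error: parse_status ok requires a category_index",
         call. = FALSE)
  }
  if (!is.null(scheme)) {
    out_of_range <- ok & (df$category_index < 1 |
                            df$category_index > nrow(scheme))
    if (any(out_of_range)) {
      stop("validation error: category_index out of scheme range at record ",
           which(out_of_range)[1], call. = FALSE)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("category_assignments", "data.frame")
  df
}
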