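#' Construct and validate a benchmark table
#'
#' A benchmark pairs each response with the category a human coder chose
#' for it, and is the yardstick every strategy is scored against.
#'
#' @param df Data.frame with columns `response_id`, `text`,
#'   `human_category`.
#' @param scheme Optional [category_scheme()] for range-checking
#'   `human_category`.
#' @return The validated data.frame with class `benchmark_examples`.
#' @export
benchmark_examples <- function(df, scheme = NULL) {
  stopifnot(is.data.frame(df))
  for (col in c("response_id", "text", "human_category")) {
    if (!col %in% names(df)) {
      stop("validation error: benchmark missing column '", col, "'",
           call. = FALSE)
    }
  }
  df$response_id <- as.character(df$response_id)
  df$text <- as.character(df$text)
  df$human_category <- as.integer(df$human_category)
  if (anyDuplicated(df$response_id)) {
    stop("validation error: duplicate response_id in benchmark",
         call. = FALSE)
  }
  if (anyNA(df$human_category) || any(df$human_category < 1)) {
    stop("validation error: human_category must be a positive integer",
         call. = FALSE)
  }
  if (!is.null(scheme) && any(df$human_category > nrow(scheme))) {
    stop("validation error: human_category outside scheme range",
         call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("benchmark_examples", "data.frame")
  df
}

#' Split a benchmark into train and test sets
#'
#' Draws a seeded uniform sample without replacement for the test set; the
#' remainder (in input order) is the training set. The same seed always
#' reproduces the same split.
#'
#' @param examples A [benchmark_examples()] table.
#' @param n_test Test-set size, strictly between 0 and `nrow(examples)`.
#' @param seed Integer seed.
#' @return A `benchmark_split` list with `train`, `test`, `seed`.
#' @export
split_benchmark <- function(examples, n_test, seed = 1L) {
  examples <- benchmark_examples(as.data.frame(examples))
  n <- nrow(examples)
  if (n_test <= 0 || n_test >= n) {
    stop("configuration error: n_test must be in (0, ", n, ")",
         call. = FALSE)
  }
  test_idx <- sort(with_local_seed(seed, sample.int(n, n_test)))
  out <- list(train = benchmark_examples(examples[-test_idx, , drop = FALSE]),
              test = benchmark_examples(examples[test_idx, , drop = FALSE]),
              seed = as.integer(seed))
  class(out) <- "benchmark_split"
  out
}

#' @export
print.benchmark_split <- function(x, ...) {
  cat("<benchmark_split> ", nrow(x$train), " train / ", nrow(x$test),
      " test (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

align_to_truth <- function(assignments, truths) {
  assignments <- as.data.frame(assignments)
  truths <- benchmark_examples(as.data.frame(truths))
  if (nrow(assignments) != nrow(truths)) {
    stop("alignment error: ", nrow(assignments), " assignments vs ",
         nrow(truths), " benchmark examples", call. = FALSE)
  }
  idx <- match(truths$response_id, assignments$response_id)
  if (anyNA(idx)) {
    stop("alignment error: no assignment for response_id '",
         truths$response_id[is.na(idx)][1], "'", call. = FALSE)
  }
  cbind(truths,
        model_category = assignments$category_index[idx],
        parse_status = assignments$parse_status[idx])
}

#' Strict benchmark accuracy
#'
#' The share of responses the model categorized the same as the human
#' coder. A failed parse counts as discordant.
#'
#' @param assignments [category_assignments()] covering the benchmark.
#' @param truths A [benchmark_examples()] table, aligned by `response_id`.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(assignments, truths) {
  aligned <- align_to_truth(assignments, truths)
  concordant <- !is.na(aligned$model_category) &
    aligned$parse_status != "failed" &
    aligned$model_category == aligned$human_category
  sum(concordant) / nrow(aligned)
}

#' Adjudicated accuracy ceiling
#'
#' Strict accuracy treats any human-model disagreement as an error, but a
#' vague or compound response can make the model's different choice
#' arguably correct. The ceiling re-scores after a human review of all
#' discordant pairs: pairs judged `acceptable` join the numerator, so the
#' ceiling is always at least the strict accuracy. Discordant pairs without
#' a review verdict count as `not_acceptable`, so a partial review can only
#' lower the ceiling, never inflate it.
#'
#' @inheritParams accuracy
#' @param adjudications Data.frame with columns `response_id`,
#'   `human_category`, `model_category`, `verdict` (one of `acceptable`,
#'   `not_acceptable`, `unreviewed`), e.g. re-imported from
#'   [export_discordances()] after review. A record for a concordant pair
#'   is a validation error.
#' @return Ceiling accuracy in `[0, 1]`.
#' @export
accuracy_ceiling <- function(assignments, truths, adjudications) {
  aligned <- align_to_truth(assignments, truths)
  adjudications <- as.data.frame(adjudications)
  for (col in c("response_id", "verdict")) {
    if (!col %in% names(adjudications)) {
      stop("validation error: adjudications missing column '", col, "'",
           call. = FALSE)
    }
  }
  bad_v <- !adjudications$verdict %in% c("acceptable", "not_acceptable",
                                         "unreviewed")
  if (any(bad_v)) {
    stop("validation error: unknown verdict '",
         adjudications$verdict[which(bad_v)[1]], "'", call. = FALSE)
  }
  concordant <- !is.na(aligned$model_category) &
    aligned$parse_status != "failed" &
    aligned$model_category == aligned$human_category
  concordant_ids <- aligned$response_id[concordant]
  clash <- adjudications$response_id %in% concordant_ids
  if (any(clash)) {
    stop("validation error: adjudication record for concordant response '",
         adjudications$response_id[which(clash)[1]], "'", call. = FALSE)
  }
  verdict <- setNames(adjudications$verdict, adjudications$response_id)
  discordant_ids <- aligned$response_id[!concordant]
  acceptable <- sum(verdict[discordant_ids] == "acceptable", na.rm = TRUE)
  (sum(concordant) + acceptable) / nrow(aligned)
}

#' Margin of error for a proportion
#'
#' Half-width of the normal-approximation confidence interval,
#' `z * sqrt(p * (1 - p) / n)`. With an assumed accuracy of 0.85 and a test
#' set of 200, this gives 0.0495 — the ~5% margin at 95% confidence that
#' motivates a 200-response test set.
#'
#' @param p Assumed proportion, strictly inside (0, 1).
#' @param n Sample size, at least 1.
#' @param z Critical value; 1.96 for 95% confidence.
#' @return The margin of error.
#' @export
margin_of_error <- function(p, n, z = 1.96) {
  if (any(p <= 0 | p >= 1)) {
    stop("domain error: p must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(n < 1)) stop("domain error: n must be at least 1", call. = FALSE)
  z * sqrt(p * (1 - p) / n)
}

#' Smallest sample size achieving a target margin of error
#'
#' The smallest `n` with `margin_of_error(p, n, z) <= target_margin`,
#' i.e. `ceiling(z^2 * p * (1 - p) / target_margin^2)`.
#'
#' @inheritParams margin_of_error
#' @param target_margin Desired margin, strictly positive.
#' @return A positive integer sample size.
#' @export
required_sample_size <- function(p, target_margin, z = 1.96) {
  if (any(p <= 0 | p >= 1)) {
    stop("domain error: p must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(target_margin <= 0)) {
    stop("domain error: target_margin must be positive", call. = FALSE)
  }
  n <- as.integer(ceiling(z^2 * p * (1 - p) / target_margin^2))
  pmax(n, 1L)
}

#' Export discordant pairs as a review worksheet
#'
#' Writes one row per human-model disagreement with verdict `unreviewed`;
#' a reviewer edits the verdict column and the file feeds back into
#' [accuracy_ceiling()] via [read_adjudications()].
#'
#' @inheritParams accuracy
#' @param path Optional output path (comma-delimited, UTF-8).
#' @return The worksheet data.frame (invisibly when `path` is given).
#' @export
export_discordances <- function(assignments, truths, path = NULL) {
  aligned <- align_to_truth(assignments, truths)
  discordant <- is.na(aligned$model_category) |
    aligned$parse_status == "failed" |
    aligned$model_category != aligned$human_category
  out <- data.frame(response_id = aligned$response_id[discordant],
                    text = aligned$text[discordant],
                    human_category = aligned$human_category[discordant],
                    model_category = aligned$model_category[discordant],
                    verdict = rep("unreviewed", sum(discordant)),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    write.csv(out, con, row.names = FALSE, na = "")
    return(invisible(out))
  }
  out
}

#' Read a reviewed adjudication worksheet
#'
#' @param path File written by [export_discordances()], verdicts filled in.
#' @return Data.frame of adjudication records.
#' @export
read_adjudications <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  df$response_id <- as.character(df$response_id)
  df$verdict[is.na(df$verdict) | df$verdict == ""] <- "unreviewed"
  df
}

#' Per-category accuracy with an underpowered flag
#'
#' Category-level accuracy is reported but flagged `underpowered` whenever
#' a category has fewer benchmark examples than `min_n`: with dozens of
#' categories and a test set of a few hundred, per-category estimates
#' rarely support real claims.
#'
#' @inheritParams accuracy
#' @param scheme A [category_scheme()].
#' @param min_n Minimum per-category n for a powered estimate.
#' @return Data.frame with columns `index`, `label`, `n`, `accuracy`,
#'   `underpowered`.
#' @export
per_category_accuracy <- function(assignments, truths, scheme, min_n = 10L) {
  aligned <- align_to_truth(assignments, truths)
  concordant <- !is.na(aligned$model_category) &
    aligned$parse_status != "failed" &
    aligned$model_category == aligned$human_category
  n <- tabulate(aligned$human_category, nbins = nrow(scheme))
  hits <- tabulate(aligned$human_category[concordant], nbins = nrow(scheme))
  data.frame(index = scheme$index, label = scheme$label, n = n,
             accuracy = ifelse(n > 0, hits / n, NA_real_),
             underpowered = n < min_n, stringsAsFactors = FALSE)
}
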