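#' Write / read category assignments
#'
#' @param assignments A [category_assignments()] table.
#' @param path Delimited file path (UTF-8).
#' @return `path` invisibly; `read_assignments()` returns the table.
#' @export
write_assignments <- function(assignments, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(as.data.frame(assignments), con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  category_assignments(read.csv(path, stringsAsFactors = FALSE,
                                encoding = "UTF-8", na.strings = ""))
}

#' Write / read a benchmark table
#'
#' @param benchmark A [benchmark_examples()] table.
#' @param path Delimited file path (UTF-8).
#' @return `path` invisibly; `read_benchmark()` returns the table.
#' @export
write_benchmark <- function(benchmark, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(as.data.frame(benchmark), con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_benchmark
#' @export
read_benchmark <- function(path) {
  benchmark_examples(read.csv(path, stringsAsFactors = FALSE,
                              encoding = "UTF-8"))
}

#' Category frequency table
#'
#' Weighted counts and shares of assigned categories, optionally grouped
#' by survey round or admin unit — the aggregation behind
#' category-frequency panels and trends-over-time figures. Shares are
#' computed within each group over successfully parsed assignments and sum
#' to 1 per group; failed parses are dropped from the table (their count is
#' recorded in the `n_failed` attribute). When grouping by round, rounds in
#' `exclude_rounds` are omitted — by default the 2020 round, whose question
#' format and sampling are not comparable across years; pass
#' `exclude_rounds = integer(0)` to re-include it.
#'
#' @param assignments A [category_assignments()] table.
#' @param responses The matching [survey_responses()] table (weights,
#'   rounds, admin units are read from here).
#' @param grouping `"none"`, `"round"` or `"admin_unit"`.
#' @param weighted Use sampling weights (`TRUE`) or raw counts.
#' @param exclude_rounds Rounds dropped when grouping by round.
#' @return A `frequency_table` data.frame with columns `category_index`,
#'   `group`, `count`, `share`.
#' @export
aggregate_assignments <- function(assignments, responses,
                                  grouping = c("none", "round",
                                               "admin_unit"),
                                  weighted = TRUE,
                                  exclude_rounds = 2020L) {
  grouping <- match.arg(grouping)
  assignments <- as.data.frame(assignments)
  responses <- survey_responses(as.data.frame(responses))
  idx <- match(assignments$response_id, responses$response_id)
  if (anyNA(idx)) {
    stop("alignment error: assignment for unknown response_id '",
         assignments$response_id[is.na(idx)][1], "'", call. = FALSE)
  }
  df <- data.frame(category_index = assignments$category_index,
                   weight = if (weighted) responses$weight[idx] else 1,
                   group = switch(grouping,
                                  none = "all",
                                  round = as.character(
                                    responses$survey_round[idx]),
                                  admin_unit = responses$admin_unit[idx]),
                   failed = assignments$parse_status == "failed",
                   stringsAsFactors = FALSE)
  n_failed <- sum(df$failed)
  df <- df[!df$failed & !is.na(df$category_index), , drop = FALSE]
  if (grouping == "round" && length(exclude_rounds) > 0) {
    df <- df[!df$group %in% as.character(exclude_rounds), , drop = FALSE]
  }
  agg <- aggregate(weight ~ category_index + group, data = df, FUN = sum)
  names(agg)[names(agg) == "weight"] <- "count"
  totals <- tapply(agg$count, agg$group, sum)
  agg$share <- agg$count / as.numeric(totals[agg$group])
  agg <- agg[order(agg$category_index, agg$group), , drop = FALSE]
  agg <- agg[c("category_index", "group", "count", "share")]
  rownames(agg) <- NULL
  attr(agg, "grouping") <- grouping
  attr(agg, "n_failed") <- n_failed
  class(agg) <- c("frequency_table", "data.frame")
  agg
}

#' Share of assignments falling in researcher-added categories
#'
#' The weighted share of categorized responses whose category carries
#' origin `added_category` — how much of the free-text channel the original
#' questionnaire options failed to cover.
#'
#' @param table A `frequency_table` from [aggregate_assignments()].
#' @param scheme A [category_scheme()] with origin flags.
#' @return Share in `[0, 1]`.
#' @export
new_vs_original_share <- function(table, scheme) {
  stopifnot(inherits(table, "frequency_table"),
            inherits(scheme, "category_scheme"))
  origin <- scheme$origin[match(table$category_index, scheme$index)]
  if (anyNA(origin)) {
    stop("validation error: frequency table references categories outside ",
         "the scheme", call. = FALSE)
  }
  sum(table$count[origin == "added_category"]) / sum(table$count)
}
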