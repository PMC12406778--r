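#' Token pricing model
#'
#' Four per-million-token prices: completion input and output, embeddings,
#' and fine-tune training. Defaults are the OpenAI GPT-4o list prices of
#' September 2024 (US$2.5/M input, US$10/M output, US$0.020/M embedding,
#' US$25/M training); override from a JSON config for other providers.
#'
#' @param input_per_million,output_per_million,embedding_per_million,training_per_million
#'   Non-negative US$ prices per 1e6 tokens.
#' @return A `pricing_model` list.
#' @export
pricing_model <- function(input_per_million = 2.5, output_per_million = 10,
                          embedding_per_million = 0.020,
                          training_per_million = 25) {
  prices <- c(input_per_million, output_per_million, embedding_per_million,
              training_per_million)
  if (any(prices < 0)) stop("domain error: prices must be >= 0", call. = FALSE)
  structure(list(input_per_million = input_per_million,
                 output_per_million = output_per_million,
                 embedding_per_million = embedding_per_million,
                 training_per_million = training_per_million),
            class = "pricing_model")
}

#' Read a pricing model from a JSON config
#'
#' @param path JSON file with any of the four per-million price keys.
#' @return A [pricing_model()].
#' @export
read_pricing <- function(path) {
  obj <- jsonlite::fromJSON(path)
  do.call(pricing_model, obj[intersect(names(obj),
                                       names(formals(pricing_model)))])
}

#' Cost of one completion call
#'
#' `prompt_tokens * input_price/1e6 + completion_tokens * output_price/1e6`,
#' kept at full precision: display rounding happens only in
#' [format_cost_table()], never inside arithmetic, because a campaign total
#' computed from a display-rounded per-call cost drifts visibly (9865 calls
#' at a true 0.001005 cost 9.91, not 9865 x 0.0010 = 9.87).
#'
#' @param prompt_tokens,completion_tokens Non-negative token counts
#'   (averages are fine; cost is linear).
#' @param pricing A [pricing_model()].
#' @return US$ cost (vectorized).
#' @export
per_call_cost <- function(prompt_tokens, completion_tokens,
                          pricing = pricing_model()) {
  if (any(prompt_tokens < 0) || any(completion_tokens < 0)) {
    stop("domain error: token counts must be >= 0", call. = FALSE)
  }
  prompt_tokens * pricing$input_per_million / 1e6 +
    completion_tokens * pricing$output_per_million / 1e6
}

#' Project the cost of a categorization campaign
#'
#' One cost line for a method: upfront cost (embedding pass or fine-tune
#' training) plus the unrounded per-call cost times the number of calls.
#' For direct strategies `n_calls` is the unique-string count of the
#' dataset; for cluster-then-label it is the number of clusters.
#'
#' @param method Method name.
#' @param n_calls Number of API calls the campaign issues.
#' @param avg_prompt_tokens,avg_completion_tokens Average tokens per call.
#' @param upfront One-time US$ cost before any categorization call.
#' @param pricing A [pricing_model()].
#' @return A one-row `cost_table` data.frame with columns `method`,
#'   `n_calls`, `avg_prompt_tokens`, `avg_completion_tokens`, `upfront`,
#'   `per_call`, `total`.
#' @export
campaign_cost <- function(method, n_calls, avg_prompt_tokens,
                          avg_completion_tokens, upfront = 0,
                          pricing = pricing_model()) {
  if (n_calls < 0) stop("domain error: n_calls must be >= 0", call. = FALSE)
  if (upfront < 0) stop("domain error: upfront must be >= 0", call. = FALSE)
  per_call <- per_call_cost(avg_prompt_tokens, avg_completion_tokens, pricing)
  out <- data.frame(method = method, n_calls = as.integer(n_calls),
                    avg_prompt_tokens = avg_prompt_tokens,
                    avg_completion_tokens = avg_completion_tokens,
                    upfront = upfront, per_call = per_call,
                    total = upfront + per_call * n_calls,
                    stringsAsFactors = FALSE)
  class(out) <- c("cost_table", "data.frame")
  out
}

#' Build a cost table for several methods
#'
#' @param specs Data.frame with columns `method`, `n_calls`,
#'   `avg_prompt_tokens`, `avg_completion_tokens` and optionally `upfront`;
#'   one row per method, kept in the given order. An empty data.frame
#'   yields an empty table.
#' @param pricing A [pricing_model()].
#' @return A `cost_table` data.frame, one row per method.
#' @export
cost_table <- function(specs, pricing = pricing_model()) {
  specs <- as.data.frame(specs)
  if (nrow(specs) == 0) {
    out <- data.frame(method = character(), n_calls = integer(),
                      avg_prompt_tokens = numeric(),
                      avg_completion_tokens = numeric(), upfront = numeric(),
                      per_call = numeric(), total = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("cost_table", "data.frame")
    return(out)
  }
  if (!"upfront" %in% names(specs)) specs$upfront <- 0
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    campaign_cost(specs$method[i], specs$n_calls[i],
                  specs$avg_prompt_tokens[i], specs$avg_completion_tokens[i],
                  specs$upfront[i], pricing)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cost_table", "data.frame")
  out
}

#' Display rounding for a cost table
#'
#' Per-call costs round to 4 decimals, upfront and total to 2 — at display
#' time only; the underlying table keeps full precision.
#'
#' @param table A `cost_table`.
#' @return Data.frame with rounded `upfront`, `per_call`, `total`.
#' @export
format_cost_table <- function(table) {
  out <- as.data.frame(table)
  out$per_call <- round(out$per_call, 4)
  out$upfront <- round(out$upfront, 2)
  out$total <- round(out$total, 2)
  out
}

#' @export
print.cost_table <- function(x, ...) {
  cat("<cost_table> (display-rounded; internals keep full precision)\n")
  print(format_cost_table(x))
  invisible(x)
}

#' Exact cost of a logged run
#'
#' Sums [per_call_cost()] over the actual calls of a run log; equals the
#' [campaign_cost()] projection when all calls share identical token
#' counts.
#'
#' @param run_log A list of [completion_result()]s, or a data.frame with
#'   columns `prompt_tokens`, `completion_tokens`.
#' @param pricing A [pricing_model()].
#' @return Total US$ cost.
#' @export
measured_cost <- function(run_log, pricing = pricing_model()) {
  if (is.data.frame(run_log)) {
    pt <- run_log$prompt_tokens; ct <- run_log$completion_tokens
  } else {
    pt <- vapply(run_log, `[[`, numeric(1), "prompt_tokens")
    ct <- vapply(run_log, `[[`, numeric(1), "completion_tokens")
  }
  if (length(pt) == 0) return(0)
  sum(per_call_cost(pt, ct, pricing))
}

#' Reference method specifications for the DRC vaccination-barrier campaign
#'
#' The eight categorization approaches benchmarked on the DRC
#' vaccination-coverage survey free-text channel, with their observed
#' average token counts per API call, upfront costs (US$0.0003 embedding
#' pass for cluster-then-label; US$13 fine-tune training) and campaign call
#' counts (9865 unique strings for the per-response strategies; 200 calls
#' for the 200-cluster run). Feed to [cost_table()] to project campaign
#' costs under any [pricing_model()].
#'
#' @param n_unique Unique-string count for the per-response strategies.
#' @return Data.frame of method specs.
#' @export
default_method_specs <- function(n_unique = 9865L) {
  data.frame(
    method = c("cluster_label_200", "zero_shot", "chain_of_thought",
               "few_shot_20", "few_shot_50", "few_shot_400", "few_shot_799",
               "fine_tuned_799"),
    n_calls = c(200L, rep(as.integer(n_unique), 7)),
    avg_prompt_tokens = c(605, 398, 472, 621, 943, 4486, 8464, 398),
    avg_completion_tokens = c(1, 1, 52, 1, 1, 1, 1, 1),
    upfront = c(0.0003, 0, 0, 0, 0, 0, 0, 13),
    stringsAsFactors = FALSE)
}
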