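# Seeded evaluation without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Prompt template
#'
#' Prompts are rendered from plain-text templates with the placeholders
#' `{response}`, `{category_list}` and `{examples}`. `answer_format`
#' declares how replies are parsed: `"bare_index"` expects a single
#' category number, `"reasoning_then_index"` expects free reasoning ending
#' in `ANSWER: <number>`.
#'
#' @param system_role System-role text.
#' @param body_template Template body with placeholders.
#' @param answer_format `"bare_index"` or `"reasoning_then_index"`.
#' @return A `prompt_template` list.
#' @export
prompt_template <- function(system_role, body_template,
                            answer_format = c("bare_index",
                                              "reasoning_then_index")) {
  answer_format <- match.arg(answer_format)
  stopifnot(nzchar(system_role), nzchar(body_template))
  structure(list(system_role = system_role, body_template = body_template,
                 answer_format = answer_format),
            class = "prompt_template")
}

read_prompt_file <- function(name) {
  path <- system.file("prompts", name, package = "survcat")
  paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
}

#' Shipped default prompt templates
#'
#' `default_direct_template()` drives zero-shot and few-shot prompting;
#' `default_cot_template()` adds a reasoning instruction and the `ANSWER:`
#' marker; `default_cluster_template()` is the cluster-labeling prompt with
#' its system role, which asks for "the number associated with the chosen
#' label, nothing else". All three ship as editable plain-text files under
#' `inst/prompts/`.
#'
#' @return A [prompt_template()].
#' @export
default_direct_template <- function() {
  prompt_template(read_prompt_file("direct_system.txt"),
                  read_prompt_file("direct_body.txt"), "bare_index")
}

#' @rdname default_direct_template
#' @export
default_cot_template <- function() {
  prompt_template(read_prompt_file("cot_system.txt"),
                  read_prompt_file("cot_body.txt"), "reasoning_then_index")
}

#' @rdname default_direct_template
#' @export
default_cluster_template <- function() {
  prompt_template(read_prompt_file("cluster_system.txt"),
                  read_prompt_file("cluster_body.txt"), "bare_index")
}

#' Render the numbered category list for a prompt
#'
#' @param scheme A [category_scheme()].
#' @return `"1. label1; 2. label2; ..."` in index order.
#' @export
render_category_list <- function(scheme) {
  stopifnot(inherits(scheme, "category_scheme"))
  paste(paste0(scheme$index, ". ", scheme$label), collapse = "; ")
}

render_prompt <- function(template, scheme, response = "", examples = "") {
  body <- template$body_template
  body <- stringi::stri_replace_all_fixed(body, "{category_list}",
                                          render_category_list(scheme))
  body <- stringi::stri_replace_all_fixed(body, "{examples}", examples)
  body <- stringi::stri_replace_all_fixed(body, "{response}", response)
  if (!nzchar(trimws(body))) stop("rendered prompt is empty", call. = FALSE)
  body
}

#' Parse a category reply
#'
#' In `bare_index` mode the trimmed reply must be a single integer; in
#' `reasoning_then_index` mode the integer following the last `ANSWER:`
#' marker is used. An absent or out-of-range integer yields a `failed`
#' status with index `NA`; parse failures are encoded in the status, never
#' raised.
#'
#' @param raw Backend reply text.
#' @param scheme A [category_scheme()].
#' @param answer_format `"bare_index"` or `"reasoning_then_index"`.
#' @return List with `index` (integer or `NA`) and `status`.
#' @export
parse_category_reply <- function(raw, scheme,
                                 answer_format = c("bare_index",
                                                   "reasoning_then_index")) {
  answer_format <- match.arg(answer_format)
  failed <- list(index = NA_integer_, status = "failed")
  if (is.na(raw)) return(failed)
  if (answer_format == "bare_index") {
    trimmed <- trimws(raw)
    if (!stringi::stri_detect_regex(trimmed, "^[0-9]+$")) return(failed)
    idx <- as.integer(trimmed)
  } else {
    parts <- stringi::stri_split_fixed(raw, "ANSWER:")[[1]]
    if (length(parts) < 2) return(failed)
    tail_part <- parts[length(parts)]
    m <- stringi::stri_match_first_regex(tail_part, "([0-9]+)")
    if (is.na(m[1, 2])) return(failed)
    idx <- as.integer(m[1, 2])
  }
  if (is.na(idx) || idx < 1 || idx > nrow(scheme)) return(failed)
  list(index = idx, status = "ok")
}

render_examples_block <- function(examples) {
  if (nrow(examples) == 0) return("")
  lines <- paste0(examples$text, " -> ", examples$category_index)
  paste0("Here are example responses with the number of their label:\n",
         paste(lines, collapse = "\n"), "\n\n")
}

as_response_table <- function(responses) {
  if (is.character(responses)) {
    responses <- data.frame(response_id = responses, survey_round = NA_integer_,
                            text = responses, stringsAsFactors = FALSE)
  }
  survey_responses(as.data.frame(responses))
}

direct_strategy <- function(responses, scheme, backend, template, method,
                            examples_block = "") {
  responses <- as_response_table(responses)
  n <- nrow(responses)
  idx <- integer(n); status <- character(n); raw <- character(n)
  calls <- 0L
  for (i in seq_len(n)) {
    prompt <- render_prompt(template, scheme, response = responses$text[i],
                            examples = examples_block)
    result <- tryCatch(complete(backend, template$system_role, prompt),
                       error = function(e) e)
    calls <- calls + 1L
    if (inherits(result, "error")) {
      idx[i] <- NA_integer_; status[i] <- "failed"
      raw[i] <- paste0("<backend error: ", conditionMessage(result), ">")
      next
    }
    parsed <- parse_category_reply(result$text, scheme,
                                   template$answer_format)
    idx[i] <- parsed$index
    status[i] <- if (parsed$status == "ok" && isTRUE(result$fallback))
      "fallback" else parsed$status
    raw[i] <- result$text
  }
  out <- category_assignments(data.frame(response_id = responses$response_id,
                                         category_index = idx,
                                         method = method,
                                         raw_output = raw,
                                         parse_status = status,
                                         stringsAsFactors = FALSE),
                              scheme)
  attr(out, "n_calls") <- calls
  out
}

#' Zero-shot categorization
#'
#' One completion call per response: the prompt shows the response and the
#' full numbered category list, and the model returns the chosen number.
#'
#' @param responses A [survey_responses()] table or a character vector of
#'   texts (ids default to the texts, which suits the unique-string
#'   workflow).
#' @param scheme A [category_scheme()].
#' @param backend A completion backend.
#' @param template A [prompt_template()] in `bare_index` format.
#' @return [category_assignments()] with attribute `n_calls`.
#' @export
zero_shot <- function(responses, scheme, backend,
                      template = default_direct_template()) {
  direct_strategy(responses, scheme, backend, template, "zero_shot")
}

#' Few-shot categorization
#'
#' As [zero_shot()], with `k` labeled example pairs embedded in every
#' prompt. For `k` below the full example set, a seeded uniform sample
#' without replacement is drawn once and rendered in the examples' original
#' order, so the same seed always yields the identical prompt.
#'
#' @inheritParams zero_shot
#' @param examples Data.frame with columns `text`, `category_index`.
#' @param k Number of example pairs to embed; `k <= nrow(examples)`.
#' @param seed Seed for example selection.
#' @return [category_assignments()] with attribute `n_calls`.
#' @export
few_shot <- function(responses, scheme, backend, examples, k,
                     seed = 1L, template = default_direct_template()) {
  examples <- as.data.frame(examples)
  stopifnot(all(c("text", "category_index") %in% names(examples)))
  if (k > nrow(examples)) {
    stop("configuration error: k (", k, ") exceeds available examples (",
         nrow(examples), ")", call. = FALSE)
  }
  keep <- if (k == nrow(examples)) seq_len(nrow(examples)) else
    sort(with_local_seed(seed, sample.int(nrow(examples), k)))
  block <- render_examples_block(examples[keep, , drop = FALSE])
  direct_strategy(responses, scheme, backend, template,
                  paste0("few_shot_", k), examples_block = block)
}

#' Chain-of-thought categorization
#'
#' As [zero_shot()], but the prompt asks the model to reason step by step
#' and finish with `ANSWER: <number>`; the reply is parsed via the marker.
#' Completions are multi-token, which the cost model picks up through the
#' recorded completion token counts.
#'
#' @inheritParams zero_shot
#' @param template A [prompt_template()] in `reasoning_then_index` format.
#' @return [category_assignments()] with attribute `n_calls`.
#' @export
chain_of_thought <- function(responses, scheme, backend,
                             template = default_cot_template()) {
  if (template$answer_format != "reasoning_then_index") {
    stop("configuration error: chain_of_thought needs a ",
         "reasoning_then_index template", call. = FALSE)
  }
  direct_strategy(responses, scheme, backend, template, "chain_of_thought")
}

#' Cluster embedding vectors
#'
#' Fits k-means, a Gaussian mixture model (full covariance, falling back to
#' diagonal then spherical when the fit is singular), or Ward hierarchical
#' clustering. Empty clusters are dropped and the remainder renumbered
#' densely from 1. At `k` equal to the number of vectors every point is its
#' own cluster.
#'
#' @param vectors Numeric matrix, one row per text.
#' @param algorithm `"kmeans"`, `"gmm"` or `"hierarchical"`.
#' @param k Number of clusters; at most `nrow(vectors)`.
#' @param seed Seed controlling initialization.
#' @return A `cluster_model` list with elements `algorithm`, `k`,
#'   `assignments` (dense 1-based ids), `n_clusters`, `seed`.
#' @export
fit_clusters <- function(vectors, algorithm = c("kmeans", "gmm",
                                                "hierarchical"),
                         k, seed = 1L) {
  algorithm <- match.arg(algorithm)
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (k > n) {
    stop("configuration error: k (", k, ") exceeds number of vectors (",
         n, ")", call. = FALSE)
  }
  if (k < 1) stop("configuration error: k must be positive", call. = FALSE)

  if (k == n) {
    assignments <- seq_len(n)
  } else {
    # distinct rows only: duplicate vectors must share a cluster and would
    # break k-means when k exceeds the distinct count
    keys <- apply(vectors, 1, paste, collapse = ",")
    first <- !duplicated(keys)
    distinct <- vectors[first, , drop = FALSE]
    k_eff <- min(k, nrow(distinct))
    cl <- if (k_eff == nrow(distinct)) {
      seq_len(nrow(distinct))
    } else if (algorithm == "kmeans") {
      with_local_seed(seed,
                      stats::kmeans(distinct, centers = k_eff, nstart = 5,
                                    iter.max = 100)$cluster)
    } else if (algorithm == "hierarchical") {
      stats::cutree(stats::hclust(stats::dist(distinct), method = "ward.D2"),
                    k = k_eff)
    } else {
      fit_gmm(distinct, k_eff, seed)
    }
    assignments <- cl[match(keys, keys[first])]
  }
  dense <- match(assignments, sort(unique(assignments)))
  model <- list(algorithm = algorithm, k = as.integer(k),
                assignments = as.integer(dense),
                n_clusters = length(unique(dense)), seed = as.integer(seed))
  class(model) <- "cluster_model"
  model
}

fit_gmm <- function(x, k, seed) {
  for (models in list("VVV", "VVI", "EII")) {
    fit <- with_local_seed(seed, tryCatch(
      mclust::Mclust(x, G = k, modelNames = models, verbose = FALSE),
      error = function(e) NULL))
    if (!is.null(fit)) return(fit$classification)
  }
  # all mixture parameterizations singular: k-means partition as last resort
  with_local_seed(seed, stats::kmeans(x, centers = k, nstart = 5,
                                      iter.max = 100)$cluster)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> ", x$algorithm, ", k = ", x$k, " (",
      x$n_clusters, " non-empty), n = ", length(x$assignments),
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Cluster-then-label categorization
#'
#' The unsupervised strategy: embed every unique text, cluster the
#' embedding vectors, then issue exactly one completion call per cluster
#' showing up to `exemplars_per_cluster` sampled member texts
#' (semicolon-separated) together with the category list. The parsed
#' category propagates to every member of the cluster, so API cost scales
#' with the number of clusters, not responses. At `k` equal to the number
#' of unique texts this converges on zero-shot.
#'
#' @param texts Character vector of unique response texts.
#' @param scheme A [category_scheme()].
#' @param embed_backend An embedding backend.
#' @param llm_backend A completion backend.
#' @param algorithm,k Passed to [fit_clusters()].
#' @param exemplars_per_cluster Maximum exemplars shown per cluster.
#' @param seed Seed for clustering and exemplar sampling.
#' @param template A [prompt_template()] in `bare_index` format.
#' @return [category_assignments()] keyed by text, with attributes
#'   `n_calls` and `cluster_model`.
#' @export
cluster_label <- function(texts, scheme, embed_backend, llm_backend,
                          algorithm = "kmeans", k, exemplars_per_cluster = 25L,
                          seed = 1L, template = default_cluster_template()) {
  stopifnot(is.character(texts), length(texts) > 0)
  if (anyDuplicated(texts)) {
    stop("configuration error: texts must be unique strings ",
         "(deduplicate first)", call. = FALSE)
  }
  vectors <- embed_texts(embed_backend, texts)
  model <- fit_clusters(vectors, algorithm = algorithm, k = k, seed = seed)

  idx <- integer(length(texts)); status <- character(length(texts))
  raw <- character(length(texts))
  calls <- 0L
  for (cl in seq_len(model$n_clusters)) {
    members <- which(model$assignments == cl)
    take <- min(length(members), exemplars_per_cluster)
    shown <- if (take == length(members)) members else
      sort(with_local_seed(seed + cl, sample(members, take)))
    block <- paste(texts[shown], collapse = "; ")
    prompt <- render_prompt(template, scheme, examples = block)
    result <- tryCatch(complete(llm_backend, template$system_role, prompt),
                       error = function(e) e)
    calls <- calls + 1L
    if (inherits(result, "error")) {
      idx[members] <- NA_integer_; status[members] <- "failed"
      raw[members] <- paste0("<backend error: ",
                             conditionMessage(result), ">")
      next
    }
    parsed <- parse_category_reply(result$text, scheme, "bare_index")
    idx[members] <- parsed$index
    status[members] <- if (parsed$status == "ok" && isTRUE(result$fallback))
      "fallback" else parsed$status
    raw[members] <- result$text
  }
  out <- category_assignments(data.frame(response_id = texts,
                                         category_index = idx,
                                         method = paste0("cluster_label_",
                                                         algorithm, "_", k),
                                         raw_output = raw,
                                         parse_status = status,
                                         stringsAsFactors = FALSE),
                              scheme)
  attr(out, "n_calls") <- calls
  attr(out, "cluster_model") <- model
  out
}

#' Export a fine-tuning dataset in chat JSON-lines format
#'
#' Writes one JSON-lines record per example with three chat messages:
#' system (the supplied role), user (the rendered response plus category
#' list) and assistant (the bare category index). Field order is stable for
#' diffability. Once a model is trained on such pairs, inference prompts no
#' longer need embedded examples, which is what makes the fine-tuned
#' campaign cheap per call.
#'
#' @param examples Data.frame with columns `text`, `category_index`.
#' @param scheme A [category_scheme()].
#' @param path Output path.
#' @param system_role System message; defaults to the direct-prompt role.
#' @param template Template used to render the user message.
#' @return Invisibly, a list with `path`, `n_records` and `total_tokens`
#'   (whitespace tokens summed over all messages of all records).
#' @export
export_finetune_dataset <- function(examples, scheme, path,
                                    system_role = NULL,
                                    template = default_direct_template()) {
  examples <- as.data.frame(examples)
  stopifnot(all(c("text", "category_index") %in% names(examples)))
  if (nrow(examples) == 0) stop("no examples to export", call. = FALSE)
  bad <- examples$category_index < 1 | examples$category_index > nrow(scheme)
  if (any(bad)) {
    stop("validation error: category_index out of range at example ",
         which(bad)[1], call. = FALSE)
  }
  if (is.null(system_role)) system_role <- template$system_role
  total_tokens <- 0L
  lines <- character(nrow(examples))
  for (i in seq_len(nrow(examples))) {
    user <- render_prompt(template, scheme, response = examples$text[i])
    assistant <- as.character(examples$category_index[i])
    msgs <- list(
      list(role = "system", content = system_role),
      list(role = "user", content = user),
      list(role = "assistant", content = assistant))
    total_tokens <- total_tokens +
      sum(count_tokens(c(system_role, user, assistant)))
    lines[i] <- jsonlite::toJSON(list(messages = msgs), auto_unbox = TRUE)
  }
  writeLines(lines, path, useBytes = FALSE)
  invisible(list(path = path, n_records = nrow(examples),
                 total_tokens = total_tokens))
}

#' Read back a fine-tuning dataset
#'
#' Re-parses each chat record to its `(text, category_index)` pair; the
#' round trip through [export_finetune_dataset()] is the identity on those
#' fields.
#'
#' @param path JSON-lines file written by [export_finetune_dataset()].
#' @return Data.frame with columns `text`, `category_index`.
#' @export
read_finetune_dataset <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(line) {
    rec <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    msgs <- rec$messages
    roles <- vapply(msgs, `[[`, character(1), "role")
    user <- msgs[[which(roles == "user")[1]]]$content
    assistant <- msgs[[which(roles == "assistant")[1]]]$content
    m <- stringi::stri_match_all_regex(user, 'Response: "([^"]*)"')[[1]]
    data.frame(text = m[nrow(m), 2],
               category_index = as.integer(trimws(assistant)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
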