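#' Count tokens in a text
#'
#' The package's cost and accounting layer is a pure function of token
#' counts, so any counter can stand in for a provider tokenizer. The
#' default `"whitespace"` counter counts maximal non-whitespace runs; it is
#' additive over space-joined parts. A custom tokenizer (for provider-exact
#' counts) can be supplied as a function taking a character scalar and
#' returning an integer.
#'
#' @param text Character scalar (or vector; counted element-wise).
#' @param counter `"whitespace"` or a function.
#' @return Integer vector of token counts.
#' @export
count_tokens <- function(text, counter = "whitespace") {
  if (is.function(counter)) {
    return(vapply(as.character(text), counter, numeric(1), USE.NAMES = FALSE))
  }
  if (!identical(counter, "whitespace")) {
    stop("unknown token counter: ", counter, call. = FALSE)
  }
  vapply(strsplit(as.character(text), "\\s+"),
         function(p) sum(nzchar(p)), integer(1))
}

#' Backend configuration
#'
#' Completion temperature is fixed at 0 throughout the package: categorical
#' coding wants maximal run-to-run consistency, not sampling diversity.
#'
#' @param backend_id Identifier recorded on every result.
#' @param seed Integer seed for any backend randomness.
#' @param token_counter Passed to [count_tokens()].
#' @return A `backend_config` list.
#' @export
backend_config <- function(backend_id, seed = 1L, token_counter = "whitespace") {
  structure(list(backend_id = backend_id, temperature = 0,
                 seed = as.integer(seed), token_counter = token_counter),
            class = "backend_config")
}

#' A completion result with exact token accounting
#'
#' @param text Reply text.
#' @param prompt_tokens,completion_tokens Non-negative token counts.
#' @param backend_id Producing backend.
#' @param fallback `TRUE` when the backend declares it answered with its
#'   fallback category rather than a fired rule.
#' @return A `completion_result` list.
#' @export
completion_result <- function(text, prompt_tokens, completion_tokens,
                              backend_id, fallback = FALSE) {
  stopifnot(prompt_tokens >= 0, completion_tokens >= 0)
  structure(list(text = text,
                 prompt_tokens = as.integer(prompt_tokens),
                 completion_tokens = as.integer(completion_tokens),
                 backend_id = backend_id,
                 fallback = isTRUE(fallback)),
            class = "completion_result")
}

#' Issue one completion request
#'
#' @param backend A completion backend (e.g. [mock_rule_backend()],
#'   [cached_backend()], [http_backend()]).
#' @param system_role System-role text.
#' @param prompt Prompt body; must be non-empty.
#' @return A [completion_result()].
#' @export
complete <- function(backend, system_role, prompt) {
  if (!nzchar(trimws(prompt))) stop("empty prompt", call. = FALSE)
  UseMethod("complete")
}

#' Embed a batch of texts
#'
#' @param backend An embedding backend (e.g. [mock_embedding_backend()]).
#' @param texts Non-empty character vector; every element non-empty.
#' @return Numeric matrix, one row per text, `backend$dim` columns.
#' @export
embed_texts <- function(backend, texts) {
  if (length(texts) == 0) stop("no texts to embed", call. = FALSE)
  empty <- !nzchar(trimws(texts)) | is.na(texts)
  if (any(empty)) {
    stop("input error: empty text at position ", which(empty)[1],
         call. = FALSE)
  }
  UseMethod("embed_texts")
}

# ---- rule engine ------------------------------------------------------------

#' Build an ordered keyword-rule table
#'
#' @param pattern Character vector of phrases (matched after
#'   trim + casefold normalization).
#' @param index Category index each phrase maps to.
#' @return A `rule_table` data.frame ordered as given; exact phrase matches
#'   take precedence, then first containment match in row order.
#' @export
rule_table <- function(pattern, index) {
  stopifnot(length(pattern) == length(index))
  df <- data.frame(pattern = normalize_text(pattern, "trim_casefold"),
                   index = as.integer(index), stringsAsFactors = FALSE)
  class(df) <- c("rule_table", "data.frame")
  df
}

#' Apply an ordered rule table to one text
#'
#' Matching is two-stage: an exact match of the normalized text against a
#' rule phrase wins outright; otherwise the first rule (in table order)
#' whose phrase is contained in the text fires; otherwise the fallback
#' category is used.
#'
#' @param text Character scalar.
#' @param rules A [rule_table()].
#' @param fallback_index Category index used when no rule fires.
#' @return List with `index`, `matched` (the phrase or `NA`), `fallback`.
#' @export
apply_rules <- function(text, rules, fallback_index) {
  key <- normalize_text(text, "trim_casefold")
  hit <- match(key, rules$pattern)
  if (!is.na(hit)) {
    return(list(index = rules$index[hit], matched = rules$pattern[hit],
                fallback = FALSE))
  }
  if (nrow(rules) > 0) {
    contains <- stringi::stri_detect_fixed(key, rules$pattern)
    if (any(contains)) {
      i <- which(contains)[1]
      return(list(index = rules$index[i], matched = rules$pattern[i],
                  fallback = FALSE))
    }
  }
  list(index = as.integer(fallback_index), matched = NA_character_,
       fallback = TRUE)
}

# ---- mock completion backend ------------------------------------------------

#' Deterministic keyword-rule completion backend
#'
#' A fully offline stand-in for an LLM completion endpoint: it extracts the
#' response text (or cluster exemplars) from the rendered prompt, applies
#' an ordered keyword-rule table, and replies with the chosen category
#' index. When the prompt asks for reasoning followed by an `ANSWER:`
#' marker, it emits a short reasoning line first. Identical calls give
#' byte-identical results, making every strategy end-to-end testable with
#' knowable accuracy.
#'
#' @param rules A [rule_table()]; may have zero rows.
#' @param fallback_index Category index returned when no rule fires.
#' @param config A [backend_config()].
#' @return A completion backend.
#' @export
mock_rule_backend <- function(rules, fallback_index,
                              config = backend_config("mock-rules")) {
  stopifnot(inherits(rules, "rule_table"))
  structure(list(rules = rules, fallback_index = as.integer(fallback_index),
                 config = config),
            class = c("mock_rule_backend", "completion_backend"))
}

# The mock reads only the response content out of a rendered prompt, never
# the category list, so label words cannot trigger rules.
extract_prompt_subject <- function(prompt) {
  m <- stringi::stri_match_all_regex(prompt, 'Response: "([^"]*)"')[[1]]
  if (!anyNA(m[, 1]) && nrow(m) > 0) {
    return(m[nrow(m), 2])
  }
  m <- stringi::stri_match_first_regex(
    prompt,
    "(?s)example responses, separated by semicolons:\\s*(.*?)\\n\\s*\\n")
  if (!is.na(m[1, 2])) {
    return(m[1, 2])
  }
  prompt
}

#' @export
complete.mock_rule_backend <- function(backend, system_role, prompt) {
  subject <- extract_prompt_subject(prompt)
  res <- apply_rules(subject, backend$rules, backend$fallback_index)
  wants_reasoning <- stringi::stri_detect_fixed(prompt, "ANSWER:")
  if (wants_reasoning) {
    theme <- if (is.na(res$matched)) "no clear theme" else
      paste0("the theme '", res$matched, "'")
    text <- paste0("The response mentions ", theme,
                   ", which points to one label. ANSWER: ", res$index)
  } else {
    text <- as.character(res$index)
  }
  counter <- backend$config$token_counter
  completion_result(text,
                    prompt_tokens = count_tokens(paste(system_role, prompt),
                                                 counter),
                    completion_tokens = count_tokens(text, counter),
                    backend_id = backend$config$backend_id,
                    fallback = res$fallback)
}

# ---- mock embedding backend -------------------------------------------------

#' Deterministic hashed n-gram embedding backend
#'
#' Embeds each text as a bag of hashed character trigrams, L2-normalized to
#' the unit sphere. Texts sharing phrase templates land close in cosine
#' distance, which is the property the cluster-then-label strategy relies
#' on. Dimension defaults to 256; provider embeddings of dimension 1536
#' drop in behind the same contract.
#'
#' @param dim Embedding dimension.
#' @param config A [backend_config()].
#' @return An embedding backend.
#' @export
mock_embedding_backend <- function(dim = 256L,
                                   config = backend_config("mock-embed")) {
  stopifnot(dim >= 2)
  structure(list(dim = as.integer(dim), config = config),
            class = c("mock_embedding_backend", "embedding_backend"))
}

hash_trigram_vector <- function(text, dim) {
  key <- paste0(" ", normalize_text(text, "trim_casefold"), " ")
  n <- stringi::stri_length(key)
  if (n < 3) key <- stringi::stri_pad_right(key, 3)
  grams <- stringi::stri_sub(key, seq_len(max(n - 2, 1)), length = 3)
  codes <- lapply(grams, utf8ToInt)
  buckets <- vapply(codes, function(cs) {
    h <- 0
    for (c in cs) h <- (h * 31 + c) %% 1048573
    (h %% dim) + 1
  }, numeric(1))
  v <- tabulate(buckets, nbins = dim)
  v / sqrt(sum(v^2))
}

#' @export
embed_texts.mock_embedding_backend <- function(backend, texts) {
  out <- t(vapply(texts, hash_trigram_vector, numeric(backend$dim),
                  dim = backend$dim, USE.NAMES = FALSE))
  rownames(out) <- NULL
  out
}

# ---- response cache ---------------------------------------------------------

string_hash <- function(s) {
  b <- as.integer(charToRaw(enc2utf8(s)))
  h <- 5381
  for (x in b) h <- (h * 33 + x) %% 4294967291
  sprintf("%010.0f", h)
}

#' Wrap a completion backend with a response cache
#'
#' Identical (system role, prompt) pairs are served from the cache with the
#' identical [completion_result()], so reruns of a categorization campaign
#' cost nothing. The cache is keyed by backend id plus a hash of the
#' request; full request strings are stored alongside, so a hash collision
#' degrades to a miss, never a wrong answer. Optionally persisted as
#' JSON-lines; corrupted entries are skipped with a warning.
#'
#' @param backend The completion backend to wrap.
#' @param path Optional JSON-lines file for persistence; loaded if it
#'   exists, appended to on every miss.
#' @return A caching backend; inspect with [cache_stats()].
#' @export
cached_backend <- function(backend, path = NULL) {
  env <- new.env(parent = emptyenv())
  env$store <- new.env(parent = emptyenv())
  env$hits <- 0L
  env$misses <- 0L
  if (!is.null(path) && file.exists(path)) {
    for (line in readLines(path, encoding = "UTF-8", warn = FALSE)) {
      if (!nzchar(trimws(line))) next
      rec <- tryCatch(jsonlite::fromJSON(line), error = function(e) NULL)
      if (is.null(rec) || is.null(rec$key) || is.null(rec$result) ||
          is.null(rec$result$text)) {
        warning("skipping corrupted cache entry", call. = FALSE)
        next
      }
      assign(rec$key,
             list(system_role = rec$system_role, prompt = rec$prompt,
                  result = completion_result(rec$result$text,
                                             rec$result$prompt_tokens,
                                             rec$result$completion_tokens,
                                             rec$result$backend_id,
                                             isTRUE(rec$result$fallback))),
             envir = env$store)
    }
  }
  structure(list(backend = backend, env = env, path = path,
                 config = backend$config),
            class = c("cached_backend", "completion_backend"))
}

#' @export
complete.cached_backend <- function(backend, system_role, prompt) {
  key <- paste0(backend$config$backend_id, ":",
                string_hash(paste(system_role, prompt, sep = "\x1f")))
  env <- backend$env
  if (exists(key, envir = env$store, inherits = FALSE)) {
    entry <- get(key, envir = env$store)
    if (identical(entry$system_role, system_role) &&
        identical(entry$prompt, prompt)) {
      env$hits <- env$hits + 1L
      return(entry$result)
    }
  }
  env$misses <- env$misses + 1L
  result <- complete(backend$backend, system_role, prompt)
  assign(key, list(system_role = system_role, prompt = prompt,
                   result = result), envir = env$store)
  if (!is.null(backend$path)) {
    rec <- jsonlite::toJSON(list(key = key, system_role = system_role,
                                 prompt = prompt,
                                 result = unclass(result)),
                            auto_unbox = TRUE)
    cat(rec, "\n", sep = "", file = backend$path, append = TRUE)
  }
  result
}

#' Cache hit/miss counters
#'
#' @param backend A [cached_backend()].
#' @return List with `hits`, `misses`, `size`.
#' @export
cache_stats <- function(backend) {
  stopifnot(inherits(backend, "cached_backend"))
  list(hits = backend$env$hits, misses = backend$env$misses,
       size = length(ls(backend$env$store)))
}

# ---- remote adapter ---------------------------------------------------------

#' Completion backend over a user-supplied transport
#'
#' Thin adapter for real completion APIs: `transport` is a function
#' `(system_role, prompt) -> reply text` (wrap your HTTP client of choice).
#' Transport errors are retried up to 3 attempts, then surfaced as a
#' backend error carrying the attempt count. Token counts use the
#' configured counter unless the transport returns a list with `text`,
#' `prompt_tokens`, `completion_tokens` (provider-exact accounting).
#'
#' No offline functionality depends on this adapter.
#'
#' @param transport Function of (system_role, prompt).
#' @param config A [backend_config()].
#' @param attempts Fixed retry budget.
#' @return A completion backend.
#' @export
http_backend <- function(transport, config = backend_config("remote"),
                         attempts = 3L) {
  stopifnot(is.function(transport))
  structure(list(transport = transport, config = config,
                 attempts = as.integer(attempts)),
            class = c("http_backend", "completion_backend"))
}

#' @export
complete.http_backend <- function(backend, system_role, prompt) {
  last <- NULL
  for (attempt in seq_len(backend$attempts)) {
    out <- tryCatch(backend$transport(system_role, prompt),
                    error = function(e) e)
    if (!inherits(out, "error")) {
      counter <- backend$config$token_counter
      if (is.list(out) && !is.null(out$text)) {
        return(completion_result(out$text,
                                 out$prompt_tokens %||%
                                   count_tokens(paste(system_role, prompt),
                                                counter),
                                 out$completion_tokens %||%
                                   count_tokens(out$text, counter),
                                 backend$config$backend_id))
      }
      return(completion_result(out,
                               count_tokens(paste(system_role, prompt),
                                            counter),
                               count_tokens(out, counter),
                               backend$config$backend_id))
    }
    last <- out
  }
  stop("backend error after ", backend$attempts, " attempts: ",
       conditionMessage(last), call. = FALSE)
}
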