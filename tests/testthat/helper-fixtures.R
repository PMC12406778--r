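# Shared fixtures, all built in code at test time.

tiny_scheme <- function() {
  category_scheme(data.frame(
    index = 1:4,
    label = c("Travel", "Strike", "Too far", "Other"),
    origin = c("original_option", "added_category", "original_option",
               "added_category"),
    stringsAsFactors = FALSE), name = "tiny")
}

tiny_responses <- function(texts, rounds = 2021L) {
  survey_responses(data.frame(
    response_id = paste0("id", seq_along(texts)),
    survey_round = rounds,
    text = texts,
    stringsAsFactors = FALSE))
}

# backend wrapper that counts completion calls
counting_backend <- function(backend) {
  env <- new.env(parent = emptyenv())
  env$calls <- 0L
  structure(list(backend = backend, env = env, config = backend$config),
            class = c("counting_backend", "completion_backend"))
}

complete.counting_backend <- function(backend, system_role, prompt) {
  backend$env$calls <- backend$env$calls + 1L
  complete(backend$backend, system_role, prompt)
}

# backend wrapper that records every completion result
recording_backend <- function(backend) {
  env <- new.env(parent = emptyenv())
  env$results <- list()
  structure(list(backend = backend, env = env, config = backend$config),
            class = c("recording_backend", "completion_backend"))
}

complete.recording_backend <- function(backend, system_role, prompt) {
  res <- complete(backend$backend, system_role, prompt)
  backend$env$results[[length(backend$env$results) + 1L]] <- res
  res
}

# registered so S3 dispatch finds the test-only methods
registerS3method("complete", "counting_backend", complete.counting_backend,
                 envir = asNamespace("survcat"))
registerS3method("complete", "recording_backend", complete.recording_backend,
                 envir = asNamespace("survcat"))

# deterministic function-of-text-only backend contract check helper
truth_lookup <- function(truths) {
  setNames(truths$true_category, truths$response_id)
}

unique_truths <- function(gen, dd) {
  gen$truths[match(dd$representative[dd$unique_texts],
                   gen$truths$response_id), ]
}
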