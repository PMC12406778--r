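test_that("category list renders in index order with semicolons, deterministically", {
  sc <- category_scheme(data.frame(index = 1:2, label = c("A", "B")))
  expect_equal(render_category_list(sc), "1. A; 2. B")
  full <- render_category_list(default_scheme())
  expect_equal(length(strsplit(full, "; ")[[1]]), 43)
  expect_identical(full, render_category_list(default_scheme()))
})

test_that("reply parsing handles bare indices, markers, and range failures", {
  sc <- default_scheme()
  expect_equal(parse_category_reply("24", sc, "bare_index"),
               list(index = 24L, status = "ok"))
  expect_equal(parse_category_reply("  7 \n", sc, "bare_index")$index, 7L)
  expect_equal(parse_category_reply("44", sc, "bare_index")$status, "failed")
  expect_equal(parse_category_reply("7 maybe", sc, "bare_index")$status,
               "failed")

  cot <- "I think the answer is travel. ANSWER: 7"
  expect_equal(parse_category_reply(cot, sc, "reasoning_then_index"),
               list(index = 7L, status = "ok"))
  multi <- "ANSWER: 3 no wait. ANSWER: 9"
  expect_equal(parse_category_reply(multi, sc, "reasoning_then_index")$index,
               9L)
  expect_equal(parse_category_reply("no marker here", sc,
                                    "reasoning_then_index")$status,
               "failed")
})

test_that("zero-shot assigns by rule, records fallbacks, and is fully recovered on clean data", {
  sc <- tiny_scheme()
  rules <- rule_table(c("voyage", "grève"), c(1L, 2L))
  be <- mock_rule_backend(rules, fallback_index = 4L)
  out <- zero_shot(c("le voyage", "grève ici", "rien"), sc, be)
  expect_equal(out$category_index, c(1L, 2L, 4L))
  expect_equal(out$parse_status, c("ok", "ok", "fallback"))
  expect_equal(attr(out, "n_calls"), 3L)

  # empty-rule backend: every assignment is the fallback category
  none <- mock_rule_backend(rule_table(character(0), integer(0)), 3L)
  out2 <- zero_shot(c("a b", "c d"), sc, none)
  expect_equal(out2$category_index, c(3L, 3L))
  expect_equal(out2$parse_status, c("fallback", "fallback"))

  # parameter recovery on a clean corpus
  cfg <- generator_config(n_responses = 300, vague_rate = 0,
                          compound_rate = 0, seed = 4)
  gen <- generate(cfg)
  got <- zero_shot(gen$responses, cfg$scheme, mock_backend_from_config(cfg))
  expect_equal(got$category_index, gen$truths$true_category)
})

test_that("few-shot samples are seeded, order-stable, and grow prompt tokens strictly with k", {
  sc <- tiny_scheme()
  examples <- data.frame(text = paste0("ex", 1:30),
                         category_index = rep(1:3, 10))
  be <- mock_rule_backend(rule_table("voyage", 1L), 4L)

  expect_error(few_shot("voyage", sc, be, examples, k = 31),
               "configuration error")

  # k = full set embeds all examples in input order
  cb <- cached_backend(be)
  full <- few_shot("voyage", sc, cb, examples, k = 30)
  expect_equal(full$category_index, 1L)

  # same seed -> identical prompt (cache hit proves byte-identity)
  cb2 <- cached_backend(be)
  few_shot("voyage", sc, cb2, examples, k = 5, seed = 11)
  few_shot("voyage", sc, cb2, examples, k = 5, seed = 11)
  expect_equal(cache_stats(cb2), list(hits = 1L, misses = 1L, size = 1L))

  token_at_k <- vapply(c(5, 10, 20, 30), function(k) {
    rec <- recording_backend(be)
    few_shot("voyage", sc, rec, examples, k = k, seed = 1)
    rec$env$results[[1]]$prompt_tokens
  }, numeric(1))
  expect_true(all(diff(token_at_k) > 0))
})

test_that("chain of thought parses the marker and accounts multi-token completions", {
  sc <- default_scheme()
  cfg <- generator_config(n_responses = 5, vague_rate = 0, compound_rate = 0,
                          seed = 2)
  be <- mock_backend_from_config(cfg)
  gen <- generate(cfg)
  out <- chain_of_thought(gen$responses, sc, be)
  expect_equal(out$category_index, gen$truths$true_category)
  expect_true(all(grepl("ANSWER:", out$raw_output)))

  res <- complete(be, "r",
                  'Response: "voyage de la famille"\n\nFinish with ANSWER:')
  expect_gt(res$completion_tokens, 1L)

  expect_error(chain_of_thought(gen$responses, sc, be,
                                template = default_direct_template()),
               "reasoning_then_index")

  # reasoning with no marker fails the parse
  expect_equal(parse_category_reply("just rambling", sc,
                                    "reasoning_then_index")$status, "failed")
})

test_that("clustering is deterministic, drops empty clusters, handles the singleton limit", {
  cfg <- generator_config(n_responses = 60, vague_rate = 0,
                          compound_rate = 0, seed = 13)
  gen <- generate(cfg)
  texts <- unique(gen$responses$text)
  v <- embed_texts(mock_embedding_backend(dim = 48), texts)

  m1 <- fit_clusters(v, "kmeans", k = 5, seed = 3)
  m2 <- fit_clusters(v, "kmeans", k = 5, seed = 3)
  expect_identical(m1$assignments, m2$assignments)
  expect_equal(sort(unique(m1$assignments)), seq_len(m1$n_clusters))

  singleton <- fit_clusters(v, "kmeans", k = nrow(v), seed = 1)
  expect_equal(singleton$assignments, seq_len(nrow(v)))

  expect_error(fit_clusters(v, "kmeans", k = nrow(v) + 1),
               "configuration error")

  # two well-separated template families cluster to purity 1
  fam <- c(rep("grève des infirmiers aujourd'hui encore", 10),
           rep("voyage de toute la famille au loin", 10))
  fam <- paste(fam, rep(1:10, 2))  # distinct strings, shared family core
  vf <- embed_texts(mock_embedding_backend(dim = 64), fam)
  for (alg in c("kmeans", "gmm", "hierarchical")) {
    mf <- fit_clusters(vf, alg, k = 2, seed = 5)
    purity <- max(table(mf$assignments[1:10])) +
      max(table(mf$assignments[11:20]))
    expect_equal(purity, 20L, label = alg)
  }
})

test_that("cluster-label issues one call per cluster and propagates labels", {
  cfg <- generator_config(n_responses = 400, vague_rate = 0,
                          compound_rate = 0, seed = 17)
  gen <- generate(cfg)
  dd <- deduplicate(gen$responses)
  be <- counting_backend(mock_backend_from_config(cfg))
  out <- cluster_label(dd$unique_texts, cfg$scheme,
                       mock_embedding_backend(dim = 64), be,
                       algorithm = "kmeans", k = 25, seed = 1)
  expect_equal(attr(out, "n_calls"),
               attr(out, "cluster_model")$n_clusters)
  expect_equal(be$env$calls, attr(out, "n_calls"))

  # members of one cluster share one label
  model <- attr(out, "cluster_model")
  for (cl in seq_len(model$n_clusters)) {
    expect_equal(length(unique(out$category_index[model$assignments == cl])),
                 1L)
  }
})

test_that("cluster-label at k = n converges on zero-shot under a text-only backend", {
  cfg <- generator_config(n_responses = 300, seed = 23)
  gen <- generate(cfg)
  dd <- deduplicate(gen$responses)
  be <- mock_backend_from_config(cfg)
  cl <- cluster_label(dd$unique_texts, cfg$scheme,
                      mock_embedding_backend(dim = 48), be,
                      k = length(dd$unique_texts), seed = 2)
  zs <- zero_shot(dd$unique_texts, cfg$scheme, be)
  expect_equal(cl$category_index, zs$category_index)
})

test_that("fine-tune export writes valid chat records that round-trip, with token totals", {
  sc <- tiny_scheme()
  examples <- data.frame(text = c("voyage demain", "grève ici"),
                         category_index = c(1L, 2L))
  path <- withr::local_tempfile(fileext = ".jsonl")
  info <- export_finetune_dataset(examples, sc, path)
  expect_equal(info$n_records, 2L)

  lines <- readLines(path)
  expect_equal(length(lines), 2)
  rec <- jsonlite::fromJSON(lines[1], simplifyVector = FALSE)
  expect_equal(vapply(rec$messages, `[[`, character(1), "role"),
               c("system", "user", "assistant"))
  expect_equal(rec$messages[[3]]$content, "1")

  back <- read_finetune_dataset(path)
  expect_equal(back$text, examples$text)
  expect_equal(back$category_index, examples$category_index)

  # token total equals the whitespace-token sum over all message contents
  total <- sum(vapply(lines, function(l) {
    msgs <- jsonlite::fromJSON(l, simplifyVector = FALSE)$messages
    sum(count_tokens(vapply(msgs, `[[`, character(1), "content")))
  }, numeric(1)))
  expect_equal(info$total_tokens, total)

  expect_error(export_finetune_dataset(
    data.frame(text = "x", category_index = 9L), sc, path),
    "out of range")
})
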