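test_that("generator is reproducible and respects degenerate configs", {
  cfg <- generator_config(n_responses = 300, seed = 5)
  g1 <- generate(cfg)
  g2 <- generate(cfg)
  expect_identical(g1$responses$text, g2$responses$text)
  expect_identical(g1$truths, g2$truths)

  clean <- generate(generator_config(n_responses = 200, vague_rate = 0,
                                     compound_rate = 0, seed = 2))
  expect_true(all(clean$truths$kind == "clean"))
  expect_true(all(clean$truths$acceptable_set ==
                    as.character(clean$truths$true_category)))

  vague <- generate(generator_config(n_responses = 400, vague_rate = 0.5,
                                     compound_rate = 0.3, seed = 2))
  sets <- strsplit(vague$truths$acceptable_set, "|", fixed = TRUE)
  ambiguous <- vague$truths$kind != "clean"
  expect_true(all(lengths(sets)[ambiguous] >= 2))
  expect_true(all(mapply(function(s, t) as.character(t) %in% s,
                         sets, vague$truths$true_category)))

  expect_error(generator_config(vague_rate = 0.8, compound_rate = 0.4),
               "sum to <= 1")
  expect_error(generator_config(duplication_exponent = 0),
               "duplication_exponent")
  expect_error(generator_config(templates = list(`1` = "x")),
               "no template for category")
})

test_that("duplication is heavy-tailed: fewer uniques, monotone in the tail exponent", {
  gen <- generate(generator_config(n_responses = 10000,
                                   duplication_exponent = 1.2, seed = 31))
  n_unique <- length(deduplicate(gen$responses)$unique_texts)
  expect_lt(n_unique, 10000)

  uniques <- vapply(c(0.6, 1.2, 3), function(a) {
    g <- generate(generator_config(n_responses = 4000,
                                   duplication_exponent = a, seed = 11))
    length(deduplicate(g$responses)$unique_texts)
  }, numeric(1))
  expect_true(all(diff(uniques) > 0))
})

test_that("truths round-trip through the delimited truths file", {
  gen <- generate(generator_config(n_responses = 150, seed = 6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_truths(gen$truths, path)
  expect_equal(read_truths(path), gen$truths)
})

test_that("synthetic benchmarks split unique strings with generator truth as human code", {
  cfg <- generator_config(n_responses = 3000, seed = 12)
  bm <- generate_benchmark(cfg, n_benchmark = 500, n_test = 100, seed = 3)
  expect_equal(nrow(bm$split$train), 400)
  expect_equal(nrow(bm$split$test), 100)
  expect_length(intersect(bm$split$train$response_id,
                          bm$split$test$response_id), 0)
  expect_equal(bm$truths$true_category[match(bm$split$test$response_id,
                                             bm$truths$response_id)],
               bm$split$test$human_category)

  expect_error(generate_benchmark(cfg, n_benchmark = 1e6, n_test = 10),
               "configuration error")

  # mock-backend accuracy on a clean benchmark is exactly 1
  cfg0 <- generator_config(n_responses = 1500, vague_rate = 0,
                           compound_rate = 0, seed = 12)
  bm0 <- generate_benchmark(cfg0, n_benchmark = 300, n_test = 80, seed = 3)
  got <- zero_shot(bm0$split$test$text, cfg0$scheme,
                   mock_backend_from_config(cfg0))
  expect_equal(accuracy(got, bm0$split$test), 1.0)
})

test_that("expected mock accuracy matches simulation within binomial error", {
  expect_equal(expected_mock_accuracy(
    generator_config(vague_rate = 0, compound_rate = 0)), 1.0)
  expect_equal(expected_mock_accuracy(
    generator_config(vague_rate = 0.2, compound_rate = 0)), 0.9)

  cfg <- generator_config(n_responses = 2000, vague_rate = 0.2,
                          compound_rate = 0, seed = 19)
  gen <- generate(cfg)
  dd <- deduplicate(gen$responses)
  ua <- zero_shot(unique_responses(dd), cfg$scheme,
                  mock_backend_from_config(cfg))
  utr <- unique_truths(gen, dd)
  observed <- mean(ua$category_index == utr$true_category)
  expected <- expected_mock_accuracy(cfg, level = "unique")
  se <- sqrt(expected * (1 - expected) / nrow(utr))
  expect_lt(abs(observed - expected), 3 * se)

  # the unique-level closed form tracks truth-only simulation across seeds
  sim <- vapply(101:104, function(s) {
    g <- generate(generator_config(n_responses = 2000, vague_rate = 0.2,
                                   compound_rate = 0, seed = s))
    d <- deduplicate(g$responses)
    ut <- unique_truths(g, d)
    first_of_set <- vapply(strsplit(ut$acceptable_set, "|", fixed = TRUE),
                           function(x) as.integer(x[1]), integer(1))
    mean(ifelse(ut$kind == "vague", first_of_set == ut$true_category, TRUE))
  }, numeric(1))
  expect_equal(mean(sim), expected_mock_accuracy(cfg, level = "unique"),
               tolerance = 0.02)
})

test_that("acceptable-set adjudication reproduces the accuracy-ceiling gap", {
  cfg <- generator_config(n_responses = 2500, vague_rate = 0.25,
                          compound_rate = 0.1, seed = 29)
  bm <- generate_benchmark(cfg, n_benchmark = 400, n_test = 150, seed = 4)
  test_set <- bm$split$test
  got <- zero_shot(test_set$text, cfg$scheme, mock_backend_from_config(cfg))

  ws <- export_discordances(got, test_set)
  sets <- setNames(bm$truths$acceptable_set, bm$truths$response_id)
  ws$verdict <- ifelse(mapply(function(id, model) {
    as.character(model) %in% strsplit(sets[[id]], "|", fixed = TRUE)[[1]]
  }, ws$response_id, ws$model_category), "acceptable", "not_acceptable")

  acc <- accuracy(got, test_set)
  ceil <- accuracy_ceiling(got, test_set, ws)
  expect_gte(ceil, acc)
  expect_gt(ceil, acc)  # vague responses present, so strictly greater
})
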