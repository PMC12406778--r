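make_bench <- function(n, seed = 1) {
  with_seed <- function(expr) { set.seed(seed); expr }
  benchmark_examples(data.frame(
    response_id = paste0("b", seq_len(n)),
    text = paste("texte", seq_len(n)),
    human_category = with_seed(sample.int(4, n, replace = TRUE)),
    stringsAsFactors = FALSE))
}

assign_for <- function(bench, model_category, status = "ok") {
  category_assignments(data.frame(
    response_id = bench$response_id,
    category_index = as.integer(model_category),
    method = "m", raw_output = as.character(model_category),
    parse_status = status, stringsAsFactors = FALSE))
}

test_that("benchmark splitting partitions exactly, disjointly, reproducibly", {
  bench <- make_bench(999)
  sp <- split_benchmark(bench, n_test = 200, seed = 8)
  expect_equal(nrow(sp$train), 799)
  expect_equal(nrow(sp$test), 200)
  expect_length(intersect(sp$train$response_id, sp$test$response_id), 0)
  expect_setequal(c(sp$train$response_id, sp$test$response_id),
                  bench$response_id)

  sp2 <- split_benchmark(bench, n_test = 200, seed = 8)
  expect_identical(sp$test$response_id, sp2$test$response_id)

  expect_error(split_benchmark(bench, n_test = 0), "configuration error")
  expect_error(split_benchmark(bench, n_test = 999), "configuration error")
})

test_that("accuracy is the concordant share; failed parses count discordant", {
  bench <- make_bench(200)
  perfect <- assign_for(bench, bench$human_category)
  expect_equal(accuracy(perfect, bench), 1.0)

  # 167 concordant of 200
  model <- bench$human_category
  model[1:33] <- model[1:33] %% 4 + 1
  expect_equal(accuracy(assign_for(bench, model), bench), 0.835)

  # failed parse on a concordant index still scores discordant
  status <- rep("ok", 200); status[200] <- "failed"
  expect_equal(accuracy(assign_for(bench, bench$human_category, status),
                        bench), 199 / 200)

  expect_error(accuracy(perfect[-1, ], bench), "alignment error")

  # permutation-invariant under consistent reordering
  perm <- sample(200)
  expect_equal(accuracy(assign_for(bench, model)[perm, ], bench), 0.835)

  # brute-force counting oracle on random assignment vectors
  for (seed in 1:5) {
    set.seed(seed)
    guess <- sample.int(4, 200, replace = TRUE)
    brute <- sum(vapply(seq_len(200), function(i)
      guess[i] == bench$human_category[i], logical(1))) / 200
    expect_equal(accuracy(assign_for(bench, guess), bench), brute)
  }
})

test_that("accuracy ceiling adds acceptable discordances and bounds accuracy", {
  bench <- make_bench(200)
  model <- bench$human_category
  model[1:33] <- model[1:33] %% 4 + 1
  assignments <- assign_for(bench, model)

  worksheet <- export_discordances(assignments, bench)
  expect_equal(nrow(worksheet), 33)
  expect_true(all(worksheet$verdict == "unreviewed"))

  # 25 of 33 adjudicated acceptable: ceiling (167 + 25) / 200 = 0.96
  worksheet$verdict[1:25] <- "acceptable"
  expect_equal(accuracy_ceiling(assignments, bench, worksheet), 0.96)

  # zero acceptable: ceiling equals accuracy; all acceptable: 1.0
  none <- export_discordances(assignments, bench)
  expect_equal(accuracy_ceiling(assignments, bench, none), 0.835)
  all_ok <- none; all_ok$verdict <- "acceptable"
  expect_equal(accuracy_ceiling(assignments, bench, all_ok), 1.0)

  # adjudicating a concordant pair is a validation error
  bad <- rbind(none, data.frame(response_id = bench$response_id[100],
                                text = "x", human_category = 1,
                                model_category = 1,
                                verdict = "acceptable"))
  expect_error(accuracy_ceiling(assignments, bench, bad),
               "concordant")

  # worksheet round-trips through the review file
  path <- withr::local_tempfile(fileext = ".csv")
  export_discordances(assignments, bench, path)
  expect_equal(read_adjudications(path)$response_id, worksheet$response_id)
})

test_that("ceiling dominates accuracy over random adjudication configurations", {
  bench <- make_bench(120, seed = 3)
  set.seed(42)
  for (i in 1:25) {
    guess <- sample.int(4, 120, replace = TRUE)
    assignments <- assign_for(bench, guess)
    ws <- export_discordances(assignments, bench)
    if (nrow(ws) > 0) {
      ws$verdict <- sample(c("acceptable", "not_acceptable", "unreviewed"),
                           nrow(ws), replace = TRUE)
    }
    acc <- accuracy(assignments, bench)
    ceil <- accuracy_ceiling(assignments, bench, ws)
    expect_gte(ceil, acc)
    if (any(ws$verdict == "acceptable")) expect_gt(ceil, acc)
  }
})

test_that("margin of error matches the closed form and its scaling laws", {
  expect_equal(margin_of_error(0.85, 200), 0.0495, tolerance = 1e-3)
  expect_equal(margin_of_error(0.5, 100), 0.098)
  expect_equal(margin_of_error(0.3, 400), margin_of_error(0.3, 100) / 2)
  # decreasing in n, maximized at p = 0.5
  expect_true(all(diff(margin_of_error(0.4, c(50, 100, 200, 400))) < 0))
  expect_true(all(margin_of_error(c(0.1, 0.3, 0.7, 0.9), 100) <
                    margin_of_error(0.5, 100)))
  expect_error(margin_of_error(1, 100), "domain error")
})

test_that("required sample size is the smallest n meeting the margin", {
  expect_equal(required_sample_size(0.85, 0.05), 196L)
  expect_equal(required_sample_size(0.5, 0.5), 4L)
  set.seed(7)
  for (i in 1:20) {
    p <- runif(1, 0.05, 0.95); m <- runif(1, 0.01, 0.3)
    n <- required_sample_size(p, m)
    expect_lte(margin_of_error(p, n), m)
    if (n > 1) expect_gt(margin_of_error(p, n - 1), m)
  }
  expect_error(required_sample_size(0.85, 0), "domain error")
})

test_that("per-category accuracy flags underpowered categories", {
  bench <- make_bench(40)
  sc <- tiny_scheme()
  out <- per_category_accuracy(assign_for(bench, bench$human_category),
                               bench, sc, min_n = 15)
  expect_equal(nrow(out), 4)
  expect_true(all(out$accuracy[out$n > 0] == 1))
  expect_equal(out$underpowered, out$n < 15)
})
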