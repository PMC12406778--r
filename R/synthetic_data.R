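#' Default phrase templates for the synthetic corpus
#'
#' Short French/English noun phrases per category of [default_scheme()],
#' mirroring the register of caregiver free-text answers ("voyage de la
#' famille", "grève des infirmiers", ...). Shipped as an editable CSV; the
#' same phrases seed the mock backend's keyword rules, which is what makes
#' synthetic accuracy knowable in advance.
#'
#' @return Named list mapping category index to a character vector of
#'   phrases.
#' @export
default_templates <- function() {
  path <- system.file("extdata", "default_templates.csv",
                      package = "survcat")
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  split(df$phrase, df$index)
}

#' Default vague-phrase pool
#'
#' Phrases deliberately ambiguous between two categories ("long trajet"
#' could mean the site is too far or the family travelled), with their
#' acceptable category sets. These drive the accuracy-vs-ceiling gap in
#' synthetic benchmarks.
#'
#' @return Data.frame with columns `phrase`, `acceptable_set`
#'   (pipe-separated indices).
#' @export
default_vague_pool <- function() {
  path <- system.file("extdata", "default_vague_pool.csv",
                      package = "survcat")
  read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}

parse_set <- function(s) as.integer(strsplit(s, "|", fixed = TRUE)[[1]])

#' Synthetic-corpus generator configuration
#'
#' Defines the study conditions a generated corpus emulates: a closed
#' category scheme with at least one phrase template per category, mixture
#' rates for vague and compound responses, and a heavy-tailed duplication
#' distribution over response strings (popular answers like "Travel" recur
#' hundreds of times in real survey data). `duplication_exponent` is the
#' Pareto tail index of string popularity: smaller values mean heavier
#' duplication and fewer unique strings.
#'
#' @param scheme A [category_scheme()].
#' @param templates Named list mapping category index to phrases; every
#'   category needs at least one.
#' @param n_responses Number of responses to generate.
#' @param vague_rate,compound_rate Mixture rates in `[0, 1]`, summing to at
#'   most 1.
#' @param duplication_exponent Positive Pareto tail index.
#' @param pool_size Size of the latent phrase pool the duplication
#'   distribution draws from; defaults to `3 * n_responses`.
#' @param vague_pool Data.frame as [default_vague_pool()]; required when
#'   `vague_rate > 0`.
#' @param prefixes,suffixes Neutral filler phrases (including the empty
#'   string) wrapped around the core phrase of each latent response,
#'   emulating phrasing variation around a shared theme ("c'est que
#'   maman trop occupée cette fois"). They contain no rule keyword, so
#'   they change text diversity without touching the accuracy contract.
#' @param rounds Survey rounds assigned uniformly to responses.
#' @param seed Integer seed; identical configs are byte-identical.
#' @return A `generator_config` list.
#' @export
generator_config <- function(scheme = default_scheme(),
                             templates = default_templates(),
                             n_responses = 1000L,
                             vague_rate = 0.10, compound_rate = 0.05,
                             duplication_exponent = 2,
                             pool_size = NULL,
                             vague_pool = default_vague_pool(),
                             prefixes = c("", "", "parce que", "c'est que",
                                          "ici", "chez nous", "souvent",
                                          "on dit que", "cette année"),
                             suffixes = c("", "", "cette fois", "au village",
                                          "pour le moment", "vraiment",
                                          "depuis des mois", "encore"),
                             rounds = c(2021L, 2022L, 2023L),
                             seed = 1L) {
  stopifnot(inherits(scheme, "category_scheme"))
  n_phrases <- vapply(as.character(scheme$index),
                      function(i) length(templates[[i]]), integer(1))
  missing_t <- as.character(scheme$index)[n_phrases == 0]
  if (length(missing_t) > 0) {
    stop("configuration error: no template for category ",
         missing_t[1], call. = FALSE)
  }
  if (vague_rate < 0 || compound_rate < 0 ||
      vague_rate + compound_rate > 1) {
    stop("configuration error: rates must be nonnegative and sum to <= 1",
         call. = FALSE)
  }
  if (duplication_exponent <= 0) {
    stop("configuration error: duplication_exponent must be > 0",
         call. = FALSE)
  }
  if (vague_rate > 0) {
    sets <- lapply(vague_pool$acceptable_set, parse_set)
    bad <- vapply(sets, function(s) length(s) < 2 ||
                    any(s < 1 | s > nrow(scheme)), logical(1))
    if (nrow(vague_pool) == 0 || any(bad)) {
      stop("configuration error: vague_pool needs phrases with >= 2 ",
           "in-scheme acceptable categories", call. = FALSE)
    }
  }
  structure(list(scheme = scheme, templates = templates,
                 n_responses = as.integer(n_responses),
                 vague_rate = vague_rate, compound_rate = compound_rate,
                 duplication_exponent = duplication_exponent,
                 pool_size = as.integer(pool_size %||% (3 * n_responses)),
                 vague_pool = vague_pool,
                 prefixes = prefixes, suffixes = suffixes,
                 rounds = as.integer(rounds),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Compile the mock backend's keyword rules from a generator config
#'
#' One rule per template phrase (ordered by category index, then template
#' order) plus one per vague phrase mapping to the first category of its
#' acceptable set. With these rules the mock backend's expected accuracy on
#' a generated corpus is known in closed form
#' ([expected_mock_accuracy()]).
#'
#' @param config A [generator_config()].
#' @return A [rule_table()].
#' @export
compile_rules <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  idx <- sort(as.integer(names(config$templates)))
  pattern <- unlist(lapply(idx, function(i)
    config$templates[[as.character(i)]]), use.names = FALSE)
  index <- rep(idx, vapply(idx, function(i)
    length(config$templates[[as.character(i)]]), integer(1)))
  if (config$vague_rate > 0 && nrow(config$vague_pool) > 0) {
    pattern <- c(pattern, config$vague_pool$phrase)
    index <- c(index, vapply(config$vague_pool$acceptable_set,
                             function(s) parse_set(s)[1], integer(1)))
  }
  rules <- rule_table(pattern, index)
  inside <- outer(rules$pattern, rules$pattern,
                  Vectorize(function(a, b) a != b &&
                              stringi::stri_detect_fixed(b, a)))
  if (any(inside & outer(rules$index, rules$index, "!="))) {
    warning("rule phrases of different categories are substrings of one ",
            "another; containment matching may misfire", call. = FALSE)
  }
  rules
}

#' Mock completion backend matched to a generator config
#'
#' @param config A [generator_config()].
#' @param backend_id Identifier for the backend.
#' @return A [mock_rule_backend()] whose fallback is the scheme's last
#'   category.
#' @export
mock_backend_from_config <- function(config, backend_id = "mock-rules") {
  mock_rule_backend(compile_rules(config),
                    fallback_index = nrow(config$scheme),
                    config = backend_config(backend_id))
}

decorate <- function(core, config) {
  pre <- sample(config$prefixes, 1)
  suf <- sample(config$suffixes, 1)
  trimws(paste(pre, core, suf))
}

draw_slot <- function(config) {
  u <- runif(1)
  scheme_n <- nrow(config$scheme)
  if (u < config$vague_rate) {
    row <- sample.int(nrow(config$vague_pool), 1)
    set <- parse_set(config$vague_pool$acceptable_set[row])
    list(text = decorate(config$vague_pool$phrase[row], config),
         true_category = sample(set, 1),
         acceptable_set = set, kind = "vague")
  } else if (u < config$vague_rate + config$compound_rate) {
    cats <- sample.int(scheme_n, 2)
    p1 <- sample(config$templates[[as.character(cats[1])]], 1)
    p2 <- sample(config$templates[[as.character(cats[2])]], 1)
    list(text = decorate(paste(p1, "et", p2), config),
         true_category = cats[1],
         acceptable_set = sort(cats), kind = "compound")
  } else {
    cat_i <- sample.int(scheme_n, 1)
    list(text = decorate(sample(config$templates[[as.character(cat_i)]], 1),
                         config),
         true_category = cat_i, acceptable_set = cat_i, kind = "clean")
  }
}

#' Generate a synthetic survey corpus with known ground truth
#'
#' Builds a latent pool of phrase slots (clean single-template responses,
#' vague phrases with a recorded acceptable set, compound concatenations of
#' two categories' phrases at the configured rates), merges slots with
#' identical text, assigns each slot a Pareto popularity weight, and draws
#' `n_responses` strings from that popularity distribution — so common
#' answers repeat heavily, as in real free-text survey data. Fully
#' reproducible under the config seed.
#'
#' @param config A [generator_config()].
#' @return List with `responses` (a [survey_responses()] table) and
#'   `truths` (data.frame: `response_id`, `true_category`,
#'   `acceptable_set` pipe-separated, `kind`).
#' @export
generate <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed, {
    slots <- lapply(seq_len(config$pool_size),
                    function(i) draw_slot(config))
    texts <- vapply(slots, `[[`, character(1), "text")
    first <- !duplicated(normalize_text(texts, "exact"))
    slots <- slots[first]
    m <- length(slots)
    weights <- runif(m)^(-1 / config$duplication_exponent)
    picks <- sample.int(m, config$n_responses, replace = TRUE,
                        prob = weights)
    ids <- sprintf("r%06d", seq_len(config$n_responses))
    responses <- survey_responses(data.frame(
      response_id = ids,
      survey_round = sample(config$rounds, config$n_responses,
                            replace = TRUE),
      text = vapply(slots[picks], `[[`, character(1), "text"),
      weight = 1,
      stratum = "zero_dose",
      admin_unit = paste0("unit", sample.int(10, config$n_responses,
                                             replace = TRUE)),
      stringsAsFactors = FALSE))
    truths <- data.frame(
      response_id = ids,
      true_category = vapply(slots[picks], `[[`, integer(1),
                             "true_category"),
      acceptable_set = vapply(slots[picks], function(s)
        paste(s$acceptable_set, collapse = "|"), character(1)),
      kind = vapply(slots[picks], `[[`, character(1), "kind"),
      stringsAsFactors = FALSE)
    list(responses = responses, truths = truths)
  })
}

#' Write / read a ground-truth table
#'
#' @param truths Truths data.frame from [generate()].
#' @param path Delimited file path.
#' @return `path` invisibly; `read_truths()` returns the data.frame.
#' @export
write_truths <- function(truths, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(truths, con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_truths
#' @export
read_truths <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                 colClasses = c(acceptable_set = "character"))
  df$response_id <- as.character(df$response_id)
  df
}

#' Generate a benchmark with the generator playing the human coder
#'
#' Deduplicates a generated corpus, samples `n_benchmark` unique strings,
#' labels each with its generator truth as the human category, and splits
#' into train/test. Benchmark `response_id`s are the unique texts
#' themselves, matching the unique-string categorization workflow.
#'
#' @param config A [generator_config()].
#' @param n_benchmark Number of unique strings in the benchmark.
#' @param n_test Test-set size for [split_benchmark()].
#' @param seed Seed for benchmark sampling and splitting.
#' @return List with `split` (a `benchmark_split`) and `truths` (the
#'   benchmark rows' generator truths, keyed by text).
#' @export
generate_benchmark <- function(config, n_benchmark, n_test, seed = 1L) {
  gen <- generate(config)
  dd <- deduplicate(gen$responses, "exact")
  if (n_benchmark > length(dd$unique_texts)) {
    stop("configuration error: n_benchmark (", n_benchmark,
         ") exceeds unique strings (", length(dd$unique_texts), ")",
         call. = FALSE)
  }
  truth_by_id <- gen$truths[match(dd$representative[dd$unique_texts],
                                  gen$truths$response_id), ]
  keep <- sort(with_local_seed(seed,
                               sample.int(length(dd$unique_texts),
                                          n_benchmark)))
  bench <- benchmark_examples(data.frame(
    response_id = dd$unique_texts[keep],
    text = dd$unique_texts[keep],
    human_category = truth_by_id$true_category[keep],
    stringsAsFactors = FALSE), config$scheme)
  truths <- data.frame(response_id = dd$unique_texts[keep],
                       true_category = truth_by_id$true_category[keep],
                       acceptable_set = truth_by_id$acceptable_set[keep],
                       kind = truth_by_id$kind[keep],
                       stringsAsFactors = FALSE)
  list(split = split_benchmark(bench, n_test, seed = seed), truths = truths)
}

#' Expected accuracy of the matched mock backend
#'
#' Closed-form expectation of strict accuracy when a corpus from a config
#' is categorized by [mock_backend_from_config()]. Per response kind:
#' clean responses always resolve to their true category (their template
#' phrase is the only rule contained in the text); a vague response is
#' correct only when the uniformly drawn human category equals the rule's
#' fixed choice, probability `1 / set size`; a compound response resolves
#' by first containment match in scheme-index order, so the first phrase's
#' category wins with probability 1/2.
#'
#' At `level = "slot"` these combine at the configured mixture rates:
#' `1 - vague_rate * (1 - mean(1/set size)) - compound_rate / 2` — the
#' expectation for one freshly drawn latent response.
#'
#' At `level = "unique"` the expectation refers to accuracy measured over
#' the deduplicated unique strings of a corpus (the unit the benchmark
#' protocol scores). The kind mix of unique strings differs from the slot
#' rates because each kind draws from a finite text space (phrases x
#' decorations) and collisions merge: the expected number of distinct texts
#' of a kind is `sum_c (1 - (1 - rate * p_c)^pool)` over that kind's
#' decorated text space with combination probabilities `p_c`. The unique
#' level mixes the per-kind correctness by these expected distinct counts;
#' as the text space grows, it converges to the slot-level value.
#'
#' @param config A [generator_config()].
#' @param level `"slot"` or `"unique"` (see above).
#' @return Expected accuracy in `[0, 1]`.
#' @export
expected_mock_accuracy <- function(config, level = c("slot", "unique")) {
  stopifnot(inherits(config, "generator_config"))
  level <- match.arg(level)
  sizes <- if (config$vague_rate > 0) {
    vapply(lapply(config$vague_pool$acceptable_set, parse_set),
           length, integer(1))
  } else integer(0)

  if (level == "slot") {
    vague_err <- if (config$vague_rate > 0)
      config$vague_rate * (1 - mean(1 / sizes)) else 0
    return(1 - vague_err - config$compound_rate * 0.5)
  }

  pool <- config$pool_size
  combo_p <- as.vector(outer(prop.table(table(config$prefixes)),
                             prop.table(table(config$suffixes))))
  expected_distinct <- function(rate, phrase_p) {
    # P(text never drawn into the pool), per phrase x decoration combo
    probs <- rate * outer(phrase_p, combo_p)
    1 - (1 - probs)^pool
  }

  clean_rate <- 1 - config$vague_rate - config$compound_rate
  n_cat <- nrow(config$scheme)
  t_cat <- vapply(as.character(config$scheme$index),
                  function(i) length(config$templates[[i]]), integer(1))
  phrase_p_clean <- rep(1 / (n_cat * t_cat), t_cat)
  d_clean <- sum(expected_distinct(clean_rate, phrase_p_clean))
  hit_clean <- d_clean

  d_vague <- 0; hit_vague <- 0
  if (config$vague_rate > 0) {
    n_v <- nrow(config$vague_pool)
    dv <- expected_distinct(config$vague_rate, rep(1 / n_v, n_v))
    d_vague <- sum(dv)
    hit_vague <- sum(rowSums(dv) / sizes)
  }

  # compound text space (category pairs x phrases x decorations) is vast;
  # collisions there are negligible, so distinct ~= draws
  d_comp <- pool * config$compound_rate
  hit_comp <- d_comp / 2

  (hit_clean + hit_vague + hit_comp) / (d_clean + d_vague + d_comp)
}
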