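---
title: "Categorizing open-ended survey responses with LLM-assisted strategies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Categorizing open-ended survey responses with LLM-assisted strategies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survcat)
```

## The problem

Household vaccination-coverage surveys ask caregivers why a child missed
vaccination. Alongside closed option lists, the "Other, specify" channel
collects free text — tens of thousands of short French or English phrases
("voyage de la famille", "grève des infirmiers") that traditionally go
unanalyzed because manual coding is too costly. survcat implements and
evaluates machine-assisted coding of such free text into a closed,
researcher-defined category scheme, together with the economics of doing so
through a commercial LLM API.

Three design commitments run through the package:

1. **Closed-set coding.** Strategies never invent categories; they return
   the index of one category from a fixed numbered scheme. This keeps
   outputs aligned with policy-relevant themes and makes accuracy
   well-defined.
2. **Unique-string workflow.** Free-text answers repeat heavily, so each
   distinct normalized string is categorized once and the label is
   propagated to all duplicates (`deduplicate()` /
   `expand_assignments()`). API cost then scales with unique strings, not
   responses.
3. **Offline determinism.** Every strategy runs end-to-end against
   deterministic mock backends with *knowable* expected accuracy, so the
   whole pipeline is testable without network access or nondeterministic
   model output. Completion temperature is fixed at 0 throughout, because
   categorical coding wants run-to-run consistency, not sampling
   diversity.

## The categorization strategies

All five strategies share one contract: given a response text and a scheme,
produce a `category_index` with a parse status.

- **Zero-shot** (`zero_shot()`): one completion call per unique string; the
  prompt shows the response and the numbered category list and asks for
  "the number associated with the chosen label, nothing else".
- **Few-shot** (`few_shot()`): the same, with `k` labeled example pairs
  embedded in every prompt. Example selection for `k` below the full set is
  a seeded uniform sample without replacement, rendered in the examples'
  original order, so a seed pins the exact prompt bytes. Prompt token
  counts grow strictly with `k`, which drives the cost trade-off.
- **Chain-of-thought** (`chain_of_thought()`): asks for step-by-step
  reasoning ending in `ANSWER: <number>`; the reply is parsed from the last
  marker. Completions are multi-token, which raises output-token cost.
- **Cluster-then-label** (`cluster_label()`): embed every unique string,
  cluster the vectors (k-means, Gaussian mixture, or Ward hierarchical
  clustering), and issue exactly **one** completion per cluster, showing up
  to 25 sampled member texts semicolon-separated. The parsed category
  propagates to all members. Cost scales with the number of clusters; at
  `k` equal to the number of unique texts the strategy provably coincides
  with zero-shot for any backend that depends only on the presented text
  (the package tests this label-for-label).
- **Fine-tune export** (`export_finetune_dataset()`): writes training pairs
  as chat-format JSON-lines (system/user/assistant messages, assistant =
  bare index) for a provider fine-tuning job. Running the remote job is out
  of scope; the value modeled here is that a tuned model no longer needs
  embedded examples, making its per-call cost equal to zero-shot's while
  retaining few-shot-like accuracy.

Answer parsing is deliberately strict: a bare-index reply must be a single
in-range integer after whitespace trimming; reasoning replies must carry
the marker. Anything else yields `parse_status = "failed"` with a null
index, and failed parses count as *discordant* in every accuracy
computation — the conservative choice, since an unparseable reply codes
nothing.

## The evaluation protocol

A benchmark pairs responses with a human coder's category.
`split_benchmark()` draws a seeded test set without replacement (the
canonical configuration is 999 examples split 799 train / 200 test).
`accuracy()` is strict concordance with the human code.

Strict concordance understates usefulness when responses are vague ("long
trajet" could mean the site is too far *or* the family travelled) or
compound (two reasons in one answer). `accuracy_ceiling()` therefore
re-scores after a human review of all discordant pairs
(`export_discordances()` writes the review worksheet): pairs judged
`acceptable` join the numerator. Two safeguards keep the ceiling honest: a
verdict on a concordant pair is a validation error, and unreviewed
discordances count as not acceptable, so partial review can only lower the
ceiling. The ceiling consequently dominates accuracy for every verdict
configuration, strictly when at least one verdict is acceptable — both
property-tested.

The test-set size rests on the usual normal-approximation power
calculation: `margin_of_error(p, n, z) = z * sqrt(p(1-p)/n)`, giving 0.0495
at p = 0.85, n = 200 — i.e. a ~5% margin at 95% confidence —
and `required_sample_size(0.85, 0.05)` = 196. With 43 categories on a
200-example test set, per-category estimates are underpowered almost
everywhere; `per_category_accuracy()` computes them but flags any category
below a configurable minimum n (default 10).

## The cost model

Costs are pure functions of token counts and four per-million prices
(input, output, embedding, training). The defaults are the GPT-4o list
prices of September 2024: US$2.5/M input, US$10/M output, US$0.020/M
embedding, US$25/M training. A campaign total is
`upfront + per_call * n_calls` with the per-call cost kept at full
precision; rounding (4 decimals per call, 2 for totals) happens only at
display. This discipline is observable: 9865 zero-shot calls at a true
0.001005 per call cost US$9.91, while the display-rounded 0.0010 would give
9.87. `default_method_specs()` ships the eight benchmarked methods of the
DRC campaign with their observed token averages; `measured_cost()` sums a
real run log and equals the projection under homogeneous calls.

Two documented quirks: the fine-tuned campaign line uses its printed
upfront US$13 plus base inference pricing, and the embedding upfront
(US$0.0003) is config-supplied rather than derived, since no embedding
token count is published for it. The campaign `n_calls` defaults to the
unique-string count of the *collated* dataset (9865), which exceeds the
8807 unique strings of the benchmark-era subset; both counts appear in the
shipped specs' documentation and either can be configured.

## The synthetic generator and the mock backends

`generate()` emulates the *structure* of the real free-text channel so the
pipeline is testable offline with known truth:

- **Latent phrase pool.** Each pool slot is clean (one category template
  phrase), vague (a phrase ambiguous between ≥2 categories, the acceptable
  set recorded), or compound (two categories' phrases joined), at
  configured rates. Phrases are short French/English noun phrases per
  category, wrapped in neutral prefix/suffix decorations that add phrasing
  variety without touching category semantics. Slots with identical text
  are merged.
- **Heavy-tailed duplication.** Each distinct text gets a Pareto
  popularity weight (`U^(-1/duplication_exponent)`); responses are drawn
  from that popularity distribution, so common answers recur hundreds of
  times. Smaller exponents mean heavier tails and fewer unique strings —
  the package tests this monotonicity. The defaults (exponent 2, pool 3×n)
  were chosen to approximate the published duplication structure of the
  DRC data (top-string share about 1.6% versus the reported 2.6%; unique
  fraction about 0.36 versus 0.49, bounded by the finite template ×
  decoration text space). The generator emulates duplication, ambiguity
  and bilingual register; it does **not** model spelling noise, dialect,
  interviewer effects, or real linguistic variation — passing synthetic
  tests shows pipeline correctness, not real-data accuracy.
- **Matched mock backends.** `mock_backend_from_config()` compiles the
  same templates into an ordered keyword-rule completion backend (exact
  phrase match first, then first containment match in scheme-index order,
  then a declared fallback category); `mock_embedding_backend()` hashes
  character trigrams onto a unit sphere (default dimension 256, standing
  in for 1536-dimensional provider embeddings). Both are bitwise
  deterministic.

Because rules and corpus come from the same templates, expected accuracy is
analytic (`expected_mock_accuracy()`): clean responses are always correct;
a vague response is correct with probability 1/|acceptable set| (the rule
picks a fixed element, the simulated human coder a uniform one); a
compound resolves to the lower-indexed category, correct with probability
1/2. At slot level this gives
`1 - vague_rate*(1 - mean(1/set size)) - compound_rate/2`. Accuracy is
*measured* over unique strings (the unit the benchmark scores), whose kind
mix shifts slightly because each kind draws from a finite text space and
collisions merge — the vague space (8 phrases × decorations) saturates
before the clean space does. The `level = "unique"` variant corrects for
this with the exact expected-distinct-count formula
`sum_c (1 - (1 - rate*p_c)^pool)` per kind; tests verify observed accuracy
within 3 binomial standard errors of it, and verify the formula itself
against truth-only simulation across seeds.

## Numerical and design choices

- **Normalization.** "Unique string" defaults to exact match after Unicode
  NFC and whitespace trim (conservative), with `trim_casefold` optional.
  All IO is UTF-8; French diacritics round-trip.
- **Clustering details.** k-means uses 5 restarts under a local seed; the
  Gaussian mixture tries full covariance (VVV), then diagonal (VVI), then
  spherical (EII) on singular fits; hierarchical is Ward.D2 on Euclidean
  distance. Duplicate embedding vectors are clustered once and mapped
  back, empty clusters are dropped and ids renumbered densely from 1, and
  `k = n` short-circuits to singleton clusters. Cluster ids are 1-based as
  is idiomatic in R.
- **Seeding.** Every stochastic step (example selection, exemplar
  sampling, splits, generation, clustering) takes an explicit seed and
  restores the caller's RNG state, so library calls never perturb user
  code.
- **Caching.** The response cache keys on backend id plus a string hash of
  the request but stores the full request alongside, so a hash collision
  degrades to a cache miss, never a wrong reply. Corrupted persisted
  entries are skipped with a warning.
- **Weights** are carried on responses and used only by the reporting
  aggregations; categorization ignores them. When grouping by round, the
  2020 round is excluded by default (its question format and sampling are
  not comparable); an argument re-includes it.
- **Problem sizes in tests.** The shipped tests and the acceptance script
  use corpora of 2,000–20,000 responses (≈1,300–6,900 unique strings),
  200-draw property loops, and clustering at k = 200 over ≈6,900 unique
  texts — sizes chosen to exercise every contract at full fidelity while
  keeping the default check fast.

## Known limitations

- Real accuracies of GPT-class models are not reproducible offline; the
  mock-backend results validate the pipeline's bookkeeping, not model
  quality.
- The cluster-labeling reply is a single category per cluster; impure
  clusters mislabel their minority members by construction. The remedy is
  more clusters, which is exactly the cost trade-off the package models.
- The shipped 43-category scheme is a best-effort default for the DRC
  vaccination-barrier setting; exact label strings are configuration.
- The remote backend adapter is a thin shim with a fixed 3-attempt retry;
  no offline functionality depends on it, and no test exercises a live
  API.
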