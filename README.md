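# survcat

LLM-assisted categorization of open-ended survey responses into a closed,
researcher-defined category scheme — with the benchmark protocol and
token-cost model needed to decide *which* strategy to pay for.

## The problem

Vaccination-coverage household surveys (such as the DRC's Enquête de
Couverture Vaccinale) ask caregivers why a child missed vaccination. The
"Other, specify" channel collects tens of thousands of short free-text
answers in French and English that usually go unanalyzed: manual coding at
that scale is prohibitively expensive. survcat implements five
machine-assisted coding strategies against a fixed numbered category
scheme, evaluates them against a human-coded benchmark, and projects what a
full categorization campaign costs through a commercial LLM API.

**Strategies** (all return a category index from the scheme):

| strategy | calls | supervision |
|---|---|---|
| cluster-then-label | one per *cluster* | none |
| zero-shot | one per unique string | none |
| chain-of-thought | one per unique string | none |
| few-shot (k examples) | one per unique string | k labeled pairs |
| fine-tune export | one per unique string after training | full training set |

**Evaluation**: strict accuracy (concordance with the human code, failed
parses discordant), plus an adjudicated *accuracy ceiling* that credits
discordant model choices a reviewer judges acceptable — vague responses
like "long trajet" legitimately fit more than one category. The test-set
size rests on the proportion margin of error `z·sqrt(p(1−p)/n)`: 0.0495 at
p = 0.85, n = 200, i.e. a ~5% margin at 95% confidence.

**Cost model**: campaign cost = upfront + unrounded per-call cost × calls,
with per-call cost linear in prompt/completion tokens at per-million-token
prices. Rounding happens only at display — 9865 calls at a true US$0.001005
cost US$9.91, not 0.0010 × 9865 = 9.87.

Everything runs fully offline against deterministic mock completion and
embedding backends whose expected accuracy on the shipped synthetic
generator is known in closed form.

## Worked example

```r
library(survcat)

cfg <- generator_config(n_responses = 5000, vague_rate = 0.1,
                        compound_rate = 0.05, seed = 42)
gen <- generate(cfg)                      # synthetic corpus + ground truth
dd  <- deduplicate(gen$responses)
dd
#> <dedup_table> 5000 responses -> 2915 unique strings (exact normalization)
#>   c'est que child born at home vraiment (N=35)
#>   souvent session at the wrong time pour le moment (N=25)
#>   ...

bm <- generate_benchmark(cfg, n_benchmark = 999, n_test = 200, seed = 42)
bm$split
#> <benchmark_split> 799 train / 200 test (seed 42)

be  <- mock_backend_from_config(cfg)      # deterministic rule backend
got <- zero_shot(bm$split$test$text, cfg$scheme, be)
accuracy(got, bm$split$test)
#> [1] 0.915
```

The 8.5% shortfall is exactly the generator's ambiguity: vague responses
where the simulated human coder legitimately picked the other acceptable
category. Adjudicating the discordances with the recorded acceptable sets
closes the gap:

```r
ws <- export_discordances(got, bm$split$test)   # review worksheet
# ... mark verdicts acceptable/not_acceptable ...
accuracy_ceiling(got, bm$split$test, ws)
#> [1] 1
```

Campaign economics for the eight benchmarked methods, from their observed
token counts at US$2.5/M input and US$10/M output:

```r
cost_table(default_method_specs())
#>              method n_calls ... per_call  total
#> 1 cluster_label_200     200 ...   0.0015   0.30
#> 2         zero_shot    9865 ...   0.0010   9.91
#> 3  chain_of_thought    9865 ...   0.0017  16.77
#> 4       few_shot_20    9865 ...   0.0016  15.41
#> 5       few_shot_50    9865 ...   0.0024  23.36
#> 6      few_shot_400    9865 ...   0.0112 110.73
#> 7      few_shot_799    9865 ...   0.0212 208.84
#> 8    fine_tuned_799    9865 ...   0.0010  22.91
```

Cluster-then-label is ~30× cheaper than zero-shot (200 calls instead of
9865); the fine-tuned model matches few-shot-799 per-call prompts at ~1/9
of its campaign cost after a US$13 training investment.

A command-line wrapper covers the same workflow
(`simulate`, `categorize`, `cluster-label`, `evaluate`,
`adjudicate-template`, `cost`, `aggregate`, `export-finetune`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "survcat.R", package = "survcat"))')" \
  simulate --n 1000 --seed 7 --out-responses resp.csv --out-truths truths.csv
```

Real LLM APIs plug in behind the same backend contract via
`http_backend()` (with `cached_backend()` to avoid paying twice for
identical prompts); no shipped functionality depends on network access.

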