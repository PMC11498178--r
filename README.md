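# phenomark

Extraction and normalization of abnormal key findings from short
clinical observation texts to [Human Phenotype Ontology
(HPO)](https://hpo.jax.org/) concepts, using a large language model as
the extractor and deterministic rule-based post-processing for span
recovery and concept normalization.

## The problem

Dysmorphology physical examinations are recorded as short
organ-system observations — `EYES: partial synophrys, long lashes,
horizontal slant` — and clinical genetics workflows need each
abnormal finding mapped to a unique HPO concept id together with its
character-level boundaries (possibly discontinuous, as in
`MOUTH: [normal] lips, [tongue], high palate` where one normal-tongue
finding spans two segments). Generative models extract such findings
well but hallucinate ontology identifiers and character offsets, so
this package asks the model for neither. Instead it requests, per
finding:

* the **preferred HPO term** — a natural-language stand-in for the
  concept id, later resolved by dictionary matching; and
* the **marked text** — the observation repeated verbatim with the
  entity wrapped in square brackets, from which exact offsets are
  recovered by parsing: the span starts where a `[` opens and ends
  where its `]` closes, one bracket pair per segment of a
  discontinuous mention. Input text is pre-processed so square
  brackets are reserved for this codec.

Normalization is then a two-step dictionary lookup over stemmed,
case-folded keys built from HPO preferred terms, HPO synonyms, and
annotated training surfaces: first the *observed term* (the bracketed
mention as written) is looked up; only if that misses is the model's
*preferred term* suggestion tried; if both miss, no concept is
recorded. Disabling the second step trades recall for precision.
Rows whose unmarked text does not match the input (a model "fixing" a
typo, or appending a stray character) are discarded rather than
realigned, so boundary errors never enter the output.

The package also implements the surrounding machinery: corpus and
ontology I/O, dataset curation (span/concept inconsistency detection,
concept merges, normal-finding removal), a three-step per-query
few-shot example selector (15 most similar annotated observations +
5 curated "tricky" examples for the query's organ system + 5 most
similar negative examples, shuffled), fine-tuning dataset export in
chat JSON Lines, deterministic mock backends for fully offline runs,
micro-averaged evaluation under the normalization-only / overlapping /
strict settings, and a synthetic corpus generator that reproduces the
structural statistics of real dysmorphology datasets (12% empty
observations, 14% discontinuous spans, ~1.5 concepts per observation,
20 organ systems).

## Worked example

```r
library(phenomark)

## span recovery from marked text (0-based, end-exclusive offsets)
rec <- recover_spans("MOUTH: [normal] lips, [tongue], high palate")
rec$spans
#>      start end
#> [1,]     7  13
#> [2,]    20  26
serialize_spans(rec$spans)
#> [1] "7–13, 20–26"

## fully offline end-to-end run on a synthetic corpus
syn  <- generate_corpus(synthetic_config(seed = 1, n_observations = 200))
cur  <- curate_corpus(list(observations = syn$observations,
                           annotations  = syn$annotations))
dict <- build_dictionary(syn$ontology, training_surfaces(cur))
pool <- build_example_pool(cur, syn$ontology)
run  <- run_pipeline(syn$observations,
                     mock_replay_backend(build_gold_index(cur, syn$ontology)),
                     dict, mode = "fewshot", pool = pool,
                     registry = syn$registry, gold = cur$annotations)
run
#> <phenomark run> fewshot mode, 200 observation(s), 258 prediction(s), 0 failure(s)
#> <normalization_only> TP=258 FP=0 FN=0  P=1.0000 R=1.0000 F1=1.0000
#> <overlapping> TP=258 FP=0 FN=0  P=1.0000 R=1.0000 F1=1.0000
#> <strict> TP=258 FP=0 FN=0  P=1.0000 R=1.0000 F1=1.0000
```

The 258 predictions are the corpus' 258 curated abnormal findings:
with a faithful (replayed) model response and a dictionary covering
every gold surface, the pipeline is lossless, which is the
correctness baseline every component is tested against. Each
prediction row records the suggested preferred term, the observed
term recovered from the brackets, the resolved id and which
normalization step resolved it:

```
  observation_id         preferred_term          observed_term     hpo_id norm_step
1       OBS00001    upslanted cheekbone    ascending cheekbone HP:9349667  observed
2       OBS00001       drooping eyebrow       drooping eyebrow HP:9291804  observed
```

(`ascending cheekbone` is a paraphrased surface: it resolves at the
observed step here because the dictionary includes training surfaces;
against an ontology-only dictionary it would need the preferred-term
step.)

A command-line front end wrapping these functions ships at
`inst/cli/phenomark.R` with subcommands `synth`, `curate`,
`build-dict`, `export-finetune`, `run` and `evaluate`.

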