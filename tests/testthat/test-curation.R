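# corpus with the documented inconsistency patterns: one concept
# annotated with and without a leading modifier, and one surface form
# split across two close-match concepts
inconsistent_corpus <- function() {
  obs <- data.frame(
    id = c("o1", "o2", "o3", "o4", "o5"),
    text = c("EYES: Prominent infraorbital creases",
             "EYES: infraorbital creases noted",
             "NECK: Excess nuchal skin",
             "NECK: excess nuchal skin and",
             "NECK: excess nuchal skin seen"),
    stringsAsFactors = FALSE)
  obs$organ_header <- vapply(obs$text, organ_header, character(1),
                             USE.NAMES = FALSE)
  ann <- data.frame(
    observation_id = obs$id,
    hpo_id = c("HP:0100876", "HP:0100876", "HP:0005989", "HP:0000474",
               "HP:0000474"),
    polarity = "abnormal", stringsAsFactors = FALSE)
  ann$spans <- list(span_set(6, 36),   # "Prominent infraorbital creases"
                    span_set(6, 26),   # "infraorbital creases"
                    span_set(6, 24),   # "Excess nuchal skin"
                    span_set(6, 24),   # "excess nuchal skin"
                    span_set(6, 24))
  list(observations = obs, annotations = ann)
}

test_that("span inconsistencies are modifier-edge differences only", {
  corpus <- inconsistent_corpus()
  reports <- detect_span_inconsistencies(corpus$annotations,
                                         corpus$observations)
  expect_length(reports, 1)
  expect_equal(reports[[1]]$kind, "span")
  expect_equal(reports[[1]]$key, "HP:0100876")
  expect_setequal(reports[[1]]$variants$variant,
                  c("Prominent infraorbital creases",
                    "infraorbital creases"))

  # surfaces differing by content words are not flagged
  obs <- data.frame(id = c("a", "b"),
                    text = c("FACE: long face", "FACE: elongated face"),
                    organ_header = "FACE", stringsAsFactors = FALSE)
  ann <- data.frame(observation_id = c("a", "b"), hpo_id = "HP:0000276",
                    polarity = "abnormal", stringsAsFactors = FALSE)
  ann$spans <- list(span_set(6, 15), span_set(6, 20))
  expect_length(detect_span_inconsistencies(ann, obs), 0)

  # a single consistent surface form yields no report
  one <- corpus
  one$annotations <- one$annotations[3, , drop = FALSE]
  expect_length(detect_span_inconsistencies(one$annotations,
                                            one$observations), 0)
})

test_that("concept inconsistencies group case-folded surfaces by id", {
  corpus <- inconsistent_corpus()
  reports <- detect_concept_inconsistencies(corpus$annotations,
                                            corpus$observations)
  expect_length(reports, 1)
  expect_equal(reports[[1]]$key, "excess nuchal skin")
  expect_setequal(reports[[1]]$variants$variant,
                  c("HP:0005989", "HP:0000474"))
  # descending count order
  expect_equal(reports[[1]]$variants$variant[1], "HP:0000474")
  expect_equal(reports[[1]]$variants$count, c(2, 1))
})

test_that("majority resolution rewrites to the most frequent concept", {
  corpus <- inconsistent_corpus()
  reports <- detect_concept_inconsistencies(corpus$annotations,
                                            corpus$observations)
  fixed <- resolve_concept_inconsistencies(corpus$annotations,
                                           corpus$observations, reports)
  expect_equal(fixed$hpo_id[3:5], rep("HP:0000474", 3))
  expect_length(attr(fixed, "ties"), 0)
  # after resolution, detection is empty
  expect_length(detect_concept_inconsistencies(fixed,
                                               corpus$observations), 0)

  # a tie is flagged and left unchanged
  tied <- corpus
  tied$annotations <- tied$annotations[3:4, , drop = FALSE]
  reports2 <- detect_concept_inconsistencies(tied$annotations,
                                             tied$observations)
  out <- resolve_concept_inconsistencies(tied$annotations,
                                         tied$observations, reports2)
  expect_equal(attr(out, "ties"), "excess nuchal skin")
  expect_equal(out$hpo_id, c("HP:0005989", "HP:0000474"))

  # manual map overrides regardless of counts
  manual <- resolve_concept_inconsistencies(
    corpus$annotations, corpus$observations, reports,
    policy = "manual_map",
    manual_map = c("excess nuchal skin" = "HP:0005989"))
  expect_equal(manual$hpo_id[3:5], rep("HP:0005989", 3))
})

test_that("merge rules union co-occurring concepts into one", {
  obs <- data.frame(id = "e1",
                    text = "EARS: low-set, posteriorly rotated ears",
                    organ_header = "EARS", stringsAsFactors = FALSE)
  ann <- data.frame(observation_id = c("e1", "e1"),
                    hpo_id = c("HP:0000369", "HP:0000358"),
                    polarity = "abnormal", stringsAsFactors = FALSE)
  ann$spans <- list(span_set(6, 13), span_set(15, 39))
  rule <- merge_rule(c("HP:0000369", "HP:0000358"), "HP:0000368")
  merged <- apply_merge_rules(ann, list(rule))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$hpo_id, "HP:0000368")
  expect_equal(unclass(merged$spans[[1]]),
               unclass(span_set(c(6, 15), c(13, 39))))

  # only one source present: no merge
  solo <- ann[1, , drop = FALSE]
  expect_equal(apply_merge_rules(solo, list(rule))$hpo_id,
               "HP:0000369")

  # touching segments coalesce after union
  ann2 <- ann
  ann2$spans <- list(span_set(6, 15), span_set(15, 39))
  merged2 <- apply_merge_rules(ann2, list(rule))
  expect_equal(unclass(merged2$spans[[1]]), unclass(span_set(6, 39)))

  expect_error(merge_rule("HP:0000369", "HP:0000368"))
})

test_that("normal findings are removed and abnormal kept", {
  corpus <- read_annotated_corpus(table1_corpus_tsv())
  kept <- remove_normal_findings(corpus$annotations)
  expect_equal(nrow(kept), 3)
  expect_false(any(c("HP:0000159", "HP:0000157") %in% kept$hpo_id))
  expect_true("HP:0000218" %in% kept$hpo_id)

  # all-abnormal input unchanged
  expect_equal(nrow(remove_normal_findings(kept)), 3)

  # generator bookkeeping: output shrinks by exactly the normal count
  syn <- generate_corpus(synthetic_config(seed = 5,
                                          n_observations = 80))
  n_normal <- sum(syn$annotations$polarity == "normal")
  expect_equal(n_normal, syn$stats$n_normal)
  expect_equal(nrow(remove_normal_findings(syn$annotations)),
               nrow(syn$annotations) - n_normal)
})

test_that("the full curation pass is idempotent and text-preserving", {
  syn <- generate_corpus(synthetic_config(seed = 9,
                                          n_observations = 80))
  corpus <- list(observations = syn$observations,
                 annotations = syn$annotations)
  once <- curate_corpus(corpus)
  twice <- curate_corpus(once)
  expect_identical(once$annotations, twice$annotations)
  expect_identical(once$observations, corpus$observations)
})
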