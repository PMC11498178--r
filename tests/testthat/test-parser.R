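test_that("span recovery reproduces the printed dataset offsets", {
  r1 <- recover_spans(
    "EYES: partial [synophrys], long lashes, horizontal slant")
  expect_equal(unclass(r1$spans), unclass(span_set(14, 23)))
  expect_equal(r1$unmarked,
               "EYES: partial synophrys, long lashes, horizontal slant")

  r2 <- recover_spans("MOUTH: normal lips, tongue, [high palate]")
  expect_equal(unclass(r2$spans), unclass(span_set(28, 39)))

  r3 <- recover_spans("MOUTH: [normal] lips, [tongue], high palate")
  expect_equal(unclass(r3$spans),
               unclass(span_set(c(7, 20), c(13, 26))))

  r4 <- recover_spans("FACE: [elongated face]; flattened midface")
  expect_equal(r4$unmarked, "FACE: elongated face; flattened midface")
  expect_equal(unclass(r4$spans), unclass(span_set(6, 20)))
})

test_that("unbalanced and nested brackets are rejected", {
  expect_error(recover_spans("EYES: [redness"),
               class = "phenomark_unbalanced")
  expect_error(recover_spans("EYES: redness]"),
               class = "phenomark_unbalanced")
  expect_error(recover_spans("EYES: [[redness]]"),
               class = "phenomark_unbalanced")
  expect_error(recover_spans("EYES: ]redness["),
               class = "phenomark_unbalanced")
})

test_that("the marked-text codec round-trips on random inputs", {
  set.seed(402)
  for (i in 1:300) {
    case <- random_marked_case()
    marked <- mark_text(case$text, case$spans)
    rec <- recover_spans(marked)
    expect_identical(rec$unmarked, case$text)
    expect_equal(unclass(rec$spans), unclass(case$spans))
  }
})

test_that("entity tables parse with discard rules applied", {
  user <- "FACE: elongated face; flattened midface"
  assistant <- paste(
    "| HPO Preferred Term | Marked Observation |",
    "| long face | FACE: [elongated face]; flattened midface |",
    "| midface retrusion | FACE: elongated face; [flattened midface] |",
    sep = "\n")
  preds <- parse_entity_table(assistant, user)
  expect_equal(nrow(preds), 2)
  expect_equal(preds$preferred_term, c("long face", "midface retrusion"))
  expect_equal(unclass(preds$spans[[1]]), unclass(span_set(6, 20)))
  expect_equal(unclass(preds$spans[[2]]), unclass(span_set(22, 39)))
  expect_equal(preds$observed_term,
               c("elongated face", "flattened midface"))

  # header-only response: no entities
  expect_equal(nrow(parse_entity_table(
    "| HPO Preferred Term | Marked Observation |", user)), 0)

  # markdown separator rows and missing outer pipes are tolerated
  md <- paste("| HPO Preferred Term | Marked Observation |",
              "| --- | --- |",
              "long face | FACE: [elongated face]; flattened midface",
              sep = "\n")
  expect_equal(nrow(parse_entity_table(md, user)), 1)

  # no table at all
  expect_warning(none <- parse_entity_table("I cannot help.", user),
                 "no recognizable")
  expect_equal(nrow(none), 0)
})

test_that("model-edited text is discarded as a mismatch, not repaired", {
  user <- "HEAD: +cephalohematoma"
  resp <- paste("| HPO Preferred Term | Marked Observation |",
                "| cephalohematoma | HEAD: +[cephalohematoma]+ |",
                sep = "\n")
  preds <- parse_entity_table(resp, user)
  expect_equal(preds$discard_reason, "text_mismatch")
  expect_equal(nrow(preds$spans[[1]]), 0)

  # a row that marks nothing is flagged, not silently dropped
  resp2 <- paste("| HPO Preferred Term | Marked Observation |",
                 "| cephalohematoma | HEAD: +cephalohematoma |",
                 sep = "\n")
  expect_equal(parse_entity_table(resp2, user)$discard_reason,
               "no_brackets")

  # unbalanced brackets in one row do not poison the others
  resp3 <- paste("| HPO Preferred Term | Marked Observation |",
                 "| cephalohematoma | HEAD: +[cephalohematoma |",
                 "| cephalohematoma | HEAD: +[cephalohematoma] |",
                 sep = "\n")
  preds3 <- parse_entity_table(resp3, user)
  expect_equal(preds3$discard_reason,
               c("unbalanced_brackets", "none"))
})

test_that("whitespace-only drift is tolerated, real edits are not", {
  user <- "EYES: partial synophrys"
  drift <- paste("| HPO Preferred Term | Marked Observation |",
                 "| synophrys | EYES:  partial [synophrys] |",
                 sep = "\n")
  preds <- parse_entity_table(drift, user)
  expect_equal(preds$discard_reason, "none")
  expect_equal(unclass(preds$spans[[1]]), unclass(span_set(14, 23)))

  typo <- paste("| HPO Preferred Term | Marked Observation |",
                "| synophrys | EYES: parzial [synophrys] |",
                sep = "\n")
  expect_equal(parse_entity_table(typo, user)$discard_reason,
               "text_mismatch")
})

test_that("non-discarded spans always index the original text", {
  sm <- small_synthetic()
  for (txt in names(sm$gold_index)) {
    preds <- parse_entity_table(sm$gold_index[[txt]], txt)
    for (i in seq_len(nrow(preds))) {
      expect_equal(preds$discard_reason[i], "none")
      expect_true(all(preds$spans[[i]][, "end"] <= nchar(txt)))
      expect_equal(span_surface(preds$spans[[i]], txt),
                   preds$observed_term[i])
    }
  }
})
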