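test_that("text similarity is mean-vector cosine", {
  expect_equal(text_similarity("long face noted", "long face noted"), 1,
               tolerance = 1e-9)
  expect_equal(text_similarity("", "anything"), 0)
  expect_equal(text_similarity("a b", ""), 0)

  # hand-built embedder with known vectors: cosine computed by hand
  vecs <- list(aa = c(1, 0), bb = c(0, 1), cc = c(1, 1))
  emb <- function(tokens) do.call(rbind, vecs[tokens])
  expect_equal(text_similarity("aa", "bb", emb), 0)
  # mean("aa","bb") = (0.5, 0.5); cos with cc = 1
  expect_equal(text_similarity("aa bb", "cc", emb), 1, tolerance = 1e-12)
  # cos((1,0),(0.5,0.5)) = 1/sqrt(2)
  expect_equal(text_similarity("aa", "aa bb", emb), 1 / sqrt(2),
               tolerance = 1e-12)

  # the default embedder is deterministic across calls
  e1 <- hash_embedder()
  e2 <- hash_embedder()
  expect_identical(e1("synophrys"), e2("synophrys"))
})

test_that("selection returns the budgeted 15/5/5 composition", {
  sm <- small_synthetic(seed = 42, n = 120)
  query <- sm$syn$observations$text[1]
  sel <- select_examples(preprocess_text(query), sm$pool,
                         sm$syn$registry)
  expect_length(sel, 25)
  cats <- vapply(sel, `[[`, character(1), "category")
  expect_equal(sum(cats == "similar_positive"), 15)
  expect_equal(sum(cats == "tricky"), 5)
  expect_equal(sum(cats == "negative"), 5)

  # positives contain >= 1 entity, negatives none
  for (ex in sel) {
    if (ex$category == "negative") {
      expect_equal(nrow(parse_entity_table(ex$assistant, ex$user)), 0)
    }
    if (ex$category == "similar_positive") {
      expect_gt(nrow(parse_entity_table(ex$assistant, ex$user)), 0)
    }
  }
})

test_that("selection is deterministic and shuffle is a permutation", {
  sm <- small_synthetic(seed = 42, n = 120)
  query <- preprocess_text(sm$syn$observations$text[2])
  s1 <- select_examples(query, sm$pool, sm$syn$registry)
  s2 <- select_examples(query, sm$pool, sm$syn$registry)
  expect_identical(s1, s2)

  # different shuffle seed: same multiset, (almost surely) new order
  s3 <- select_examples(query, sm$pool, sm$syn$registry,
                        selection_config(shuffle_seed = 99L))
  key <- function(s) sort(vapply(s, function(e) {
    paste(e$category, e$user)
  }, character(1)))
  expect_equal(key(s1), key(s3))
})

test_that("step-1 similarity selection is top-k against a brute oracle", {
  sm <- small_synthetic(seed = 13, n = 80)
  emb <- hash_embedder()
  query <- preprocess_text(sm$syn$observations$text[3])
  sel <- select_examples(query, sm$pool, sm$syn$registry,
                         embedder = emb)
  chosen <- vapply(sel[vapply(sel, `[[`, character(1),
                              "category") == "similar_positive"],
                   `[[`, character(1), "source_id")
  sims <- vapply(sm$pool, function(p) {
    text_similarity(query, p$user, emb)
  }, numeric(1))
  pos <- vapply(sm$pool, function(p) p$n_entities >= 1, logical(1))
  ids <- vapply(sm$pool, `[[`, character(1), "source_id")
  worst_chosen <- min(sims[ids %in% chosen])
  best_unchosen <- suppressWarnings(
    max(sims[pos & !(ids %in% chosen)]))
  expect_gte(worst_chosen, best_unchosen)
})

test_that("shortfalls take what exists and unregistered headers fall back", {
  ont <- tiny_ontology()
  obs <- data.frame(
    id = c("p1", "p2", "p3", "n1"),
    text = c("EYES: synophrys", "MOUTH: high palate",
             "MOUTH: wide mouth", "SKIN: clear"),
    stringsAsFactors = FALSE)
  obs$organ_header <- vapply(obs$text, organ_header, character(1),
                             USE.NAMES = FALSE)
  ann <- data.frame(observation_id = c("p1", "p2", "p3"),
                    hpo_id = c("HP:0000664", "HP:0000218", "HP:0000154"),
                    polarity = "abnormal", stringsAsFactors = FALSE)
  ann$spans <- list(span_set(6, 15), span_set(7, 18), span_set(7, 17))
  pool <- build_example_pool(list(observations = obs,
                                  annotations = ann), ont)
  registry <- build_tricky_registry("EYES", ont, seed = 2)

  # 3 positives + 5 tricky + 1 negative = 9
  expect_message(sel <- select_examples("EYES: redness", pool, registry),
                 "shortfall")
  expect_length(sel, 9)

  # unregistered header with no default: only positives and negatives
  expect_message(sel2 <- select_examples("NOSE: bulbous", pool,
                                         registry), "shortfall")
  cats2 <- vapply(sel2, `[[`, character(1), "category")
  expect_equal(sum(cats2 == "tricky"), 0)

  # with a default set, the fallback fills the tricky slots
  sel3 <- suppressMessages(
    select_examples("NOSE: bulbous", pool, registry,
                    default_tricky = registry[["EYES"]]))
  expect_equal(sum(vapply(sel3, `[[`, character(1),
                          "category") == "tricky"), 5)

  expect_error(select_examples("EYES: redness", list(), registry),
               "empty")
})

test_that("tricky registries round-trip through TSV", {
  ont <- tiny_ontology()
  registry <- build_tricky_registry(c("EYES", "MOUTH"), ont, seed = 4)
  rows <- list()
  for (h in names(registry)) {
    for (ex in registry[[h]]) {
      preds <- parse_entity_table(ex$assistant, ex$user)
      marked <- vapply(preds$spans, function(s) mark_text(ex$user, s),
                       character(1))
      rows[[length(rows) + 1]] <- data.frame(
        organ_header = h, preferred_term = preds$preferred_term,
        marked_text = marked, stringsAsFactors = FALSE)
    }
  }
  path <- tempfile(fileext = ".tsv")
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  back <- read_tricky_registry(path)
  expect_setequal(names(back), c("EYES", "MOUTH"))
  expect_length(back[["EYES"]], 5)
  expect_equal(back[["EYES"]][[2]]$user, registry[["EYES"]][[2]]$user)
})
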