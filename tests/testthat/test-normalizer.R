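test_that("the stemmer matches the published sample vocabulary", {
  pairs <- c(caresses = "caress", ponies = "poni", ties = "ti",
             caress = "caress", cats = "cat", feed = "feed",
             agreed = "agre", plastered = "plaster", bled = "bled",
             motoring = "motor", sing = "sing", itemization = "item",
             sensational = "sensat", traditional = "tradit",
             reference = "refer", colonizer = "colon",
             plotted = "plot", flattened = "flatten",
             flatten = "flatten", creases = "creas", lashes = "lash")
  expect_equal(porter_stem(names(pairs)), unname(pairs))
})

test_that("key normalization folds case, punctuation and inflection", {
  expect_equal(normalize_key("Excess nuchal skin"),
               normalize_key("excess nuchal skin"))
  expect_equal(normalize_key("flattened midface"),
               normalize_key("flatten midface"))
  expect_equal(normalize_key("  high   palate. "),
               normalize_key("high palate"))
  expect_equal(normalize_key(""), "")
  expect_equal(normalize_key("Long Lashes"), normalize_key("long lash"))
  # stemming is injectable
  expect_equal(normalize_key("flattened", stemmer = identity),
               "flattened")
})

test_that("dictionaries apply exclusions and source precedence", {
  ont <- tiny_ontology()
  d <- build_dictionary(ont)
  expect_equal(unname(d$lookup[normalize_key("excess nuchal skin")]),
               "HP:0000474")
  expect_equal(unname(d$lookup[normalize_key("redundant neck skin")]),
               "HP:0005989")

  # excluded ids vanish from every source
  d2 <- build_dictionary(ont, exclusions = "HP:0000474")
  expect_false(normalize_key("excess nuchal skin") %in% d2$entries$key)
  expect_false("HP:0000474" %in% d2$entries$hpo_id)

  # training surfaces outrank ontology synonyms on collision
  train <- data.frame(surface = "excess nuchal skin",
                      hpo_id = "HP:0005989", stringsAsFactors = FALSE)
  expect_message(d3 <- build_dictionary(ont, train), "collisions")
  expect_equal(unname(d3$lookup[normalize_key("excess nuchal skin")]),
               "HP:0005989")
  src <- d3$entries$source[d3$entries$key ==
                             normalize_key("excess nuchal skin")]
  expect_equal(src, "training_surface")
})

test_that("two-step normalization tries observed then preferred", {
  d <- build_dictionary(tiny_ontology())

  # step 1 hit on the observed term
  r1 <- normalize_entity("high palate", "elevated palate shape", d)
  expect_equal(r1$step, "observed")
  expect_equal(r1$hpo_id, "HP:0000218")

  # observed misses, preferred hits
  r2 <- normalize_entity("brows meeting midline", "synophrys", d)
  expect_equal(r2$step, "preferred")
  expect_equal(r2$hpo_id, "HP:0000664")

  # both miss: no concept recorded
  r3 <- normalize_entity("totally novel finding", "unknown term", d)
  expect_equal(r3$step, "none")
  expect_true(is.na(r3$hpo_id))

  # discarded rows (empty observed term) go straight to step 2
  r4 <- normalize_entity("", "high palate", d)
  expect_equal(r4$step, "preferred")

  # lookup is casing/inflection invariant
  expect_equal(normalize_entity("Thickened Nuchal Skin Folds", "", d),
               normalize_entity("thickened nuchal skin fold", "", d))
})

test_that("observed-only mode disables the preferred-term fallback", {
  d <- build_dictionary(tiny_ontology())
  r <- normalize_entity("brows meeting midline", "synophrys", d,
                        mode = "observed_only")
  expect_equal(r$step, "none")

  # step-1 hits agree across modes
  expect_equal(normalize_entity("high palate", "x", d,
                                mode = "observed_only")$hpo_id,
               normalize_entity("high palate", "x", d)$hpo_id)
})

test_that("observed-only normalizations are a subset of two-step ones", {
  sm <- small_synthetic(seed = 21, n = 60)
  dict_onto <- build_dictionary(sm$syn$ontology)  # no training surfaces
  for (txt in names(sm$gold_index)) {
    preds <- parse_entity_table(sm$gold_index[[txt]], txt)
    both <- normalize_predictions(preds, dict_onto,
                                  "observed_and_preferred")
    only <- normalize_predictions(preds, dict_onto, "observed_only")
    hit_only <- which(!is.na(only$hpo_id))
    expect_true(all(hit_only %in% which(!is.na(both$hpo_id))))
    expect_equal(only$hpo_id[hit_only], both$hpo_id[hit_only])
  }
})

test_that("no normalization ever returns an excluded concept", {
  sm <- small_synthetic(seed = 22, n = 40)
  excl <- unique(sm$cur$annotations$hpo_id)[1:3]
  d <- suppressMessages(
    build_dictionary(sm$syn$ontology, training_surfaces(sm$cur),
                     exclusions = excl))
  for (txt in names(sm$gold_index)) {
    preds <- normalize_predictions(
      parse_entity_table(sm$gold_index[[txt]], txt), d)
    expect_false(any(preds$hpo_id %in% excl, na.rm = TRUE))
  }
})

test_that("exclusion lists read one id per line with comments", {
  path <- tempfile()
  writeLines(c("# modifier concepts", "HP:0000001", "", "HP:0012825"),
             path)
  expect_equal(read_exclusions(path), c("HP:0000001", "HP:0012825"))
})
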