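# Shared fixtures built in code. The table1-style corpus mirrors the
# published dataset example rows (en-dash span strings, "NA" empty
# observation, polarity markers).

table1_corpus_tsv <- function(path = tempfile(fileext = ".tsv")) {
  lines <- c(
    "observation_id\ttext\thpo_id\tspans\tpolarity",
    "D433F04E6AD5E56\tEYES: partial synophrys, long lashes, horizontal slant\tHP:0000664\t14–23\t–",
    "D433F04E6AD5E56\tEYES: partial synophrys, long lashes, horizontal slant\tHP:0000527\t25–36\t–",
    "8A1EEF66A345576\tMOUTH: normal lips, tongue, high palate\tHP:0000218\t28–39\t–",
    "8A1EEF66A345576\tMOUTH: normal lips, tongue, high palate\tHP:0000159\t7–18\tX",
    "8A1EEF66A345576\tMOUTH: normal lips, tongue, high palate\tHP:0000157\t7–13, 20–26\tX",
    "879246677902DE5\tNEUROLOGIC: very active\tNA\tNA\tNA")
  writeLines(lines, path, useBytes = TRUE)
  path
}

tiny_ontology <- function() {
  new_ontology(
    c("HP:0000664", "HP:0000527", "HP:0000218", "HP:0000159",
      "HP:0000157", "HP:0005989", "HP:0000474", "HP:0000154"),
    c("synophrys", "long eyelashes", "high palate", "abnormal lip",
      "abnormal tongue morphology", "redundant neck skin",
      "thickened nuchal skin fold", "wide mouth"),
    list(character(0), c("increased length of eyelashes"),
         c("elevated palate", "high arched palate"), character(0),
         character(0), c("excess neck skin"), c("excess nuchal skin"),
         c("broad mouth", "large mouth")))
}

# small deterministic corpus used across module tests
small_synthetic <- function(seed = 11L, n = 60L) {
  syn <- generate_corpus(synthetic_config(seed = seed,
                                          n_observations = n))
  cur <- curate_corpus(list(observations = syn$observations,
                            annotations = syn$annotations))
  dict <- suppressMessages(
    build_dictionary(syn$ontology, training_surfaces(cur)))
  list(syn = syn, cur = cur, dict = dict,
       gold_index = build_gold_index(cur, syn$ontology),
       pool = build_example_pool(cur, syn$ontology))
}

# random pre-processed text + valid random span set, for codec
# property tests
random_marked_case <- function() {
  n <- sample(10:80, 1)
  chars <- c(letters, " ", ",", ";", ":", "+", ".")
  text <- paste(sample(chars, n, replace = TRUE), collapse = "")
  k <- sample(0:3, 1)
  if (k == 0) {
    return(list(text = text, spans = span_set()))
  }
  cuts <- sort(sample(0:n, 2 * k))
  ok <- cuts[seq(1, 2 * k, 2)] < cuts[seq(2, 2 * k, 2)]
  starts <- cuts[seq(1, 2 * k, 2)][ok]
  ends <- cuts[seq(2, 2 * k, 2)][ok]
  list(text = text, spans = span_set(starts, ends))
}
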