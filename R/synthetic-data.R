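# Vocabulary for the synthetic dysmorphology-style corpus. Adjective
# sets are pairwise stem-disjoint across the three columns so that a
# paraphrased surface never collides with a preferred term or synonym
# key in the dictionary.
.syn_adjectives <- c("elongated", "flattened", "enlarged", "hypoplastic",
                     "broad", "narrow", "pointed", "asymmetric",
                     "bulbous", "crumpled", "drooping", "everted",
                     "depressed", "protruding", "shortened", "thickened",
                     "underdeveloped", "upslanted", "downslanted",
                     "widened")

# surface paraphrase of each adjective (what a clinician might write)
.syn_paraphrase <- c(elongated = "long", flattened = "flat",
                     enlarged = "large", hypoplastic = "small",
                     broad = "wide", narrow = "thin", pointed = "sharp",
                     asymmetric = "uneven", bulbous = "rounded",
                     crumpled = "folded", drooping = "sagging",
                     everted = "outturned", depressed = "sunken",
                     protruding = "jutting", shortened = "short",
                     thickened = "thick", underdeveloped = "immature",
                     upslanted = "ascending", downslanted = "descending",
                     widened = "expanded")

# ontology-synonym adjective (distinct stems from both columns above)
.syn_synonym_adj <- c(elongated = "stretched", flattened = "leveled",
                      enlarged = "oversized", hypoplastic = "undersized",
                      broad = "widespread", narrow = "slender",
                      pointed = "tapered", asymmetric = "lopsided",
                      bulbous = "bulging", crumpled = "wrinkled",
                      drooping = "ptotic", everted = "outward",
                      depressed = "recessed", protruding = "projecting",
                      shortened = "abbreviated", thickened = "dense",
                      underdeveloped = "rudimentary",
                      upslanted = "oblique", downslanted = "declining",
                      widened = "dilated")

.syn_nouns <- c("palpebral fissure", "nasal bridge", "philtrum", "helix",
                "ear lobe", "eyebrow", "forehead", "chin", "jaw",
                "cheekbone", "nostril", "lip", "hard palate", "tongue",
                "neck fold", "hairline", "finger", "thumb", "toe",
                "nail", "palm", "skull", "midface", "mandible",
                "maxilla", "iris", "pupil", "cornea", "fontanelle",
                "columella")

.syn_fillers <- c("normal", "unremarkable", "within normal limits",
                  "very active", "no abnormalities noted",
                  "well formed", "age appropriate")

#' Default organ-system headers
#'
#' Twenty organ/body-system headers of the kind dysmorphology
#' physical-examination observations begin with.
#'
#' @return Character vector of 20 upper-case headers.
#' @export
default_organ_systems <- function() {
  c("EYES", "EARS", "MOUTH", "NOSE", "FACE", "HEAD", "NECK", "CHEST",
    "ABDOMEN", "SKIN", "HANDS", "FEET", "SPINE", "GENITALIA",
    "NEUROLOGIC", "CARDIOVASCULAR", "MUSCULOSKELETAL", "EXTREMITIES",
    "HAIR", "PALATE")
}

#' Synthetic corpus configuration
#'
#' The structural parameters of the generated corpus, defaulting to
#' the statistics of real dysmorphology observation datasets: 12\%
#' empty observations, 14\% discontinuous spans, 1.49 concepts per
#' observation overall, 20 organ systems. Rates with no published
#' value (modifier, paraphrase, normal-finding) default to realistic
#' choices documented in the methods vignette.
#'
#' @param seed RNG seed; a fixed seed yields a byte-identical corpus.
#' @param n_observations Number of observations.
#' @param empty_rate Fraction of observations with no findings.
#' @param disjoint_rate Fraction of findings realized with a
#'   discontinuous span.
#' @param concepts_per_observation_mean Corpus-wide mean concepts per
#'   observation (empty observations counted as zero).
#' @param organ_systems Header list.
#' @param modifier_rate Fraction of abnormal findings prefixed with a
#'   modifier excluded from the gold boundary.
#' @param paraphrase_rate Fraction of abnormal findings whose surface
#'   is a paraphrase of the preferred term rather than the term
#'   itself.
#' @param normal_rate Fraction of findings annotated with normal
#'   polarity (removed by curation, never scored).
#' @return A \code{synthetic_config}.
#' @export
synthetic_config <- function(seed = 1L, n_observations = 500L,
                             empty_rate = 0.12, disjoint_rate = 0.14,
                             concepts_per_observation_mean = 1.49,
                             organ_systems = default_organ_systems(),
                             modifier_rate = 0.15,
                             paraphrase_rate = 0.3,
                             normal_rate = 0.11) {
  stopifnot(n_observations > 0,
            all(c(empty_rate, disjoint_rate, modifier_rate,
                  paraphrase_rate, normal_rate) >= 0),
            all(c(empty_rate, disjoint_rate, modifier_rate,
                  paraphrase_rate, normal_rate) <= 1))
  structure(list(seed = as.integer(seed),
                 n_observations = as.integer(n_observations),
                 empty_rate = empty_rate, disjoint_rate = disjoint_rate,
                 concepts_per_observation_mean =
                   concepts_per_observation_mean,
                 organ_systems = organ_systems,
                 modifier_rate = modifier_rate,
                 paraphrase_rate = paraphrase_rate,
                 normal_rate = normal_rate),
            class = "synthetic_config")
}

#' Generate a miniature HPO-style ontology
#'
#' Synthetic concepts with HP-style ids, multiword preferred terms and
#' 0-3 synonyms each, plus four real exemplar concepts kept as fixed
#' fixtures: HP:0005989 (redundant neck skin / excess neck skin),
#' HP:0000474 (thickened nuchal skin fold / excess nuchal skin),
#' HP:0000218 (high palate) and HP:0000664 (synophrys).
#'
#' @param seed RNG seed.
#' @param n_terms Total number of concepts (including the 4 fixtures).
#' @return A term table (hpo_id, preferred_term, synonyms).
#' @export
generate_mini_ontology <- function(seed = 1L, n_terms = 60L) {
  stopifnot(n_terms >= 4)
  fixtures <- new_ontology(
    c("HP:0005989", "HP:0000474", "HP:0000218", "HP:0000664"),
    c("redundant neck skin", "thickened nuchal skin fold",
      "high palate", "synophrys"),
    list("excess neck skin", "excess nuchal skin", character(0),
         character(0)))
  n_extra <- n_terms - 4L
  if (n_extra == 0) {
    return(fixtures)
  }
  combos <- expand.grid(adj = .syn_adjectives, noun = .syn_nouns,
                        stringsAsFactors = FALSE)
  stopifnot(n_extra <= nrow(combos))
  with_seed(seed, {
    pick <- combos[sample.int(nrow(combos), n_extra), , drop = FALSE]
    ids <- sprintf("HP:9%06d", sample.int(999999L, n_extra))
    syn <- lapply(seq_len(n_extra), function(i) {
      n_syn <- sample(0:3, 1, prob = c(0.3, 0.4, 0.2, 0.1))
      base <- paste(.syn_synonym_adj[[pick$adj[i]]], pick$noun[i])
      extra <- c(base,
                 paste("abnormal", pick$noun[i], "shape"),
                 paste(pick$adj[i], "appearance of the", pick$noun[i]))
      extra[seq_len(n_syn)]
    })
    rbind(fixtures,
          new_ontology(ids, paste(pick$adj, pick$noun), syn))
  })
}

# lambda of a zero-truncated Poisson whose conditional mean is m
.ztpois_lambda <- function(m) {
  if (m <= 1 + 1e-9) {
    return(0)
  }
  stats::uniroot(function(l) l / (1 - exp(-l)) - m,
                 c(1e-8, 50))$root
}

#' Generate a synthetic annotated corpus
#'
#' Builds observations of the form \code{"HEADER: finding, finding;
#' finding"} with gold annotations exhibiting the structural features
#' the pipeline must handle: empty observations (normal filler text,
#' no annotations), discontinuous spans (a term split around an
#' uninvolved side word, \code{"[Low-set] left [ear]"} style),
#' modifier words excluded from gold boundaries, paraphrased surfaces
#' that only the preferred-term normalization step can resolve against
#' an ontology-only dictionary, and normal-polarity findings for the
#' curation pass to remove. Also returns a tricky-example registry
#' covering every configured organ header and the indices of the
#' negative (empty) observations. Byte-deterministic under a fixed
#' seed.
#'
#' @param cfg A \code{\link{synthetic_config}}.
#' @param ontology A term table; default
#'   \code{generate_mini_ontology(cfg$seed)}.
#' @return A list: \code{observations}, \code{annotations} (with
#'   bookkeeping columns \code{paraphrased}, \code{disjoint}),
#'   \code{registry}, \code{negative_ids}, \code{ontology},
#'   \code{config}, \code{stats} (realized rates).
#' @export
generate_corpus <- function(cfg = synthetic_config(),
                            ontology = NULL) {
  if (is.null(ontology)) {
    ontology <- generate_mini_ontology(cfg$seed)
  }
  stopifnot(nrow(ontology) > 0)
  m_pos <- cfg$concepts_per_observation_mean /
    max(1 - cfg$empty_rate, 1e-9)
  lambda <- .ztpois_lambda(m_pos)
  modifiers <- c("mild", "slightly", "very", "partial")

  obs_id <- character(cfg$n_observations)
  obs_text <- character(cfg$n_observations)
  ann <- list()
  negative_ids <- character(0)

  with_seed(cfg$seed, {
    for (i in seq_len(cfg$n_observations)) {
      id <- sprintf("OBS%05d", i)
      header <- sample(cfg$organ_systems, 1)
      obs_id[i] <- id
      if (stats::runif(1) < cfg$empty_rate) {
        obs_text[i] <- paste0(header, ": ", sample(.syn_fillers, 1))
        negative_ids <- c(negative_ids, id)
        next
      }
      k <- if (lambda == 0) {
        1L
      } else {
        repeat {
          k_try <- stats::rpois(1, lambda)
          if (k_try >= 1) break
        }
        min(k_try, nrow(ontology))
      }
      rows <- sample.int(nrow(ontology), k)
      text <- paste0(header, ": ")
      for (j in seq_len(k)) {
        if (j > 1) {
          text <- paste0(text, sample(c(", ", "; "), 1))
        }
        term <- ontology$preferred_term[rows[j]]
        hpo <- ontology$hpo_id[rows[j]]
        toks <- strsplit(term, " ", fixed = TRUE)[[1]]
        is_normal <- stats::runif(1) < cfg$normal_rate
        if (is_normal) {
          phrase <- paste("normal", toks[length(toks)])
          s0 <- nchar(text)
          text <- paste0(text, phrase)
          ann[[length(ann) + 1]] <-
            list(id = id, hpo = hpo,
                 spans = span_set(s0, s0 + nchar(phrase)),
                 polarity = "normal", paraphrased = FALSE,
                 disjoint = FALSE)
          next
        }
        paraphrased <- toks[1] %in% names(.syn_paraphrase) &&
          stats::runif(1) < cfg$paraphrase_rate
        if (paraphrased) {
          toks[1] <- .syn_paraphrase[[toks[1]]]
        }
        if (stats::runif(1) < cfg$modifier_rate) {
          mod <- sample(modifiers, 1)
          text <- paste0(text, mod, " ")
        }
        disjoint <- length(toks) >= 2 &&
          stats::runif(1) < cfg$disjoint_rate
        if (disjoint) {
          side <- sample(c("left", "right"), 1)
          s1 <- nchar(text)
          e1 <- s1 + nchar(toks[1])
          rest <- paste(toks[-1], collapse = " ")
          s2 <- e1 + 1L + nchar(side) + 1L
          e2 <- s2 + nchar(rest)
          text <- paste0(text, toks[1], " ", side, " ", rest)
          spans <- span_set(c(s1, s2), c(e1, e2))
        } else {
          phrase <- paste(toks, collapse = " ")
          s0 <- nchar(text)
          text <- paste0(text, phrase)
          spans <- span_set(s0, s0 + nchar(phrase))
        }
        ann[[length(ann) + 1]] <-
          list(id = id, hpo = hpo, spans = spans,
               polarity = "abnormal", paraphrased = paraphrased,
               disjoint = disjoint)
      }
      obs_text[i] <- text
    }
  })

  observations <- new_observations(obs_id, obs_text)
  annotations <- new_annotations(
    vapply(ann, `[[`, character(1), "id"),
    vapply(ann, `[[`, character(1), "hpo"),
    lapply(ann, `[[`, "spans"),
    vapply(ann, `[[`, character(1), "polarity"))
  annotations$paraphrased <- vapply(ann, `[[`, logical(1), "paraphrased")
  annotations$disjoint <- vapply(ann, `[[`, logical(1), "disjoint")

  registry <- build_tricky_registry(cfg$organ_systems, ontology,
                                    cfg$seed)
  n_ab <- sum(annotations$polarity == "abnormal")
  stats_out <- list(
    empty_rate = length(negative_ids) / cfg$n_observations,
    disjoint_rate = if (n_ab == 0) 0 else {
      sum(annotations$disjoint[annotations$polarity == "abnormal"]) /
        n_ab
    },
    concepts_per_observation = nrow(annotations) / cfg$n_observations,
    n_normal = sum(annotations$polarity == "normal"),
    n_paraphrased = sum(annotations$paraphrased))
  list(observations = observations, annotations = annotations,
       registry = registry, negative_ids = negative_ids,
       ontology = ontology, config = cfg, stats = stats_out)
}

#' Build a tricky-example registry for given headers
#'
#' Five curated-style examples per organ header demonstrating the
#' task-specific behaviors few-shot prompts must enforce:
#' discontinuous spans, modifier exclusion, organ-header annotation,
#' and their combination.
#'
#' @param headers Organ headers to register.
#' @param ontology Term table the example findings are drawn from.
#' @param seed RNG seed.
#' @return Named list: header -> list of 5 examples (user, assistant).
#' @export
build_tricky_registry <- function(headers, ontology, seed = 1L) {
  multi <- ontology[vapply(strsplit(ontology$preferred_term, " "),
                           length, 1L) >= 2, , drop = FALSE]
  stopifnot(nrow(multi) >= 1)
  with_seed(seed, {
    registry <- list()
    for (h in headers) {
      rows <- multi[sample.int(nrow(multi), min(5, nrow(multi)),
                               replace = nrow(multi) < 5), ,
                    drop = FALSE]
      exs <- list()
      mk <- function(user, terms, markeds) {
        fewshot_example(user, render_entity_table(terms, markeds),
                        "tricky")
      }
      t1 <- strsplit(rows$preferred_term[1], " ")[[1]]
      exs[[1]] <- mk(  # disjoint span around a side word
        paste0(h, ": ", t1[1], " left ",
               paste(t1[-1], collapse = " ")),
        rows$preferred_term[1],
        paste0(h, ": [", t1[1], "] left [",
               paste(t1[-1], collapse = " "), "]"))
      exs[[2]] <- mk(  # modifier excluded from the boundary
        paste0(h, ": Mildly ", rows$preferred_term[2]),
        rows$preferred_term[2],
        paste0(h, ": Mildly [", rows$preferred_term[2], "]"))
      exs[[3]] <- mk(  # organ header inside the entity
        paste0(h, ": ", rows$preferred_term[3]),
        rows$preferred_term[3],
        paste0("[", h, "]: [", rows$preferred_term[3], "]"))
      exs[[4]] <- mk(  # plain whole-phrase annotation
        paste0(h, ": ", rows$preferred_term[4]),
        rows$preferred_term[4],
        paste0(h, ": [", rows$preferred_term[4], "]"))
      t5 <- strsplit(rows$preferred_term[5], " ")[[1]]
      exs[[5]] <- mk(  # all of the above
        paste0(h, ": slightly ", rows$preferred_term[5]),
        rows$preferred_term[5],
        paste0("[", h, "]: slightly [", rows$preferred_term[5], "]"))
      registry[[h]] <- exs
    }
    registry
  })
}

#' Extract training surfaces from a corpus
#'
#' The (surface form, id) pairs of a corpus' abnormal annotations, the
#' third dictionary source. Surfaces of discontinuous mentions are the
#' segment substrings joined by single spaces.
#'
#' @param corpus A list with \code{observations} and
#'   \code{annotations}.
#' @return A data frame with columns \code{surface}, \code{hpo_id}.
#' @export
training_surfaces <- function(corpus) {
  ann <- corpus$annotations[corpus$annotations$polarity == "abnormal", ,
                            drop = FALSE]
  data.frame(surface = annotation_surfaces(ann, corpus$observations),
             hpo_id = ann$hpo_id, stringsAsFactors = FALSE)
}
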