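#' Normalize a term into a dictionary key
#'
#' Case-folds, strips punctuation at token edges, collapses
#' whitespace, stems every token with the Porter stemmer and re-joins
#' with single spaces — so surface variants like
#' \code{"Excess nuchal skin"} / \code{"excess nuchal skin"} and
#' \code{"flattened midface"} / \code{"flatten midface"} collide on
#' one key.
#'
#' @param term A term string (or character vector).
#' @param stemmer Word-stemming function; default
#'   \code{\link{porter_stem}}. Pass \code{identity} to disable
#'   stemming.
#' @return Normalized key(s), same length as \code{term}.
#' @export
normalize_key <- function(term, stemmer = porter_stem) {
  vapply(term, function(t) {
    toks <- strsplit(tolower(t), "[[:space:]]+")[[1]]
    toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0) {
      return("")
    }
    paste(stemmer(toks), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Build the normalization dictionary
#'
#' Maps normalized keys to HPO ids from three sources: ontology
#' preferred terms, ontology synonyms, and annotated training
#' surfaces. Entries whose id is on the exclusion list (modifier
#' concepts, unobservable concepts — supplied by the user as the task
#' organizers supply theirs) are dropped. Key collisions resolve by
#' source precedence training_surface > hpo_preferred > hpo_synonym;
#' within a precedence level the later-loaded entry wins, and every
#' override is logged as a message.
#'
#' @param ontology Term table (hpo_id, preferred_term, synonyms).
#' @param training_surfaces Optional data frame with columns
#'   \code{surface} and \code{hpo_id} (annotated training mentions).
#' @param exclusions Character vector of HPO ids to exclude.
#' @param stemmer Passed to \code{\link{normalize_key}}.
#' @return A \code{term_dictionary}: entries data frame (key, hpo_id,
#'   source) plus the exclusion set and the stemmer used.
#' @export
build_dictionary <- function(ontology, training_surfaces = NULL,
                             exclusions = character(0),
                             stemmer = porter_stem) {
  key <- character(0)
  id <- character(0)
  source <- character(0)
  add <- function(k, i, s) {
    keep <- nzchar(k) & !(i %in% exclusions)
    key <<- c(key, k[keep])
    id <<- c(id, i[keep])
    source <<- c(source, rep(s, sum(keep)))
  }
  add(normalize_key(ontology$preferred_term, stemmer), ontology$hpo_id,
      "hpo_preferred")
  n_syn <- lengths(ontology$synonyms)
  if (sum(n_syn) > 0) {
    add(normalize_key(unlist(ontology$synonyms), stemmer),
        rep(ontology$hpo_id, n_syn), "hpo_synonym")
  }
  if (!is.null(training_surfaces) && nrow(training_surfaces) > 0) {
    add(normalize_key(training_surfaces$surface, stemmer),
        training_surfaces$hpo_id, "training_surface")
  }
  precedence <- c(hpo_synonym = 1L, hpo_preferred = 2L,
                  training_surface = 3L)
  # stable sort: load order preserved within key+precedence, last wins
  ord <- order(precedence[source])
  key <- key[ord]
  id <- id[ord]
  source <- source[ord]
  last <- !duplicated(key, fromLast = TRUE)
  overridden <- key[duplicated(key)]
  dup_diff <- unique(overridden[vapply(unique(overridden), function(k) {
    length(unique(id[key == k])) > 1
  }, logical(1))])
  if (length(dup_diff) > 0) {
    message("dictionary collisions resolved by precedence for ",
            length(dup_diff), " key(s)")
  }
  entries <- data.frame(key = key[last], hpo_id = id[last],
                        source = source[last], stringsAsFactors = FALSE)
  structure(list(entries = entries,
                 lookup = stats::setNames(entries$hpo_id, entries$key),
                 exclusions = exclusions, stemmer = stemmer),
            class = "term_dictionary")
}

#' @export
print.term_dictionary <- function(x, ...) {
  cat("<term_dictionary>", nrow(x$entries), "entries,",
      length(x$exclusions), "excluded id(s)\n")
  print(table(x$entries$source))
  invisible(x)
}

#' Dump a dictionary as TSV for inspection
#'
#' @param dict A \code{term_dictionary}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_dictionary <- function(dict, path) {
  utils::write.table(dict$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

dict_lookup <- function(dict, term) {
  k <- normalize_key(term, dict$stemmer)
  if (!nzchar(k)) {
    return(NA_character_)
  }
  out <- unname(dict$lookup[k])
  if (length(out) == 0) NA_character_ else out
}

#' Normalize one prediction to an HPO concept
#'
#' The two-step process: step 1 looks the observed term (the mention
#' as it appears in the text) up in the dictionary; on a miss, step 2
#' looks up the model-suggested preferred term; if both miss, no
#' concept is recorded. \code{mode = "observed_only"} disables step 2
#' — the higher-precision, lower-recall configuration that never
#' trusts the model's preferred-term suggestion. Predictions discarded
#' by the parser have no usable observed term and go straight to the
#' preferred-term step.
#'
#' @param observed_term Mention surface form ("" when the row was
#'   discarded).
#' @param preferred_term Model-suggested preferred HPO term.
#' @param dict A \code{term_dictionary}.
#' @param mode \code{"observed_and_preferred"} or
#'   \code{"observed_only"}.
#' @return A list with \code{hpo_id} (NA on failure) and \code{step}
#'   (\code{"observed"}, \code{"preferred"} or \code{"none"}).
#' @export
normalize_entity <- function(observed_term, preferred_term, dict,
                             mode = c("observed_and_preferred",
                                      "observed_only")) {
  mode <- match.arg(mode)
  if (nzchar(observed_term)) {
    hit <- dict_lookup(dict, observed_term)
    if (!is.na(hit)) {
      return(list(hpo_id = hit, step = "observed"))
    }
  }
  if (mode == "observed_and_preferred" && nzchar(preferred_term)) {
    hit <- dict_lookup(dict, preferred_term)
    if (!is.na(hit)) {
      return(list(hpo_id = hit, step = "preferred"))
    }
  }
  list(hpo_id = NA_character_, step = "none")
}

#' Normalize a parsed prediction table
#'
#' Applies \code{\link{normalize_entity}} to every row of a
#' \code{\link{parse_entity_table}} result, adding \code{hpo_id} and
#' \code{norm_step} columns.
#'
#' @param predictions Parsed prediction data frame.
#' @param dict A \code{term_dictionary}.
#' @param mode See \code{\link{normalize_entity}}.
#' @return The predictions with normalization columns filled in.
#' @export
normalize_predictions <- function(predictions, dict,
                                  mode = "observed_and_preferred") {
  n <- nrow(predictions)
  hpo_id <- character(n)
  step <- character(n)
  for (i in seq_len(n)) {
    res <- normalize_entity(predictions$observed_term[i],
                            predictions$preferred_term[i], dict, mode)
    hpo_id[i] <- res$hpo_id
    step[i] <- res$step
  }
  predictions$hpo_id <- hpo_id
  predictions$norm_step <- step
  predictions
}

#' Read an exclusion list
#'
#' One HPO id per line; blank lines and \code{#} comments ignored.
#'
#' @param path File path.
#' @return Character vector of ids.
#' @export
read_exclusions <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
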