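#' Default system instruction for extraction prompts
#'
#' Asks the model to extract HPO concepts into a two-column table of
#' preferred term and marked observation text. Overridable everywhere a
#' system text is accepted.
#'
#' @return A single string.
#' @export
default_system_text <- function() {
  paste("Extract Human Phenotype Ontology (HPO) concepts from the given",
        "text of a physical examination note into a table containing",
        "standard HPO preferred term and marked original text with square",
        "brackets surrounding the words associated with the HPO term.")
}

#' Pre-process observation text for marked-text prompting
#'
#' Square brackets are reserved for delimiting entity spans in model
#' output, so any pre-existing square brackets in the input are
#' replaced with round brackets. The substitution is one-to-one, so
#' string length — and therefore every gold character offset — is
#' preserved. Idempotent.
#'
#' @param text Observation text.
#' @return The pre-processed text, same length.
#' @examples
#' preprocess_text("EYES: [old] scar")
#' @export
preprocess_text <- function(text) {
  chartr("[]", "()", text)
}

#' Mark entity spans in text with square brackets
#'
#' Inserts \code{"["} before each segment start and \code{"]"} after
#' each segment end, working right-to-left so earlier offsets are
#' unaffected by the insertions. Discontinuous entities get one bracket
#' pair per segment. Inverse of \code{\link{recover_spans}}.
#'
#' @param text Pre-processed observation text (no square brackets).
#' @param spans A \code{\link{span_set}} valid for \code{text}.
#' @return The marked string.
#' @examples
#' mark_text("EARS: Low-set left ear", span_set(c(6, 19), c(13, 22)))
#' @export
mark_text <- function(text, spans) {
  validate_spans(spans, text)
  out <- text
  for (i in rev(seq_len(nrow(spans)))) {
    s <- spans[i, "start"]
    e <- spans[i, "end"]
    out <- paste0(substr(out, 1L, s), "[",
                  substr(out, s + 1L, e), "]",
                  substring(out, e + 1L))
  }
  out
}

#' Render predictions as a pipe-delimited entity table
#'
#' The assistant-message format: a header row
#' \code{"| HPO Preferred Term | Marked Observation |"} followed by one
#' row per entity. Zero rows render the header alone, which the parser
#' reads back as "no entities". Literal pipes inside cells are replaced
#' by \code{"/"} with a warning to keep the table parseable.
#'
#' @param preferred_terms Character vector of preferred HPO terms.
#' @param marked_texts Character vector of marked observations, same
#'   length.
#' @return A single multi-line string.
#' @export
render_entity_table <- function(preferred_terms = character(0),
                                marked_texts = character(0)) {
  stopifnot(length(preferred_terms) == length(marked_texts))
  cells <- c(preferred_terms, marked_texts)
  if (any(grepl("|", cells, fixed = TRUE))) {
    warning("replaced literal '|' inside table cells with '/'")
    preferred_terms <- gsub("|", "/", preferred_terms, fixed = TRUE)
    marked_texts <- gsub("|", "/", marked_texts, fixed = TRUE)
  }
  header <- "| HPO Preferred Term | Marked Observation |"
  if (length(preferred_terms) == 0) {
    return(header)
  }
  paste(c(header,
          paste0("| ", preferred_terms, " | ", marked_texts, " |")),
        collapse = "\n")
}

chat_message <- function(role, content) {
  stopifnot(role %in% c("system", "user", "assistant"))
  if (role %in% c("system", "user") && !nzchar(content)) {
    stop("system and user messages must be non-empty")
  }
  list(role = role, content = content)
}

new_prompt <- function(messages) {
  roles <- vapply(messages, `[[`, character(1), "role")
  if (length(roles) == 0 || roles[1] != "system" ||
      sum(roles == "system") != 1) {
    stop("prompt must start with exactly one system message")
  }
  body <- roles[-1]
  if (length(body) > 0) {
    expected <- rep(c("user", "assistant"), length.out = length(body))
    if (!all(body == expected)) {
      stop("after the system message, roles must alternate user/assistant")
    }
  }
  structure(list(messages = messages), class = "phenomark_prompt")
}

#' @export
print.phenomark_prompt <- function(x, ...) {
  cat("<prompt:", length(x$messages), "messages>\n")
  for (m in x$messages) {
    preview <- substr(gsub("\n", " ", m$content), 1L, 60L)
    cat(sprintf("  [%s] %s\n", m$role, preview))
  }
  invisible(x)
}

#' Build an inference prompt
#'
#' Message order: the system message, then the few-shot
#' (user, assistant) pairs in the given order, then a final user
#' message carrying the query text. With zero pairs this is the plain
#' two-message prompt used against fine-tuned models.
#'
#' @param query_text Pre-processed observation text to extract from.
#' @param fewshot A list of \code{list(user =, assistant =)} content
#'   pairs (e.g. from \code{\link{select_examples}}).
#' @param system_text System instruction; default
#'   \code{\link{default_system_text}()}.
#' @return A \code{phenomark_prompt}.
#' @export
build_inference_prompt <- function(query_text, fewshot = list(),
                                   system_text = default_system_text()) {
  msgs <- list(chat_message("system", system_text))
  for (ex in fewshot) {
    msgs <- c(msgs, list(chat_message("user", ex$user),
                         chat_message("assistant", ex$assistant)))
  }
  msgs <- c(msgs, list(chat_message("user", query_text)))
  new_prompt(msgs)
}

#' Build one fine-tuning training record
#'
#' A three-message prompt (system, user, assistant) for one
#' observation: the user message is the pre-processed text and the
#' assistant message is the rendered entity table of its gold
#' annotations, rows ordered by first-segment start offset.
#'
#' @param text Observation text (raw; pre-processed internally).
#' @param annotations Annotation data frame rows for this observation
#'   (post-curation, abnormal only).
#' @param preferred_lookup Named character vector mapping HPO id to
#'   preferred term; must cover every annotated id.
#' @param system_text System instruction.
#' @return A 3-message \code{phenomark_prompt}.
#' @export
build_training_record <- function(text, annotations, preferred_lookup,
                                  system_text = default_system_text()) {
  clean <- preprocess_text(text)
  n <- nrow(annotations)
  if (n > 0) {
    missing_ids <- setdiff(annotations$hpo_id, names(preferred_lookup))
    if (length(missing_ids) > 0) {
      stop("no preferred term for: ", paste(missing_ids, collapse = ", "))
    }
    first_start <- vapply(annotations$spans, function(s) {
      if (nrow(s) == 0) NA_integer_ else s[1, "start"]
    }, integer(1))
    ord <- order(first_start)
    marked <- vapply(annotations$spans[ord], function(s) {
      mark_text(clean, s)
    }, character(1))
    table_text <- render_entity_table(
      unname(preferred_lookup[annotations$hpo_id[ord]]), marked)
  } else {
    table_text <- render_entity_table()
  }
  new_prompt(list(chat_message("system", system_text),
                  chat_message("user", clean),
                  chat_message("assistant", table_text)))
}

#' Build the full fine-tuning prompt dataset
#'
#' One training record per observation in the corpus, including empty
#' observations (whose assistant message is the header-only table, so
#' the model learns the no-findings format).
#'
#' @param corpus A list with \code{observations} and
#'   \code{annotations} (post-curation).
#' @param ontology Term table supplying preferred terms.
#' @param system_text System instruction.
#' @return A list of \code{phenomark_prompt} records.
#' @export
build_finetune_dataset <- function(corpus, ontology,
                                   system_text = default_system_text()) {
  lookup <- stats::setNames(ontology$preferred_term, ontology$hpo_id)
  lapply(seq_len(nrow(corpus$observations)), function(i) {
    obs <- corpus$observations[i, ]
    ann <- corpus$annotations[
      corpus$annotations$observation_id == obs$id, , drop = FALSE]
    build_training_record(obs$text, ann, lookup, system_text)
  })
}
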