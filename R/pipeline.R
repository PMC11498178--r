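#' Build a replay gold index from a corpus
#'
#' Maps each observation's pre-processed text to the entity table its
#' gold annotations render to — the lookup a
#' \code{\link{mock_replay_backend}} answers from.
#'
#' @param corpus A list with \code{observations} and \code{annotations}
#'   (curated: abnormal only).
#' @param ontology Term table supplying preferred terms.
#' @return Named list: user text -> gold assistant table.
#' @export
build_gold_index <- function(corpus, ontology) {
  pool <- build_example_pool(corpus, ontology)
  stats::setNames(lapply(pool, `[[`, "assistant"),
                  vapply(pool, `[[`, character(1), "user"))
}

#' Run the extraction and normalization pipeline
#'
#' Per observation: pre-process the text, build the prompt (with
#' per-query few-shot selection in \code{"fewshot"} mode, or the plain
#' system+user prompt in \code{"finetuned"} mode, where the examples
#' live in the model weights), request a completion, parse the entity
#' table, recover spans, and normalize each prediction to an HPO
#' concept. Backend failures are logged per observation and never
#' abort the run. When gold annotations are supplied the predictions
#' are scored under all three settings.
#'
#' @param observations Observation data frame.
#' @param backend A backend for \code{\link{complete}}.
#' @param dict A \code{term_dictionary}.
#' @param mode \code{"fewshot"} or \code{"finetuned"}.
#' @param normalization_mode See \code{\link{normalize_entity}}.
#' @param pool,registry,selection_cfg Few-shot machinery (required in
#'   fewshot mode): see \code{\link{select_examples}}.
#' @param embedder Similarity embedder for selection.
#' @param system_text System instruction.
#' @param gold Optional gold annotations (abnormal) for scoring.
#' @param max_attempts Backend retry cap.
#' @return A \code{phenomark_run}: \code{predictions} data frame
#'   (observation_id, preferred_term, observed_term, discard_reason,
#'   hpo_id, norm_step, spans), \code{reports} (when gold given),
#'   \code{failures}, \code{manifest}.
#' @export
run_pipeline <- function(observations, backend, dict,
                         mode = c("fewshot", "finetuned"),
                         normalization_mode = "observed_and_preferred",
                         pool = NULL, registry = list(),
                         selection_cfg = selection_config(),
                         embedder = hash_embedder(),
                         system_text = default_system_text(),
                         gold = NULL, max_attempts = 3L) {
  mode <- match.arg(mode)
  if (mode == "fewshot") {
    if (is.null(pool)) {
      stop("fewshot mode requires an example pool")
    }
    if (is.null(attr(pool, "doc_vectors"))) {
      pool <- precompute_pool_vectors(pool, embedder)
    }
  }
  all_preds <- list()
  failures <- character(0)
  for (i in seq_len(nrow(observations))) {
    obs <- observations[i, ]
    clean <- preprocess_text(obs$text)
    fewshot <- if (mode == "fewshot") {
      select_examples(clean, pool, registry, selection_cfg, embedder)
    } else {
      list()
    }
    prompt <- build_inference_prompt(clean, fewshot, system_text)
    res <- tryCatch(
      complete_with_retry(backend, prompt, max_attempts,
                          base_delay = 0),
      error = function(e) e)
    if (inherits(res, "condition")) {
      failures <- c(failures, obs$id)
      next
    }
    preds <- parse_entity_table(res$content, clean)
    preds <- normalize_predictions(preds, dict, normalization_mode)
    if (nrow(preds) > 0) {
      preds <- cbind(data.frame(observation_id = obs$id,
                                stringsAsFactors = FALSE), preds)
      all_preds[[length(all_preds) + 1]] <- preds
    }
  }
  predictions <- if (length(all_preds) > 0) {
    do.call(rbind, all_preds)
  } else {
    p <- new_predictions()
    cbind(data.frame(observation_id = character(0),
                     stringsAsFactors = FALSE), p)
  }
  rownames(predictions) <- NULL
  reports <- NULL
  if (!is.null(gold)) {
    reports <- evaluate_all_settings(gold, predictions,
                                     observations$id)
  }
  manifest <- list(mode = mode,
                   normalization_mode = normalization_mode,
                   backend = class(backend)[1],
                   selection = unclass(selection_cfg),
                   system_text = system_text,
                   n_observations = nrow(observations),
                   n_failures = length(failures),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  structure(list(predictions = predictions, reports = reports,
                 failures = failures, manifest = manifest),
            class = "phenomark_run")
}

#' @export
print.phenomark_run <- function(x, ...) {
  cat("<phenomark run>", x$manifest$mode, "mode,",
      x$manifest$n_observations, "observation(s),",
      nrow(x$predictions), "prediction(s),",
      length(x$failures), "failure(s)\n")
  if (!is.null(x$reports)) {
    for (r in x$reports) {
      print(r)
    }
  }
  invisible(x)
}

#' Write run predictions in the corpus tabular dialect
#'
#' Serializes predictions in the same TSV dialect as gold annotations
#' so \code{\link{evaluate_predictions}} inputs are uniform; discarded
#' and un-normalized rows are included with their reason for audit.
#'
#' @param run A \code{phenomark_run}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_predictions <- function(run, path) {
  p <- run$predictions
  df <- data.frame(
    observation_id = p$observation_id,
    hpo_id = ifelse(is.na(p$hpo_id), "NA", p$hpo_id),
    spans = vapply(p$spans, serialize_spans, character(1)),
    preferred_term = p$preferred_term,
    observed_term = p$observed_term,
    discard_reason = p$discard_reason,
    norm_step = p$norm_step,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a run manifest as JSON
#'
#' The configuration record sufficient to re-run: mode, normalization
#' mode, backend class, selection configuration and seeds.
#'
#' @param run A \code{phenomark_run}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(run, path) {
  jsonlite::write_json(run$manifest, path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
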