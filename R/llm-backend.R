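#' Request a chat completion from a backend
#'
#' Backends are black boxes to the pipeline: given a prompt ending in
#' a user message they return an assistant content string plus
#' free-form metadata. Implementations: \code{\link{mock_replay_backend}}
#' (deterministic, offline) and \code{\link{chat_api_backend}} (thin
#' HTTP adapter).
#'
#' @param backend A backend object.
#' @param prompt A \code{phenomark_prompt} whose final message has role
#'   \code{user}.
#' @param ... Passed to methods.
#' @return A list with \code{content} (string) and \code{meta} (list).
#' @export
complete <- function(backend, prompt, ...) {
  roles <- vapply(prompt$messages, `[[`, character(1), "role")
  if (roles[length(roles)] != "user") {
    stop("prompt must end in a user message")
  }
  UseMethod("complete")
}

retryable_error <- function(msg) {
  structure(class = c("phenomark_retryable", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Complete with retries
#'
#' Wraps \code{\link{complete}} with up to \code{max_attempts}
#' attempts and exponential backoff on retryable (transport) errors;
#' other errors propagate immediately.
#'
#' @inheritParams complete
#' @param max_attempts Attempt cap (default 3).
#' @param base_delay First backoff delay in seconds (doubles per
#'   retry); tests use 0.
#' @return As \code{\link{complete}}.
#' @export
complete_with_retry <- function(backend, prompt, max_attempts = 3L,
                                base_delay = 0.5) {
  for (attempt in seq_len(max_attempts)) {
    res <- tryCatch(complete(backend, prompt),
                    phenomark_retryable = function(e) e)
    if (!inherits(res, "condition")) {
      return(res)
    }
    if (attempt < max_attempts) {
      Sys.sleep(base_delay * 2^(attempt - 1))
    }
  }
  stop(retryable_error(paste("backend failed after", max_attempts,
                             "attempts")))
}

#' Deterministic replay backend
#'
#' Answers each prompt by looking its final user text up in a gold
#' index (user text -> gold entity table) and replaying the gold
#' table, optionally corrupted to emulate the failure behaviors real
#' models exhibit: \code{fix_typo} makes one character-level edit in a
#' row's marked text outside the brackets (a model "fixing" the
#' input), \code{bracket_append} appends a stray character to the
#' marked text (the \code{+cephalohematoma+} behavior, discarded
#' downstream as a text mismatch), \code{drop_rows} removes a random
#' subset of rows (missed findings). Texts absent from the index get
#' the header-only no-entities response. Fully deterministic under a
#' fixed seed.
#'
#' @param gold_index Named character vector or list: user text ->
#'   assistant table.
#' @param corruption One of \code{"none"}, \code{"fix_typo"},
#'   \code{"bracket_append"}, \code{"drop_rows"}.
#' @param seed RNG seed for the corruption draws.
#' @param corruption_rate Fraction of responses the corruption is
#'   applied to (default 1 = every response with at least one row).
#' @return A backend usable with \code{\link{complete}}.
#' @export
mock_replay_backend <- function(gold_index,
                                corruption = c("none", "fix_typo",
                                               "bracket_append",
                                               "drop_rows"),
                                seed = 1L, corruption_rate = 1) {
  corruption <- match.arg(corruption)
  structure(list(gold_index = as.list(gold_index),
                 corruption = corruption, seed = as.integer(seed),
                 corruption_rate = corruption_rate,
                 counter = new.env(parent = emptyenv())),
            class = c("mock_replay_backend", "phenomark_backend"))
}

split_table_rows <- function(table_text) {
  lines <- strsplit(table_text, "\n", fixed = TRUE)[[1]]
  is_header <- grepl("HPO Preferred Term", lines, fixed = TRUE)
  list(header = lines[is_header], rows = lines[!is_header])
}

corrupt_response <- function(table_text, corruption, rng_seed) {
  parts <- split_table_rows(table_text)
  if (length(parts$rows) == 0) {
    return(table_text)
  }
  with_seed(rng_seed, {
    rows <- parts$rows
    if (corruption == "drop_rows") {
      keep <- stats::runif(length(rows)) < 0.5
      rows <- rows[keep]
    } else {
      i <- sample.int(length(rows), 1)
      cells <- strsplit(sub("\\|$", "", sub("^\\|", "", rows[i])),
                        "|", fixed = TRUE)[[1]]
      term <- trimws(cells[1])
      marked <- trimws(cells[2])
      if (corruption == "bracket_append") {
        last <- substr(marked, nchar(marked), nchar(marked))
        stray <- if (grepl("[[:punct:]]", last) && last != "]") {
          last
        } else {
          "+"
        }
        marked <- paste0(marked, stray)
      } else if (corruption == "fix_typo") {
        chars <- strsplit(marked, "")[[1]]
        depth <- cumsum((chars == "[") - c(0, (chars == "]")[-length(chars)]))
        editable <- which(grepl("[[:alpha:]]", chars) & depth == 0)
        if (length(editable) > 0) {
          j <- editable[sample.int(length(editable), 1)]
          repl <- sample(setdiff(letters, chars[j]), 1)
          chars[j] <- repl
          marked <- paste(chars, collapse = "")
        }
      }
      rows[i] <- paste0("| ", term, " | ", marked, " |")
    }
    paste(c(parts$header, rows), collapse = "\n")
  })
}

#' @export
complete.mock_replay_backend <- function(backend, prompt, ...) {
  query <- prompt$messages[[length(prompt$messages)]]$content
  gold <- backend$gold_index[[query]]
  if (is.null(gold)) {
    return(list(content = render_entity_table(),
                meta = list(model = "mock-replay", hit = FALSE)))
  }
  n <- get0("n", envir = backend$counter, ifnotfound = 0L) + 1L
  assign("n", n, envir = backend$counter)
  content <- gold
  if (backend$corruption != "none") {
    apply_it <- with_seed(backend$seed + 7L * n,
                          stats::runif(1)) <= backend$corruption_rate
    if (apply_it) {
      content <- corrupt_response(gold, backend$corruption,
                                  backend$seed + n)
    }
  }
  list(content = content,
       meta = list(model = "mock-replay", hit = TRUE,
                   corruption = backend$corruption))
}

#' Chat-API HTTP backend adapter
#'
#' A thin adapter for the common chat-completion API shape (model,
#' messages, temperature), shelling out to the \code{curl} binary.
#' Live calls and remote fine-tune initiation are vendor-side
#' operations outside the tested surface; this adapter exists so the
#' same pipeline runs against a real endpoint when credentials and
#' network are available. Temperature defaults to 0 for
#' reproducibility.
#'
#' @param model Model identifier.
#' @param endpoint Chat-completions URL.
#' @param api_key_env Name of the environment variable holding the key.
#' @param temperature Sampling temperature.
#' @return A backend usable with \code{\link{complete}}.
#' @export
chat_api_backend <- function(model,
                             endpoint =
                               "https://api.openai.com/v1/chat/completions",
                             api_key_env = "OPENAI_API_KEY",
                             temperature = 0) {
  structure(list(model = model, endpoint = endpoint,
                 api_key_env = api_key_env, temperature = temperature),
            class = c("chat_api_backend", "phenomark_backend"))
}

#' @export
complete.chat_api_backend <- function(backend, prompt, ...) {
  key <- Sys.getenv(backend$api_key_env, unset = "")
  if (!nzchar(key)) {
    stop("no API key in $", backend$api_key_env)
  }
  body <- jsonlite::toJSON(list(model = backend$model,
                                temperature = backend$temperature,
                                messages = lapply(prompt$messages,
                                                  function(m) {
                                                    list(role = m$role,
                                                         content =
                                                           m$content)
                                                  })),
                           auto_unbox = TRUE)
  res <- suppressWarnings(system2(
    "curl", c("-sS", "--fail", "-X", "POST", backend$endpoint,
              "-H", shQuote(paste("Authorization: Bearer", key)),
              "-H", shQuote("Content-Type: application/json"),
              "-d", shQuote(body)),
    stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    stop(retryable_error(paste("chat API transport failure:",
                               paste(res, collapse = " "))))
  }
  parsed <- jsonlite::fromJSON(paste(res, collapse = ""),
                               simplifyVector = FALSE)
  list(content = parsed$choices[[1]]$message$content,
       meta = list(model = backend$model))
}

#' Export a fine-tuning prompt dataset as JSON Lines
#'
#' One line per record: a JSON object with a \code{"messages"} array
#' of \code{{"role", "content"}} objects in order. Records must be
#' 3-message system/user/assistant prompts.
#'
#' @param records List of \code{phenomark_prompt} objects.
#' @param path Output .jsonl path.
#' @return \code{path}, invisibly.
#' @export
export_finetune_dataset <- function(records, path) {
  lines <- character(length(records))
  for (i in seq_along(records)) {
    roles <- vapply(records[[i]]$messages, `[[`, character(1), "role")
    if (!identical(roles, c("system", "user", "assistant"))) {
      stop("record ", i,
           ": expected role sequence system/user/assistant, got ",
           paste(roles, collapse = "/"))
    }
    lines[i] <- jsonlite::toJSON(
      list(messages = lapply(records[[i]]$messages, function(m) {
        list(role = m$role, content = m$content)
      })), auto_unbox = TRUE)
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Re-import a fine-tuning JSON Lines dataset
#'
#' Round-trip inverse of \code{\link{export_finetune_dataset}}.
#'
#' @param path A .jsonl path.
#' @return A list of \code{phenomark_prompt} objects.
#' @export
import_finetune_dataset <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    new_prompt(lapply(obj$messages, function(m) {
      chat_message(m$role, m$content)
    }))
  })
}

#' Initiate a remote fine-tuning job (interface stub)
#'
#' Uploading the exported dataset and launching the job happen on the
#' vendor side; this function only validates the export and returns a
#' job descriptor for the caller's tooling.
#'
#' @param dataset_path Exported .jsonl path.
#' @param base_model Base model identifier.
#' @return A list describing the requested job (not submitted).
#' @export
request_finetune_job <- function(dataset_path, base_model) {
  records <- import_finetune_dataset(dataset_path)
  list(status = "not_submitted", base_model = base_model,
       n_records = length(records), dataset_path = dataset_path)
}
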