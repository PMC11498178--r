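#' Recover character spans from marked text
#'
#' Inverse of \code{\link{mark_text}}: strips the square brackets and
#' reports, for each bracketed run, its 0-based start and exclusive end
#' offset in the unmarked string. Discontinuous entities (multiple
#' bracket pairs) yield one segment per pair.
#'
#' @param marked A marked observation string.
#' @return A list with \code{unmarked} (the string with all brackets
#'   removed) and \code{spans} (a \code{\link{span_set}}); unbalanced
#'   or nested brackets raise an error of class
#'   \code{phenomark_unbalanced}.
#' @examples
#' recover_spans("MOUTH: [normal] lips, [tongue], high palate")
#' @export
recover_spans <- function(marked) {
  bad <- function(msg) {
    stop(structure(class = c("phenomark_unbalanced", "error", "condition"),
                   list(message = msg, call = NULL)))
  }
  chars <- strsplit(marked, "")[[1]]
  is_open <- chars == "["
  is_close <- chars == "]"
  is_bracket <- is_open | is_close
  # bracket sequence must strictly alternate [, ], [, ], ...
  seq_b <- chars[is_bracket]
  if (length(seq_b) %% 2 != 0) {
    bad("unbalanced brackets in marked text")
  }
  if (length(seq_b) > 0 &&
      !all(seq_b == rep(c("[", "]"), length(seq_b) / 2))) {
    bad("nested or mismatched brackets in marked text")
  }
  # offset of each character in the unmarked string
  unmarked_pos <- cumsum(!is_bracket)
  starts <- unmarked_pos[is_open]        # chars consumed before the '['
  ends <- unmarked_pos[is_close]
  keep <- ends > starts                  # ignore empty "[]" pairs
  list(unmarked = paste(chars[!is_bracket], collapse = ""),
       spans = span_set(starts[keep], ends[keep]))
}

collapse_ws <- function(x) {
  gsub("[[:space:]]+", " ", trimws(x))
}

new_predictions <- function() {
  out <- data.frame(preferred_term = character(0),
                    observed_term = character(0),
                    discard_reason = character(0),
                    stringsAsFactors = FALSE)
  out$spans <- list()
  out
}

#' Parse an assistant entity table against its observation
#'
#' Splits a model response into pipe-delimited rows (header and
#' \code{---} separator lines are skipped; leading/trailing pipes
#' optional), recovers spans from each row's marked text, and applies
#' the discard rules: a row is discarded with reason
#' \code{text_mismatch} when the unmarked text does not equal the
#' observation text (whitespace runs collapsed before comparison —
#' anything further, such as model typo "fixes", is rejected rather
#' than realigned), \code{out_of_bounds} when an offset exceeds the
#' observation's length, \code{no_brackets} when a row marks nothing,
#' and \code{unbalanced_brackets} when brackets do not pair. Discarded
#' rows are kept in the output with empty spans for logging; rows with
#' an empty preferred-term cell are kept (the observed term may still
#' normalize).
#'
#' @param response Assistant message text.
#' @param original_text The pre-processed observation text the model
#'   was given.
#' @return A data frame with columns \code{preferred_term},
#'   \code{observed_term}, \code{discard_reason} ("none" when valid)
#'   and a \code{spans} list-column.
#' @export
parse_entity_table <- function(response, original_text) {
  lines <- strsplit(response, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  is_table <- grepl("|", lines, fixed = TRUE)
  if (!any(is_table)) {
    if (length(lines) > 0) {
      warning("response contains no recognizable entity table")
    }
    return(new_predictions())
  }
  lines <- lines[is_table]
  is_sep <- grepl("^[-|: ]+$", lines)
  is_header <- grepl("HPO Preferred Term", lines, fixed = TRUE)
  rows <- lines[!is_sep & !is_header]

  preferred <- character(0)
  observed <- character(0)
  reason <- character(0)
  spans <- list()
  for (row in rows) {
    body <- sub("^\\|", "", sub("\\|$", "", row))
    cells <- trimws(strsplit(body, "|", fixed = TRUE)[[1]])
    if (length(cells) < 2) {
      next
    }
    term <- cells[1]
    marked <- cells[2]
    rec <- tryCatch(recover_spans(marked), phenomark_unbalanced =
                      function(e) NULL)
    if (is.null(rec)) {
      preferred <- c(preferred, term)
      observed <- c(observed, "")
      reason <- c(reason, "unbalanced_brackets")
      spans <- c(spans, list(span_set()))
      next
    }
    this_reason <- "none"
    this_spans <- rec$spans
    if (rec$unmarked != original_text) {
      # tolerate whitespace-only drift when the observation itself has
      # no whitespace runs (offsets then still index the original)
      if (collapse_ws(rec$unmarked) == collapse_ws(original_text) &&
          original_text == collapse_ws(original_text)) {
        rec2 <- recover_spans(collapse_ws(marked))
        this_spans <- rec2$spans
        if (nrow(this_spans) > 0 &&
            any(this_spans[, "end"] > nchar(original_text))) {
          this_reason <- "out_of_bounds"
        }
      } else {
        this_reason <- "text_mismatch"
      }
    }
    if (this_reason == "none" && nrow(this_spans) == 0) {
      this_reason <- "no_brackets"
    }
    if (this_reason == "none" &&
        any(this_spans[, "end"] > nchar(original_text))) {
      this_reason <- "out_of_bounds"
    }
    if (this_reason != "none") {
      this_spans <- span_set()
    }
    preferred <- c(preferred, term)
    observed <- c(observed,
                  if (this_reason == "none") {
                    span_surface(this_spans, original_text)
                  } else {
                    ""
                  })
    reason <- c(reason, this_reason)
    spans <- c(spans, list(this_spans))
  }
  out <- data.frame(preferred_term = preferred, observed_term = observed,
                    discard_reason = reason, stringsAsFactors = FALSE)
  out$spans <- spans
  out
}
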