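#' Tabular dialect for annotated corpora
#'
#' Corpus files are tab-separated with a header row and one row per
#' (observation, finding) pair; empty observations carry the
#' missing-value token in the annotation columns. The dialect names the
#' five required columns so files with different headers or column
#' orders can be read without code changes.
#'
#' @param id,text,hpo_id,spans,polarity Column names in the file.
#' @param na_token Missing-value token marking empty observations.
#' @param normal_marker,abnormal_marker Polarity column values for
#'   normal ("X") and abnormal ("–") findings; the ASCII hyphen is also
#'   accepted for abnormal on read.
#' @return A list of class \code{corpus_dialect}.
#' @export
corpus_dialect <- function(id = "observation_id", text = "text",
                           hpo_id = "hpo_id", spans = "spans",
                           polarity = "polarity", na_token = "NA",
                           normal_marker = "X", abnormal_marker = "–") {
  structure(list(id = id, text = text, hpo_id = hpo_id, spans = spans,
                 polarity = polarity, na_token = na_token,
                 normal_marker = normal_marker,
                 abnormal_marker = abnormal_marker),
            class = "corpus_dialect")
}

new_observations <- function(id = character(0), text = character(0)) {
  data.frame(id = id, text = text,
             organ_header = vapply(text, organ_header, character(1),
                                   USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

new_annotations <- function(observation_id = character(0),
                            hpo_id = character(0), spans = list(),
                            polarity = character(0)) {
  out <- data.frame(observation_id = observation_id, hpo_id = hpo_id,
                    polarity = polarity, stringsAsFactors = FALSE)
  out$spans <- spans
  out
}

#' Organ-system header of an observation
#'
#' The text before the first colon, upper-cased; the empty string when
#' no colon is present.
#'
#' @param text Observation text.
#' @return A single string.
#' @examples
#' organ_header("EYES: partial synophrys")
#' @export
organ_header <- function(text) {
  pos <- regexpr(":", text, fixed = TRUE)
  if (pos < 0) {
    return("")
  }
  toupper(substr(text, 1L, pos - 1L))
}

#' Read an annotated observation corpus
#'
#' Reads the shared-task tabular format: one row per gold finding,
#' observations repeated across their findings, rows with the
#' missing-value token in the HPO-ID column contributing an observation
#' with zero annotations. Span strings accept both en dash and hyphen
#' separators. Duplicate (observation, concept, spans) triples are
#' deduplicated with a warning; malformed span strings are reported
#' with their row number.
#'
#' @param path Path to a TSV file.
#' @param dialect A \code{\link{corpus_dialect}}.
#' @return A list with elements \code{observations} (data frame: id,
#'   text, organ_header) and \code{annotations} (data frame:
#'   observation_id, hpo_id, polarity, spans list-column of
#'   \code{span_set}).
#' @export
read_annotated_corpus <- function(path, dialect = corpus_dialect()) {
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL,
                           fileEncoding = "UTF-8")
  need <- c(dialect$id, dialect$text, dialect$hpo_id, dialect$spans,
            dialect$polarity)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }

  first <- !duplicated(raw[[dialect$id]])
  obs <- new_observations(raw[[dialect$id]][first], raw[[dialect$text]][first])
  if (anyDuplicated(obs$id)) {
    stop("duplicate observation id with conflicting text")
  }
  conflicting <- raw[[dialect$text]] !=
    obs$text[match(raw[[dialect$id]], obs$id)]
  if (any(conflicting)) {
    stop("observation id maps to more than one text, first at row ",
         which(conflicting)[1])
  }

  is_na <- raw[[dialect$hpo_id]] == dialect$na_token |
    !nzchar(trimws(raw[[dialect$hpo_id]]))
  ann_rows <- which(!is_na)
  spans <- vector("list", length(ann_rows))
  for (k in seq_along(ann_rows)) {
    i <- ann_rows[k]
    spans[[k]] <- tryCatch(parse_spans(raw[[dialect$spans]][i]),
                           error = function(e) {
                             stop("row ", i, ": ", conditionMessage(e),
                                  call. = FALSE)
                           })
    text_i <- obs$text[match(raw[[dialect$id]][i], obs$id)]
    validate_spans(spans[[k]], text_i)
  }
  pol_raw <- raw[[dialect$polarity]][ann_rows]
  polarity <- ifelse(pol_raw == dialect$normal_marker, "normal", "abnormal")
  ann <- new_annotations(raw[[dialect$id]][ann_rows],
                         raw[[dialect$hpo_id]][ann_rows], spans, polarity)

  key <- paste(ann$observation_id, ann$hpo_id,
               vapply(ann$spans, serialize_spans, character(1)))
  if (anyDuplicated(key)) {
    warning("deduplicated ", sum(duplicated(key)),
            " duplicate annotation row(s)")
    ann <- ann[!duplicated(key), , drop = FALSE]
    rownames(ann) <- NULL
  }
  list(observations = obs, annotations = ann)
}

#' Write an annotated corpus
#'
#' Inverse of \code{\link{read_annotated_corpus}}; round-trips the
#' corpus losslessly. Observations without annotations are written as a
#' single row carrying the missing-value token.
#'
#' @param corpus A list with \code{observations} and \code{annotations}.
#' @param path Output TSV path.
#' @param dialect A \code{\link{corpus_dialect}}.
#' @return \code{path}, invisibly.
#' @export
write_annotated_corpus <- function(corpus, path,
                                   dialect = corpus_dialect()) {
  obs <- corpus$observations
  ann <- corpus$annotations
  rows <- list()
  for (i in seq_len(nrow(obs))) {
    a <- ann[ann$observation_id == obs$id[i], , drop = FALSE]
    if (nrow(a) == 0) {
      rows[[length(rows) + 1]] <- c(obs$id[i], obs$text[i],
                                    dialect$na_token, dialect$na_token,
                                    dialect$na_token)
    } else {
      for (j in seq_len(nrow(a))) {
        pol <- if (a$polarity[j] == "normal") dialect$normal_marker
               else dialect$abnormal_marker
        rows[[length(rows) + 1]] <- c(obs$id[i], obs$text[i], a$hpo_id[j],
                                      serialize_spans(a$spans[[j]]), pol)
      }
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- c(dialect$id, dialect$text, dialect$hpo_id,
                   dialect$spans, dialect$polarity)
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an ontology term table
#'
#' Two formats are supported: a TSV with columns \code{hpo_id},
#' \code{preferred_term} and an optional \code{synonyms} column
#' (pipe-separated), and a minimal OBO file of \code{[Term]} stanzas
#' with \code{id}, \code{name} and \code{synonym} lines (OBO quoting
#' and scope qualifiers are stripped). Stanzas missing an id or name
#' are skipped with a warning.
#'
#' @param path File path.
#' @param format \code{"tsv"} or \code{"obo"}.
#' @return A data frame with columns \code{hpo_id},
#'   \code{preferred_term} and a \code{synonyms} list-column.
#' @export
read_term_table <- function(path, format = c("tsv", "obo")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "tsv") {
    raw <- utils::read.delim(path, colClasses = "character",
                             check.names = FALSE, na.strings = NULL,
                             fileEncoding = "UTF-8")
    syn <- if ("synonyms" %in% names(raw)) {
      lapply(raw$synonyms, function(s) {
        out <- strsplit(s, "|", fixed = TRUE)[[1]]
        out[nzchar(out)]
      })
    } else {
      rep(list(character(0)), nrow(raw))
    }
    return(new_ontology(raw$hpo_id, raw$preferred_term, syn))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  ids <- character(0)
  names_ <- character(0)
  syns <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$id) || is.null(cur$name)) {
      warning("skipping [Term] stanza without id or name")
    } else {
      ids <<- c(ids, cur$id)
      names_ <<- c(names_, cur$name)
      syns[[length(syns) + 1]] <<- cur$syn
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      cur <- list(id = NULL, name = NULL, syn = character(0))
    } else if (startsWith(ln, "[")) {
      flush()
      cur <- NULL
    } else if (!is.null(cur)) {
      if (startsWith(ln, "id:")) {
        cur$id <- trimws(sub("^id:", "", ln))
      } else if (startsWith(ln, "name:")) {
        cur$name <- trimws(sub("^name:", "", ln))
      } else if (startsWith(ln, "synonym:")) {
        m <- regmatches(ln, regexpr('"[^"]*"', ln))
        if (length(m) == 1) {
          cur$syn <- c(cur$syn, substr(m, 2L, nchar(m) - 1L))
        }
      }
    }
  }
  flush()
  new_ontology(ids, names_, syns)
}

new_ontology <- function(hpo_id, preferred_term,
                         synonyms = rep(list(character(0)),
                                        length(hpo_id))) {
  stopifnot(!anyDuplicated(hpo_id), all(nzchar(preferred_term)))
  out <- data.frame(hpo_id = hpo_id, preferred_term = preferred_term,
                    stringsAsFactors = FALSE)
  out$synonyms <- synonyms
  out
}

#' Write an ontology term table
#'
#' @param ontology A term table as returned by
#'   \code{\link{read_term_table}}.
#' @param path Output path.
#' @param format \code{"tsv"} or \code{"obo"}.
#' @return \code{path}, invisibly.
#' @export
write_term_table <- function(ontology, path, format = c("tsv", "obo")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(hpo_id = ontology$hpo_id,
                     preferred_term = ontology$preferred_term,
                     synonyms = vapply(ontology$synonyms, paste,
                                       character(1), collapse = "|"),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(ontology))) {
      writeLines(c("[Term]", paste0("id: ", ontology$hpo_id[i]),
                   paste0("name: ", ontology$preferred_term[i]),
                   vapply(ontology$synonyms[[i]], function(s) {
                     paste0("synonym: \"", s, "\" EXACT []")
                   }, character(1)), ""), con)
    }
  }
  invisible(path)
}
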