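#' Default modifier lexicon
#'
#' Severity/degree words that annotation guidelines exclude from
#' entity boundaries; span-inconsistency detection flags surface forms
#' that differ only by these tokens at the edges.
#'
#' @return Character vector of lower-case modifier tokens.
#' @export
default_modifier_lexicon <- function() {
  c("mild", "mildly", "slightly", "slight", "prominent", "partial",
    "very")
}

annotation_surfaces <- function(annotations, observations) {
  texts <- observations$text[match(annotations$observation_id,
                                   observations$id)]
  vapply(seq_len(nrow(annotations)), function(i) {
    span_surface(annotations$spans[[i]], texts[i])
  }, character(1))
}

strip_edge_modifiers <- function(surface, lexicon) {
  toks <- strsplit(tolower(surface), "[[:space:]]+")[[1]]
  toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
  toks <- toks[nzchar(toks)]
  while (length(toks) > 0 && toks[1] %in% lexicon) {
    toks <- toks[-1]
  }
  while (length(toks) > 0 && toks[length(toks)] %in% lexicon) {
    toks <- toks[-length(toks)]
  }
  paste(toks, collapse = " ")
}

inconsistency_report <- function(kind, key, variants) {
  structure(list(kind = kind, key = key, variants = variants),
            class = "inconsistency_report")
}

#' @export
print.inconsistency_report <- function(x, ...) {
  cat(sprintf("<%s inconsistency> %s\n", x$kind, x$key))
  for (i in seq_len(nrow(x$variants))) {
    cat(sprintf("  %-40s n=%d  e.g. %s\n", x$variants$variant[i],
                x$variants$count[i], x$variants$example_id[i]))
  }
  invisible(x)
}

#' Detect span inconsistencies across a corpus
#'
#' For each HPO concept, groups the annotated surface forms and
#' reports concepts annotated with two or more surfaces that differ
#' only by leading/trailing modifier tokens (e.g. \code{"Prominent
#' infraorbital creases"} vs \code{"infraorbital creases"} under the
#' same id) — the tell-tale of inconsistent modifier inclusion in gold
#' boundaries. Repair is a manual-review activity; this function only
#' reports.
#'
#' @param annotations,observations A corpus' annotation and observation
#'   data frames.
#' @param modifier_lexicon Lower-case modifier tokens; default
#'   \code{\link{default_modifier_lexicon}()}.
#' @return A list of \code{inconsistency_report} objects (kind
#'   \code{"span"}), each with a \code{variants} data frame (variant,
#'   count, example_id) sorted by descending count.
#' @export
detect_span_inconsistencies <- function(annotations, observations,
                                        modifier_lexicon =
                                          default_modifier_lexicon()) {
  surfaces <- annotation_surfaces(annotations, observations)
  reports <- list()
  for (id in unique(annotations$hpo_id)) {
    idx <- which(annotations$hpo_id == id)
    forms <- unique(surfaces[idx])
    if (length(forms) < 2) {
      next
    }
    core <- vapply(forms, strip_edge_modifiers, character(1),
                   lexicon = modifier_lexicon)
    # inconsistent iff >=2 distinct surfaces share a stripped core
    for (ck in unique(core[duplicated(core)])) {
      group <- forms[core == ck]
      if (length(unique(tolower(group))) < 2) {
        next
      }
      variants <- do.call(rbind, lapply(group, function(f) {
        rows <- idx[surfaces[idx] == f]
        data.frame(variant = f, count = length(rows),
                   example_id = annotations$observation_id[rows[1]],
                   stringsAsFactors = FALSE)
      }))
      variants <- variants[order(-variants$count), , drop = FALSE]
      rownames(variants) <- NULL
      reports[[length(reports) + 1]] <-
        inconsistency_report("span", id, variants)
    }
  }
  reports
}

#' Detect concept inconsistencies across a corpus
#'
#' Reports every case-folded surface form that is mapped to two or
#' more distinct HPO ids across the corpus (close-match concepts
#' competing for one entity, e.g. \code{"excess nuchal skin"} split
#' between two neck-skin concepts). Variants are listed in descending
#' count order.
#'
#' @inheritParams detect_span_inconsistencies
#' @return A list of \code{inconsistency_report} objects (kind
#'   \code{"concept"}).
#' @export
detect_concept_inconsistencies <- function(annotations, observations) {
  surfaces <- tolower(annotation_surfaces(annotations, observations))
  reports <- list()
  for (sf in unique(surfaces)) {
    idx <- which(surfaces == sf)
    ids <- annotations$hpo_id[idx]
    if (length(unique(ids)) < 2) {
      next
    }
    variants <- do.call(rbind, lapply(unique(ids), function(id) {
      rows <- idx[ids == id]
      data.frame(variant = id, count = length(rows),
                 example_id = annotations$observation_id[rows[1]],
                 stringsAsFactors = FALSE)
    }))
    variants <- variants[order(-variants$count), , drop = FALSE]
    rownames(variants) <- NULL
    reports[[length(reports) + 1]] <-
      inconsistency_report("concept", sf, variants)
  }
  reports
}

#' Resolve concept inconsistencies
#'
#' Under the \code{"majority"} policy every variant id of an
#' inconsistent surface form is rewritten to that surface's most
#' frequent id; ties are left unchanged and flagged in the returned
#' \code{ties} attribute. Under \code{"manual_map"} a user-supplied
#' surface-to-id table (reviewed by a human) is applied instead.
#'
#' @param annotations,observations Corpus components.
#' @param reports Output of \code{\link{detect_concept_inconsistencies}}
#'   on the same corpus.
#' @param policy \code{"majority"} or \code{"manual_map"}.
#' @param manual_map Named character vector surface -> hpo_id
#'   (required for \code{"manual_map"}).
#' @return Updated annotations; attribute \code{ties} lists surfaces
#'   left unresolved under majority.
#' @export
resolve_concept_inconsistencies <- function(annotations, observations,
                                            reports,
                                            policy = c("majority",
                                                       "manual_map"),
                                            manual_map = NULL) {
  policy <- match.arg(policy)
  surfaces <- tolower(annotation_surfaces(annotations, observations))
  ties <- character(0)
  for (rep_ in reports) {
    if (rep_$kind != "concept") {
      next
    }
    target <- if (policy == "majority") {
      top <- rep_$variants$count == max(rep_$variants$count)
      if (sum(top) > 1) {
        ties <- c(ties, rep_$key)
        next
      }
      rep_$variants$variant[which.max(rep_$variants$count)]
    } else {
      if (is.null(manual_map) || !(rep_$key %in% names(manual_map))) {
        next
      }
      manual_map[[rep_$key]]
    }
    annotations$hpo_id[surfaces == rep_$key] <- target
  }
  attr(annotations, "ties") <- ties
  annotations
}

#' Define a concept merge rule
#'
#' When all \code{source_ids} co-occur within one observation, their
#' annotations are replaced by a single annotation of
#' \code{target_id} whose span set is the union of the sources'
#' segments (e.g. low-set ears + posteriorly rotated ears merged into
#' the combined low-set-and-posteriorly-rotated-ears concept).
#'
#' @param source_ids Two or more HPO ids that trigger the merge.
#' @param target_id The combined concept id.
#' @return A \code{merge_rule}.
#' @export
merge_rule <- function(source_ids, target_id) {
  stopifnot(length(source_ids) >= 2, !(target_id %in% source_ids))
  structure(list(source_ids = source_ids, target_id = target_id),
            class = "merge_rule")
}

#' Apply concept merge rules
#'
#' @param annotations Annotation data frame.
#' @param rules A list of \code{\link{merge_rule}} objects.
#' @return Updated annotations; overlapping segments after span union
#'   are coalesced.
#' @export
apply_merge_rules <- function(annotations, rules) {
  for (rule in rules) {
    for (obs_id in unique(annotations$observation_id)) {
      idx <- which(annotations$observation_id == obs_id &
                     annotations$hpo_id %in% rule$source_ids)
      if (!all(rule$source_ids %in% annotations$hpo_id[idx])) {
        next
      }
      merged <- Reduce(union_spans, annotations$spans[idx])
      keep_row <- idx[1]
      annotations$hpo_id[keep_row] <- rule$target_id
      annotations$spans[[keep_row]] <- merged
      annotations <- annotations[-idx[-1], , drop = FALSE]
    }
  }
  rownames(annotations) <- NULL
  annotations
}

#' Remove normal findings
#'
#' Drops every annotation with polarity \code{"normal"}; only abnormal
#' findings are scored in the task, and keeping normals would teach
#' the model to extract them.
#'
#' @param annotations Annotation data frame.
#' @return Annotations restricted to polarity \code{"abnormal"}.
#' @export
remove_normal_findings <- function(annotations) {
  out <- annotations[annotations$polarity == "abnormal", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full curation pass
#'
#' Concept-inconsistency resolution (majority policy), merge rules,
#' then normal-finding removal. Observation texts are never modified.
#' The pass is idempotent.
#'
#' @param corpus A list with \code{observations} and \code{annotations}.
#' @param merge_rules List of \code{\link{merge_rule}} objects.
#' @param policy Concept-resolution policy; see
#'   \code{\link{resolve_concept_inconsistencies}}.
#' @param manual_map Optional manual surface -> id map.
#' @return The corpus with curated annotations.
#' @export
curate_corpus <- function(corpus, merge_rules = list(),
                          policy = "majority", manual_map = NULL) {
  ann <- corpus$annotations
  reports <- detect_concept_inconsistencies(ann, corpus$observations)
  ann <- resolve_concept_inconsistencies(ann, corpus$observations,
                                         reports, policy, manual_map)
  attr(ann, "ties") <- NULL
  ann <- apply_merge_rules(ann, merge_rules)
  ann <- remove_normal_findings(ann)
  list(observations = corpus$observations, annotations = ann)
}

#' Write inconsistency reports as TSV
#'
#' @param reports List of \code{inconsistency_report} objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_inconsistency_reports <- function(reports, path) {
  rows <- do.call(rbind, lapply(reports, function(r) {
    data.frame(kind = r$kind, key = r$key, variant = r$variants$variant,
               count = r$variants$count,
               example_id = r$variants$example_id,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(kind = character(0), key = character(0),
                       variant = character(0), count = integer(0),
                       example_id = character(0))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
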