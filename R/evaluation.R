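#' Score predictions against gold annotations
#'
#' Micro-averaged precision/recall/F1 under one of the three
#' shared-task settings. Within each observation, predictions are
#' matched one-to-one to gold findings carrying the same HPO id;
#' the span condition depends on the setting: \code{strict} requires
#' identical span sets, \code{overlapping} at least one overlapping
#' character between any segments, \code{normalization_only} imposes
#' no span condition (id-only scoring). Matching is greedy with both
#' sides sorted by first span start (then id), which makes the counts
#' invariant to input order. Duplicate identical predictions are
#' deduplicated first; un-normalized predictions (no id) are excluded
#' from scoring by default, or counted as false positives in the span
#' settings when \code{count_unnormalized = TRUE}.
#'
#' @param gold Annotation data frame (abnormal findings only).
#' @param predictions Normalized prediction data frame with columns
#'   \code{observation_id}, \code{hpo_id}, and a \code{spans}
#'   list-column.
#' @param setting \code{"normalization_only"}, \code{"strict"} or
#'   \code{"overlapping"}.
#' @param observation_ids Ids of all scored observations; predictions
#'   referencing unknown observations are an error.
#' @param count_unnormalized Count id-less predictions as FP in the
#'   span settings.
#' @return An \code{eval_report}: setting, tp, fp, fn, precision,
#'   recall, f1.
#' @export
evaluate_predictions <- function(gold, predictions,
                                 setting = c("normalization_only",
                                             "strict", "overlapping"),
                                 observation_ids = NULL,
                                 count_unnormalized = FALSE) {
  setting <- match.arg(setting)
  if (!is.null(observation_ids)) {
    unknown <- setdiff(predictions$observation_id, observation_ids)
    if (length(unknown) > 0) {
      stop("predictions reference unknown observation(s): ",
           paste(utils::head(unknown, 3), collapse = ", "))
    }
  }

  has_id <- !is.na(predictions$hpo_id) & nzchar(predictions$hpo_id)
  pred <- predictions[has_id, , drop = FALSE]
  # deduplicate identical (observation, id, spans) predictions
  pkey <- paste(pred$observation_id, pred$hpo_id,
                vapply(pred$spans, serialize_spans, character(1)))
  pred <- pred[!duplicated(pkey), , drop = FALSE]

  tp <- 0L
  fp <- 0L
  fn <- 0L
  if (setting != "normalization_only" && count_unnormalized) {
    fp <- fp + sum(!has_id)
  }

  first_start <- function(spans) {
    if (nrow(spans) == 0) .Machine$integer.max else spans[1, "start"]
  }
  for (obs_id in unique(c(gold$observation_id, pred$observation_id))) {
    g <- gold[gold$observation_id == obs_id, , drop = FALSE]
    p <- pred[pred$observation_id == obs_id, , drop = FALSE]
    g_ord <- order(vapply(g$spans, first_start, integer(1)), g$hpo_id)
    p_ord <- order(vapply(p$spans, first_start, integer(1)), p$hpo_id)
    g <- g[g_ord, , drop = FALSE]
    p <- p[p_ord, , drop = FALSE]
    g_used <- rep(FALSE, nrow(g))
    for (i in seq_len(nrow(p))) {
      match_j <- 0L
      for (j in seq_len(nrow(g))) {
        if (g_used[j] || g$hpo_id[j] != p$hpo_id[i]) {
          next
        }
        ok <- switch(setting,
                     normalization_only = TRUE,
                     strict = spans_equal(g$spans[[j]], p$spans[[i]]),
                     overlapping = spans_overlap(g$spans[[j]],
                                                 p$spans[[i]]))
        if (ok) {
          match_j <- j
          break
        }
      }
      if (match_j > 0) {
        g_used[match_j] <- TRUE
        tp <- tp + 1L
      } else {
        fp <- fp + 1L
      }
    }
    fn <- fn + sum(!g_used)
  }
  eval_report(setting, tp, fp, fn)
}

eval_report <- function(setting, tp, fp, fn) {
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) {
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(setting = setting, tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, f1 = f1),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<%s> TP=%d FP=%d FN=%d  P=%.4f R=%.4f F1=%.4f\n",
              x$setting, x$tp, x$fp, x$fn, x$precision, x$recall,
              x$f1))
  invisible(x)
}

#' Score under all three settings
#'
#' @inheritParams evaluate_predictions
#' @return A named list of \code{eval_report}s:
#'   \code{normalization_only}, \code{overlapping}, \code{strict}.
#' @export
evaluate_all_settings <- function(gold, predictions,
                                  observation_ids = NULL,
                                  count_unnormalized = FALSE) {
  settings <- c("normalization_only", "overlapping", "strict")
  stats::setNames(lapply(settings, function(s) {
    evaluate_predictions(gold, predictions, s, observation_ids,
                         count_unnormalized)
  }), settings)
}

#' Write evaluation reports as JSON
#'
#' @param reports A list of \code{eval_report}s.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_eval_reports <- function(reports, path) {
  jsonlite::write_json(lapply(reports, unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
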