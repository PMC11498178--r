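#' Construct a span set
#'
#' A span set is the character-offset representation of a (possibly
#' discontinuous) entity mention: an integer matrix with columns
#' \code{start} and \code{end}, one row per contiguous segment, using
#' 0-based offsets with an exclusive end. Segments must be sorted by
#' start, non-overlapping, and non-empty.
#'
#' @param starts Integer vector of 0-based segment start offsets.
#' @param ends Integer vector of exclusive segment end offsets.
#' @return An integer matrix of class \code{span_set} with columns
#'   \code{start} and \code{end}; zero rows for an empty span set.
#' @examples
#' span_set(c(7, 20), c(13, 26))
#' @export
span_set <- function(starts = integer(0), ends = integer(0)) {
  starts <- as.integer(starts)
  ends <- as.integer(ends)
  if (length(starts) != length(ends)) {
    stop("starts and ends must have equal length")
  }
  m <- cbind(start = starts, end = ends)
  if (nrow(m) > 0) {
    if (any(m[, "start"] >= m[, "end"])) {
      stop("every segment must satisfy start < end")
    }
    o <- order(m[, "start"])
    m <- m[o, , drop = FALSE]
    if (nrow(m) > 1 && any(m[-1, "start"] < m[-nrow(m), "end"])) {
      stop("segments must not overlap")
    }
  }
  class(m) <- c("span_set", class(m))
  m
}

#' Validate a span set against its owning text
#'
#' @param spans A \code{span_set}.
#' @param text The observation text the offsets index into.
#' @return TRUE invisibly; errors when any offset is out of bounds.
#' @export
validate_spans <- function(spans, text) {
  if (nrow(spans) > 0 && any(spans[, "end"] > nchar(text))) {
    stop("span end exceeds text length (", nchar(text), ")")
  }
  invisible(TRUE)
}

#' Parse a printed span string
#'
#' Accepts the tabular rendering of a span set: \code{"start-end"} pairs
#' joined by commas, with either an en dash (U+2013) or an ASCII hyphen
#' between start and end. Offsets are 0-based with exclusive end.
#'
#' @param x A span string such as \code{"7–13, 20–26"}; the
#'   missing-value token \code{"NA"} or an empty string yields an empty
#'   span set.
#' @return A \code{span_set}.
#' @examples
#' parse_spans("14–23")
#' parse_spans("7-13, 20-26")
#' @export
parse_spans <- function(x) {
  if (is.na(x) || !nzchar(trimws(x)) || identical(trimws(x), "NA")) {
    return(span_set())
  }
  parts <- strsplit(trimws(x), ",")[[1]]
  starts <- integer(0)
  ends <- integer(0)
  for (p in parts) {
    seg <- strsplit(trimws(p), "–|-")[[1]]
    seg <- seg[nzchar(seg)]
    if (length(seg) != 2 || anyNA(suppressWarnings(as.integer(seg)))) {
      stop("malformed span segment: '", trimws(p), "'")
    }
    starts <- c(starts, as.integer(seg[1]))
    ends <- c(ends, as.integer(seg[2]))
  }
  span_set(starts, ends)
}

#' Serialize a span set to its printed form
#'
#' Inverse of \code{\link{parse_spans}}: emits \code{"start–end"}
#' pairs (en dash) joined by \code{", "}. The empty span set serializes
#' to the empty string.
#'
#' @param spans A \code{span_set}.
#' @return A single string.
#' @export
serialize_spans <- function(spans) {
  if (nrow(spans) == 0) {
    return("")
  }
  paste(paste0(spans[, "start"], "–", spans[, "end"]), collapse = ", ")
}

#' Extract the surface form a span set covers
#'
#' The observed term of a possibly discontinuous mention: the segment
#' substrings of \code{text}, joined by single spaces.
#'
#' @param spans A \code{span_set}.
#' @param text The owning observation text.
#' @return A single string ("" for an empty span set).
#' @export
span_surface <- function(spans, text) {
  if (nrow(spans) == 0) {
    return("")
  }
  paste(substring(text, spans[, "start"] + 1L, spans[, "end"]),
        collapse = " ")
}

# Merge two span sets, coalescing any segments that touch or overlap.
union_spans <- function(a, b) {
  m <- rbind(a, b)
  if (nrow(m) == 0) {
    return(span_set())
  }
  m <- m[order(m[, "start"]), , drop = FALSE]
  starts <- m[1, "start"]
  ends <- m[1, "end"]
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      k <- length(ends)
      if (m[i, "start"] <= ends[k]) {
        ends[k] <- max(ends[k], m[i, "end"])
      } else {
        starts <- c(starts, m[i, "start"])
        ends <- c(ends, m[i, "end"])
      }
    }
  }
  span_set(starts, ends)
}

spans_equal <- function(a, b) {
  nrow(a) == nrow(b) &&
    all(a[, "start"] == b[, "start"]) &&
    all(a[, "end"] == b[, "end"])
}

spans_overlap <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(FALSE)
  }
  for (i in seq_len(nrow(a))) {
    if (any(a[i, "start"] < b[, "end"] & b[, "start"] < a[i, "end"])) {
      return(TRUE)
    }
  }
  FALSE
}
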