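# Porter (1980) English suffix stemmer, implemented over per-word
# character vectors. Only lower-case ASCII words are meaningfully
# stemmed; anything else passes through after case folding.

# consonant test at position i (1-based) of character vector w:
# a,e,i,o,u are vowels; y is a vowel iff preceded by a consonant.
.p_cons <- function(w, i) {
  ch <- w[i]
  if (ch %in% c("a", "e", "i", "o", "u")) {
    return(FALSE)
  }
  if (ch == "y") {
    if (i == 1) {
      return(TRUE)
    }
    return(!.p_cons(w, i - 1))
  }
  TRUE
}

# measure m: number of VC sequences in [C](VC)^m[V]
.p_measure <- function(w) {
  n <- length(w)
  if (n == 0) {
    return(0L)
  }
  types <- vapply(seq_len(n), function(i) .p_cons(w, i), logical(1))
  m <- 0L
  i <- 1L
  while (i <= n && types[i]) i <- i + 1L            # leading consonants
  repeat {
    while (i <= n && !types[i]) i <- i + 1L         # vowels
    if (i > n) break
    while (i <= n && types[i]) i <- i + 1L          # consonants
    m <- m + 1L
  }
  m
}

.p_has_vowel <- function(w) {
  any(!vapply(seq_along(w), function(i) .p_cons(w, i), logical(1)))
}

.p_double_cons <- function(w) {
  n <- length(w)
  n >= 2 && w[n] == w[n - 1] && .p_cons(w, n)
}

# *o condition: stem ends consonant-vowel-consonant where the final
# consonant is not w, x or y
.p_cvc <- function(w) {
  n <- length(w)
  n >= 3 && .p_cons(w, n) && !.p_cons(w, n - 1) && .p_cons(w, n - 2) &&
    !(w[n] %in% c("w", "x", "y"))
}

.p_ends <- function(w, suffix) {
  s <- strsplit(suffix, "")[[1]]
  n <- length(w)
  k <- length(s)
  n >= k && all(w[(n - k + 1):n] == s)
}

.p_stem_part <- function(w, suffix) {
  w[seq_len(length(w) - nchar(suffix))]
}

# try rules in order; each rule = c(suffix, replacement); condition on
# the measure of the stem. Returns the new word or NULL if none fired.
.p_rule_set <- function(w, rules, min_m) {
  for (r in rules) {
    if (.p_ends(w, r[1])) {
      stem <- .p_stem_part(w, r[1])
      if (.p_measure(stem) > min_m) {
        return(c(stem, strsplit(r[2], "")[[1]]))
      }
      return(w)  # longest suffix matched but condition failed: stop
    }
  }
  NULL
}

.porter_one <- function(word) {
  w <- strsplit(word, "")[[1]]
  if (length(w) <= 2) {
    return(word)
  }

  # step 1a
  if (.p_ends(w, "sses")) {
    w <- c(.p_stem_part(w, "sses"), "s", "s")
  } else if (.p_ends(w, "ies")) {
    w <- c(.p_stem_part(w, "ies"), "i")
  } else if (!.p_ends(w, "ss") && .p_ends(w, "s")) {
    w <- .p_stem_part(w, "s")
  }

  # step 1b
  fired <- FALSE
  if (.p_ends(w, "eed")) {
    stem <- .p_stem_part(w, "eed")
    if (.p_measure(stem) > 0) {
      w <- c(stem, "e", "e")
    }
  } else if (.p_ends(w, "ed") && .p_has_vowel(.p_stem_part(w, "ed"))) {
    w <- .p_stem_part(w, "ed")
    fired <- TRUE
  } else if (.p_ends(w, "ing") && .p_has_vowel(.p_stem_part(w, "ing"))) {
    w <- .p_stem_part(w, "ing")
    fired <- TRUE
  }
  if (fired) {
    if (.p_ends(w, "at") || .p_ends(w, "bl") || .p_ends(w, "iz")) {
      w <- c(w, "e")
    } else if (.p_double_cons(w) && !(w[length(w)] %in% c("l", "s", "z"))) {
      w <- w[-length(w)]
    } else if (.p_measure(w) == 1 && .p_cvc(w)) {
      w <- c(w, "e")
    }
  }

  # step 1c
  if (.p_ends(w, "y") && .p_has_vowel(.p_stem_part(w, "y"))) {
    w <- c(.p_stem_part(w, "y"), "i")
  }

  # step 2 (m > 0)
  step2 <- list(c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
                c("anci", "ance"), c("izer", "ize"), c("abli", "able"),
                c("alli", "al"), c("entli", "ent"), c("eli", "e"),
                c("ousli", "ous"), c("ization", "ize"), c("ation", "ate"),
                c("ator", "ate"), c("alism", "al"), c("iveness", "ive"),
                c("fulness", "ful"), c("ousness", "ous"), c("aliti", "al"),
                c("iviti", "ive"), c("biliti", "ble"))
  step2 <- step2[order(-vapply(step2, function(r) nchar(r[1]), 1L))]
  out <- .p_rule_set(w, step2, 0L)
  if (!is.null(out)) w <- out

  # step 3 (m > 0)
  step3 <- list(c("icate", "ic"), c("ative", ""), c("alize", "al"),
                c("iciti", "ic"), c("ical", "ic"), c("ful", ""),
                c("ness", ""))
  out <- .p_rule_set(w, step3, 0L)
  if (!is.null(out)) w <- out

  # step 4 (m > 1); "ion" only when preceded by s or t
  step4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant",
             "ent", "ism", "ate", "iti", "ous", "ive", "ize", "ion",
             "al", "er", "ic", "ou")
  step4 <- step4[order(-nchar(step4))]
  for (s in step4) {
    if (.p_ends(w, s)) {
      stem <- .p_stem_part(w, s)
      ok <- .p_measure(stem) > 1 &&
        (s != "ion" || (length(stem) > 0 &&
                          stem[length(stem)] %in% c("s", "t")))
      if (ok) {
        w <- stem
      }
      break
    }
  }

  # step 5a
  if (.p_ends(w, "e")) {
    stem <- .p_stem_part(w, "e")
    m <- .p_measure(stem)
    if (m > 1 || (m == 1 && !.p_cvc(stem))) {
      w <- stem
    }
  }

  # step 5b
  if (.p_measure(w) > 1 && .p_double_cons(w) && w[length(w)] == "l") {
    w <- w[-length(w)]
  }

  paste(w, collapse = "")
}

#' Stem English words with the Porter algorithm
#'
#' The classic suffix-stripping stemmer used for dictionary key
#' normalization: it conflates inflectional variants
#' (\code{"flattened"}, \code{"flattening"}, \code{"flatten"}) onto one
#' stem so surface variation does not defeat exact dictionary lookup.
#' Input is case-folded first.
#'
#' @param words Character vector of single words.
#' @return Character vector of stems, same length.
#' @examples
#' porter_stem(c("caresses", "ponies", "flattened", "lashes"))
#' @export
porter_stem <- function(words) {
  vapply(tolower(words), .porter_one, character(1), USE.NAMES = FALSE)
}
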