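# evaluate expr under a fixed RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

tokenize_words <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

# deterministic 31-bit hash of a token (polynomial, base 31)
token_hash <- function(token) {
  bytes <- utf8ToInt(token)
  h <- 0
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

#' Deterministic hash-seeded token embedder
#'
#' Supplies a fixed-dimension vector per token by seeding a random
#' normal draw with a hash of the token: the same token always maps to
#' the same vector, in any session, with no model download. This is
#' the offline-testable default; any function with the same signature
#' (token vector in, matrix of row-vectors out) can stand in for a
#' pretrained word-vector model.
#'
#' @param dim Embedding dimension.
#' @return A function \code{(tokens) -> matrix} with one row per token.
#' @export
hash_embedder <- function(dim = 64L) {
  force(dim)
  cache <- new.env(parent = emptyenv())
  function(tokens) {
    out <- matrix(0, nrow = length(tokens), ncol = dim)
    for (i in seq_along(tokens)) {
      tok <- tokens[i]
      if (is.null(cache[[tok]])) {
        cache[[tok]] <- with_seed(token_hash(tok), stats::rnorm(dim))
      }
      out[i, ] <- cache[[tok]]
    }
    out
  }
}

#' Cosine similarity between two texts
#'
#' Each text is represented by the average of its token vectors; the
#' score is the cosine of the two averages, as in document-similarity
#' scoring over word embeddings. Texts with no embeddable tokens score
#' 0 against anything.
#'
#' @param a,b Texts to compare.
#' @param embedder A token-embedding provider; default
#'   \code{\link{hash_embedder}()}.
#' @return A score in [-1, 1].
#' @export
text_similarity <- function(a, b, embedder = hash_embedder()) {
  ta <- tokenize_words(a)
  tb <- tokenize_words(b)
  if (length(ta) == 0 || length(tb) == 0) {
    return(0)
  }
  va <- colMeans(embedder(ta))
  vb <- colMeans(embedder(tb))
  na <- sqrt(sum(va^2))
  nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) {
    return(0)
  }
  sum(va * vb) / (na * nb)
}

doc_vector <- function(text, embedder) {
  toks <- tokenize_words(text)
  if (length(toks) == 0) {
    return(NULL)
  }
  colMeans(embedder(toks))
}

#' Precompute document vectors for an example pool
#'
#' Attaches the mean token vector of every pool entry as an attribute
#' so repeated \code{\link{select_examples}} calls over the same pool
#' skip re-embedding. Purely an optimization; selection results are
#' identical.
#'
#' @param pool Output of \code{\link{build_example_pool}}.
#' @param embedder Token-embedding provider.
#' @return The pool with a \code{doc_vectors} attribute.
#' @export
precompute_pool_vectors <- function(pool, embedder = hash_embedder()) {
  attr(pool, "doc_vectors") <- lapply(pool, function(p) {
    doc_vector(p$user, embedder)
  })
  pool
}

#' Few-shot selection configuration
#'
#' The per-request example budget and its split: similarity-selected
#' positives, curated tricky examples for the query's organ system,
#' and most-similar negatives, 15 + 5 + 5 = 25 by default.
#'
#' @param k_similar Similar positive examples (default 15).
#' @param k_tricky Tricky examples (default 5).
#' @param k_negative Negative examples (default 5).
#' @param shuffle_seed Seed for the final shuffle.
#' @return A \code{selection_config}.
#' @export
selection_config <- function(k_similar = 15L, k_tricky = 5L,
                             k_negative = 5L, shuffle_seed = 1L) {
  structure(list(k_similar = as.integer(k_similar),
                 k_tricky = as.integer(k_tricky),
                 k_negative = as.integer(k_negative),
                 shuffle_seed = as.integer(shuffle_seed)),
            class = "selection_config")
}

fewshot_example <- function(user, assistant, category, source_id = "") {
  list(user = user, assistant = assistant, category = category,
       source_id = source_id)
}

#' Build a few-shot example pool from an annotated corpus
#'
#' Renders every observation as a (user, assistant) pair: user content
#' is the pre-processed text, assistant content the entity table of
#' its gold annotations. Observations keep an entity count so the
#' selector can split positives from negatives.
#'
#' @param corpus A list with \code{observations} and \code{annotations}
#'   (post-curation: abnormal findings only).
#' @param ontology Term table supplying preferred terms.
#' @return A list of pool entries (user, assistant, n_entities,
#'   source_id), in corpus order.
#' @export
build_example_pool <- function(corpus, ontology) {
  lookup <- stats::setNames(ontology$preferred_term, ontology$hpo_id)
  lapply(seq_len(nrow(corpus$observations)), function(i) {
    obs <- corpus$observations[i, ]
    ann <- corpus$annotations[
      corpus$annotations$observation_id == obs$id, , drop = FALSE]
    rec <- build_training_record(obs$text, ann, lookup)
    list(user = rec$messages[[2]]$content,
         assistant = rec$messages[[3]]$content,
         n_entities = nrow(ann), source_id = obs$id)
  })
}

#' Read or build a tricky-example registry
#'
#' A registry maps an organ-system header to its five curated examples
#' demonstrating task-specific behaviors (disjoint spans, modifier
#' exclusion, organ-header annotation). File format: TSV with columns
#' \code{organ_header}, \code{preferred_term}, \code{marked_text};
#' consecutive rows sharing header + marked_text become rows of one
#' example's entity table.
#'
#' @param path TSV path.
#' @return A named list: header -> list of examples (user, assistant).
#' @export
read_tricky_registry <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL,
                           fileEncoding = "UTF-8")
  stopifnot(all(c("organ_header", "preferred_term", "marked_text")
                %in% names(raw)))
  registry <- list()
  key <- paste(raw$organ_header, vapply(raw$marked_text, function(m) {
    recover_spans(m)$unmarked
  }, character(1)), sep = "\r")
  for (k in unique(key)) {
    rows <- raw[key == k, , drop = FALSE]
    header <- rows$organ_header[1]
    user <- recover_spans(rows$marked_text[1])$unmarked
    assistant <- render_entity_table(rows$preferred_term,
                                     rows$marked_text)
    registry[[header]] <- c(registry[[header]],
                            list(fewshot_example(user, assistant,
                                                 "tricky")))
  }
  registry
}

#' Select few-shot examples for one query
#'
#' The three-step per-request selection: (1) the \code{k_similar} pool
#' observations with at least one annotation most similar to the query
#' text; (2) the registry's \code{k_tricky} curated examples for the
#' query's organ-system header (falling back to
#' \code{default_tricky}); (3) the \code{k_negative} most similar pool
#' observations with zero annotations, teaching the no-findings output
#' format. The concatenated list is then shuffled
#' (seeded Fisher-Yates via the configured seed) to randomize category
#' positions. Top-k ties break by pool order; when a category pool
#' falls short all available members are taken.
#'
#' @param query_text Pre-processed query observation text.
#' @param pool Output of \code{\link{build_example_pool}}.
#' @param registry Tricky registry (named list header -> examples).
#' @param cfg A \code{\link{selection_config}}.
#' @param embedder Token-embedding provider for the similarity scores.
#' @param default_tricky Fallback tricky examples for unregistered
#'   headers.
#' @return An ordered list of examples (user, assistant, category,
#'   source_id); length is the budget when all pools suffice.
#' @export
select_examples <- function(query_text, pool, registry,
                            cfg = selection_config(),
                            embedder = hash_embedder(),
                            default_tricky = list()) {
  if (length(pool) == 0) {
    stop("example pool is empty")
  }
  n_entities <- vapply(pool, `[[`, numeric(1), "n_entities")
  pv <- attr(pool, "doc_vectors")
  qv <- doc_vector(query_text, embedder)
  sims <- if (is.null(pv)) {
    vapply(pool, function(p) {
      text_similarity(query_text, p$user, embedder)
    }, numeric(1))
  } else {
    vapply(pv, function(v) {
      if (is.null(v) || is.null(qv)) {
        return(0)
      }
      nq <- sqrt(sum(qv^2))
      nv <- sqrt(sum(v^2))
      if (nq == 0 || nv == 0) 0 else sum(qv * v) / (nq * nv)
    }, numeric(1))
  }

  top_k <- function(idx, k) {
    # stable by pool order among ties: order() is stable on the index
    idx[order(-sims[idx])][seq_len(min(k, length(idx)))]
  }
  pos_idx <- top_k(which(n_entities >= 1), cfg$k_similar)
  neg_idx <- top_k(which(n_entities == 0), cfg$k_negative)

  header <- organ_header(query_text)
  tricky_pool <- if (!is.null(registry[[header]])) {
    registry[[header]]
  } else {
    default_tricky
  }
  tricky <- tricky_pool[seq_len(min(cfg$k_tricky, length(tricky_pool)))]

  as_example <- function(i, category) {
    fewshot_example(pool[[i]]$user, pool[[i]]$assistant, category,
                    pool[[i]]$source_id)
  }
  out <- c(lapply(pos_idx, as_example, category = "similar_positive"),
           lapply(tricky, function(ex) {
             fewshot_example(ex$user, ex$assistant, "tricky",
                             if (is.null(ex$source_id)) "" else
                               ex$source_id)
           }),
           lapply(neg_idx, as_example, category = "negative"))
  shortfall <- (cfg$k_similar - length(pos_idx)) +
    (cfg$k_tricky - length(tricky)) + (cfg$k_negative - length(neg_idx))
  if (shortfall > 0) {
    message("few-shot shortfall: ", shortfall,
            " example(s) fewer than budget")
  }
  with_seed(cfg$shuffle_seed, out[sample.int(length(out))])
}
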