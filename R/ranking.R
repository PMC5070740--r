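# The four-component multiplicative score. A matching document d scores
#   S_d(q) = T_d(q)^a * N_d^b * Q_d^c * R_d^p
# where T is coordination-weighted TF-IDF, N penalizes entity-crowded
# documents, Q rewards high-impact journals and R decays with age; an entity
# scores S_e(q) = sum of S_d(q) over the documents containing both the query
# and the entity. All powers default to 1, which is the plain product; a
# power of 0 switches its component off.

#' Score-component weights
#'
#' Exponents applied to the four document-score components. The default of 1
#' for every component reproduces the plain product; raising `recency` to,
#' say, 4 weights freshness four times more, and 0 removes a component
#' entirely.
#'
#' @param term,entity_count,reputation,recency Non-negative exponents.
#' @return A `score_weights` list.
#' @export
score_weights <- function(term = 1, entity_count = 1, reputation = 1,
                          recency = 1) {
  w <- list(term = term, entity_count = entity_count,
            reputation = reputation, recency = recency)
  if (any(vapply(w, function(v) !is.numeric(v) || length(v) != 1L || v < 0,
                 logical(1)))) {
    abort("All score-weight powers must be non-negative scalars.")
  }
  structure(w, class = "score_weights")
}

#' Recency score
#'
#' Exponential decay halving every 24 months: a document published in the
#' reference month scores 1, a two-year-old one 0.5, and anything older than
#' 96 months sits at the floor 0.0625. Missing ages (undated documents) are
#' treated as the floor.
#'
#' @param age_months Document age in months (reference month minus
#'   publication month index); vectorized. Negative ages (future-dated
#'   documents) clamp to 0, `NA` to the 96-month cap.
#' @return Scores in \[0.0625, 1\].
#' @examples
#' recency_score(c(0, 24, 48, 120))
#' @export
recency_score <- function(age_months) {
  age <- ifelse(is.na(age_months), 96, pmin(pmax(age_months, 0), 96))
  0.5^(age / 24)
}

#' Journal reputation score
#'
#' Linear map of the journal impact factor onto \[1, 10\]:
#' `1 + IF / max(IF) * 9`. Articles in journals without an impact factor
#' score 1.
#'
#' @param impact_factor Vector of impact factors (`NA` = none).
#' @param max_if Maximum impact factor over the corpus.
#' @return Scores in \[1, 10\].
#' @export
reputation_score <- function(impact_factor, max_if) {
  if (max_if == 0) {
    if (any(!is.na(impact_factor) & impact_factor > 0)) {
      abort("max_if is 0 but a positive impact factor was supplied.")
    }
    return(rep(1, length(impact_factor)))
  }
  if (any(!is.na(impact_factor) & impact_factor > max_if)) {
    abort("impact_factor exceeds the corpus maximum `max_if`.")
  }
  ifelse(is.na(impact_factor) | impact_factor == 0, 1,
         1 + impact_factor / max_if * 9)
}

#' Entity-number score
#'
#' Documents mentioning many entities dilute the evidence each one gets:
#' `1 / min(|E_d|, 10)`, bounded below at 1/10.
#'
#' @param n_entities Number of distinct entities in the document (>= 1).
#' @return Scores in \[0.1, 1\].
#' @export
entity_number_score <- function(n_entities) {
  if (any(n_entities < 1L)) {
    abort("entity_number_score is undefined for documents with no entities.")
  }
  1 / pmin(n_entities, 10)
}

# idf dialect: 1 + ln(N / (df + 1)); contribution of a matched element is
# boost * sqrt(tf) * idf^2 (classic Lucene-style similarity, no norms)
idf_weight <- function(n_docs, df) {
  1 + log(n_docs / (df + 1))
}

# ---- query evaluation over the index ---------------------------------------

# count occurrences of a token subsequence in each document's token vector
phrase_tf <- function(index, doc_ids, ptoks) {
  toks <- index$documents$tokens[match(doc_ids, index$documents$doc_id)]
  vapply(toks, function(tk) {
    n <- length(tk); L <- length(ptoks)
    if (n < L) return(0L)
    hits <- which(tk == ptoks[1])
    if (L == 1L) return(length(hits))
    cnt <- 0L
    for (s in hits) {
      if (s + L - 1L <= n && all(tk[s:(s + L - 1L)] == ptoks)) cnt <- cnt + 1L
    }
    cnt
  }, integer(1))
}

# docs (character vector) matching a leaf
leaf_docs <- function(index, leaf) {
  if (leaf$kind == "term") {
    unique(index$terms$doc_id[index$terms$term == leaf$tokens])
  } else {
    cand <- NULL
    for (tt in leaf$tokens) {
      ids <- unique(index$terms$doc_id[index$terms$term == tt])
      cand <- if (is.null(cand)) ids else intersect(cand, ids)
      if (length(cand) == 0L) return(character())
    }
    cand[phrase_tf(index, cand, leaf$tokens) > 0L]
  }
}

# Boolean evaluation of a group node -> character vector of doc ids
eval_node <- function(index, node) {
  if (!is.null(node$leaf)) return(leaf_docs(index, node$leaf))
  should <- NULL; must <- NULL; must_not <- character()
  has_should <- FALSE; has_must <- FALSE
  for (cl in node$clauses) {
    ids <- eval_node(index, cl)
    if (identical(cl$occur, "MUST")) {
      must <- if (has_must) intersect(must, ids) else ids
      has_must <- TRUE
    } else if (identical(cl$occur, "MUST_NOT")) {
      must_not <- union(must_not, ids)
    } else {
      should <- union(should, ids)
      has_should <- TRUE
    }
  }
  base <- if (has_must) must else if (has_should) should else character()
  setdiff(base, must_not)
}

# per-document term-match data for all positive leaves:
# tibble(doc_id, n_matched, tfidf)
match_positive <- function(index, query) {
  stats <- corpus_stats(index)
  n_docs <- stats$n_docs
  rows <- purrr::map_dfr(query$positive, function(leaf) {
    ids <- leaf_docs(index, leaf)
    if (length(ids) == 0L) return(NULL)
    if (leaf$kind == "term") {
      tf <- index$terms$tf[index$terms$term == leaf$tokens][
        match(ids, index$terms$doc_id[index$terms$term == leaf$tokens])]
      df <- length(ids)
    } else {
      tf <- phrase_tf(index, ids, leaf$tokens)
      df <- length(ids)
    }
    idf <- idf_weight(n_docs, df)
    tibble(doc_id = ids,
           contrib = leaf$boost * sqrt(tf) * idf^2)
  })
  if (nrow(rows) == 0L) {
    return(tibble(doc_id = character(), n_matched = integer(),
                  tfidf = double()))
  }
  dplyr::summarise(dplyr::group_by(rows, .data$doc_id),
                   n_matched = dplyr::n(), tfidf = sum(.data$contrib),
                   .groups = "drop")
}

resolve_ref_month <- function(index, as_of) {
  if (is.null(as_of)) {
    mi <- index$documents$month_idx
    if (all(is.na(mi))) return(NA_integer_)
    return(max(mi, na.rm = TRUE))
  }
  if (is.character(as_of)) {
    parts <- as.integer(strsplit(as_of, "-")[[1]])
    if (length(parts) != 2L || any(is.na(parts))) {
      abort("`as_of` must be \"YYYY-MM\" or an integer month index.")
    }
    return(month_index(parts[1], parts[2]))
  }
  as.integer(as_of)
}

#' Term-match score of documents for a query
#'
#' `T_d(q) = coord(q, d) * tfidf(q, d)`, where `coord` is the fraction of
#' the query's positive elements the document matches (in (0, 1\]) and
#' `tfidf` sums `boost * sqrt(tf) * (1 + ln(N/(df+1)))^2` over the matched
#' elements. Only documents matching at least one positive element appear.
#'
#' @param index An `entrank_index`.
#' @param query An `entrank_query` or raw query string.
#' @return Tibble: `doc_id`, `coord`, `tfidf`, `term_score`.
#' @export
term_match_score <- function(index, query) {
  if (is.character(query)) query <- parse_query(query)
  m <- match_positive(index, query)
  nq <- length(query$positive)
  tibble(doc_id = m$doc_id, coord = m$n_matched / nq, tfidf = m$tfidf,
         term_score = m$n_matched / nq * m$tfidf)
}

#' Per-document score breakdown for a query
#'
#' Evaluates the Boolean clauses and year filter, drops documents without
#' entities, and reports every component and the combined score
#' `S_d = T^a N^b Q^c R^p`.
#'
#' @inheritParams term_match_score
#' @param weights A [score_weights()] object.
#' @param as_of Reference month for recency: `"YYYY-MM"`, an integer month
#'   index (year*12+month), or NULL for the newest publication month in the
#'   corpus.
#' @return Tibble: `doc_id`, `coord`, `tfidf`, `term_score`, `n_entities`,
#'   `entity_number`, `reputation`, `recency`, `score`.
#' @export
document_score <- function(index, query, weights = score_weights(),
                           as_of = NULL) {
  if (is.character(query)) query <- parse_query(query)
  stopifnot(inherits(index, "entrank_index"),
            inherits(weights, "score_weights"))
  stats <- corpus_stats(index)

  cand <- eval_node(index, query$clauses)
  docs <- index$documents[index$documents$doc_id %in% cand, , drop = FALSE]
  docs <- apply_year_filter(docs, query$year_filter)

  post <- index$postings[match(docs$doc_id, index$postings$doc_id), ,
                         drop = FALSE]
  n_ent <- lengths(post$entity_ids)
  docs <- docs[n_ent > 0L, , drop = FALSE]
  n_ent <- n_ent[n_ent > 0L]
  if (nrow(docs) == 0L) {
    return(tibble(doc_id = character(), coord = double(), tfidf = double(),
                  term_score = double(), n_entities = integer(),
                  entity_number = double(), reputation = double(),
                  recency = double(), score = double()))
  }

  tm <- term_match_score(index, query)
  tm <- tm[match(docs$doc_id, tm$doc_id), , drop = FALSE]
  ref <- resolve_ref_month(index, as_of)
  age <- if (is.na(ref)) rep(NA_real_, nrow(docs)) else ref - docs$month_idx

  comp <- tibble(
    doc_id = docs$doc_id,
    coord = tm$coord,
    tfidf = tm$tfidf,
    term_score = tm$term_score,
    n_entities = n_ent,
    entity_number = entity_number_score(n_ent),
    reputation = reputation_score(docs$impact_factor, stats$max_if),
    recency = recency_score(age)
  )
  comp$score <- comp$term_score^weights$term *
    comp$entity_number^weights$entity_count *
    comp$reputation^weights$reputation *
    comp$recency^weights$recency
  comp[!is.na(comp$term_score), , drop = FALSE]
}

#' Search an index for ranked entities
#'
#' The core retrieval operation: candidate documents are found through the
#' Boolean clauses and year filter, scored with the four-component document
#' score, and every entity accumulates the scores of the documents it
#' appears in (`S_e = sum over D_e of S_d`). Entities are then filtered by
#' type, ties broken by contributing-document count and then concept id, and
#' the top k returned.
#'
#' @inheritParams document_score
#' @param top_k Number of entities to return (>= 1).
#' @param type Optional entity-type filter (e.g. `"drug"`); overrides the
#'   query's own `type_filter`. An entity passes when any of its types
#'   matches.
#' @param explain If TRUE, attach the per-document component breakdown as
#'   attribute `"documents"`.
#' @return An `entrank_ranking` tibble: `rank`, `concept_id`, `name`,
#'   `group`, `score`, `n_docs`, `doc_ids` (list-column, contributing
#'   documents in descending document-score order).
#' @examples
#' fx <- generate_fixture(fixture_spec(n_docs = 30, seed = 7))
#' idx <- add_documents(entity_index(fx$dictionary), fx$corpus)
#' search_entities(idx, "q0", top_k = 5)
#' @export
search_entities <- function(index, query, top_k = 10,
                            weights = score_weights(), type = NULL,
                            as_of = NULL, explain = FALSE) {
  if (is.character(query)) query <- parse_query(query)
  if (!is.numeric(top_k) || length(top_k) != 1L || top_k < 1) {
    abort("`top_k` must be a positive integer.")
  }
  type <- type %||% query$type_filter

  comp <- document_score(index, query, weights = weights, as_of = as_of)
  pairs <- tidyr::unnest(
    dplyr::select(
      index$postings[index$postings$doc_id %in% comp$doc_id, , drop = FALSE],
      "doc_id", concept_id = "entity_ids"),
    "concept_id")
  ranking_skeleton <- function() {
    structure(
      tibble(rank = integer(), concept_id = character(), name = character(),
             group = character(), score = double(), n_docs = integer(),
             doc_ids = list()),
      class = c("entrank_ranking", "tbl_df", "tbl", "data.frame"),
      query = query, weights = weights)
  }
  if (nrow(pairs) == 0L) return(ranking_skeleton())

  pairs <- dplyr::left_join(pairs, comp[, c("doc_id", "score")],
                            by = "doc_id")
  meta <- dplyr::bind_rows(
    dplyr::select(index$dictionary$concepts, "concept_id", "name", "group",
                  "types"),
    index$entities
  )
  meta <- dplyr::distinct(meta, .data$concept_id, .keep_all = TRUE)

  pairs <- dplyr::arrange(pairs, dplyr::desc(.data$score), .data$doc_id)
  agg <- dplyr::summarise(
    dplyr::group_by(pairs, .data$concept_id),
    doc_ids = list(.data$doc_id),
    n_docs = dplyr::n(),
    score = sum(.data$score),
    .groups = "drop")
  agg <- dplyr::left_join(agg, meta, by = "concept_id")

  if (!is.null(type)) {
    keep <- vapply(agg$types, function(tt) any(tolower(tt) == tolower(type)),
                   logical(1))
    agg <- agg[keep, , drop = FALSE]
  }
  agg <- dplyr::arrange(agg, dplyr::desc(.data$score),
                        dplyr::desc(.data$n_docs), .data$concept_id)
  agg <- utils::head(agg, as.integer(top_k))
  out <- tibble(rank = seq_len(nrow(agg)), concept_id = agg$concept_id,
                name = agg$name, group = agg$group, score = agg$score,
                n_docs = agg$n_docs, doc_ids = agg$doc_ids)
  out <- structure(out,
                   class = c("entrank_ranking", class(tibble())),
                   query = query, weights = weights)
  if (explain) attr(out, "documents") <- comp
  out
}

#' @export
print.entrank_ranking <- function(x, ...) {
  q <- attr(x, "query")
  cat("# Entity ranking for: ", format_query(q), "\n", sep = "")
  NextMethod()
}
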