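# Independent brute-force oracles. They re-derive every quantity from the
# raw corpus with plain loops and their own tokenizer, sharing no code with
# the package's retrieval path.

oracle_tokens <- function(text) {
  m <- regmatches(text,
                  gregexpr("[A-Za-z0-9]+(?:-[A-Za-z0-9]+)*", text,
                           perl = TRUE))[[1]]
  tolower(m)
}

# Full re-scoring of a bag-of-terms query over a corpus whose per-document
# entity sets are known exactly (e.g. the fixture's gold annotations).
# Returns a data.frame ranked like search_entities().
oracle_search <- function(corpus, entity_sets, query_terms,
                          powers = c(term = 1, entity = 1, reputation = 1,
                                     recency = 1),
                          ref_month = NULL) {
  toks <- lapply(corpus$text, oracle_tokens)
  n <- nrow(corpus)
  month_idx <- ifelse(is.na(corpus$pub_year) | is.na(corpus$pub_month), NA,
                      corpus$pub_year * 12 + corpus$pub_month)
  if (is.null(ref_month)) ref_month <- max(month_idx, na.rm = TRUE)
  max_if <- suppressWarnings(max(corpus$impact_factor, na.rm = TRUE))
  if (!is.finite(max_if)) max_if <- 0

  df <- vapply(query_terms,
               function(t) sum(vapply(toks, function(tk) t %in% tk,
                                      logical(1))),
               numeric(1))

  scores <- numeric(0)    # named by concept id
  ndocs <- integer(0)
  for (i in seq_len(n)) {
    ents <- entity_sets[[i]]
    matched <- query_terms[vapply(query_terms,
                                  function(t) t %in% toks[[i]], logical(1))]
    if (length(matched) == 0 || length(ents) == 0) next
    coord <- length(matched) / length(query_terms)
    tfidf <- 0
    for (t in matched) {
      tf <- sum(toks[[i]] == t)
      idf <- 1 + log(n / (df[[t]] + 1))
      tfidf <- tfidf + sqrt(tf) * idf^2
    }
    Td <- coord * tfidf
    Nd <- 1 / min(length(ents), 10)
    IF <- corpus$impact_factor[i]
    Qd <- if (is.na(IF) || IF == 0 || max_if == 0) 1 else 1 + IF / max_if * 9
    age <- if (is.na(month_idx[i])) 96 else
      min(max(ref_month - month_idx[i], 0), 96)
    Rd <- 0.5^(age / 24)
    Sd <- Td^powers["term"] * Nd^powers["entity"] *
      Qd^powers["reputation"] * Rd^powers["recency"]
    for (e in ents) {
      scores[e] <- (if (e %in% names(scores)) scores[e] else 0) + Sd
      ndocs[e] <- (if (e %in% names(ndocs)) ndocs[e] else 0L) + 1L
    }
  }
  if (length(scores) == 0) {
    return(data.frame(concept_id = character(), score = numeric(),
                      n_docs = integer()))
  }
  out <- data.frame(concept_id = names(scores), score = unname(scores),
                    n_docs = unname(ndocs[names(scores)]),
                    stringsAsFactors = FALSE)
  out[order(-out$score, -out$n_docs, out$concept_id), , drop = FALSE]
}

# entity sets per document of a fixture, aligned with its corpus rows
oracle_entity_sets <- function(fx) {
  lapply(fx$corpus$doc_id, function(id) {
    unique(fx$gold$concept_id[fx$gold$doc_id == id])
  })
}

# brute-force dictionary matching: enumerate every surface occurrence on
# word boundaries, then greedy leftmost-longest selection
oracle_extract <- function(text, surfaces, concept_ids) {
  hits <- NULL
  for (i in seq_along(surfaces)) {
    pat <- paste0("(?<![A-Za-z0-9])",
                  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", surfaces[i]),
                  "(?![A-Za-z0-9])")
    m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    hits <- rbind(hits, data.frame(start = as.integer(m - 1),
                                   end = as.integer(m - 1 + len),
                                   concept_id = concept_ids[i]))
  }
  if (is.null(hits)) {
    return(data.frame(start = integer(), end = integer(),
                      concept_id = character()))
  }
  hits <- hits[order(hits$start, -hits$end, hits$concept_id), , drop = FALSE]
  keep <- NULL
  last_end <- -1
  for (r in seq_len(nrow(hits))) {
    if (hits$start[r] >= last_end) {
      keep <- c(keep, r)
      last_end <- hits$end[r]
    }
  }
  hits[keep, , drop = FALSE]
}
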