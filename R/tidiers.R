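# broom-style tidiers for the package's objects

#' Tidy an entity ranking
#'
#' @param x An `entrank_ranking` from [search_entities()].
#' @param ... Unused.
#' @return A plain tibble with one row per ranked entity.
#' @method tidy entrank_ranking
#' @export
tidy.entrank_ranking <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "query") <- NULL
  attr(out, "weights") <- NULL
  attr(out, "documents") <- NULL
  class(out) <- class(tibble())
  out
}

#' @rdname tidy.entrank_ranking
#' @method glance entrank_ranking
#' @export
glance.entrank_ranking <- function(x, ...) {
  docs <- unique(unlist(x$doc_ids))
  tibble(query = format_query(attr(x, "query")),
         n_entities = nrow(x),
         n_docs = length(docs),
         top_name = if (nrow(x) > 0) x$name[1] else NA_character_,
         top_score = if (nrow(x) > 0) x$score[1] else NA_real_)
}

#' Tidy a paired-posting index
#'
#' One row per document-entity pair (the exploded postings).
#'
#' @param x An `entrank_index`.
#' @param ... Unused.
#' @return Tibble: `doc_id`, `concept_id`.
#' @method tidy entrank_index
#' @export
tidy.entrank_index <- function(x, ...) {
  tidyr::unnest(
    dplyr::select(x$postings, "doc_id", concept_id = "entity_ids"),
    "concept_id")
}

#' @rdname tidy.entrank_index
#' @method glance entrank_index
#' @export
glance.entrank_index <- function(x, ...) {
  s <- corpus_stats(x)
  tibble(n_docs = s$n_docs, n_terms = s$n_terms,
         n_entities = s$n_entities, max_if = s$max_if)
}

#' Tidy a dictionary
#'
#' One row per surface name with its concept, group and types.
#'
#' @param x An `entrank_dictionary`.
#' @param ... Unused.
#' @return Tibble: `concept_id`, `name`, `group`, `types`, `surface`.
#' @method tidy entrank_dictionary
#' @export
tidy.entrank_dictionary <- function(x, ...) {
  tidyr::unnest(
    dplyr::select(x$concepts, "concept_id", "name", "group", "types",
                  surface = "names"),
    "surface")
}

#' @rdname tidy.entrank_dictionary
#' @method glance entrank_dictionary
#' @export
glance.entrank_dictionary <- function(x, ...) {
  tibble(n_concepts = nrow(x$concepts),
         n_surfaces = nrow(x$name_index),
         n_groups = dplyr::n_distinct(x$concepts$group))
}
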