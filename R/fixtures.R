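# Deterministic synthetic fixtures: corpora, dictionaries and gold
# annotations with planted structure. Filler vocabulary and entity surfaces
# are disjoint by construction, so extraction ground truth is exact and a
# collision-free fixture must give precision = recall = 1.

# run code under a fixed seed without disturbing the session RNG
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic corpus fixture
#'
#' All randomness is controlled by `seed`: two calls to
#' [generate_fixture()] with equal specs are identical.
#'
#' @param n_docs Number of documents.
#' @param n_concepts Named integer vector: concepts per priority group
#'   (`gene`, `chem`, `disease`, `pathway`).
#' @param vocab_size Filler-vocabulary size (tokens disjoint from entity
#'   surfaces).
#' @param mean_mentions Mean planted entity mentions per document (Poisson).
#' @param max_if Upper end of the uniform impact-factor distribution.
#' @param if_missing_rate Fraction of documents whose journal has no impact
#'   factor.
#' @param year_range Inclusive publication-year range.
#' @param topic NULL, or a list describing a planted query topic:
#'   `token` (the query term), `n_relevant` (how many concepts co-occur
#'   with it), `rate_relevant` (fraction of documents pairing the topic
#'   token with a relevant concept) and `rate_background` (probability any
#'   other document carries the bare topic token).
#' @param seed RNG seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_docs = 100,
                         n_concepts = c(gene = 8, chem = 6, disease = 5,
                                        pathway = 3),
                         vocab_size = 300,
                         mean_mentions = 2,
                         max_if = 30,
                         if_missing_rate = 0.3,
                         year_range = c(2008, 2016),
                         topic = list(token = "q0", n_relevant = 1,
                                      rate_relevant = 0.3,
                                      rate_background = 0.05),
                         seed = 42) {
  stopifnot(n_docs >= 1, all(n_concepts >= 0), sum(n_concepts) >= 1,
            vocab_size >= 10, mean_mentions >= 0, max_if >= 0,
            length(year_range) == 2L, year_range[1] <= year_range[2])
  structure(list(n_docs = n_docs, n_concepts = n_concepts,
                 vocab_size = vocab_size, mean_mentions = mean_mentions,
                 max_if = max_if, if_missing_rate = if_missing_rate,
                 year_range = year_range, topic = topic, seed = seed),
            class = "fixture_spec")
}

group_types_for <- function(short) {
  switch(short,
         gene = c("gene/protein", "target", "transcription factor", "miRNA"),
         chem = c("chemical compound", "drug", "toxin"),
         disease = "disease",
         pathway = "pathway")
}

#' Generate a synthetic corpus, dictionary and gold annotations
#'
#' Concepts carry 1-3 synonym surfaces drawn from a vocabulary disjoint from
#' the filler tokens (and a shared cross-reference id per concept, so the
#' dictionary build exercises synonym merging). Documents are filler tokens
#' with entity surfaces planted at recorded character offsets. When
#' `spec$topic` is set, a topic token is planted so that the designated
#' relevant concepts co-occur with it far more often than background
#' concepts, and ranked retrieval for that token should recover them.
#'
#' @param spec A [fixture_spec()].
#' @return A list: `records` (source records), `dictionary` (built
#'   `entrank_dictionary`), `corpus` (document tibble), `gold` (mention
#'   tibble with `doc_id`), `relevant` (character vector of the planted
#'   relevant concept names; empty when no topic), `topic_token`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  local_seed(spec$seed, {
    n_total <- sum(spec$n_concepts)
    # surface token pool, disjoint from filler ("w...") and topic tokens
    surface_pool <- sprintf("ent%04dx", seq_len(n_total * 8))
    pool_i <- 0L
    next_token <- function() {
      pool_i <<- pool_i + 1L
      if (pool_i > length(surface_pool)) {
        abort("Vocabulary too small to keep surfaces collision-free.")
      }
      surface_pool[pool_i]
    }
    filler <- sprintf("w%03d", seq_len(spec$vocab_size))

    groups <- rep(names(spec$n_concepts), spec$n_concepts)
    records <- purrr::map_dfr(seq_along(groups), function(i) {
      g <- groups[i]
      n_syn <- sample(1:3, 1)
      surfaces <- vapply(seq_len(n_syn), function(j) {
        if (j > 1L && stats::runif(1) < 0.25) {
          paste(next_token(), next_token())    # a two-token synonym
        } else next_token()
      }, character(1))
      types <- sample(group_types_for(g), n_syn, replace = TRUE)
      tibble(source = paste0("src", (i %% 3) + 1L),
             surface = surfaces, entity_type = types,
             xrefs = sprintf("X%04d", i))
    })
    dict <- merge_records(records)

    # map each concept to its surfaces for planting
    concept_ids <- dict$concepts$concept_id
    surfaces_of <- stats::setNames(dict$concepts$names, concept_ids)

    topic <- spec$topic
    relevant_ids <- character()
    topic_docs <- integer()
    if (!is.null(topic)) {
      relevant_ids <- utils::head(concept_ids, topic$n_relevant)
      n_topic <- round(topic$rate_relevant * spec$n_docs)
      topic_docs <- if (n_topic > 0)
        sample(spec$n_docs, min(n_topic, spec$n_docs)) else integer()
    }

    docs <- vector("list", spec$n_docs)
    gold <- vector("list", spec$n_docs)
    for (d in seq_len(spec$n_docs)) {
      n_mentions <- stats::rpois(1, spec$mean_mentions)
      planted_ids <- if (n_mentions > 0)
        sample(concept_ids, min(n_mentions, length(concept_ids))) else
          character()
      extra <- character()
      if (!is.null(topic)) {
        if (d %in% topic_docs) {
          planted_ids <- union(planted_ids,
                               sample(relevant_ids, 1))
          extra <- topic$token
        } else {
          planted_ids <- setdiff(planted_ids, relevant_ids)
          if (stats::runif(1) < topic$rate_background) extra <- topic$token
        }
      }
      planted_surfaces <- unname(vapply(planted_ids, function(cid) {
        s <- surfaces_of[[cid]]
        s[sample(length(s), 1)]
      }, character(1)))

      n_fill <- sample(8:15, 1)
      pieces <- c(sample(filler, n_fill, replace = TRUE), extra,
                  planted_surfaces)
      is_mention <- c(rep(FALSE, n_fill + length(extra)),
                      rep(TRUE, length(planted_surfaces)))
      ord <- sample(length(pieces))
      pieces <- pieces[ord]; is_mention <- is_mention[ord]
      # track offsets while joining with single spaces
      starts <- cumsum(c(0L, nchar(pieces[-length(pieces)]) + 1L))
      text <- paste(pieces, collapse = " ")
      mention_idx <- which(is_mention)
      # map pieces back to the concept that produced them
      piece_concept <- rep(NA_character_, length(pieces))
      piece_concept[is_mention] <- planted_ids[match(pieces[is_mention],
                                                     planted_surfaces)]
      gold[[d]] <- tibble(
        doc_id = sprintf("d%04d", d),
        concept_id = piece_concept[mention_idx],
        start = starts[mention_idx],
        end = starts[mention_idx] + nchar(pieces[mention_idx]),
        surface = pieces[mention_idx])
      docs[[d]] <- tibble(
        doc_id = sprintf("d%04d", d),
        text = text,
        journal = sprintf("J%02d", sample(12, 1)),
        impact_factor = if (stats::runif(1) < spec$if_missing_rate)
          NA_real_ else stats::runif(1, 0, spec$max_if),
        pub_year = sample(spec$year_range[1]:spec$year_range[2], 1),
        pub_month = sample(12, 1))
    }
    list(records = records,
         dictionary = dict,
         corpus = dplyr::bind_rows(docs),
         gold = dplyr::bind_rows(gold),
         relevant = unname(vapply(relevant_ids, function(cid)
           surfaces_of[[cid]][1], character(1))),
         relevant_ids = relevant_ids,
         topic_token = if (is.null(topic)) NULL else topic$token)
  })
}

#' Two-cohort corpus for recency-power experiments
#'
#' Builds an old cohort (default age 100 months, beyond the 96-month recency
#' floor window) whose documents carry concept "OLDCPT" and a new cohort
#' (age 0) carrying "NEWCPT", with identical document counts, identical
#' filler text and no impact factors, all containing the query token. With
#' the recency power at 0 the two concepts tie exactly; with positive power
#' the new concept outranks the old by the recency ratio raised to that
#' power.
#'
#' @param n_per_cohort Documents per cohort.
#' @param age_old,age_new Cohort ages in months relative to the reference
#'   month.
#' @param ref_year,ref_month Reference (query-time) year and month.
#' @param seed RNG seed (used only for journal names).
#' @return A list: `records`, `dictionary`, `corpus`, `query`,
#'   `concept_old`, `concept_new`, `ref` (`"YYYY-MM"` string),
#'   `recency_old`, `recency_new`.
#' @export
cohort_fixture <- function(n_per_cohort = 10, age_old = 100, age_new = 0,
                           ref_year = 2016, ref_month = 6, seed = 1) {
  stopifnot(n_per_cohort >= 1, age_old > 96, age_new < 12)
  ref_idx <- month_index(ref_year, ref_month)
  records <- tibble(
    source = "synth",
    surface = c("oldcohorttoken", "newcohorttoken"),
    entity_type = "drug",
    xrefs = c("XOLD", "XNEW"))
  dict <- merge_records(records)
  mk_docs <- function(prefix, surface, age) {
    idx <- as.integer(ref_idx - age)
    mo <- idx %% 12L
    yr <- idx %/% 12L
    if (mo == 0L) { mo <- 12L; yr <- yr - 1L }
    tibble(doc_id = sprintf("%s%03d", prefix, seq_len(n_per_cohort)),
           text = paste("q0", surface, "w001 w002 w003"),
           journal = NA_character_,
           impact_factor = NA_real_,
           pub_year = yr,
           pub_month = mo)
  }
  old_docs <- mk_docs("old", "oldcohorttoken", age_old)
  new_docs <- mk_docs("new", "newcohorttoken", age_new)
  corpus <- dplyr::bind_rows(old_docs, new_docs)
  id_of <- function(surface) {
    ni <- dict$name_index
    ni$concept_id[ni$folded == surface]
  }
  list(records = records, dictionary = dict, corpus = corpus,
       query = "q0",
       concept_old = id_of("oldcohorttoken"),
       concept_new = id_of("newcohorttoken"),
       ref = sprintf("%d-%02d", ref_year, ref_month),
       recency_old = recency_score(age_old),
       recency_new = recency_score(age_new))
}
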