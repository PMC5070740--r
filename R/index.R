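# Paired-posting inverted index: every token of every document is a key
# pointing at the document's single posting <doc_id, [entity ids]>; corpus
# statistics (N, df, tf, max impact factor) feed the ranking components.

month_index <- function(year, month) {
  as.integer(year) * 12L + as.integer(month)
}

#' Create an empty paired-posting index
#'
#' @param dict An `entrank_dictionary` used to tag every added document.
#' @return An `entrank_index` object holding documents, postings (one per
#'   document: its id plus the distinct entity concepts found in it), the
#'   term table (term, doc, in-document frequency) and entity metadata.
#' @seealso [add_documents()], [search_entities()]
#' @export
entity_index <- function(dict) {
  stopifnot(inherits(dict, "entrank_dictionary"))
  structure(
    list(
      dictionary = dict,
      documents = tibble(doc_id = character(), text = character(),
                         journal = character(), impact_factor = double(),
                         pub_year = integer(), pub_month = integer(),
                         month_idx = integer(), date_missing = logical(),
                         tokens = list()),
      postings = tibble(doc_id = character(), entity_ids = list()),
      terms = tibble(term = character(), doc_id = character(),
                     tf = integer()),
      entities = tibble(concept_id = character(), name = character(),
                        group = character(), types = list())
    ),
    class = "entrank_index"
  )
}

normalize_corpus <- function(docs) {
  docs <- as_tibble(docs)
  if (!all(c("doc_id", "text") %in% names(docs))) {
    abort("`docs` needs at least columns `doc_id` and `text`.")
  }
  defaults <- list(journal = NA_character_, impact_factor = NA_real_,
                   pub_year = NA_integer_, pub_month = NA_integer_)
  for (col in names(defaults)) {
    if (!col %in% names(docs)) docs[[col]] <- defaults[[col]]
  }
  docs$doc_id <- as.character(docs$doc_id)
  docs$text <- ifelse(is.na(docs$text), "", as.character(docs$text))
  docs$journal <- as.character(docs$journal)
  docs$impact_factor <- as.double(docs$impact_factor)
  docs$pub_year <- as.integer(docs$pub_year)
  docs$pub_month <- as.integer(docs$pub_month)
  bad_month <- !is.na(docs$pub_month) &
    (docs$pub_month < 1L | docs$pub_month > 12L)
  if (any(bad_month)) {
    abort(paste0("pub_month out of 1..12 for doc(s): ",
                 paste(docs$doc_id[bad_month], collapse = ", ")))
  }
  if (any(!is.na(docs$impact_factor) & docs$impact_factor < 0)) {
    abort("impact_factor must be non-negative.")
  }
  docs$date_missing <- is.na(docs$pub_year) | is.na(docs$pub_month)
  docs$month_idx <- ifelse(docs$date_missing, NA_integer_,
                           month_index(docs$pub_year, docs$pub_month))
  docs
}

#' Add documents to a paired-posting index
#'
#' Each document's text is tokenized; entity and mutation mentions are
#' extracted; the document gets exactly one posting carrying its distinct
#' entity ids; and every token becomes (or extends) a term key pointing at
#' that posting. Adding in several batches yields exactly the same index as
#' one batch. Documents with a missing publication date are accepted but
#' flagged (they score at the recency floor).
#'
#' @param index An `entrank_index`.
#' @param docs Data frame with columns `doc_id`, `text` and optionally
#'   `journal`, `impact_factor`, `pub_year`, `pub_month`.
#' @return The updated index; an error (index unchanged) on duplicate ids.
#' @export
add_documents <- function(index, docs) {
  stopifnot(inherits(index, "entrank_index"))
  docs <- normalize_corpus(docs)
  if (nrow(docs) == 0L) return(index)
  dup <- docs$doc_id[docs$doc_id %in% index$documents$doc_id |
                       duplicated(docs$doc_id)]
  if (length(dup) > 0L) {
    abort(paste0("Duplicate doc_id(s): ", paste(unique(dup), collapse = ", ")))
  }
  if (any(docs$date_missing)) {
    warn(paste0(sum(docs$date_missing),
                " document(s) lack a publication date; ",
                "they will score at the recency floor."))
  }

  docs$tokens <- tokenize(docs$text)
  mention_sets <- lapply(docs$text, extract_all_mentions,
                         dict = index$dictionary)
  entity_ids <- lapply(mention_sets, function(m) unique(m$concept_id))

  new_terms <- purrr::map2_dfr(docs$tokens, docs$doc_id, function(tok, id) {
    if (length(tok) == 0L) return(NULL)
    tt <- table(tok)
    tibble(term = names(tt), doc_id = id, tf = as.integer(tt))
  })

  # entity metadata for mutation concepts discovered on the fly
  mut <- dplyr::bind_rows(mention_sets)
  mut <- mut[startsWith(mut$concept_id, "MUT:"), , drop = FALSE]
  new_entities <- index$entities
  if (nrow(mut) > 0L) {
    mut_meta <- dplyr::distinct(
      tibble(concept_id = mut$concept_id,
             name = toupper(mut$surface),
             group = "mutation_group",
             types = list("mutation")),
      .data$concept_id, .keep_all = TRUE
    )
    new_entities <- dplyr::distinct(
      dplyr::bind_rows(new_entities, mut_meta),
      .data$concept_id, .keep_all = TRUE
    )
  }

  index$documents <- dplyr::arrange(
    dplyr::bind_rows(index$documents, docs[, names(index$documents)]),
    .data$doc_id
  )
  index$postings <- dplyr::arrange(
    dplyr::bind_rows(index$postings,
                     tibble(doc_id = docs$doc_id, entity_ids = entity_ids)),
    .data$doc_id
  )
  index$terms <- dplyr::arrange(
    dplyr::bind_rows(index$terms, new_terms),
    .data$term, .data$doc_id
  )
  index$entities <- dplyr::arrange(new_entities, .data$concept_id)
  index
}

#' Retrieve the paired postings for a term
#'
#' @param index An `entrank_index`.
#' @param term A normalized (lowercased) token.
#' @return Tibble of postings (`doc_id`, `entity_ids` list-column) for
#'   exactly the documents containing the term; zero rows for unknown terms.
#' @export
retrieve_postings <- function(index, term) {
  stopifnot(inherits(index, "entrank_index"), length(term) == 1L)
  ids <- index$terms$doc_id[index$terms$term == term]
  index$postings[index$postings$doc_id %in% ids, , drop = FALSE]
}

#' Corpus statistics backing the ranking function
#'
#' @param index An `entrank_index`.
#' @return A list: `n_docs` (N), `df` (tibble term/df), `max_if` (maximum
#'   journal impact factor in the corpus, 0 if none recorded), `n_terms`,
#'   `n_entities`.
#' @export
corpus_stats <- function(index) {
  stopifnot(inherits(index, "entrank_index"))
  df <- dplyr::count(index$terms, .data$term, name = "df")
  max_if <- if (all(is.na(index$documents$impact_factor))) 0 else
    max(index$documents$impact_factor, na.rm = TRUE)
  ents <- unique(unlist(index$postings$entity_ids))
  list(n_docs = nrow(index$documents), df = df, max_if = max_if,
       n_terms = nrow(df), n_entities = length(ents))
}

#' @export
print.entrank_index <- function(x, ...) {
  s <- corpus_stats(x)
  cat("<entrank_index> ", s$n_docs, " documents, ", s$n_terms,
      " terms, ", s$n_entities, " entities (max IF ",
      format(s$max_if), ")\n", sep = "")
  invisible(x)
}

# term -> document frequency; 0 for unknown terms
term_df <- function(index, terms) {
  df <- dplyr::count(index$terms[index$terms$term %in% terms, , drop = FALSE],
                     .data$term, name = "df")
  out <- stats::setNames(rep(0L, length(terms)), terms)
  out[df$term] <- df$df
  out
}

#' Read a line-delimited corpus file
#'
#' Tab-separated with header `id`, `text`, `journal`, `impact_factor`,
#' `year`, `month`; empty fields mean missing.
#'
#' @param path File path.
#' @return A corpus tibble for [add_documents()].
#' @export
read_corpus <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       na = c("", "NA"), progress = FALSE)
  required <- c("id", "text")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    abort(paste0("Corpus file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tibble(doc_id = x$id,
         text = ifelse(is.na(x$text), "", x$text),
         journal = x[["journal"]] %||% NA_character_,
         impact_factor = as.double(x[["impact_factor"]] %||% NA),
         pub_year = as.integer(x[["year"]] %||% NA),
         pub_month = as.integer(x[["month"]] %||% NA))
}

#' Write a corpus tibble in the line-delimited format
#'
#' @param docs Corpus tibble (`doc_id`, `text`, ...).
#' @param path File path.
#' @export
write_corpus <- function(docs, path) {
  docs <- normalize_corpus(docs)
  out <- tibble(id = docs$doc_id, text = docs$text, journal = docs$journal,
                impact_factor = docs$impact_factor, year = docs$pub_year,
                month = docs$pub_month)
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read MEDLINE citation XML into a corpus tibble
#'
#' Maps PMID to `doc_id`, ArticleTitle + AbstractText to `text`, the journal
#' title to `journal` and PubDate to `pub_year`/`pub_month`. Impact factors
#' are not part of MEDLINE records; supply them as a `journal` -> `IF` table.
#'
#' @param path Path to a MedlineCitationSet XML file.
#' @param impact_factors Optional data frame with columns `journal` and
#'   `impact_factor` (or a path to such a TSV).
#' @return A corpus tibble for [add_documents()].
#' @export
read_medline_xml <- function(path, impact_factors = NULL) {
  doc <- xml2::read_xml(path)
  cites <- xml2::xml_find_all(doc, ".//MedlineCitation")
  month_names <- stats::setNames(1:12, tolower(month.abb))
  rows <- purrr::map_dfr(cites, function(cite) {
    pmid <- xml2::xml_text(xml2::xml_find_first(cite, ".//PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(cite,
                                                 ".//Article/ArticleTitle"))
    abst <- paste(xml2::xml_text(
      xml2::xml_find_all(cite, ".//Article/Abstract/AbstractText")),
      collapse = " ")
    journal <- xml2::xml_text(xml2::xml_find_first(cite,
                                                   ".//Journal/Title"))
    yr <- xml2::xml_text(xml2::xml_find_first(
      cite, ".//Journal/JournalIssue/PubDate/Year"))
    mo <- xml2::xml_text(xml2::xml_find_first(
      cite, ".//Journal/JournalIssue/PubDate/Month"))
    mo_num <- suppressWarnings(as.integer(mo))
    if (is.na(mo_num) && !is.na(mo)) {
      mo_num <- unname(month_names[tolower(substr(mo, 1, 3))])
    }
    tibble(doc_id = pmid,
           text = stringr::str_squish(paste(title, abst)),
           journal = journal,
           impact_factor = NA_real_,
           pub_year = suppressWarnings(as.integer(yr)),
           pub_month = mo_num)
  })
  if (!is.null(impact_factors)) {
    if (is.character(impact_factors)) {
      impact_factors <- readr::read_tsv(
        impact_factors,
        col_types = readr::cols(journal = "c", impact_factor = "d"),
        progress = FALSE)
    }
    rows$impact_factor <- impact_factors$impact_factor[
      match(rows$journal, impact_factors$journal)]
  }
  rows
}

#' Persist and restore an index directory
#'
#' Writes `documents.tsv`, `postings.tsv`, `terms.tsv`, `dictionary.tsv` and
#' `stats.json` as line-delimited records; bit-reproducible given identical
#' inputs. `read_index()` restores an equivalent index.
#'
#' @param index An `entrank_index`.
#' @param dir Directory path (created if needed).
#' @return `read_index()` returns the restored `entrank_index`.
#' @export
write_index <- function(index, dir) {
  stopifnot(inherits(index, "entrank_index"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  docs <- index$documents
  write_corpus(docs[, c("doc_id", "text", "journal", "impact_factor",
                        "pub_year", "pub_month")],
               file.path(dir, "documents.tsv"))
  readr::write_tsv(
    tibble(doc_id = index$postings$doc_id,
           entity_ids = vapply(index$postings$entity_ids, paste,
                               character(1), collapse = "|")),
    file.path(dir, "postings.tsv"), na = "", progress = FALSE)
  readr::write_tsv(index$terms, file.path(dir, "terms.tsv"),
                   progress = FALSE)
  write_dictionary(index$dictionary, file.path(dir, "dictionary.tsv"))
  s <- corpus_stats(index)
  jsonlite::write_json(list(n_docs = s$n_docs, max_if = s$max_if,
                            n_terms = s$n_terms, n_entities = s$n_entities),
                       file.path(dir, "stats.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_index
#' @export
read_index <- function(dir) {
  dict <- read_dictionary(file.path(dir, "dictionary.tsv"))
  idx <- entity_index(dict)
  docs <- read_corpus(file.path(dir, "documents.tsv"))
  suppressWarnings(add_documents(idx, docs))
}
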