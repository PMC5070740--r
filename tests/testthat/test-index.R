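index_core <- function(index) {
  list(docs = index$documents[, c("doc_id", "text", "journal",
                                  "impact_factor", "pub_year", "pub_month")],
       postings = index$postings,
       terms = index$terms,
       entities = index$entities)
}

test_that("a document becomes one posting keyed by all of its terms", {
  d <- demo_dictionary()
  idx <- add_documents(entity_index(d), tibble::tibble(
    doc_id = "24524212", text = cml_sentence(),
    journal = "J", impact_factor = 2, pub_year = 2014, pub_month = 2))
  p <- idx$postings
  expect_equal(nrow(p), 1L)
  expect_length(p$entity_ids[[1]], 2L)
  expect_setequal(p$entity_ids[[1]],
                  c(concept_of(d, "imatinib"),
                    concept_of(d, "chronic myeloid leukemia")))
  for (term in c("consistent", "use", "imatinib", "critical", "treatment",
                 "success", "of", "in")) {   # stop words stay indexed
    expect_equal(retrieve_postings(idx, term)$doc_id, "24524212")
  }
})

test_that("adding zero documents leaves the index unchanged", {
  idx <- entity_index(demo_dictionary())
  idx2 <- add_documents(idx, tibble::tibble(doc_id = character(),
                                            text = character()))
  expect_identical(index_core(idx2), index_core(idx))
  s <- corpus_stats(idx2)
  expect_equal(s$n_docs, 0L)
  expect_equal(nrow(s$df), 0L)
})

test_that("duplicate doc ids are rejected and the index is untouched", {
  idx <- quiet_add(entity_index(demo_dictionary()),
                   tibble::tibble(doc_id = "d1", text = "imatinib works"))
  expect_error(add_documents(idx, tibble::tibble(doc_id = "d1",
                                                 text = "again")),
               "Duplicate")
  expect_equal(corpus_stats(idx)$n_docs, 1L)
  expect_error(add_documents(entity_index(demo_dictionary()),
                             tibble::tibble(doc_id = c("a", "a"),
                                            text = c("x", "y"))),
               "Duplicate")
})

test_that("incremental batches equal one scratch-built batch", {
  fx <- generate_fixture(fixture_spec(n_docs = 20, seed = 17))
  one <- quiet_add(entity_index(fx$dictionary), fx$corpus)
  two <- quiet_add(quiet_add(entity_index(fx$dictionary),
                             fx$corpus[1:10, ]), fx$corpus[11:20, ])
  expect_identical(index_core(two), index_core(one))
  expect_identical(corpus_stats(two), corpus_stats(one))
})

test_that("insertion order never changes the index or the ranking", {
  fx <- generate_fixture(fixture_spec(n_docs = 20, seed = 19))
  a <- quiet_add(entity_index(fx$dictionary), fx$corpus)
  set.seed(1)
  b <- quiet_add(entity_index(fx$dictionary),
                 fx$corpus[sample(nrow(fx$corpus)), ])
  expect_identical(index_core(b), index_core(a))
  ra <- tidy(search_entities(a, "q0", top_k = 10))
  rb <- tidy(search_entities(b, "q0", top_k = 10))
  expect_equal(rb, ra)
})

test_that("retrieval returns exactly the documents holding a term", {
  d <- merge_records(tibble::tibble(
    source = "demo", surface = "imatinib", entity_type = "drug",
    xrefs = ""))
  docs <- tibble::tibble(
    doc_id = c("d1", "d2", "d3", "d4"),
    text = c("resistant cases take imatinib",
             "resistant tumors and imatinib",
             "resistant lines given imatinib",
             "imatinib alone"))
  idx <- quiet_add(entity_index(d), docs)
  expect_setequal(retrieve_postings(idx, "resistant")$doc_id,
                  c("d1", "d2", "d3"))
  expect_setequal(retrieve_postings(idx, "imatinib")$doc_id,
                  c("d1", "d2", "d3", "d4"))
  expect_equal(nrow(retrieve_postings(idx, "nilotinib")), 0L)
})

test_that("posting counts agree with document frequencies for every term", {
  fx <- generate_fixture(fixture_spec(n_docs = 100, seed = 23))
  idx <- quiet_add(entity_index(fx$dictionary), fx$corpus)
  s <- corpus_stats(idx)
  toks <- lapply(fx$corpus$text, oracle_tokens)
  for (term in sample(s$df$term, 40)) {
    by_scan <- sum(vapply(toks, function(tk) term %in% tk, logical(1)))
    expect_equal(nrow(retrieve_postings(idx, term)), by_scan)
    expect_equal(s$df$df[s$df$term == term], by_scan)
  }
  expect_equal(s$max_if, max(fx$corpus$impact_factor, na.rm = TRUE))
  expect_equal(s$n_docs, 100L)
})

test_that("documents lacking a date are accepted with a warning and flagged", {
  idx <- entity_index(demo_dictionary())
  expect_warning(
    idx <- add_documents(idx, tibble::tibble(doc_id = "nd",
                                             text = "imatinib study")),
    "recency floor")
  expect_true(idx$documents$date_missing)
})

test_that("invalid months and negative impact factors are rejected", {
  idx <- entity_index(demo_dictionary())
  expect_error(add_documents(idx, tibble::tibble(
    doc_id = "x", text = "t", pub_year = 2000, pub_month = 13)),
    "pub_month")
  expect_error(add_documents(idx, tibble::tibble(
    doc_id = "x", text = "t", impact_factor = -1)), "non-negative")
})

test_that("an index round-trips through its persistence directory", {
  fx <- generate_fixture(fixture_spec(n_docs = 15, seed = 29))
  idx <- quiet_add(entity_index(fx$dictionary), fx$corpus)
  dir <- withr::local_tempdir()
  write_index(idx, dir)
  idx2 <- read_index(dir)
  expect_equal(index_core(idx2)$docs, index_core(idx)$docs)
  expect_equal(idx2$postings, idx$postings)
  expect_equal(idx2$terms, idx$terms)
  expect_equal(corpus_stats(idx2), corpus_stats(idx))
  # bit-reproducible persistence
  dir2 <- withr::local_tempdir()
  write_index(idx2, dir2)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir2, f)),
                     readLines(file.path(dir, f)))
  }
})

test_that("corpus TSV files round-trip including missing fields", {
  fx <- generate_fixture(fixture_spec(n_docs = 8, seed = 31))
  corpus <- fx$corpus
  corpus$pub_year[2] <- NA_integer_
  corpus$pub_month[2] <- NA_integer_
  path <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(corpus, path)
  back <- read_corpus(path)
  expect_equal(back$doc_id, corpus$doc_id)
  expect_equal(back$text, corpus$text)
  expect_equal(back$impact_factor, corpus$impact_factor)
  expect_equal(back$pub_year, corpus$pub_year)
})

test_that("the MEDLINE XML reader maps citations onto corpus records", {
  xml <- c(
    '<?xml version="1.0"?>',
    "<MedlineCitationSet>",
    "<MedlineCitation><PMID>24524212</PMID><Article>",
    "<Journal><Title>Blood Journal</Title><JournalIssue><PubDate>",
    "<Year>2014</Year><Month>Feb</Month></PubDate></JournalIssue></Journal>",
    "<ArticleTitle>Adherence matters.</ArticleTitle>",
    "<Abstract><AbstractText>Consistent use of imatinib is critical.",
    "</AbstractText></Abstract>",
    "</Article></MedlineCitation>",
    "</MedlineCitationSet>")
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, path)
  ifs <- tibble::tibble(journal = "Blood Journal", impact_factor = 10.4)
  docs <- read_medline_xml(path, impact_factors = ifs)
  expect_equal(docs$doc_id, "24524212")
  expect_match(docs$text, "^Adherence matters")
  expect_match(docs$text, "imatinib")
  expect_equal(docs$pub_year, 2014L)
  expect_equal(docs$pub_month, 2L)
  expect_equal(docs$impact_factor, 10.4)
})
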