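test_that("recency decays by half every 24 months with a floor", {
  expect_equal(recency_score(0), 1)
  expect_equal(recency_score(24), 0.5)
  expect_equal(recency_score(48), 0.25)
  expect_equal(recency_score(96), 0.0625)
  expect_equal(recency_score(120), 0.0625)
  expect_equal(recency_score(NA), 0.0625)   # undated -> floor
  expect_equal(recency_score(-3), 1)        # future-dated clamps to age 0
  ages <- sort(runif(50, 0, 200))
  expect_true(all(diff(recency_score(ages)) <= 1e-12))
})

test_that("reputation maps impact factors linearly onto [1, 10]", {
  expect_equal(reputation_score(NA, 20), 1)
  expect_equal(reputation_score(0, 20), 1)
  expect_equal(reputation_score(20, 20), 10)
  expect_equal(reputation_score(10, 20), 5.5)
  expect_error(reputation_score(21, 20), "exceeds")
  expect_error(reputation_score(3, 0), "max_if is 0")
  ifs <- sort(runif(30, 0, 20))
  expect_true(all(diff(reputation_score(ifs, 20)) >= 0))
})

test_that("the entity-number penalty is 1/min(n, 10)", {
  expect_equal(entity_number_score(1), 1)
  expect_equal(entity_number_score(4), 0.25)
  expect_equal(entity_number_score(10), 0.1)
  expect_equal(entity_number_score(25), 0.1)
  expect_error(entity_number_score(0), "undefined")
})

test_that("a single matched term with tf=1, df=1, N=2 scores exactly 1", {
  d <- merge_records(tibble::tibble(
    source = "demo", surface = "imatinib", entity_type = "drug",
    xrefs = ""))
  idx <- quiet_add(entity_index(d), tibble::tibble(
    doc_id = c("d1", "d2"),
    text = c("imatinib given daily", "placebo given daily")))
  tm <- term_match_score(idx, "imatinib")
  expect_equal(tm$doc_id, "d1")
  expect_equal(tm$coord, 1)         # all |q| elements matched
  # idf = 1 + ln(2/2) = 1; tfidf = sqrt(1) * 1^2 = 1
  expect_equal(tm$tfidf, 1)
  expect_equal(tm$term_score, 1)
})

test_that("coord is the matched fraction of query elements", {
  d <- merge_records(tibble::tibble(
    source = "demo", surface = "imatinib", entity_type = "drug",
    xrefs = ""))
  idx <- quiet_add(entity_index(d), tibble::tibble(
    doc_id = c("d1", "d2"),
    text = c("imatinib only here", "imatinib dosing response study")))
  tm <- term_match_score(idx, "imatinib dosing response")
  expect_equal(tm$coord[tm$doc_id == "d1"], 1 / 3)
  expect_equal(tm$coord[tm$doc_id == "d2"], 1)
})

test_that("document scores are the product of independent components", {
  fx <- generate_fixture(fixture_spec(n_docs = 30, seed = 47))
  idx <- quiet_add(entity_index(fx$dictionary), fx$corpus)
  s <- corpus_stats(idx)
  ref <- max(idx$documents$month_idx, na.rm = TRUE)
  comp <- document_score(idx, "q0")
  expect_gt(nrow(comp), 0)
  for (i in seq_len(nrow(comp))) {
    row <- idx$documents[idx$documents$doc_id == comp$doc_id[i], ]
    expect_equal(comp$score[i],
                 comp$term_score[i] *
                   entity_number_score(comp$n_entities[i]) *
                   reputation_score(row$impact_factor, s$max_if) *
                   recency_score(ref - row$month_idx))
  }
  # a power of zero makes the score independent of publication dates
  w0 <- score_weights(recency = 0)
  comp0 <- document_score(idx, "q0", weights = w0)
  expect_equal(comp0$score,
               comp0$term_score * comp0$entity_number * comp0$reputation)
})

test_that("component values stay inside their documented bounds", {
  fx <- generate_fixture(fixture_spec(n_docs = 60, seed = 53,
                                      mean_mentions = 4))
  idx <- quiet_add(entity_index(fx$dictionary), fx$corpus)
  comp <- document_score(idx, "q0 w001 w002 w005")
  expect_true(all(comp$coord > 0 & comp$coord <= 1))
  expect_true(all(comp$entity_number >= 0.1 & comp$entity_number <= 1))
  expect_true(all(comp$reputation >= 1 & comp$reputation <= 10))
  expect_true(all(comp$recency >= 0.0625 & comp$recency <= 1))
  expect_true(all(comp$score > 0))
})

test_that("a one-document corpus gives the entity exactly that S_d", {
  d <- merge_records(tibble::tibble(
    source = "demo", surface = "imatinib", entity_type = "drug",
    xrefs = ""))
  idx <- quiet_add(entity_index(d), tibble::tibble(
    doc_id = "d1", text = "imatinib works", impact_factor = 5,
    pub_year = 2015, pub_month = 3))
  r <- search_entities(idx, "imatinib")
  comp <- document_score(idx, "imatinib")
  expect_equal(nrow(r), 1L)
  expect_equal(r$score, comp$score)
  expect_equal(r$doc_ids[[1]], "d1")
})

test_that("ranked retrieval equals the brute-force oracle on 200 documents", {
  fx <- generate_fixture(fixture_spec(n_docs = 200, seed = 59,
                                      mean_mentions = 3))
  idx <- quiet_add(entity_index(fx$dictionary), fx$corpus)
  for (qterms in list("q0", c("q0", "w001", "w010"))) {
    got <- search_entities(idx, paste(qterms, collapse = " "),
                           top_k = 1000)
    exp <- oracle_search(fx$corpus, oracle_entity_sets(fx), qterms)
    expect_equal(got$concept_id, exp$concept_id,
                 info = paste(qterms, collapse = " "))
    expect_equal(got$score, exp$score, tolerance = 1e-9)
    expect_equal(got$n_docs, exp$n_docs)
  }
})

test_that("the recency power re-ranks toward the recent cohort", {
  cf <- cohort_fixture(n_per_cohort = 8)
  idx <- quiet_add(entity_index(cf$dictionary), cf$corpus)
  score_of <- function(r, id) r$score[r$concept_id == id]

  r0 <- search_entities(idx, cf$query, as_of = cf$ref,
                        weights = score_weights(recency = 0))
  expect_lt(abs(score_of(r0, cf$concept_old) -
                  score_of(r0, cf$concept_new)), 1e-9)

  r1 <- search_entities(idx, cf$query, as_of = cf$ref)
  ratio1 <- score_of(r1, cf$concept_new) / score_of(r1, cf$concept_old)
  expect_equal(ratio1, cf$recency_new / cf$recency_old)

  r4 <- search_entities(idx, cf$query, as_of = cf$ref,
                        weights = score_weights(recency = 4))
  ratio4 <- score_of(r4, cf$concept_new) / score_of(r4, cf$concept_old)
  expect_equal(ratio4, (cf$recency_new / cf$recency_old)^4)
  expect_equal(r4$concept_id[1], cf$concept_new)
})

test_that("power 0 makes the ranking invariant to that component's input", {
  fx <- generate_fixture(fixture_spec(n_docs = 50, seed = 61))
  idx1 <- quiet_add(entity_index(fx$dictionary), fx$corpus)
  shuffled <- fx$corpus
  set.seed(7)
  perm <- sample(nrow(shuffled))
  shuffled$pub_year <- shuffled$pub_year[perm]
  shuffled$pub_month <- shuffled$pub_month[perm]
  idx2 <- quiet_add(entity_index(fx$dictionary), shuffled)
  w <- score_weights(recency = 0)
  as_of <- "2017-01"
  expect_equal(tidy(search_entities(idx2, "q0", weights = w,
                                    as_of = as_of)),
               tidy(search_entities(idx1, "q0", weights = w,
                                    as_of = as_of)))

  shuffled2 <- fx$corpus
  shuffled2$impact_factor <- shuffled2$impact_factor[perm]
  idx3 <- quiet_add(entity_index(fx$dictionary), shuffled2)
  w2 <- score_weights(reputation = 0)
  expect_equal(tidy(search_entities(idx3, "q0", weights = w2)),
               tidy(search_entities(idx1, "q0", weights = w2)))
})

test_that("adding a matching document strictly raises the entity's score", {
  fx <- generate_fixture(fixture_spec(n_docs = 30, seed = 67))
  idx <- quiet_add(entity_index(fx$dictionary), fx$corpus)
  r1 <- search_entities(idx, "q0", top_k = 5)
  target <- r1$concept_id[1]
  surface <- fx$dictionary$concepts$name[
    fx$dictionary$concepts$concept_id == target]
  idx2 <- quiet_add(idx, tibble::tibble(
    doc_id = "extra", text = paste("q0", surface),
    pub_year = 2016, pub_month = 1))
  r2 <- search_entities(idx2, "q0", top_k = 5)
  expect_gt(r2$score[r2$concept_id == target],
            r1$score[r1$concept_id == target])
})

test_that("the type filter keeps only entities carrying that type", {
  fx <- generate_fixture(fixture_spec(n_docs = 60, seed = 71,
                                      mean_mentions = 3))
  idx <- quiet_add(entity_index(fx$dictionary), fx$corpus)
  all_r <- search_entities(idx, "q0 w001", top_k = 100)
  drugs <- search_entities(idx, "q0 w001", top_k = 100, type = "drug")
  expect_true(all(drugs$group == "chem_group"))
  expect_true(nrow(drugs) < nrow(all_r))
  meta <- fx$dictionary$concepts
  for (cid in drugs$concept_id) {
    expect_true("drug" %in% meta$types[[which(meta$concept_id == cid)]])
  }
})

test_that("score ties break by document count and then concept id", {
  d <- merge_records(tibble::tibble(
    source = "demo", surface = c("aaa", "bbb"), entity_type = "drug",
    xrefs = c("x1", "x2")))
  docs <- tibble::tibble(
    doc_id = c("d1", "d2"),
    text = c("query aaa", "query bbb"),
    pub_year = 2015, pub_month = 6)
  idx <- quiet_add(entity_index(d), docs)
  r <- search_entities(idx, "query")
  expect_equal(r$score[1], r$score[2])
  expect_equal(r$concept_id, sort(r$concept_id))
})

test_that("invalid top_k and empty queries are rejected", {
  fx <- generate_fixture(fixture_spec(n_docs = 10, seed = 73))
  idx <- quiet_add(entity_index(fx$dictionary), fx$corpus)
  expect_error(search_entities(idx, "q0", top_k = 0), "top_k")
  expect_error(search_entities(idx, "to the"),
               class = "entrank_empty_query")
})
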