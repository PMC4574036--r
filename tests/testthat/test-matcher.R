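test_that("an exact curated synonym matches at rank 1 with score 100", {
  cs <- met_codebook(zwemmen_synonym = TRUE)
  idx <- build_index(cs)
  sl <- match_one("ZWEMMEN", cs, idx)
  expect_equal(sl$concept_id[1], "18310")
  expect_equal(sl$ngram_score[1], 100)
  expect_equal(sl$best_form[1], "zwemmen")
})

test_that("values sharing no token with any concept yield an empty shortlist", {
  cs <- met_codebook()
  idx <- build_index(cs)
  expect_equal(nrow(match_one("xylophone", cs, idx)), 0L)
  expect_warning(sl <- match_one("the and", cs, idx), "zero tokens")
  expect_equal(nrow(sl), 0L)
})

test_that("an input synonym equal to a concept label scores 100", {
  cs <- met_codebook()
  idx <- build_index(cs)
  v <- input_value("water sport lessons", synonyms = "swimming")
  sl <- match_one(v, cs, idx)
  expect_equal(sl$concept_id[1], "18310")
  expect_equal(sl$ngram_score[1], 100)
})

test_that("shortlists are sorted by score, retrieval, concept id and truncated", {
  corp <- small_corpus()
  idx <- build_index(corp$cs)
  cfg <- matcher_config(shortlist_size = 5, retrieval_depth = 50)
  for (v in corp$values[1:10]) {
    sl <- match_one(v, corp$cs, idx, cfg)
    expect_lte(nrow(sl), 5L)
    if (nrow(sl) > 1) {
      key <- order(-sl$ngram_score, -sl$retrieval_score, sl$concept_id)
      expect_equal(key, seq_len(nrow(sl)))
    }
  }
  expect_error(matcher_config(shortlist_size = 200, retrieval_depth = 100))
  expect_error(matcher_config(cutoff = 150))
})

test_that("auto-accept honors the cut-off strictly (accept requires >=)", {
  sl <- data.frame(concept_id = "A", ngram_score = 89.9,
                   retrieval_score = 1, best_form = "a", rank = 1L,
                   stringsAsFactors = FALSE)
  cfg <- matcher_config(cutoff = 90)
  expect_equal(auto_accept(sl, cfg)$status, "manual")
  expect_true(is.na(auto_accept(sl, cfg)$concept_id))
  sl$ngram_score <- 90
  expect_equal(auto_accept(sl, cfg)$status, "auto")
  sl$ngram_score <- 100
  expect_equal(auto_accept(sl, cfg)$status, "auto")
  expect_equal(auto_accept(sl[0, ], cfg)$status, "no_match")
})

test_that("cutoff 0 accepts every non-empty shortlist; cutoff 100 only perfect scores", {
  corp <- small_corpus()
  idx <- build_index(corp$cs)
  res0 <- match_batch(corp$values, corp$cs, idx, matcher_config(cutoff = 0))
  expect_equal(sum(res0$records$status == "manual"), 0L)
  res100 <- match_batch(corp$values, corp$cs, idx, matcher_config(cutoff = 100))
  auto <- res100$records$status == "auto"
  expect_true(all(res100$records$ngram_score[auto] == 100))
})

test_that("learning a value re-ranks it to 1 at 100 and is idempotent on labels", {
  cs <- met_codebook()
  idx <- build_index(cs)
  v <- input_value("zwemmen 2x", identifier = "p1")
  upd <- code_and_add("18310", v, cs, idx)
  sl <- match_one(v, upd$code_system, upd$index)
  expect_equal(sl$concept_id[1], "18310")
  expect_equal(sl$ngram_score[1], 100)
  expect_true("zwemmen 2x" %in% get_concept(upd$code_system, "18310")$synonyms)

  # adding a text identical to the label changes nothing
  upd2 <- code_and_add("15350", input_value("Hockey"), cs, idx)
  expect_equal(get_concept(upd2$code_system, "15350")$synonyms, character(0))
  expect_equal(nrow(upd2$index$forms), nrow(idx$forms))

  expect_error(code_and_add(NA_character_, v, cs, idx),
               class = "recoder_integrity_error")
})

test_that("learning never worsens other values' scores for retrievable concepts", {
  corp <- small_corpus(n_concepts = 25, n_queries = 20, seed = 31)
  idx <- build_index(corp$cs)
  before <- lapply(corp$values, function(v) match_one(v, corp$cs, idx))
  upd <- code_and_add(names(corp$cs$concepts)[1],
                      input_value("completely new learned form"),
                      corp$cs, idx)
  after <- lapply(corp$values, function(v)
    match_one(v, upd$code_system, upd$index))
  for (i in seq_along(before)) {
    b <- before[[i]]; a <- after[[i]]
    for (j in seq_len(nrow(b))) {
      k <- match(b$concept_id[j], a$concept_id)
      if (!is.na(k)) expect_gte(a$ngram_score[k], b$ngram_score[j])
    }
  }
})

test_that("batch learning makes repeated values hit the learned synonym", {
  cs <- met_codebook(zwemmen_synonym = TRUE)
  idx <- build_index(cs)
  vals <- list(input_value("zwemmen iedere week", identifier = "a"),
               input_value("zwemmen iedere week", identifier = "b"))
  cfg <- matcher_config(cutoff = 50)
  res_on <- match_batch(vals, cs, idx, cfg, learn = TRUE)
  expect_equal(res_on$records$status, c("auto", "auto"))
  expect_equal(res_on$records$ngram_score[2], 100)
  res_off <- match_batch(vals, cs, idx, cfg, learn = FALSE)
  expect_equal(res_off$records$ngram_score[1], res_off$records$ngram_score[2])
})

test_that("batch matching is deterministic and tallies statuses", {
  corp <- small_corpus(seed = 77)
  idx <- build_index(corp$cs)
  r1 <- match_batch(corp$values, corp$cs, idx)
  r2 <- match_batch(corp$values, corp$cs, idx)
  expect_identical(r1$records, r2$records)
  expect_equal(sum(r1$counts), length(corp$values))
})

test_that("manual-pending records are resolved by curation decisions", {
  cs <- met_codebook()
  idx <- build_index(cs)
  vals <- list(input_value("swimming pool", identifier = "q1"), # partial -> manual
               input_value("swimming", identifier = "q2"))      # exact -> auto
  res <- match_batch(vals, cs, idx, matcher_config(cutoff = 95))
  expect_equal(res$records$status, c("manual", "auto"))
  decided <- apply_decisions(res$records,
                             c(q1 = "18310", q2 = "02020"), cs)
  expect_equal(decided$concept_id[1], "18310")
  expect_equal(decided$status[1], "manual")
  # decisions never touch already-resolved records
  expect_equal(decided$concept_id[2], "18310")
  # a no-match decision clears the pending record
  cleared <- apply_decisions(res$records, c(q1 = NA_character_), cs)
  expect_equal(cleared$status[1], "no_match")
  expect_error(apply_decisions(res$records, c(q1 = "nope"), cs), "unknown")
})
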