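mk_shortlist <- function(ids, scores = seq(100, by = -5,
                                           length.out = length(ids))) {
  data.frame(concept_id = ids, ngram_score = scores,
             retrieval_score = scores / 100,
             best_form = ids, rank = seq_along(ids),
             stringsAsFactors = FALSE)
}

test_that("perfect rank-1 shortlists of length 1 give recall 1 and precision 1", {
  sls <- list(a = mk_shortlist("C1"), b = mk_shortlist("C2"))
  gold <- c(a = "C1", b = "C2")
  row <- pr_at_rank(sls, gold, 1)
  expect_equal(row$recall, 1)
  expect_equal(row$precision, 1)
  expect_equal(row$f_measure, 1)
})

test_that("precision dilutes ~1/k when gold sits at rank 1 of deep shortlists", {
  sls <- lapply(1:10, function(i) mk_shortlist(c(sprintf("C%d", i),
                                                 sprintf("X%d_%d", i, 1:9))))
  names(sls) <- sprintf("v%d", 1:10)
  gold <- setNames(sprintf("C%d", 1:10), names(sls))
  row <- pr_at_rank(sls, gold, 10)
  expect_equal(row$recall, 1)
  expect_equal(row$precision, 0.1)
})

test_that("no-match gold values are excluded from recall but dilute precision", {
  sls <- list(a = mk_shortlist("C1"), b = mk_shortlist("X9"))
  gold <- c(a = "C1", b = NA)
  row <- pr_at_rank(sls, gold, 1)
  expect_equal(row$recall, 1)       # only 'a' counts for recall
  expect_equal(row$precision, 0.5)  # b's candidate is a false positive
})

test_that("pr values equal an independent recount from raw shortlists", {
  corp <- small_corpus(n_concepts = 30, n_queries = 20, seed = 41)
  idx <- build_index(corp$cs)
  res <- match_batch(corp$values, corp$cs, idx, keep_shortlists = TRUE)
  for (k in c(1, 3, 10)) {
    row <- pr_at_rank(res$shortlists, corp$gold, k)
    # oracle recount
    hits <- 0; denom_r <- 0; emitted <- 0
    for (id in names(corp$gold)) {
      sl <- res$shortlists[[id]]
      emitted <- emitted + min(k, nrow(sl))
      if (!is.na(corp$gold[[id]])) {
        denom_r <- denom_r + 1
        top <- head(sl$concept_id, k)
        if (corp$gold[[id]] %in% top) hits <- hits + 1
      }
    }
    expect_equal(row$recall, hits / denom_r)
    expect_equal(row$precision, if (emitted) hits / emitted else 0)
    expect_equal(row$f_measure,
                 if (row$precision + row$recall > 0)
                   2 * row$precision * row$recall / (row$precision + row$recall)
                 else 0)
  }
})

test_that("recall@k is non-decreasing and pooled precision@k non-increasing in k", {
  corp <- small_corpus(n_concepts = 40, n_queries = 50, seed = 51)
  idx <- build_index(corp$cs)
  res <- match_batch(corp$values, corp$cs, idx, keep_shortlists = TRUE)
  tab <- pr_table(res$shortlists, corp$gold, ks = 1:15)
  expect_true(all(diff(tab$recall) >= -1e-12))
  # precision is non-increasing while every value still contributes candidates
  min_len <- min(vapply(res$shortlists, nrow, integer(1)))
  upto <- max(1, min(15, min_len))
  expect_true(all(diff(tab$precision[seq_len(upto)]) <= 1e-12))
})

test_that("calibration: c = 0 auto-matches everything with a shortlist", {
  corp <- small_corpus(n_concepts = 30, n_queries = 25, seed = 61)
  idx <- build_index(corp$cs)
  res <- match_batch(corp$values, corp$cs, idx, keep_shortlists = TRUE)
  tab <- cutoff_calibration(res$shortlists, corp$gold)
  n_with_sl <- sum(vapply(res$shortlists, nrow, integer(1)) > 0)
  expect_equal(tab$n_auto[tab$cutoff == 0], n_with_sl)
  expect_true(all(diff(tab$recall) <= 1e-12))  # recall non-increasing in c
  # wherever precision is 1, every auto-match equals gold
  top <- vapply(names(corp$gold), function(id) {
    sl <- res$shortlists[[id]]
    if (nrow(sl)) sl$concept_id[1] else NA_character_
  }, character(1))
  tops <- vapply(names(corp$gold), function(id) {
    sl <- res$shortlists[[id]]
    if (nrow(sl)) sl$ngram_score[1] else NA_real_
  }, numeric(1))
  for (c in tab$cutoff[tab$precision == 1 & !tab$empty_denominator]) {
    sel <- !is.na(tops) & tops >= c
    expect_true(all(top[sel] == corp$gold[sel] & !is.na(corp$gold[sel])))
  }
})

test_that("calibration above the maximum score flags the empty denominator", {
  sls <- list(a = mk_shortlist("C1", scores = 80))
  gold <- c(a = "C1")
  tab <- cutoff_calibration(sls, gold)
  r101 <- tab[tab$cutoff == 100, ]  # all scores < 100 here
  expect_true(r101$empty_denominator)
  expect_equal(r101$precision, 0)
  # on a fixture where every top score is 100 and correct, precision is 1 everywhere
  sls2 <- list(a = mk_shortlist("C1", scores = 100),
               b = mk_shortlist("C2", scores = 100))
  tab2 <- cutoff_calibration(sls2, c(a = "C1", b = "C2"))
  expect_true(all(tab2$precision == 1))
  expect_true(all(tab2$recall == 1))
})

test_that("empty gold standards are rejected", {
  expect_error(pr_at_rank(list(), setNames(character(0), character(0)), 1),
               class = "recoder_config_error")
  expect_error(pr_at_rank(list(), c(a = "C1"), 1),
               class = "recoder_config_error")
})

test_that("scorer comparison is deterministic and equal scorers give equal tables", {
  corp <- small_corpus(n_concepts = 25, n_queries = 15, seed = 71)
  t1 <- compare_scorers(corp$values, corp$gold, corp$cs,
                        scorers = c("ngram", "ngram"), ks = 1:5)
  a <- t1[t1$scorer == "ngram", ]
  expect_equal(nrow(a), 10L)
  first <- a[1:5, -1]; second <- a[6:10, -1]
  rownames(first) <- rownames(second) <- NULL
  expect_equal(first, second)
})
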