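test_that("every label and synonym becomes one indexed lexical form", {
  cs <- met_codebook()
  idx <- build_index(cs)
  expect_equal(nrow(idx$forms), 6L)
  expect_equal(idx$doc_count, 6L)

  cs2 <- code_system(list(
    concept("X1", "hearing impairment",
            synonyms = c("deafness", "hearing defect"))))
  expect_equal(nrow(build_index(cs2)$forms), 3L)
})

test_that("a label of only stop words warns and is left unindexed", {
  cs <- code_system(list(concept("A", "the and of"),
                         concept("B", "swimming")))
  expect_warning(idx <- build_index(cs), "zero tokens")
  expect_equal(idx$doc_count, 1L)
})

test_that("idf follows 1 + ln(N / (df + 1)) with df = 0 for unseen terms", {
  cs <- code_system(list(concept("A", "swimming")))
  idx <- build_index(cs)
  expect_equal(idx$doc_count, 1L)
  expect_equal(idf("swim", idx), 1 + log(1 / 2))
  expect_equal(idf("unseen", idx), 1.0)
  # equal document frequencies give equal idf
  cs2 <- met_codebook()
  idx2 <- build_index(cs2)
  expect_equal(idf("swim", idx2), idf("hockey", idx2))
})

test_that("fuzzy expansion finds terms at >= 80% OSA similarity", {
  cs <- code_system(list(concept("A", "placental"),  # indexes stem 'placent'
                         concept("B", "swimming")))
  idx <- build_index(cs)
  expect_true("placent" %in% fuzzy_expand("placenta", idx))  # sim 7/8
  expect_true("swim" %in% fuzzy_expand("swim", idx))         # exact always in
  expect_equal(fuzzy_expand("xyz", idx), character(0))
})

test_that("retrieval ranks the exact-synonym concept first", {
  cs <- met_codebook(zwemmen_synonym = TRUE)
  idx <- build_index(cs)
  r <- retrieve(normalize_text("zwemmen"), idx, k = 10)
  expect_equal(r$concept_id[1], "18310")
  expect_equal(retrieve(normalize_text("quantum physics"), idx, k = 10),
               retrieve(character(0), idx, k = 10))
  expect_equal(nrow(retrieve(character(0), idx, k = 10)), 0L)
  expect_error(retrieve("swim", idx, k = 0), ">= 1")
})

test_that("retrieve(k = Inf) equals the brute-force fuzzy-token candidate scan", {
  set.seed(505)
  for (rep in 1:8) {
    cs <- make_codebook(sample(10:50, 1), synonyms_per_concept = 1,
                        seed = 600 + rep)
    idx <- build_index(cs)
    q <- make_queries(cs, 5, corruption_model(typo_rate = 0.6),
                      seed = 700 + rep)
    for (v in q$values) {
      toks <- normalize_text(v$name)
      if (!length(toks)) next
      got <- sort(retrieve(toks, idx, k = Inf)$concept_id)
      expect_equal(got, oracle_candidates(toks, cs), info = v$name)
    }
  }
})

test_that("retrieval is deterministic and ties break by ascending concept id", {
  cs <- make_codebook(30, seed = 9)
  idx <- build_index(cs)
  toks <- normalize_text(cs$concepts[[5]]$label)
  r1 <- retrieve(toks, idx, k = Inf)
  r2 <- retrieve(toks, idx, k = Inf)
  expect_identical(r1, r2)
  ties <- r1$concept_id[duplicated(r1$retrieval_score) |
                        duplicated(r1$retrieval_score, fromLast = TRUE)]
  grp <- split(r1$concept_id, r1$retrieval_score)
  for (g in grp) expect_equal(g, sort(g))
})

test_that("adding an unrelated concept never removes an existing candidate", {
  cs <- make_codebook(20, seed = 21)
  idx <- build_index(cs)
  toks <- normalize_text(cs$concepts[[3]]$label)
  before <- retrieve(toks, idx, k = Inf)$concept_id
  cs2 <- code_system(c(cs$concepts,
                       list(concept("ZZZZ", "qqqqq wwwww"))), name = cs$name)
  after <- retrieve(toks, build_index(cs2), k = Inf)$concept_id
  expect_true(all(before %in% after))
})

test_that("an index persists to disk and reloads with identical postings", {
  cs <- make_codebook(25, synonyms_per_concept = 2, seed = 13)
  idx <- build_index(cs)
  path <- withr::local_tempfile(fileext = ".idx")
  write_index(idx, path)
  back <- read_index(path)
  expect_identical(back$vocab, idx$vocab)
  expect_identical(back$doc_freq, idx$doc_freq)
  expect_identical(back$doc_count, idx$doc_count)
  for (t in idx$vocab)
    expect_identical(back$postings[[t]], idx$postings[[t]])
  expect_identical(back$form_norm, idx$form_norm)
  toks <- normalize_text(cs$concepts[[1]]$label)
  expect_identical(retrieve(toks, back, k = Inf), retrieve(toks, idx, k = Inf))
  # rebuilding from the same code system is also identical
  idx2 <- build_index(cs)
  for (t in idx$vocab)
    expect_identical(idx2$postings[[t]], idx$postings[[t]])
  # corrupt header is a parse error
  writeLines("nonsense", path)
  expect_error(read_index(path), class = "recoder_parse_error")
})

test_that("Damerau-Levenshtein distances match a brute-force DP oracle", {
  expect_equal(recoder:::.osa_distance("placenta", "placent"), 1L)
  expect_equal(recoder:::.osa_distance("abcd", c("abdc", "abcd", "bacd", "xy")),
               c(1L, 0L, 1L, 4L))
  set.seed(808)
  for (i in 1:200) {
    a <- paste(sample(letters[1:6], sample(1:9, 1), replace = TRUE), collapse = "")
    b <- paste(sample(letters[1:6], sample(1:9, 1), replace = TRUE), collapse = "")
    expect_equal(recoder:::.osa_distance(a, b), oracle_osa(a, b),
                 info = paste(a, b))
  }
})
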