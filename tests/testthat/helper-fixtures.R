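# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's internal counting/retrieval code paths.

# the six-concept MET example codebook
met_codebook <- function(zwemmen_synonym = FALSE) {
  code_system(list(
    concept("02060", "cardio training", system_id = "MET"),
    concept("02020", "bodypump", system_id = "MET"),
    concept("18310", "swimming", system_id = "MET",
            synonyms = if (zwemmen_synonym) "zwemmen" else character(0)),
    concept("15430", "kung fu", system_id = "MET"),
    concept("15350", "hockey", system_id = "MET"),
    concept("12150", "running", system_id = "MET")
  ), name = "MET")
}

met_codebook_csv <- function(path) {
  writeLines(c(
    "Concept ID,Concept Label,System ID",
    "02060,cardio training,MET",
    "02020,bodypump,MET",
    "18310,swimming,MET",
    "15430,kung fu,MET",
    "15350,hockey,MET",
    "12150,running,MET"), path)
  path
}

# brute-force bigram-Dice oracle: enumerate bigrams by hand-rolled loops and
# count shared tokens by greedy removal from a copy (no table/min-multiplicity)
oracle_bigrams <- function(text) {
  toks <- recoder::normalize_text(text)
  out <- character(0)
  for (w in toks) {
    ww <- paste0("^", w, "$")
    for (i in seq_len(nchar(ww) - 1L))
      out <- c(out, substr(ww, i, i + 1L))
  }
  out
}

oracle_dice <- function(s1, s2) {
  b1 <- oracle_bigrams(s1)
  b2 <- oracle_bigrams(s2)
  if (length(b1) + length(b2) == 0L) return(0)
  shared <- 0L
  pool <- b2
  for (t in b1) {
    hit <- match(t, pool)
    if (!is.na(hit)) {
      shared <- shared + 1L
      pool <- pool[-hit]
    }
  }
  200 * shared / (length(b1) + length(b2))
}

# brute-force retrieval candidate set: scan every concept, fuzzy-compare every
# query token against every token of every lexical form directly
oracle_osa <- function(a, b) {
  n <- nchar(a); m <- nchar(b)
  if (n == 0) return(m)
  if (m == 0) return(n)
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in 1:n) for (j in 1:m) {
    cost <- as.integer(A[i] != B[j])
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L, d[i, j] + cost)
    if (i > 1 && j > 1 && A[i] == B[j - 1] && A[i - 1] == B[j])
      d[i + 1, j + 1] <- min(d[i + 1, j + 1], d[i - 1, j - 1] + 1L)
  }
  d[n + 1, m + 1]
}

oracle_fuzzy_match <- function(q, t, min_sim = 0.8) {
  1 - oracle_osa(q, t) / max(nchar(q), nchar(t)) >= min_sim
}

oracle_candidates <- function(query_tokens, cs, min_sim = 0.8) {
  hits <- character(0)
  for (k in cs$concepts) {
    forms <- unique(c(k$label, k$synonyms))
    ftoks <- unique(unlist(lapply(forms, recoder::normalize_text)))
    shared <- any(vapply(query_tokens, function(q)
      any(vapply(ftoks, function(t) oracle_fuzzy_match(q, t), logical(1))),
      logical(1)))
    if (shared) hits <- c(hits, k$concept_id)
  }
  sort(hits)
}

# small corpus used by several end-to-end tests
small_corpus <- function(n_concepts = 40, n_queries = 60, seed = 11,
                         typo_rate = 0.4, nomatch_frac = 0.1) {
  cs <- make_codebook(n_concepts, synonyms_per_concept = 2, seed = seed)
  q <- make_queries(cs, n_queries,
                    corruption_model(typo_rate = typo_rate),
                    nomatch_frac = nomatch_frac, seed = seed + 1)
  list(cs = cs, values = q$values, gold = q$gold)
}
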