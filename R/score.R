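# Similarity scores shown to users: the normalized bigram percentage
# (Sorensen-Dice on bigram multisets) and an idf-weighted per-word variant
# that shifts weight toward rare, informative words.

# shared count of two bigram multisets: sum over tokens of min multiplicity
.shared_bigrams <- function(a, b) {
  if (!length(a) || !length(b)) return(0L)
  ta <- table(a)
  tb <- table(b)
  common <- intersect(names(ta), names(tb))
  if (!length(common)) return(0L)
  sum(pmin(as.integer(ta[common]), as.integer(tb[common])))
}

.dice_pct <- function(a, b) {
  tot <- length(a) + length(b)
  if (tot == 0L) return(0)
  200 * .shared_bigrams(a, b) / tot
}

#' Bigram similarity between two strings (percentage)
#'
#' The Sorensen-Dice coefficient on the bigram multisets of the two strings,
#' scaled to `[0, 100]`:
#' `100 * 2 * |shared bigrams| / (|bigrams(s1)| + |bigrams(s2)|)`,
#' with shared counted by minimum multiplicity (duplicate bigrams count).
#' Strings are normalized with [normalize_text()] first, so the score is
#' invariant under case, punctuation and word order: `"hand joint"` and
#' `"joint hand"` score 100. Two strings that both normalize to nothing score
#' 0 by convention.
#'
#' @param s1,s2 raw strings.
#' @param stopwords stop-word list for normalization.
#' @return similarity percentage in `[0, 100]`.
#' @examples
#' ngram_similarity("Hand joint", "joint hand")
#' ngram_similarity("smoke", "smoky")
#' @export
ngram_similarity <- function(s1, s2, stopwords = default_stopwords()) {
  .dice_pct(string_bigrams(s1, stopwords), string_bigrams(s2, stopwords))
}

# dice on two already-tokenized forms (hot path)
.ngram_similarity_tokens <- function(tok1, tok2) {
  .dice_pct(.bigrams_of_tokens(tok1), .bigrams_of_tokens(tok2))
}

# memoized single-word bigram multisets (normalized words only)
.bigrams_word_cached <- function(w) {
  bc <- .recoder_env$bigram_cache
  if (is.null(bc)) {
    bc <- new.env(parent = emptyenv(), size = 4096L)
    .recoder_env$bigram_cache <- bc
  }
  v <- bc[[w]]
  if (is.null(v)) {
    v <- bigram_tokens(w)
    bc[[w]] <- v
  }
  v
}

# idf-weighted score from precomputed query info (see match_one) and the
# candidate form's token vector
.idf_weighted_tokens <- function(vi, cand_tokens) {
  if (!length(vi$raw)) return(0)
  b <- vapply(vi$wb, function(qb) {
    if (!length(cand_tokens)) return(0)
    max(vapply(cand_tokens,
               function(cw) .dice_pct(qb, .bigrams_word_cached(cw)) / 100,
               numeric(1)))
  }, numeric(1))
  w <- nchar(vi$raw) * vi$idfs
  if (sum(w) <= 0) w <- rep(1, length(w))
  w <- w / sum(w)
  100 * sum(w * b)
}

#' Naive letter-share weights of a query's words
#'
#' The plain bigram score implicitly weights each word of a multi-word query
#' by its share of the query's letters (boundary marks and spaces excluded,
#' words normalized but not stemmed): in `"hyperextensibility hand joint"`,
#' `joint` carries 5 of 27 letters, about 18.5%.
#'
#' @param query raw query string.
#' @param stopwords stop-word list for normalization.
#' @return named numeric vector of weights summing to 1 (names are the
#'   unstemmed normalized words); empty for an empty query.
#' @export
letter_share <- function(query, stopwords = default_stopwords()) {
  words <- normalize_text(query, stopwords = stopwords, stem = FALSE)
  if (!length(words)) return(stats::setNames(numeric(0), character(0)))
  n <- nchar(words)
  stats::setNames(n / sum(n), words)
}

#' IDF-weighted per-word similarity (percentage)
#'
#' A re-weighted variant of [ngram_similarity()] for multi-word queries. Each
#' query word is scored on its own -- `b_i` is the best bigram similarity
#' between that (stemmed) word and any single word of the candidate -- and the
#' per-word scores are combined with weights proportional to
#' `letters_i * idf_i`, normalized to sum to 1. With equal idfs this reduces
#' exactly to the naive letter-share weighting; when idfs differ, weight mass
#' is reallocated from common words (idf below the query's mean) toward
#' important ones (idf above the mean), so matching a rare discriminative word
#' raises the score more than matching a frequent one.
#'
#' @param query raw query string; must normalize to at least zero words
#'   (an empty query scores 0).
#' @param candidate raw candidate string.
#' @param idf_table named numeric vector giving the idf of every stemmed query
#'   word, e.g. from [idf()]; an uncovered query word is an error.
#' @param stopwords stop-word list for normalization.
#' @return similarity percentage in `[0, 100]`.
#' @export
idf_weighted_similarity <- function(query, candidate, idf_table,
                                    stopwords = default_stopwords()) {
  raw_words <- normalize_text(query, stopwords = stopwords, stem = FALSE)
  if (!length(raw_words)) return(0)
  qwords <- stem_words(raw_words)
  cwords <- normalize_text(candidate, stopwords = stopwords)
  missing <- setdiff(qwords, names(idf_table))
  if (length(missing))
    stop("idf_table does not cover query word(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  idfs <- as.numeric(idf_table[qwords])

  b <- vapply(qwords, function(qw) {
    if (!length(cwords)) return(0)
    qb <- bigram_tokens(qw)
    max(vapply(cwords, function(cw) .dice_pct(qb, bigram_tokens(cw)) / 100,
               numeric(1)))
  }, numeric(1))

  w <- nchar(raw_words) * idfs
  if (sum(w) <= 0) w <- rep(1, length(w))
  w <- w / sum(w)
  100 * sum(w * b)
}
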