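# Shared text normalization: one pipeline feeds both the retrieval index and
# the bigram scorer, so a value and a concept label are always compared in the
# same token space.

.recoder_env <- new.env(parent = emptyenv())

#' Default English stop words
#'
#' The standard English stop-word set of the Lucene analyzer family (33 words),
#' shipped as a plain-text resource. Override globally with
#' `options(recoder.stopwords = <character vector or file path>)` or per call
#' via the `stopwords` argument of [normalize_text()].
#'
#' @return character vector of lowercase stop words.
#' @export
default_stopwords <- function() {
  opt <- getOption("recoder.stopwords", NULL)
  if (!is.null(opt)) {
    if (is.character(opt) && length(opt) == 1L && file.exists(opt))
      return(readLines(opt, warn = FALSE))
    return(as.character(opt))
  }
  if (is.null(.recoder_env$stopwords)) {
    path <- system.file("extdata", "stopwords_english.txt", package = "recoder")
    .recoder_env$stopwords <- if (nzchar(path)) readLines(path, warn = FALSE)
      else c("a", "an", "and", "or", "the", "of", "in", "to", "is")
  }
  .recoder_env$stopwords
}

.strip_diacritics <- function(x) {
  out <- suppressWarnings(iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT"))
  out[is.na(out)] <- x[is.na(out)]
  out
}

#' Normalize a string to stemmed word tokens
#'
#' Applies the canonical normalization used everywhere in the package:
#' lowercase, strip diacritics, replace every non-alphanumeric character
#' (hyphens, commas, slashes, ...) by a space, split on whitespace, drop stop
#' words, and stem each remaining word with [stem_words()]. Digits are kept.
#'
#' Punctuation-to-space means `"Extra-Adrenal"` tokenizes exactly like
#' `"Extra Adrenal"`, which is what lets hyphenated and spaced spellings of
#' the same phrase match.
#'
#' @param text character vector of raw strings.
#' @param stopwords character vector of stop words to remove;
#'   defaults to [default_stopwords()].
#' @param stem if `FALSE`, skip the stemming step (used for letter counts in
#'   the idf-weighted scorer, which the stem would distort).
#' @return for a single string, a character vector of tokens (possibly empty);
#'   for a vector, a list of such vectors.
#' @examples
#' normalize_text("Smoking and drinking")
#' normalize_text("Extra-Adrenal Pheochromocytoma")
#' @export
normalize_text <- function(text, stopwords = default_stopwords(), stem = TRUE) {
  single <- length(text) == 1L
  text <- tolower(.strip_diacritics(as.character(text)))
  text <- gsub("[^a-z0-9]+", " ", text)
  toks <- strsplit(trimws(text), "[[:space:]]+")
  toks <- lapply(toks, function(w) {
    w <- w[nzchar(w)]
    w <- w[!w %in% stopwords]
    if (stem && length(w)) w <- stem_words(w)
    w
  })
  if (single) toks[[1]] else toks
}

#' Bigram tokens of one word
#'
#' Wraps a word with the boundary marks `^` and `$` and emits every
#' consecutive character pair, duplicates retained:
#' `smoke` becomes `^s, sm, mo, ok, ke, e$`. A word of n characters always
#' yields n + 1 bigrams.
#'
#' @param word a single non-empty word without whitespace.
#' @return character vector of bigrams (a multiset: order and duplicates kept).
#' @examples
#' bigram_tokens("smoke")
#' @export
bigram_tokens <- function(word) {
  if (length(word) != 1L || is.na(word) || !nzchar(word) || grepl("[[:space:]]", word))
    stop("`word` must be a single non-empty word without whitespace", call. = FALSE)
  wrapped <- paste0("^", word, "$")
  n <- nchar(wrapped)
  substring(wrapped, 1:(n - 1L), 2:n)
}

#' Bigram multiset of a whole string
#'
#' Normalizes `text` with [normalize_text()] and pools the [bigram_tokens()]
#' of every resulting word into one multiset. Because the pool is a bag,
#' word order (and case, and punctuation) never changes the result:
#' `"hand joint"` and `"joint hand"` yield identical multisets.
#'
#' @inheritParams normalize_text
#' @return character vector of bigrams; `character(0)` for empty input.
#' @export
string_bigrams <- function(text, stopwords = default_stopwords()) {
  toks <- normalize_text(text, stopwords = stopwords)
  if (!length(toks)) return(character(0))
  unlist(lapply(toks, bigram_tokens), use.names = FALSE)
}

# bigrams from an already-normalized token vector (hot path for the matcher)
.bigrams_of_tokens <- function(tokens) {
  if (!length(tokens)) return(character(0))
  unlist(lapply(tokens, bigram_tokens), use.names = FALSE)
}
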