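# Inverted-index candidate retrieval. Every concept label and synonym is one
# indexed "document" of normalized stemmed tokens; candidates are all forms
# sharing at least one (fuzzy-expanded) query term, ranked by TF-IDF cosine.

#' Build a retrieval index over a code system
#'
#' Indexes every lexical form (label and each synonym) of every concept as one
#' document of its [normalize_text()] tokens. Forms that normalize to zero
#' tokens (e.g. a label made only of stop words) are kept in the form table
#' but not indexed, with a warning reporting how many concepts were indexed.
#'
#' @param cs a [code_system()].
#' @param stopwords stop-word list used for normalization (stored with the
#'   index so queries are normalized identically).
#' @return object of class `match_index`.
#' @export
build_index <- function(cs, stopwords = default_stopwords()) {
  if (!inherits(cs, "code_system")) stop("`cs` must be a code_system", call. = FALSE)
  texts <- character(0); cids <- character(0)
  for (k in cs$concepts) {
    f <- .concept_forms(k)
    texts <- c(texts, f)
    cids <- c(cids, rep(k$concept_id, length(f)))
  }
  idx <- .index_from_forms(cids, texts, stopwords)
  n_tok <- lengths(idx$tokens)
  if (any(n_tok == 0L)) {
    n_indexed <- length(unique(idx$forms$concept_id[n_tok > 0L]))
    warning(sprintf(
      "%d lexical form(s) normalized to zero tokens; %d of %d concepts indexed",
      sum(n_tok == 0L), n_indexed, length(cs$concepts)), call. = FALSE)
  }
  idx
}

.index_from_forms <- function(concept_ids, texts, stopwords) {
  forms <- data.frame(form_id = seq_along(texts), concept_id = concept_ids,
                      text = texts, stringsAsFactors = FALSE)
  tokens <- normalize_text(texts, stopwords = stopwords)
  if (length(texts) == 1L) tokens <- list(tokens)
  idx <- structure(
    list(forms = forms, tokens = tokens, stopwords = stopwords),
    class = "match_index")
  .index_rebuild(idx)
}

# (re)derive postings, document frequencies and form norms from the token lists
.index_rebuild <- function(idx) {
  postings <- new.env(parent = emptyenv(), size = 1024L)
  for (i in seq_along(idx$tokens)) {
    tok <- idx$tokens[[i]]
    if (!length(tok)) next
    tf <- table(tok)
    for (j in seq_along(tf)) {
      t <- names(tf)[j]
      p <- postings[[t]]
      if (is.null(p)) p <- list(form_id = integer(0), tf = integer(0))
      p$form_id <- c(p$form_id, i)
      p$tf <- c(p$tf, as.integer(tf[[j]]))
      postings[[t]] <- p
    }
  }
  vocab <- sort(ls(postings))
  doc_freq <- stats::setNames(
    vapply(vocab, function(t) length(postings[[t]]$form_id), integer(1)), vocab)
  idx$postings <- postings
  idx$vocab <- vocab
  idx$doc_freq <- doc_freq
  idx$doc_count <- sum(lengths(idx$tokens) > 0L)
  idx$form_norm <- vapply(idx$tokens, function(tok) {
    if (!length(tok)) return(NA_real_)
    tf <- table(tok)
    sqrt(sum((as.numeric(tf) * idf(names(tf), idx)) ^ 2))
  }, numeric(1))
  # caches for the re-scorer: bigram multiset per form, form rows per concept
  idx$form_bigrams <- lapply(idx$tokens, .bigrams_of_tokens)
  idx$concept_rows <- split(seq_len(nrow(idx$forms)), idx$forms$concept_id)
  idx
}

#' @export
print.match_index <- function(x, ...) {
  cat(sprintf("<match_index> %d lexical forms (%d indexed), %d terms\n",
              nrow(x$forms), x$doc_count, length(x$vocab)))
  invisible(x)
}

#' Inverse document frequency of a term
#'
#' `idf(t) = 1 + ln(doc_count / (doc_freq(t) + 1))`, where documents are the
#' indexed lexical forms. Unseen terms have document frequency 0. Natural
#' logarithm.
#'
#' @param term character vector of stemmed tokens.
#' @param index a `match_index`.
#' @return numeric vector of idf values.
#' @export
idf <- function(term, index) {
  df <- index$doc_freq[term]
  df[is.na(df)] <- 0L
  unname(1 + log(index$doc_count / (df + 1)))
}

#' Fuzzy expansion of a query term against the index vocabulary
#'
#' Returns every indexed term whose normalized Damerau-Levenshtein similarity
#' `1 - dist/max(nchar)` with `term` is at least `min_sim` (default 0.8, the
#' conventional fuzzy-match threshold). An exact vocabulary hit has similarity
#' 1 and is always included. This absorbs stemming quirks: `placenta` (left
#' unstemmed) expands to `placent` (the stem of `placental`), similarity 7/8.
#'
#' @param term a single stemmed token.
#' @param index a `match_index`.
#' @param min_sim similarity threshold in `[0, 1]`.
#' @return character vector of matching vocabulary terms (sorted).
#' @export
fuzzy_expand <- function(term, index, min_sim = 0.8) {
  if (!length(index$vocab)) return(character(0))
  sims <- .osa_similarity(term, index$vocab)
  index$vocab[sims >= min_sim]
}

#' Retrieve candidate concepts for a query
#'
#' Candidates are all indexed forms sharing at least one (fuzzy-expanded)
#' query term. Each form is scored by TF-IDF cosine between the query vector
#' and the form vector (term weight = tf x idf, both vectors
#' length-normalized); terms reached only through fuzzy expansion contribute
#' with a 0.8 weight multiplier so exact hits dominate. A concept's score is
#' the maximum over its forms. The top `k` concepts are returned in
#' descending score order, ties broken by ascending concept id.
#'
#' @param query character vector of normalized query tokens
#'   (see [normalize_text()]).
#' @param index a `match_index`.
#' @param k number of concepts to return (`Inf` = all candidates).
#' @param fuzzy_min_sim threshold passed to [fuzzy_expand()].
#' @param fuzzy_weight multiplier applied to fuzzy (non-exact) term weights.
#' @return data frame with columns `concept_id`, `retrieval_score`,
#'   `best_form_id`, ordered by rank; zero rows when nothing shares a term.
#' @export
retrieve <- function(query, index, k = 100, fuzzy_min_sim = 0.8,
                     fuzzy_weight = 0.8) {
  if (!is.infinite(k) && (!is.numeric(k) || k < 1))
    stop("`k` must be >= 1", call. = FALSE)
  empty <- data.frame(concept_id = character(0), retrieval_score = numeric(0),
                      best_form_id = integer(0), stringsAsFactors = FALSE)
  query <- query[nzchar(query)]
  if (!length(query)) return(empty)

  tfq <- table(query)
  qw <- numeric(0)  # named: index term -> query weight
  for (q in names(tfq)) {
    ts <- fuzzy_expand(q, index, min_sim = fuzzy_min_sim)
    if (!length(ts)) next
    w <- as.numeric(tfq[[q]]) * idf(ts, index) *
      ifelse(ts == q, 1, fuzzy_weight)
    for (i in seq_along(ts)) {
      t <- ts[i]
      if (is.na(qw[t]) || w[i] > qw[t]) qw[t] <- w[i]
    }
  }
  if (!length(qw)) return(empty)
  qnorm <- sqrt(sum(qw ^ 2))

  acc <- numeric(nrow(index$forms))
  for (t in names(qw)) {
    p <- index$postings[[t]]
    acc[p$form_id] <- acc[p$form_id] + qw[[t]] * p$tf * idf(t, index)
  }
  cand <- which(acc > 0)
  if (!length(cand)) return(empty)
  score <- acc[cand] / (qnorm * index$form_norm[cand])
  cid <- index$forms$concept_id[cand]

  # concept score = max over its forms; remember which form achieved it
  o <- order(-score, cid, cand)
  cid <- cid[o]; score <- score[o]; cand <- cand[o]
  first <- !duplicated(cid)
  res <- data.frame(concept_id = cid[first], retrieval_score = score[first],
                    best_form_id = cand[first], stringsAsFactors = FALSE)
  res <- res[order(-res$retrieval_score, res$concept_id), , drop = FALSE]
  if (is.finite(k) && nrow(res) > k) res <- res[seq_len(k), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# add one lexical form for a concept; no-op if the text is already a form of
# that concept. Rebuilds postings/norms (doc_count and idfs change).
.index_add_form <- function(idx, concept_id, text) {
  have <- idx$forms$text[idx$forms$concept_id == concept_id]
  if (tolower(trimws(text)) %in% tolower(trimws(have))) return(idx)
  idx$forms <- rbind(idx$forms, data.frame(
    form_id = nrow(idx$forms) + 1L, concept_id = concept_id, text = text,
    stringsAsFactors = FALSE))
  idx$tokens <- c(idx$tokens, list(normalize_text(text, stopwords = idx$stopwords)))
  .index_rebuild(idx)
}

#' Persist a retrieval index to a plain-text file
#'
#' Writes a versioned flat file holding the stop-word list and the lexical
#' forms; postings, document frequencies and norms are rebuilt
#' deterministically on load, so [read_index()] restores an index with
#' identical postings.
#'
#' @param index a `match_index`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("#recoder_index\tversion\t1",
               paste0("#stopwords\t", paste(index$stopwords, collapse = " "))),
             con)
  txt <- gsub("[\t\n\r]", " ", index$forms$text)
  writeLines(paste(index$forms$form_id, index$forms$concept_id, txt,
                   sep = "\t"), con)
  invisible(path)
}

#' Load a retrieval index written by [write_index()]
#' @param path path to the index file.
#' @return a `match_index`.
#' @export
read_index <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!length(lines) || !startsWith(lines[1], "#recoder_index\tversion\t1"))
    .recoder_error("parse", paste0(path, ": not a recoder index file (v1)"))
  sw <- strsplit(sub("^#stopwords\t", "", lines[2]), " ", fixed = TRUE)[[1]]
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  cids <- vapply(parts, `[[`, character(1), 2L)
  txts <- vapply(parts, function(p) paste(p[-(1:2)], collapse = "\t"), character(1))
  .index_from_forms(cids, txts, sw)
}
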