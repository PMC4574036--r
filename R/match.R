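# End-to-end matching: retrieval over the input's name and synonyms, bigram
# re-scoring against every lexical form, cut-off auto-accept, and the
# curation/learning loop that adds accepted values as new synonyms.

#' Matcher configuration
#'
#' @param cutoff auto-accept percentage cut-off in `[0, 100]`; the top
#'   candidate is accepted without review when its score is >= `cutoff`.
#'   Default 90 -- a sensible default for curated inputs; free-text inputs
#'   with many typos may warrant ~70.
#' @param retrieval_depth how many concepts the retrieval stage hands to the
#'   re-scorer per query (default 100).
#' @param shortlist_size how many candidates the user sees (default 20);
#'   must not exceed `retrieval_depth`.
#' @param scorer `"ngram"` (bigram percentage, the default), `"idf_ngram"`
#'   (idf-weighted per-word variant) or `"retrieval_only"` (rank by the
#'   TF-IDF cosine retrieval score).
#' @param fuzzy_min_sim,fuzzy_weight fuzzy-expansion parameters, see
#'   [retrieve()].
#' @return object of class `matcher_config`.
#' @export
matcher_config <- function(cutoff = 90, retrieval_depth = 100,
                           shortlist_size = 20,
                           scorer = c("ngram", "idf_ngram", "retrieval_only"),
                           fuzzy_min_sim = 0.8, fuzzy_weight = 0.8) {
  scorer <- match.arg(scorer)
  if (!is.numeric(cutoff) || cutoff < 0 || cutoff > 100)
    stop("`cutoff` must be in [0, 100]", call. = FALSE)
  if (shortlist_size > retrieval_depth)
    stop("`shortlist_size` must be <= `retrieval_depth`", call. = FALSE)
  structure(list(cutoff = cutoff, retrieval_depth = retrieval_depth,
                 shortlist_size = shortlist_size, scorer = scorer,
                 fuzzy_min_sim = fuzzy_min_sim, fuzzy_weight = fuzzy_weight),
            class = "matcher_config")
}

.empty_shortlist <- function() {
  data.frame(concept_id = character(0), ngram_score = numeric(0),
             retrieval_score = numeric(0), best_form = character(0),
             rank = integer(0), stringsAsFactors = FALSE)
}

#' Match one input value against an indexed code system
#'
#' Retrieval is run for the value's name and for each of its synonyms; the
#' candidate pools are unioned (a concept's retrieval score is its maximum
#' over the queries). Every candidate concept is then re-scored as the maximum
#' bigram similarity over all pairs of input variant (name, synonyms) and
#' concept lexical form (label, synonyms); the form achieving the maximum is
#' reported as `best_form`. Candidates are sorted by n-gram score (desc), then
#' retrieval score (desc), then concept id (asc), and truncated to the
#' configured shortlist size.
#'
#' @param value an [input_value()] (a bare string is accepted and wrapped).
#' @param cs the [code_system()].
#' @param index the [build_index()] of `cs`.
#' @param config a [matcher_config()].
#' @return shortlist data frame: `concept_id`, `ngram_score`,
#'   `retrieval_score`, `best_form`, `rank`. Zero rows when the value shares
#'   no (fuzzy) token with any concept or normalizes to nothing (warning).
#' @export
match_one <- function(value, cs, index, config = matcher_config()) {
  if (is.character(value)) value <- input_value(value)
  variants <- .value_variants(value)
  var_tokens <- lapply(variants, normalize_text, stopwords = index$stopwords)
  if (!any(lengths(var_tokens) > 0L)) {
    warning("input value \"", value$name, "\" normalized to zero tokens",
            call. = FALSE)
    return(.empty_shortlist())
  }

  pool <- list()
  for (toks in var_tokens) {
    if (!length(toks)) next
    r <- retrieve(toks, index, k = config$retrieval_depth,
                  fuzzy_min_sim = config$fuzzy_min_sim,
                  fuzzy_weight = config$fuzzy_weight)
    for (i in seq_len(nrow(r))) {
      id <- r$concept_id[i]
      if (is.null(pool[[id]]) || r$retrieval_score[i] > pool[[id]])
        pool[[id]] <- r$retrieval_score[i]
    }
  }
  if (!length(pool)) return(.empty_shortlist())
  cand_ids <- names(pool)
  retr <- unlist(pool, use.names = FALSE)

  # precompute per-variant scoring inputs once
  if (config$scorer == "idf_ngram") {
    var_info <- lapply(variants, function(v) {
      raw <- normalize_text(v, stopwords = index$stopwords, stem = FALSE)
      stems <- if (length(raw)) stem_words(raw) else character(0)
      list(raw = raw, stems = stems,
           idfs = if (length(stems)) idf(stems, index) else numeric(0),
           wb = lapply(stems, .bigrams_word_cached))
    })
  } else {
    var_bigrams <- lapply(var_tokens, .bigrams_of_tokens)
  }

  scored <- lapply(cand_ids, function(id) {
    rows <- index$concept_rows[[id]]
    best <- -1; best_row <- rows[1]
    for (r in rows) {
      if (config$scorer == "idf_ngram") {
        ctoks <- index$tokens[[r]]
        for (vi in var_info) {
          s <- .idf_weighted_tokens(vi, ctoks)
          if (s > best) { best <- s; best_row <- r }
        }
      } else {
        fb <- index$form_bigrams[[r]]
        for (vb in var_bigrams) {
          s <- .dice_pct(vb, fb)
          if (s > best) { best <- s; best_row <- r }
        }
      }
    }
    list(score = best, form = index$forms$text[best_row])
  })

  sl <- data.frame(
    concept_id = cand_ids,
    ngram_score = vapply(scored, `[[`, numeric(1), "score"),
    retrieval_score = retr,
    best_form = vapply(scored, `[[`, character(1), "form"),
    stringsAsFactors = FALSE)

  o <- if (config$scorer == "retrieval_only")
    order(-sl$retrieval_score, sl$concept_id)
  else
    order(-sl$ngram_score, -sl$retrieval_score, sl$concept_id)
  sl <- sl[o, , drop = FALSE]
  if (nrow(sl) > config$shortlist_size)
    sl <- sl[seq_len(config$shortlist_size), , drop = FALSE]
  sl$rank <- seq_len(nrow(sl))
  rownames(sl) <- NULL
  sl
}

#' Apply the auto-accept cut-off to a shortlist
#'
#' If the top candidate's score is at or above the cut-off the match is
#' accepted automatically (`status = "auto"`); below it the value is left for
#' manual curation (`status = "manual"`, no concept assigned); an empty
#' shortlist yields `status = "no_match"`.
#'
#' @param shortlist a shortlist from [match_one()].
#' @param config a [matcher_config()].
#' @param value the [input_value()] the shortlist belongs to (for the record's
#'   identifier and name); optional.
#' @return one-row match-record data frame: `input_identifier`, `input_name`,
#'   `concept_id` (`NA` = no match / pending), `ngram_score`,
#'   `retrieval_score`, `rank`, `status`.
#' @export
auto_accept <- function(shortlist, config = matcher_config(), value = NULL) {
  id <- if (!is.null(value)) value$identifier else NA_character_
  nm <- if (!is.null(value)) value$name else NA_character_
  score_col <- if (config$scorer == "retrieval_only") "retrieval_score"
    else "ngram_score"
  if (nrow(shortlist) == 0L) {
    return(data.frame(input_identifier = id, input_name = nm,
                      concept_id = NA_character_, ngram_score = NA_real_,
                      retrieval_score = NA_real_, rank = NA_integer_,
                      status = "no_match", stringsAsFactors = FALSE))
  }
  top <- shortlist[1L, ]
  accepted <- top[[score_col]] >= config$cutoff
  data.frame(
    input_identifier = id, input_name = nm,
    concept_id = if (accepted) top$concept_id else NA_character_,
    ngram_score = top$ngram_score,
    retrieval_score = top$retrieval_score,
    rank = if (accepted) 1L else NA_integer_,
    status = if (accepted) "auto" else "manual",
    stringsAsFactors = FALSE)
}

#' Learn an accepted match as a new synonym ("code and add")
#'
#' Appends the input value's name to the matched concept's synonyms (a no-op
#' when the text already is a lexical form of that concept, compared
#' case-insensitively after trimming) and updates the index so the new form is
#' retrievable. Re-matching the same value afterwards puts the concept at
#' rank 1 with score 100. Learning is optional at curation time: values typed
#' by study participants often contain spelling errors that should not pollute
#' the knowledge base.
#'
#' @param concept_id the accepted concept (must exist; `NA` is an error).
#' @param value the matched [input_value()].
#' @param cs,index the code system and its index.
#' @return list with the updated `code_system` and `index`.
#' @export
code_and_add <- function(concept_id, value, cs, index) {
  if (is.na(concept_id))
    .recoder_error("integrity", "cannot learn from a no-match record")
  k <- get_concept(cs, concept_id)
  txt <- trimws(value$name)
  if (!tolower(txt) %in% tolower(.concept_forms(k))) {
    k$synonyms <- c(k$synonyms, txt)
    cs$concepts[[concept_id]] <- k
    index <- .index_add_form(index, concept_id, txt)
  }
  list(code_system = cs, index = index)
}

#' Match a batch of input values
#'
#' Values are processed in input order. With `learn = TRUE`, every
#' auto-accepted match is immediately learned via [code_and_add()], so later
#' occurrences of the same (or a similar) value hit the learned synonym at
#' 100% -- the semi-automatic reuse of earlier curation rounds. A failure on
#' one value never aborts the batch: the value is recorded as `no_match` and
#' the error logged as a warning.
#'
#' @param values list of [input_value()] (or character vector).
#' @param cs,index code system and index.
#' @param config a [matcher_config()].
#' @param learn logical; learn auto-accepted matches as synonyms.
#' @param keep_shortlists logical; retain each value's shortlist (needed for
#'   evaluation).
#' @return object of class `match_result`: list with `records` (one row per
#'   value, see [auto_accept()]), `shortlists` (named by identifier, when
#'   kept), the possibly updated `code_system` and `index`, and a `counts`
#'   tally of auto/manual/no_match.
#' @export
match_batch <- function(values, cs, index, config = matcher_config(),
                        learn = FALSE, keep_shortlists = FALSE) {
  if (is.character(values)) values <- lapply(values, input_value)
  values <- lapply(seq_along(values), function(i) {
    v <- values[[i]]
    if (is.na(v$identifier)) v$identifier <- as.character(i)
    v
  })
  records <- vector("list", length(values))
  shortlists <- if (keep_shortlists) vector("list", length(values))
  for (i in seq_along(values)) {
    v <- values[[i]]
    rec <- tryCatch({
      sl <- match_one(v, cs, index, config)
      if (keep_shortlists) shortlists[[i]] <- sl
      rec <- auto_accept(sl, config, v)
      if (learn && rec$status == "auto") {
        upd <- code_and_add(rec$concept_id, v, cs, index)
        cs <- upd$code_system
        index <- upd$index
      }
      rec
    }, error = function(e) {
      warning("value \"", v$name, "\" failed: ", conditionMessage(e),
              call. = FALSE)
      data.frame(input_identifier = v$identifier, input_name = v$name,
                 concept_id = NA_character_, ngram_score = NA_real_,
                 retrieval_score = NA_real_, rank = NA_integer_,
                 status = "no_match", stringsAsFactors = FALSE)
    })
    records[[i]] <- rec
  }
  records <- do.call(rbind, records)
  if (keep_shortlists)
    names(shortlists) <- records$input_identifier
  structure(list(
    records = records,
    shortlists = shortlists,
    code_system = cs,
    index = index,
    counts = c(auto = sum(records$status == "auto"),
               manual = sum(records$status == "manual"),
               no_match = sum(records$status == "no_match"))),
    class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d values: %d auto, %d manual, %d no_match\n",
              nrow(x$records), x$counts["auto"], x$counts["manual"],
              x$counts["no_match"]))
  invisible(x)
}

#' Apply curation decisions to pending records
#'
#' Takes the records of a matching run and a decisions table (identifier ->
#' concept id, empty/`NA` = no match) produced by a human reviewer, and
#' resolves every `manual` record accordingly (`status` becomes `"manual"`
#' with the chosen concept, or `"no_match"`). Decisions for identifiers not
#' pending are ignored. Chosen concept ids must resolve in the code system.
#'
#' @param records match-record data frame.
#' @param decisions named character vector (identifier -> concept_id or `NA`),
#'   e.g. from [read_gold_standard()]-style files.
#' @param cs the [code_system()].
#' @return updated records data frame.
#' @export
apply_decisions <- function(records, decisions, cs) {
  for (id in names(decisions)) {
    i <- which(records$input_identifier == id & records$status == "manual")
    if (!length(i)) next
    chosen <- decisions[[id]]
    if (is.na(chosen) || !nzchar(chosen)) {
      records$concept_id[i] <- NA_character_
      records$status[i] <- "no_match"
    } else {
      get_concept(cs, chosen)  # integrity check
      records$concept_id[i] <- chosen
      records$status[i] <- "manual"
    }
  }
  records
}
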