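# Gold-standard evaluation: precision/recall/F at rank cut-offs and the
# %-cut-off calibration table used to pick a safe auto-accept threshold.

.f_measure <- function(p, r) ifelse(p + r > 0, 2 * p * r / (p + r), 0)

.check_gold <- function(shortlists, gold) {
  if (!length(gold)) .recoder_error("config", "empty gold standard")
  missing <- setdiff(names(gold), names(shortlists))
  if (length(missing))
    .recoder_error("config", paste0(
      "no shortlist for gold identifier(s): ",
      paste(utils::head(missing, 5), collapse = ", ")))
}

#' Precision and recall at a rank cut-off
#'
#' Over the values whose gold annotation is a real concept, `recall@k` is the
#' fraction whose gold concept appears within the top `k` candidates.
#' `precision@k` is pooled (micro-averaged): the number of gold concepts found
#' in top-k lists divided by the total number of candidates emitted in all
#' top-k lists -- including the lists of values whose gold is "no match",
#' whose candidates are all false positives. This pooled counting reproduces
#' the characteristic dilution of precision as `k` grows (high at rank 1,
#' roughly `1/k`-shaped beyond it).
#'
#' @param shortlists named list (by input identifier) of [match_one()]
#'   shortlists; every gold identifier must have one (possibly empty).
#' @param gold named character vector identifier -> concept id (`NA` = the
#'   value has no correct match), e.g. from [read_gold_standard()].
#' @param k rank cut-off (>= 1).
#' @return one-row data frame: `cutoff`, `recall`, `precision`, `f_measure`.
#' @export
pr_at_rank <- function(shortlists, gold, k) {
  .check_gold(shortlists, gold)
  matched_ids <- names(gold)[!is.na(gold)]
  found <- vapply(matched_ids, function(id) {
    sl <- shortlists[[id]]
    nrow(sl) > 0 && gold[[id]] %in% sl$concept_id[seq_len(min(k, nrow(sl)))]
  }, logical(1))
  emitted <- sum(vapply(names(gold), function(id)
    min(k, nrow(shortlists[[id]])), numeric(1)))
  recall <- if (length(matched_ids)) mean(found) else 0
  precision <- if (emitted > 0) sum(found) / emitted else 0
  data.frame(cutoff = k, recall = recall, precision = precision,
             f_measure = .f_measure(precision, recall))
}

#' Precision/recall table over a range of ranks
#'
#' @inheritParams pr_at_rank
#' @param ks integer vector of rank cut-offs (default 1..50).
#' @return data frame with one [pr_at_rank()] row per entry of `ks`.
#' @export
pr_table <- function(shortlists, gold, ks = 1:50) {
  do.call(rbind, lapply(ks, function(k) pr_at_rank(shortlists, gold, k)))
}

#' Auto-accept cut-off calibration
#'
#' For every integer percentage cut-off c in 0..100, a value is auto-matched
#' to its top candidate iff the top n-gram score is >= c. Precision is the
#' fraction of auto-matches that equal the gold concept; recall is the number
#' of correct auto-matches over the number of gold-matched values. Scanning
#' the table from 100 downwards, the smallest c that still has precision 1.0
#' is the safe threshold above which every accepted match was correct.
#'
#' @inheritParams pr_at_rank
#' @return data frame with columns `cutoff` (0..100), `recall`, `precision`,
#'   `f_measure`, `n_auto`, and `empty_denominator` flagging rows where no
#'   value was auto-matched (precision reported as 0 there).
#' @export
cutoff_calibration <- function(shortlists, gold) {
  .check_gold(shortlists, gold)
  top_score <- vapply(names(gold), function(id) {
    sl <- shortlists[[id]]
    if (nrow(sl)) sl$ngram_score[1] else NA_real_
  }, numeric(1))
  top_concept <- vapply(names(gold), function(id) {
    sl <- shortlists[[id]]
    if (nrow(sl)) sl$concept_id[1] else NA_character_
  }, character(1))
  correct <- !is.na(top_concept) & !is.na(gold) & top_concept == gold
  n_gold <- sum(!is.na(gold))

  rows <- lapply(0:100, function(c) {
    auto <- !is.na(top_score) & top_score >= c
    n_auto <- sum(auto)
    n_correct <- sum(auto & correct)
    precision <- if (n_auto > 0) n_correct / n_auto else 0
    recall <- if (n_gold > 0) n_correct / n_gold else 0
    data.frame(cutoff = c, recall = recall, precision = precision,
               f_measure = .f_measure(precision, recall),
               n_auto = n_auto, empty_denominator = n_auto == 0L)
  })
  do.call(rbind, rows)
}

#' Compare scoring strategies on one task
#'
#' Runs the full matching pipeline once per scorer (`retrieval_only`,
#' `ngram`, `idf_ngram`) on identical retrieval pools (the retrieval stage
#' does not depend on the scorer) and tabulates precision/recall per rank for
#' each.
#'
#' @param values list of [input_value()].
#' @param gold gold standard (see [pr_at_rank()]).
#' @param cs a [code_system()].
#' @param scorers character vector, subset of
#'   `c("retrieval_only", "ngram", "idf_ngram")`.
#' @param config base [matcher_config()]; its `scorer` field is overridden.
#' @param ks rank cut-offs (default 1..50).
#' @param index optional prebuilt index of `cs`.
#' @return data frame of PR rows with a leading `scorer` column.
#' @export
compare_scorers <- function(values, gold, cs,
                            scorers = c("retrieval_only", "ngram", "idf_ngram"),
                            config = matcher_config(), ks = 1:50,
                            index = NULL) {
  stopifnot(all(scorers %in% c("retrieval_only", "ngram", "idf_ngram")))
  if (is.null(index)) index <- build_index(cs)
  out <- lapply(scorers, function(sc) {
    cfg <- config
    cfg$scorer <- sc
    res <- match_batch(values, cs, index, cfg, learn = FALSE,
                       keep_shortlists = TRUE)
    cbind(scorer = sc, pr_table(res$shortlists, gold, ks),
          stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
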