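---
title: "Matching methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recoder)
```

This vignette documents the matching model implemented by `recoder`, the
meaning and defaults of every tunable parameter, the numerical conventions the
package commits to, and the design of the synthetic evaluation corpus.

## 1. Pipeline overview

A match of one input value against a code system runs in four stages:

```
value ──normalize──► tokens ──retrieve──► candidate concepts ──re-score──► shortlist ──cut-off──► auto / manual / no_match
```

The two-stage retrieve-then-re-score design is deliberate. Bigram similarity
is an excellent ranking signal but too expensive to evaluate against every
concept of a large ontology for every value; the inverted index reduces each
query to the concepts that share at least one (fuzzily matched) token, and
only those are re-scored. The package guarantees that this pruning is
*lossless with respect to candidacy*: `retrieve(k = Inf)` returns exactly the
concepts a brute-force scan would find sharing a token (this equivalence is an
acceptance test).

## 2. Text normalization

`normalize_text()` applies, in order: lowercasing, transliteration of
diacritics to ASCII, replacement of every non-alphanumeric character by a
space, tokenization on whitespace, stop-word removal, and Porter2 stemming.

* **Stop words.** The default list is the classic 33-word English stop set
  used by mainstream search engines, shipped as
  `inst/extdata/stopwords_english.txt`. Passing `stopwords =` *replaces* the
  list (it does not extend it); `options(recoder.stopwords = ...)` changes the
  session default.
* **Stemming.** The Porter2 (Snowball English) algorithm is implemented in R
  (`stem_words()`) because no stemmer package is assumed available. It was
  verified against an independent reference implementation on a frozen
  word/stem list that ships with the test suite. Note that suffix stripping is
  defined on surface words and is *not* idempotent in general
  (`hyperextensibility` → `hyperextens`, but stemming `hyperextens` again
  gives `hyperexten`); the package therefore always stems from the original
  surface form and never re-stems stored tokens.

## 3. Retrieval: inverted index with fuzzy TF–IDF cosine

Every lexical form (concept label or synonym) is one *document*. With
`N` = number of non-empty forms and `df(t)` = number of forms containing
token `t`:

$$\mathrm{idf}(t) = 1 + \ln\!\frac{N}{df(t) + 1}$$

The `+1` in the denominator keeps unseen terms finite and slightly
discounts ubiquitous ones; the leading `1` keeps every matched term
positive. Form vectors use `tf × idf` weights and are length-normalized, so
the retrieval score is the standard cosine in `[0, 1]`.

**Fuzzy expansion.** Each query token expands to all index terms within
`fuzzy_min_sim = 0.8` normalized Damerau–Levenshtein similarity
(`1 − d/max(nchar)`, optimal string alignment, implemented in C++ via Rcpp).
Expanded (non-exact) terms contribute with a `fuzzy_weight = 0.8` multiplier,
and when several query tokens expand to the same index term the maximum
weight is kept — exact hits always dominate their own fuzzy shadows. The 0.8
threshold admits one edit in words of five letters or more, which covers the
single-typo regime that dominates real questionnaire data while keeping short
function-like words exact.

A concept's retrieval score is the maximum over its forms; ties are broken by
concept identifier, so all rankings are deterministic.

## 4. Re-scoring: normalized bigram Sørensen–Dice

A stemmed word `w` of `n` characters is wrapped in boundary marks and cut
into `n + 1` overlapping bigram tokens (`smoke` → `^s sm mo ok ke e$`);
duplicates are kept (multisets). For two strings with pooled bigram multisets
$B_1, B_2$:

$$\mathrm{sim}(s_1, s_2) = \frac{2\,|B_1 \cap B_2|}{|B_1| + |B_2|} \times 100$$

Properties (all property-tested against an independently written oracle):
symmetry, range `[0, 100]`, invariance under word order and case, 100 exactly
for normalization-equivalent strings, 0 for strings sharing no bigram. Two
strings that both normalize to zero tokens (stop words only) score 0 by
convention. The boundary marks make word edges count: they reward matching
short words exactly and penalize partial stem overlaps, which plain unwrapped
bigrams would blur.

The shortlist score of a concept is the maximum bigram similarity over all
(form, input-variant) pairs, where input variants are the value's name plus
its provided synonyms. Shortlists sort by bigram score, then retrieval score,
then concept id.

### IDF-weighted per-word variant

`idf_weighted_similarity()` (scorer `"idf_ngram"`) treats multi-word queries
word by word: each query word `i` gets `b_i` = its best bigram similarity
against any single candidate word, and the scores combine as
$\sum_i w_i b_i$ with

$$w_i = \frac{\ell_i \cdot \mathrm{idf}(t_i)}{\sum_j \ell_j \cdot \mathrm{idf}(t_j)}$$

where $\ell_i$ is the letter count of the (unstemmed, normalized) word. This
is the package's interpretation of "idf-reweighted letter shares": with equal
idfs it reduces *exactly* to naive letter-share weighting (e.g. `joint`
carries 5/27 ≈ 18.5% of `hyperextensibility hand joint`), and diverging idfs
reallocate weight from common words toward discriminative ones,
monotonically in the idf of a matched word. A formulation using idf alone
(without $\ell_i$) would not reduce to letter shares in the equal-idf limit,
so it was rejected.

## 5. Decisions, cut-off and learning

`auto_accept()` compares the top shortlist score to `cutoff` (default 90):
`score ≥ cutoff` → `auto`, below → `manual`, empty shortlist → `no_match`.
The default 90 is conservative on purpose — at 90+ the top candidate is
almost always a trivial variant (case, punctuation, word order, one typo) of
a known form.

`code_and_add()` implements the curation learning loop: the accepted value
string becomes a new synonym of the concept and the index is updated, so
re-matching the same value scores 100 at rank 1. (If the value is
normalization-identical to another concept's existing form, both concepts
score 100 and the deterministic id tie-break applies — that ambiguity is a
property of the data, not the matcher.) `match_batch(learn = TRUE)` applies
this automatically to every auto-accepted value, which helps exactly when
values recur, as they heavily do in questionnaire data.

`cutoff_calibration()` tabulates precision/recall of auto-acceptance for
every integer cut-off 0..100 against a gold standard; scanning downward from
100, the smallest cut-off still at precision 1.0 is the safe operating point.
On noisy corpora no such point may exist (a typo can turn one concept's label
into another's), in which case the table shows the attainable trade-offs.

## 6. Evaluation conventions

* **recall@k**: fraction of gold-*matched* values whose gold concept appears
  in the top `k`. Values whose gold annotation is "no match" are excluded
  from the recall denominator.
* **pooled precision@k**: total gold hits in top-`k` lists divided by total
  candidates emitted (micro-average). No-match values still emit candidates,
  so they dilute precision — exactly the cost a curator pays for reviewing
  junk values.
* `compare_scorers()` re-runs the identical pipeline with each scorer so
  differences are attributable to the scoring stage alone.

## 7. The synthetic corpus generator

Real curated mapping corpora cannot be redistributed with the package, so the
evaluation fixtures are synthetic but shaped after the questionnaire-recoding
setting: concept labels are 1–4-word phrases over a ~100-word
physical-activity vocabulary, each concept carries paraphrase synonyms
(word substitution, optional reversal, word appending), and queries corrupt a
sampled form with per-word typos (Poisson, `typo_rate = 0.5` edits/word),
word drops (0.1), word-order shuffles (0.2), hyphenation (0.1) and case
noise, plus 10% random unmatchable strings. All generation is seeded and
byte-reproducible.

Two generator guarantees matter for interpretation. First, all lexical forms
are kept distinct *under normalization* (sorted stemmed tokens), so a clean
query identifies its source concept unambiguously — with zero corruption,
end-to-end recall@1 is exactly 1. Second, corruption only ever starts from a
true form, so every non-junk query has exactly one gold concept.

Limits: the generator does not model abbreviations, multilingual values, or
semantic synonymy beyond shared words, so absolute scores on it are not
comparable to scores on real ontologies; the monotone *shapes* (recall rising
and pooled precision falling with rank, scores falling with corruption) are
what the acceptance tests pin down.

**Problem sizes** are the package's own choice, set to keep the full test
suite in minutes on a laptop: unit fixtures use 15–40 concepts; the
acceptance corpus uses 200 concepts × 2 synonyms and 500 queries, large
enough for stable rates (gold-matched n ≈ 450) and small enough to run the
whole pipeline — including a learning pass and a three-scorer comparison —
in about a minute.

## 8. Numerical and format conventions

* Scores are percentages in `[0, 100]`; files round them to 2 decimals, all
  in-memory computation is double precision.
* Natural logarithms throughout.
* The no-match sentinel is `NA` in memory and the empty string in files.
* Indices persist as versioned plain text holding only the lexical forms;
  postings and norms are rebuilt deterministically on load, so a written and
  re-read index ranks identically (tested bit-for-bit on the postings).
* All errors are classed (`recoder_config_error`, `recoder_parse_error`,
  `recoder_integrity_error`) and map to CLI exit codes 2/3/4.
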