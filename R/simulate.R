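# Seeded synthetic study material: codebooks whose labels are short activity
# phrases, query corpora derived from them under a controlled corruption model
# (typos, word drops, reordering, hyphenation, casing), and the matching gold
# standard. Emulates free-text questionnaire values (1-5 words) recoded
# against a synonym-rich codebook.

#' Built-in vocabulary for synthetic codebooks
#'
#' About a hundred physical-activity and clinical words from which synthetic
#' concept labels are composed.
#'
#' @return character vector of lowercase words.
#' @export
recoder_vocab <- function() {
  c("swimming", "running", "cycling", "walking", "jogging", "rowing",
    "skating", "skiing", "hiking", "climbing", "dancing", "boxing",
    "fencing", "sailing", "surfing", "diving", "bowling", "golf",
    "tennis", "squash", "badminton", "hockey", "football", "volleyball",
    "basketball", "handball", "baseball", "softball", "rugby", "cricket",
    "karate", "judo", "aikido", "taekwondo", "kung", "fu", "yoga",
    "pilates", "aerobics", "gymnastics", "athletics", "archery",
    "horseback", "riding", "fishing", "hunting", "gardening", "mowing",
    "digging", "sweeping", "vacuuming", "painting", "carpentry",
    "stretching", "training", "cardio", "strength", "endurance",
    "interval", "circuit", "indoor", "outdoor", "water", "beach",
    "mountain", "road", "track", "field", "table", "ice", "roller",
    "speed", "figure", "cross", "country", "downhill", "nordic",
    "general", "light", "moderate", "vigorous", "competitive",
    "recreational", "team", "class", "lesson", "weekly", "daily",
    "morning", "evening", "fitness", "exercise", "sport", "activity",
    "workout", "gym", "club", "pool", "court", "hall")
}

#' Corruption model for synthetic queries
#'
#' Describes how clean lexical forms are turned into realistic noisy data
#' values: random character edits within words (typos), dropped words,
#' reordered words, hyphenation of adjacent words, and case noise.
#'
#' @param typo_rate expected character edits per word (Poisson mean).
#' @param word_drop_prob probability of dropping each word (at least one word
#'   is always kept).
#' @param shuffle_prob probability of shuffling the word order of a query.
#' @param hyphenation_prob probability of joining two adjacent words with a
#'   hyphen.
#' @param case_noise logical; randomly upper-case/title-case queries.
#' @return object of class `corruption_model`.
#' @export
corruption_model <- function(typo_rate = 0.5, word_drop_prob = 0.1,
                             shuffle_prob = 0.2, hyphenation_prob = 0.1,
                             case_noise = TRUE) {
  probs <- c(word_drop_prob, shuffle_prob, hyphenation_prob)
  if (any(probs < 0 | probs > 1) || typo_rate < 0)
    stop("corruption probabilities must be in [0, 1] and typo_rate >= 0",
         call. = FALSE)
  structure(list(typo_rate = typo_rate, word_drop_prob = word_drop_prob,
                 shuffle_prob = shuffle_prob,
                 hyphenation_prob = hyphenation_prob,
                 case_noise = isTRUE(case_noise)),
            class = "corruption_model")
}

# one random character edit: substitute / insert / delete / transpose
.typo_word <- function(w) {
  ch <- strsplit(w, "", fixed = TRUE)[[1]]
  n <- length(ch)
  op <- sample(c("sub", "ins", "del", "trans"), 1L)
  if (n < 2L && op %in% c("del", "trans")) op <- "ins"
  switch(op,
    sub = { i <- sample(n, 1L); ch[i] <- sample(letters, 1L); ch },
    ins = { i <- sample(n + 1L, 1L); append(ch, sample(letters, 1L), after = i - 1L) },
    del = { ch[-sample(n, 1L)] },
    trans = { i <- sample(n - 1L, 1L); ch[c(i, i + 1L)] <- ch[c(i + 1L, i)]; ch }
  ) -> ch
  paste(ch, collapse = "")
}

.corrupt_string <- function(text, model) {
  words <- strsplit(tolower(text), "[[:space:]]+")[[1]]
  words <- words[nzchar(words)]
  # word drop
  keep <- stats::runif(length(words)) >= model$word_drop_prob
  if (!any(keep)) keep[sample(length(words), 1L)] <- TRUE
  words <- words[keep]
  # typos
  words <- vapply(words, function(w) {
    for (i in seq_len(stats::rpois(1L, model$typo_rate))) w <- .typo_word(w)
    w
  }, character(1), USE.NAMES = FALSE)
  words <- words[nzchar(words)]
  if (!length(words)) words <- "x"
  # reorder
  if (length(words) > 1L && stats::runif(1) < model$shuffle_prob)
    words <- sample(words)
  # hyphenate two adjacent words
  if (length(words) > 1L && stats::runif(1) < model$hyphenation_prob) {
    i <- sample(length(words) - 1L, 1L)
    words[i] <- paste0(words[i], "-", words[i + 1L])
    words <- words[-(i + 1L)]
  }
  out <- paste(words, collapse = " ")
  if (model$case_noise) {
    out <- switch(sample(3L, 1L),
                  out, toupper(out),
                  gsub("\\b(\\w)", "\\U\\1", out, perl = TRUE))
  }
  out
}

#' Generate a synthetic codebook
#'
#' Labels are 1-4 word phrases sampled from `vocab`; each concept carries
#' `synonyms_per_concept` paraphrases obtained by substituting a word
#' (optionally with word-order reversal) or appending a word. All lexical
#' forms are kept distinct across concepts under normalization so clean
#' queries are unambiguous. Deterministic per seed.
#'
#' @param n_concepts number of concepts (>= 1).
#' @param synonyms_per_concept synonyms generated per concept.
#' @param vocab word pool; must be large enough to produce `n_concepts`
#'   distinct labels.
#' @param seed integer RNG seed.
#' @param name code-system name.
#' @return a [code_system()].
#' @export
make_codebook <- function(n_concepts, synonyms_per_concept = 2,
                          vocab = recoder_vocab(), seed = 1L,
                          name = "SYN") {
  if (n_concepts < 1) stop("`n_concepts` must be >= 1", call. = FALSE)
  if (length(vocab) < 8L)
    stop("`vocab` too small to compose labels", call. = FALSE)
  set.seed(seed)
  # lexical forms are kept distinct across concepts under normalization
  # (sorted stemmed tokens), so that a clean query identifies its source
  # concept unambiguously: zero-corruption recall@1 = 1
  form_key <- function(x) paste(sort(normalize_text(x)), collapse = " ")
  labels <- character(0)
  used <- character(0)
  tries <- 0L
  while (length(labels) < n_concepts) {
    tries <- tries + 1L
    if (tries > n_concepts * 100L)
      stop("`vocab` too small for ", n_concepts, " unique labels", call. = FALSE)
    nw <- sample(1:4, 1L, prob = c(0.35, 0.35, 0.2, 0.1))
    lab <- paste(sample(vocab, nw), collapse = " ")
    k <- form_key(lab)
    if (nzchar(k) && !k %in% used) {
      labels <- c(labels, lab)
      used <- c(used, k)
    }
  }
  concepts <- lapply(seq_len(n_concepts), function(i) {
    lab <- labels[i]
    words <- strsplit(lab, " ", fixed = TRUE)[[1]]
    syns <- character(0)
    for (s in seq_len(synonyms_per_concept)) {
      syn <- NULL
      for (try in 1:20) {
        cand <- switch(sample(3L, 1L),
          { w <- words
            w[sample(length(w), 1L)] <- sample(vocab, 1L)
            paste(w, collapse = " ") },
          { w <- words
            w[sample(length(w), 1L)] <- sample(vocab, 1L)
            paste(rev(w), collapse = " ") },
          paste(c(words, sample(vocab, 1L)), collapse = " "))
        k <- form_key(cand)
        if (nzchar(k) && !k %in% used) { syn <- cand; break }
      }
      if (!is.null(syn)) {
        syns <- c(syns, syn)
        used <<- c(used, form_key(syn))
      }
    }
    concept(sprintf("C%04d", i), lab, synonyms = syns, system_id = name)
  })
  code_system(concepts, name = name)
}

#' Generate a synthetic query corpus with gold standard
#'
#' Each query is a corrupted copy of a sampled concept's label or synonym;
#' its gold annotation is the source concept. A configurable fraction of
#' queries are random strings annotated as "no match" (`NA`).
#'
#' @param cs a [code_system()] (e.g. from [make_codebook()]).
#' @param n_queries number of queries.
#' @param model a [corruption_model()].
#' @param nomatch_frac fraction of queries that are random no-match strings.
#' @param seed integer RNG seed.
#' @return list with `values` (list of [input_value()], identifiers
#'   `q00001`, ...) and `gold` (named character vector, `NA` = no match).
#' @export
make_queries <- function(cs, n_queries, model = corruption_model(),
                         nomatch_frac = 0, seed = 1L) {
  if (!length(cs$concepts)) stop("empty code system", call. = FALSE)
  set.seed(seed)
  ids <- sprintf("q%05d", seq_len(n_queries))
  is_nomatch <- stats::runif(n_queries) < nomatch_frac
  values <- vector("list", n_queries)
  gold <- stats::setNames(rep(NA_character_, n_queries), ids)
  for (i in seq_len(n_queries)) {
    if (is_nomatch[i]) {
      txt <- paste(replicate(sample(1:3, 1L), paste(
        sample(letters, sample(4:9, 1L), replace = TRUE), collapse = "")),
        collapse = " ")
      values[[i]] <- input_value(txt, identifier = ids[i])
    } else {
      k <- cs$concepts[[sample(length(cs$concepts), 1L)]]
      src <- sample(.concept_forms(k), 1L)
      values[[i]] <- input_value(.corrupt_string(src, model),
                                 identifier = ids[i])
      gold[i] <- k$concept_id
    }
  }
  list(values = values, gold = gold)
}

#' Write a synthetic corpus to disk
#'
#' Emits the three files of a simulation: the codebook (codebook dialect),
#' the queries (Name/Identifier dialect) and the gold standard.
#'
#' @param cs code system from [make_codebook()].
#' @param queries result of [make_queries()].
#' @param dir output directory (created if needed).
#' @return named character vector of the three paths, invisibly.
#' @export
write_corpus <- function(cs, queries, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(codebook = file.path(dir, "codebook.csv"),
             queries = file.path(dir, "queries.csv"),
             gold = file.path(dir, "gold.csv"))
  write_codebook(cs, paths["codebook"])
  qdf <- data.frame(
    Identifier = vapply(queries$values, `[[`, character(1), "identifier"),
    Name = vapply(queries$values, `[[`, character(1), "name"),
    stringsAsFactors = FALSE)
  .write_table(qdf, paths["queries"])
  gdf <- data.frame(identifier = names(queries$gold),
                    concept_id = ifelse(is.na(queries$gold), "", queries$gold),
                    stringsAsFactors = FALSE)
  .write_table(gdf, paths["gold"])
  invisible(paths)
}
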