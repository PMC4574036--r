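# Porter2 (English Snowball) stemming algorithm, implemented from the published
# algorithm description. Operates on single lowercase words.

.p2_vowels <- c("a", "e", "i", "o", "u", "y")
.p2_doubles <- c("bb", "dd", "ff", "gg", "mm", "nn", "pp", "rr", "tt")
.p2_li_valid <- c("c", "d", "e", "g", "h", "k", "m", "n", "r", "t")

.p2_exceptions1 <- c(
  skis = "ski", skies = "sky", dying = "die", lying = "lie", tying = "tie",
  idly = "idl", gently = "gentl", ugly = "ugli", early = "earli",
  only = "onli", singly = "singl",
  sky = "sky", news = "news", howe = "howe", atlas = "atlas",
  cosmos = "cosmos", bias = "bias", andes = "andes"
)

.p2_exceptions2 <- c("inning", "outing", "canning", "herring", "earring",
                     "proceed", "exceed", "succeed")

.p2_is_vowel <- function(ch) ch %in% .p2_vowels

# start position (1-based) of the region after the first non-vowel that
# follows a vowel, scanning from `from`; length(ch)+1 when the region is null
.p2_region <- function(ch, from) {
  n <- length(ch)
  i <- from
  while (i < n) {
    if (.p2_is_vowel(ch[i]) && !.p2_is_vowel(ch[i + 1]))
      return(i + 2L)
    i <- i + 1L
  }
  n + 1L
}

.p2_r1_start <- function(word) {
  for (p in c("gener", "commun", "arsen")) {
    if (startsWith(word, p)) return(nchar(p) + 1L)
  }
  .p2_region(strsplit(word, "", fixed = TRUE)[[1]], 1L)
}

# does `word` end in a short syllable?
.p2_ends_short_syllable <- function(ch) {
  n <- length(ch)
  if (n == 2L) return(.p2_is_vowel(ch[1]) && !.p2_is_vowel(ch[2]))
  if (n < 2L) return(FALSE)
  .p2_is_vowel(ch[n - 1]) &&
    !.p2_is_vowel(ch[n]) && !ch[n] %in% c("w", "x", "Y") &&
    !.p2_is_vowel(ch[n - 2])
}

.p2_has_vowel <- function(ch) any(ch %in% .p2_vowels)

.p2_ends <- function(word, suffix) {
  nchar(word) >= nchar(suffix) && endsWith(word, suffix)
}

.p2_in_region <- function(word, suffix, rstart) {
  nchar(word) - nchar(suffix) + 1L >= rstart
}

.p2_chop <- function(word, suffix) substr(word, 1L, nchar(word) - nchar(suffix))

#' Stem a single English word (Porter2 / Snowball)
#'
#' Reduces an English word to its stem with the Porter2 algorithm, the revised
#' ("Snowball English") version of Porter's stemmer used by standard search
#' engines. For example `smoking` stems to `smoke` and `placental` to
#' `placent`, while `placenta` is left unchanged -- the mismatch between those
#' last two is exactly why fuzzy term expansion exists in the retrieval layer
#' (see [fuzzy_expand()]).
#'
#' @param words character vector of words; expected lowercase, but input is
#'   lowercased defensively. Words of two characters or fewer are returned
#'   unchanged.
#' @return character vector of stems, same length as `words`.
#' @examples
#' stem_words(c("smoking", "placental", "placenta"))
#' @export
stem_words <- function(words) {
  vapply(tolower(words), .p2_stem_one, character(1), USE.NAMES = FALSE)
}

.p2_stem_one <- function(word) {
  if (is.na(word) || nchar(word) <= 2L) return(word)

  # apostrophe prefix/suffix handling (rarely reached after normalization)
  if (startsWith(word, "'")) word <- substr(word, 2L, nchar(word))
  for (s in c("'s'", "'s", "'")) {
    if (.p2_ends(word, s)) { word <- .p2_chop(word, s); break }
  }
  if (nchar(word) <= 2L) return(word)

  ex <- .p2_exceptions1[word]
  if (!is.na(ex)) return(unname(ex))

  # mark consonant-y as "Y"
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  if (ch[1] == "y") ch[1] <- "Y"
  if (length(ch) > 1) {
    for (i in 2:length(ch)) {
      if (ch[i] == "y" && .p2_is_vowel(ch[i - 1])) ch[i] <- "Y"
    }
  }
  word <- paste(ch, collapse = "")
  r1 <- .p2_r1_start(word)
  r2 <- .p2_region(strsplit(word, "", fixed = TRUE)[[1]],
                   min(r1, nchar(word) + 1L))

  word <- .p2_step1a(word)
  if (word %in% .p2_exceptions2) return(word)
  word <- .p2_step1b(word, r1)
  word <- .p2_step1c(word)
  word <- .p2_step2(word, r1)
  word <- .p2_step3(word, r1, r2)
  word <- .p2_step4(word, r2)
  word <- .p2_step5(word, r1, r2)
  gsub("Y", "y", word, fixed = TRUE)
}

.p2_step1a <- function(word) {
  if (.p2_ends(word, "sses")) return(paste0(.p2_chop(word, "sses"), "ss"))
  if (.p2_ends(word, "ied") || .p2_ends(word, "ies")) {
    stem <- .p2_chop(word, "ied")
    return(if (nchar(word) > 4L) paste0(stem, "i") else paste0(stem, "ie"))
  }
  if (.p2_ends(word, "us") || .p2_ends(word, "ss")) return(word)
  if (.p2_ends(word, "s")) {
    n <- nchar(word)
    if (n > 2L) {
      body <- strsplit(substr(word, 1L, n - 2L), "", fixed = TRUE)[[1]]
      if (.p2_has_vowel(body)) return(.p2_chop(word, "s"))
    }
  }
  word
}

.p2_step1b <- function(word, r1) {
  for (s in c("eedly", "eed")) {
    if (.p2_ends(word, s)) {
      if (.p2_in_region(word, s, r1)) word <- paste0(.p2_chop(word, s), "ee")
      return(word)
    }
  }
  for (s in c("ingly", "edly", "ing", "ed")) {
    if (.p2_ends(word, s)) {
      stem <- .p2_chop(word, s)
      ch <- strsplit(stem, "", fixed = TRUE)[[1]]
      if (!.p2_has_vowel(ch)) return(word)
      word <- stem
      if (.p2_ends(word, "at") || .p2_ends(word, "bl") || .p2_ends(word, "iz")) {
        word <- paste0(word, "e")
      } else if (nchar(word) >= 2L &&
                 substr(word, nchar(word) - 1L, nchar(word)) %in% .p2_doubles) {
        word <- .p2_chop(word, "x")  # drop one char
      } else if (r1 > nchar(word) && .p2_ends_short_syllable(ch)) {
        word <- paste0(word, "e")
      }
      return(word)
    }
  }
  word
}

.p2_step1c <- function(word) {
  n <- nchar(word)
  if (n > 2L && substr(word, n, n) %in% c("y", "Y")) {
    prev <- substr(word, n - 1L, n - 1L)
    if (!.p2_is_vowel(prev))
      word <- paste0(substr(word, 1L, n - 1L), "i")
  }
  word
}

# step 2 suffix table, longest-match-first
.p2_step2_map <- list(
  c("ational", "ate"), c("fulness", "ful"), c("iveness", "ive"),
  c("ization", "ize"), c("ousness", "ous"),
  c("biliti", "ble"), c("lessli", "less"), c("tional", "tion"),
  c("alism", "al"), c("aliti", "al"), c("ation", "ate"),
  c("entli", "ent"), c("fulli", "ful"), c("iviti", "ive"), c("ousli", "ous"),
  c("abli", "able"), c("alli", "al"), c("anci", "ance"), c("ator", "ate"),
  c("enci", "ence"), c("izer", "ize"),
  c("bli", "ble"), c("ogi", "og"), c("li", "")
)

.p2_step2 <- function(word, r1) {
  for (m in .p2_step2_map) {
    s <- m[1]
    if (.p2_ends(word, s)) {
      if (!.p2_in_region(word, s, r1)) return(word)
      stem <- .p2_chop(word, s)
      if (s == "ogi") {
        if (endsWith(stem, "l")) word <- paste0(stem, "og")
      } else if (s == "li") {
        if (nchar(stem) > 0L &&
            substr(stem, nchar(stem), nchar(stem)) %in% .p2_li_valid)
          word <- stem
      } else {
        word <- paste0(stem, m[2])
      }
      return(word)
    }
  }
  word
}

.p2_step3_map <- list(
  c("ational", "ate"), c("tional", "tion"), c("alize", "al"),
  c("icate", "ic"), c("iciti", "ic"), c("ative", ""),
  c("ical", "ic"), c("ness", ""), c("ful", "")
)

.p2_step3 <- function(word, r1, r2) {
  for (m in .p2_step3_map) {
    s <- m[1]
    if (.p2_ends(word, s)) {
      if (!.p2_in_region(word, s, r1)) return(word)
      if (s == "ative") {
        if (.p2_in_region(word, s, r2)) word <- .p2_chop(word, s)
      } else {
        word <- paste0(.p2_chop(word, s), m[2])
      }
      return(word)
    }
  }
  word
}

.p2_step4_sufs <- c("ement", "ance", "ence", "able", "ible", "ment",
                    "ant", "ent", "ism", "ate", "iti", "ous", "ive", "ize",
                    "ion", "al", "er", "ic")

.p2_step4 <- function(word, r2) {
  # longest matching suffix wins; its condition is then tested once
  matched <- NULL
  for (s in .p2_step4_sufs[order(-nchar(.p2_step4_sufs))]) {
    if (.p2_ends(word, s)) { matched <- s; break }
  }
  if (is.null(matched)) return(word)
  if (!.p2_in_region(word, matched, r2)) return(word)
  if (matched == "ion") {
    stem <- .p2_chop(word, "ion")
    last <- substr(stem, nchar(stem), nchar(stem))
    if (last %in% c("s", "t")) word <- stem
    return(word)
  }
  .p2_chop(word, matched)
}

.p2_step5 <- function(word, r1, r2) {
  n <- nchar(word)
  if (endsWith(word, "e")) {
    if (n >= r2) return(.p2_chop(word, "e"))
    if (n >= r1) {
      stem <- strsplit(.p2_chop(word, "e"), "", fixed = TRUE)[[1]]
      if (!.p2_ends_short_syllable(stem)) return(.p2_chop(word, "e"))
    }
    return(word)
  }
  if (endsWith(word, "l") && n >= r2 && n >= 2L &&
      substr(word, n - 1L, n - 1L) == "l") {
    return(.p2_chop(word, "l"))
  }
  word
}
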