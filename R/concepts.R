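# Domain objects: Concept, code_system (the knowledge base), input_value.
# Plain S3 lists with validating constructors and accessors.

#' Create a concept
#'
#' A concept is one code or ontology term of the target coding system: an
#' identifier, a preferred label, optional synonyms, and optional extra
#' attributes (e.g. an OMIM cross-reference).
#'
#' @param concept_id non-empty identifier, unique within its code system.
#' @param label non-empty preferred label.
#' @param synonyms character vector of alternative lexical forms; duplicates
#'   of each other or of the label (after whitespace trimming) are dropped.
#' @param system_id name of the coding system the concept belongs to.
#' @param attributes named character vector/list of additional columns.
#' @return object of class `concept`.
#' @examples
#' concept("18310", "swimming", system_id = "MET")
#' @export
concept <- function(concept_id, label, synonyms = character(0),
                    system_id = "", attributes = list()) {
  concept_id <- trimws(as.character(concept_id))
  label <- trimws(as.character(label))
  if (length(concept_id) != 1L || !nzchar(concept_id))
    stop("`concept_id` must be a single non-empty string", call. = FALSE)
  if (length(label) != 1L || !nzchar(label))
    stop("`label` must be a single non-empty string", call. = FALSE)
  synonyms <- trimws(as.character(synonyms))
  synonyms <- synonyms[nzchar(synonyms)]
  synonyms <- synonyms[!duplicated(synonyms) & synonyms != label]
  structure(
    list(concept_id = concept_id, label = label, synonyms = synonyms,
         system_id = as.character(system_id), attributes = as.list(attributes)),
    class = "concept"
  )
}

#' @export
print.concept <- function(x, ...) {
  cat(sprintf("<concept> %s [%s] \"%s\"", x$concept_id, x$system_id, x$label))
  if (length(x$synonyms))
    cat(sprintf("\n  synonyms: %s", paste(x$synonyms, collapse = "; ")))
  cat("\n")
  invisible(x)
}

#' Create a code system (knowledge base)
#'
#' A named collection of [concept()]s against which data values are matched.
#' Concept identifiers must be unique.
#'
#' @param concepts list of `concept` objects.
#' @param name name of the code system.
#' @return object of class `code_system`; concepts are stored in a list named
#'   by `concept_id`, so `cs$concepts[["18310"]]` is a total lookup.
#' @export
code_system <- function(concepts = list(), name = "") {
  if (length(concepts) && !all(vapply(concepts, inherits, logical(1), "concept")))
    stop("`concepts` must be a list of concept objects", call. = FALSE)
  ids <- vapply(concepts, `[[`, character(1), "concept_id")
  if (anyDuplicated(ids))
    stop("duplicate concept_id in code system: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(concepts) <- ids
  structure(list(name = as.character(name), concepts = concepts),
            class = "code_system")
}

#' @export
print.code_system <- function(x, ...) {
  cat(sprintf("<code_system> \"%s\": %d concepts, %d lexical forms\n",
              x$name, length(x$concepts), n_lexical_forms(x)))
  invisible(x)
}

#' @export
length.code_system <- function(x) length(x$concepts)

#' Number of lexical forms (labels + synonyms) in a code system
#' @param cs a `code_system`.
#' @return integer count.
#' @export
n_lexical_forms <- function(cs) {
  sum(vapply(cs$concepts, function(k) 1L + length(k$synonyms), integer(1)))
}

#' Look up a concept by identifier
#' @param cs a `code_system`.
#' @param concept_id identifier to resolve.
#' @return the `concept`, or an error if absent.
#' @export
get_concept <- function(cs, concept_id) {
  k <- cs$concepts[[concept_id]]
  if (is.null(k)) stop("unknown concept_id: ", concept_id, call. = FALSE)
  k
}

#' Create an input value
#'
#' One data value to (re)code: a free-text name, optional synonyms supplied by
#' the uploader, and optional extra attributes.
#'
#' @param name non-empty (after trimming) free-text value.
#' @param identifier row identifier; auto-assigned by readers when absent.
#' @param synonyms character vector of alternative spellings/terms.
#' @param attributes named list of additional columns (e.g. OMIM = "222745").
#' @return object of class `input_value`.
#' @export
input_value <- function(name, identifier = NA_character_,
                        synonyms = character(0), attributes = list()) {
  name <- trimws(as.character(name))
  if (length(name) != 1L || is.na(name) || !nzchar(name))
    stop("`name` must be non-empty after trimming", call. = FALSE)
  synonyms <- trimws(as.character(synonyms))
  synonyms <- synonyms[nzchar(synonyms)]
  structure(list(identifier = as.character(identifier), name = name,
                 synonyms = synonyms, attributes = as.list(attributes)),
            class = "input_value")
}

#' @export
print.input_value <- function(x, ...) {
  cat(sprintf("<input_value> %s: \"%s\"", x$identifier, x$name))
  if (length(x$synonyms)) cat(" | syn:", paste(x$synonyms, collapse = "; "))
  cat("\n")
  invisible(x)
}

# all lexical variants of an input value (name first)
.value_variants <- function(value) unique(c(value$name, value$synonyms))

# all lexical forms of a concept (label first)
.concept_forms <- function(k) unique(c(k$label, k$synonyms))
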