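# Readers and writers for the file dialects the tool exchanges:
# OBO ontologies, delimited/Excel codebooks (Concept ID / Concept Label /
# System ID [+ Synonym_*]), input-value files (Name [+ Synonym_*, attributes]),
# the wide Identifier/Sport_* layout, gold standards, and match results.

.recoder_error <- function(type, msg, call. = FALSE) {
  stop(structure(
    class = c(paste0("recoder_", type, "_error"), "recoder_error",
              "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

.read_table_any <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path))
    .recoder_error("config", paste0("file not found: ", path))
  if (ext == "xlsx") {
    df <- as.data.frame(readxl::read_excel(path, col_types = "text"),
                        stringsAsFactors = FALSE)
  } else {
    sep <- if (ext %in% c("tsv", "tab")) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                            colClasses = "character", check.names = FALSE,
                            na.strings = character(0), comment.char = "",
                            strip.white = TRUE, fill = TRUE)
  }
  names(df) <- trimws(names(df))
  df
}

.require_headers <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    .recoder_error("config", sprintf(
      "%s: missing required column(s) %s; found: %s", path,
      paste(missing, collapse = ", "), paste(names(df), collapse = ", ")))
}

#' Read an OBO ontology as a code system
#'
#' Parses OBO 1.2/1.4 flat files. Each non-obsolete `[Term]` stanza becomes one
#' [concept()]: `id` is the concept identifier, `name` the label, and every
#' `synonym` line's quoted string a synonym (all scopes -- EXACT, BROAD,
#' NARROW, RELATED -- are ingested alike, since the matcher treats all lexical
#' forms equally). The header's `ontology:` tag becomes the system id.
#' Obsolete terms are skipped (with a message).
#'
#' @param path path to an `.obo` file.
#' @param quiet suppress the obsolete-term message.
#' @return a [code_system()].
#' @export
read_obo <- function(path, quiet = FALSE) {
  if (!file.exists(path)) .recoder_error("config", paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  system_id <- ""
  concepts <- list()
  n_obsolete <- 0L

  stanza_starts <- which(trimws(lines) == "[Term]")
  other_stanzas <- grep("^\\[", trimws(lines))
  header_end <- if (length(other_stanzas)) min(other_stanzas) - 1L else length(lines)
  if (header_end >= 1L) {
    ont <- grep("^ontology:", trimws(lines[seq_len(header_end)]), value = TRUE)
    if (length(ont)) system_id <- trimws(sub("^ontology:", "", ont[1]))
  }

  for (si in seq_along(stanza_starts)) {
    start <- stanza_starts[si] + 1L
    nxt <- other_stanzas[other_stanzas > stanza_starts[si]]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    if (start > end) next
    block <- lines[start:end]
    lineno <- start:end
    keep <- grepl(":", block, fixed = TRUE) | !nzchar(trimws(block))
    if (any(!keep))
      .recoder_error("parse", sprintf(
        "malformed OBO stanza at line %d: \"%s\"",
        lineno[!keep][1], block[!keep][1]))
    block <- block[nzchar(trimws(block))]
    tag <- sub(":.*$", "", block)
    val <- trimws(sub("^[^:]*:", "", block))

    if (any(tag == "is_obsolete" & grepl("^true", val))) {
      n_obsolete <- n_obsolete + 1L
      next
    }
    id <- val[tag == "id"]
    nm <- val[tag == "name"]
    if (!length(id) || !length(nm))
      .recoder_error("parse", sprintf(
        "OBO [Term] stanza starting at line %d lacks an id: or name: line",
        stanza_starts[si]))
    syn_lines <- val[tag == "synonym"]
    syns <- regmatches(syn_lines, regexpr('"(\\\\.|[^"\\\\])*"', syn_lines))
    syns <- gsub('\\\\(.)', "\\1", substr(syns, 2L, nchar(syns) - 1L))
    concepts[[length(concepts) + 1L]] <-
      concept(id[1], nm[1], synonyms = syns, system_id = system_id)
  }
  if (n_obsolete > 0L && !quiet)
    message(n_obsolete, " obsolete term(s) skipped")
  code_system(concepts, name = system_id)
}

#' Read a delimited or Excel codebook
#'
#' Expects columns `Concept ID`, `Concept Label`, `System ID` and optionally
#' columns starting with `Synonym_` (and any further attribute columns).
#' Rows sharing a `Concept ID` are merged: the first label wins and the other
#' labels become synonyms, which is how MET-style codebooks list several
#' sports under one energy-cost code.
#'
#' @param path path to a `.csv`, `.tsv` or `.xlsx` file.
#' @param name code-system name; defaults to the first `System ID` value.
#' @return a [code_system()].
#' @export
read_codebook <- function(path, name = NULL) {
  df <- .read_table_any(path)
  .require_headers(df, c("Concept ID", "Concept Label", "System ID"), path)
  syn_cols <- grep("^Synonym_", names(df), value = TRUE)
  attr_cols <- setdiff(names(df),
                       c("Concept ID", "Concept Label", "System ID", syn_cols))

  merged <- list()
  for (i in seq_len(nrow(df))) {
    id <- trimws(df[["Concept ID"]][i])
    lab <- trimws(df[["Concept Label"]][i])
    if (!nzchar(id) || !nzchar(lab)) next
    syns <- trimws(unlist(df[i, syn_cols, drop = FALSE], use.names = FALSE))
    syns <- syns[nzchar(syns)]
    attrs <- as.list(df[i, attr_cols, drop = FALSE])
    if (is.null(merged[[id]])) {
      merged[[id]] <- list(label = lab, synonyms = syns,
                           system_id = trimws(df[["System ID"]][i]),
                           attributes = attrs)
    } else {
      extra <- c(if (lab != merged[[id]]$label) lab, syns)
      merged[[id]]$synonyms <- unique(c(merged[[id]]$synonyms, extra))
    }
  }
  concepts <- lapply(names(merged), function(id) {
    m <- merged[[id]]
    concept(id, m$label, synonyms = m$synonyms, system_id = m$system_id,
            attributes = m$attributes)
  })
  sys <- if (!is.null(name)) name
    else if (length(concepts)) concepts[[1]]$system_id else ""
  code_system(concepts, name = sys)
}

#' Write a code system as a delimited codebook
#'
#' Inverse of [read_codebook()]: one row per concept with `Synonym_k` columns
#' wide enough for the largest synonym set. Reading the file back yields a
#' field-identical code system.
#'
#' @param cs a [code_system()].
#' @param path output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_codebook <- function(cs, path) {
  max_syn <- if (length(cs$concepts))
    max(vapply(cs$concepts, function(k) length(k$synonyms), integer(1))) else 0L
  rows <- lapply(cs$concepts, function(k) {
    syns <- c(k$synonyms, rep("", max_syn - length(k$synonyms)))
    c(`Concept ID` = k$concept_id, `Concept Label` = k$label,
      `System ID` = k$system_id,
      if (max_syn) stats::setNames(syns, paste0("Synonym_", seq_len(max_syn))))
  })
  df <- as.data.frame(do.call(rbind, rows), check.names = FALSE,
                      stringsAsFactors = FALSE)
  if (!length(rows))
    df <- data.frame(`Concept ID` = character(0), `Concept Label` = character(0),
                     `System ID` = character(0), check.names = FALSE)
  .write_table(df, path)
  invisible(path)
}

.write_table <- function(df, path) {
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab")) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, qmethod = "double")
}

#' Read input values (long layout)
#'
#' Reads a delimited/Excel file whose required column `Name` holds the values
#' to (re)code. Columns starting `Synonym_` populate the value's synonyms
#' (empty cells dropped); an `Identifier` column, when present, supplies row
#' identifiers (row numbers otherwise); all remaining columns are kept as
#' attributes.
#'
#' @param path path to the file.
#' @return list of [input_value()].
#' @export
read_input_values <- function(path) {
  df <- .read_table_any(path)
  .require_headers(df, "Name", path)
  syn_cols <- grep("^Synonym_", names(df), value = TRUE)
  id_col <- if ("Identifier" %in% names(df)) "Identifier" else NULL
  attr_cols <- setdiff(names(df), c("Name", syn_cols, id_col))
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    syns <- trimws(unlist(df[i, syn_cols, drop = FALSE], use.names = FALSE))
    out[[i]] <- input_value(
      df$Name[i],
      identifier = if (!is.null(id_col)) df[[id_col]][i] else as.character(i),
      synonyms = syns[nzchar(syns)],
      attributes = as.list(df[i, attr_cols, drop = FALSE]))
  }
  out
}

#' Read input values (wide layout)
#'
#' Reads the wide questionnaire layout whose first column is `Identifier` and
#' whose other columns start with a common prefix (default `Sport_`), one
#' reported activity per cell. The table is melted to one [input_value()] per
#' non-empty cell; identifiers become `"<Identifier>.<column>"`. Duplicate
#' strings are preserved (de-duplication, if any, happens downstream).
#'
#' @param path path to the file.
#' @param prefix column prefix marking value columns.
#' @return list of [input_value()].
#' @export
read_wide_input <- function(path, prefix = "Sport_") {
  df <- .read_table_any(path)
  .require_headers(df, "Identifier", path)
  val_cols <- grep(paste0("^", prefix), names(df), value = TRUE)
  if (!length(val_cols))
    .recoder_error("config", sprintf(
      "%s: no columns starting with '%s'; found: %s", path, prefix,
      paste(names(df), collapse = ", ")))
  out <- list()
  for (i in seq_len(nrow(df))) {
    for (col in val_cols) {
      v <- trimws(df[[col]][i])
      if (nzchar(v))
        out[[length(out) + 1L]] <- input_value(
          v, identifier = paste0(df$Identifier[i], ".", col))
    }
  }
  out
}

#' Read a gold standard
#'
#' A delimited file with an identifier column and a concept-id column (empty
#' cell = the value has no correct match). Column names are taken from the
#' first two columns.
#'
#' @param path path to the file.
#' @return named character vector: identifier -> concept_id (`NA` = no match).
#' @export
read_gold_standard <- function(path) {
  df <- .read_table_any(path)
  if (ncol(df) < 2L)
    .recoder_error("config", paste0(path, ": gold standard needs >= 2 columns"))
  ids <- trimws(df[[1]])
  if (anyDuplicated(ids))
    .recoder_error("config", paste0(path, ": duplicate identifiers in gold standard"))
  gold <- trimws(df[[2]])
  gold[!nzchar(gold)] <- NA_character_
  stats::setNames(gold, ids)
}

#' Write match records
#'
#' Writes the result of a matching run as a delimited file with columns
#' `input_identifier`, `input_name`, `concept_id`, `concept_label`,
#' `ngram_score` (two decimals), `rank`, `status`. Unmatched records leave the
#' concept columns empty. Every matched concept id must resolve in
#' `code_system`.
#'
#' @param records match-record data frame (see [match_batch()]).
#' @param path output path.
#' @param code_system the [code_system()] the ids refer to.
#' @return `path`, invisibly.
#' @export
write_matches <- function(records, path, code_system) {
  matched <- !is.na(records$concept_id)
  bad <- setdiff(records$concept_id[matched], names(code_system$concepts))
  if (length(bad))
    .recoder_error("integrity", paste0(
      "concept_id not in code system: ", paste(bad, collapse = ", ")))
  labels <- rep("", nrow(records))
  labels[matched] <- vapply(records$concept_id[matched],
                            function(id) code_system$concepts[[id]]$label,
                            character(1))
  df <- data.frame(
    input_identifier = records$input_identifier,
    input_name = records$input_name,
    concept_id = ifelse(matched, records$concept_id, ""),
    concept_label = labels,
    ngram_score = ifelse(is.na(records$ngram_score), "",
                         sprintf("%.2f", records$ngram_score)),
    rank = ifelse(is.na(records$rank), "", as.character(records$rank)),
    status = records$status,
    stringsAsFactors = FALSE)
  .write_table(df, path)
  invisible(path)
}

#' Read match records written by [write_matches()]
#'
#' @param path path to the file.
#' @return data frame with the same columns and types as [match_batch()]
#'   records.
#' @export
read_matches <- function(path) {
  df <- .read_table_any(path)
  .require_headers(df, c("input_identifier", "input_name", "concept_id",
                         "ngram_score", "rank", "status"), path)
  data.frame(
    input_identifier = df$input_identifier,
    input_name = df$input_name,
    concept_id = ifelse(nzchar(df$concept_id), df$concept_id, NA_character_),
    ngram_score = suppressWarnings(as.numeric(df$ngram_score)),
    rank = suppressWarnings(as.integer(df$rank)),
    status = df$status,
    stringsAsFactors = FALSE)
}
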