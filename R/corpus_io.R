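# corpus_io: read/write note corpora and normalize text ---------------------

# Map common non-ASCII punctuation to ASCII, length-preserving so character
# offsets into the raw text stay valid.
std_chars <- function(x) {
  chartr(
    "\u2018\u2019\u201a\u201c\u201d\u201e\u2013\u2014\u2212\u00a0",
    "'''\"\"\"--- ",
    x
  )
}

# Normalize one token string: lower-case, drop characters outside
# [a-z0-9.-], collapse repeated punctuation, trim punctuation at the ends.
# Total and deterministic; the same function backs the span-fidelity
# invariant (normalizing the raw span text must reproduce the token).
normalize_token <- function(x) {
  x <- tolower(std_chars(x))
  # slashes that survive tokenization are shorthand; standardized to "-"
  x <- chartr("/", "-", x)
  x <- gsub("[^a-z0-9.-]+", "", x)
  x <- gsub("([.-])\\1+", "\\1", x)
  gsub("^[.-]+|[.-]+$", "", x)
}

#' Default stop words
#'
#' A small fixed list of function words removed from the search token
#' stream. The list is deliberately short: clinical shorthand is dense and
#' aggressive stop-wording destroys searchable content. Words that carry
#' meaning for context classification are never removed (see
#' [stopword_policy()]).
#'
#' @return Character vector of lowercase stop words.
#' @export
default_stopwords <- function() {
  c(
    "the", "a", "an", "of", "and", "or", "is", "are", "was", "were",
    "be", "been", "being", "to", "in", "on", "at", "by", "for", "with",
    "as", "this", "that", "these", "it"
  )
}

#' Default protected words
#'
#' Words never removed by stop-word filtering, whatever the stop-word list
#' says. Two groups: negation/uncertainty markers whose loss would flip the
#' meaning of a mention (`no`, `not`, `without`, `denies`, `negative`,
#' `doubt`), and every word occurring in the starter cue-phrase library
#' (e.g. `of` in "no evidence of"), so that cue phrases survive
#' preprocessing and remain matchable.
#'
#' @return Character vector of lowercase protected words.
#' @export
default_protected <- function() {
  if (is.null(the$protected)) {
    cues <- starter_rule_table()$cue
    cue_words <- unique(unlist(strsplit(cues, " ", fixed = TRUE)))
    cue_words <- setdiff(cue_words, TERM_PLACEHOLDER)
    the$protected <- sort(unique(c(
      c("no", "not", "without", "denies", "negative", "doubt"),
      cue_words
    )))
  }
  the$protected
}

#' Stop-word policy
#'
#' Bundles a stop-word list with a protected list; protected words win, so
#' the effective removal set is `setdiff(stopwords, protected)`.
#'
#' @param stopwords Lowercase tokens to remove from the search stream.
#' @param protected Lowercase tokens never removed.
#' @return An object of class `notephen_policy`.
#' @export
#' @examples
#' pol <- stopword_policy()
#' "no" %in% pol$protected
stopword_policy <- function(stopwords = default_stopwords(),
                            protected = default_protected()) {
  stopifnot(is.character(stopwords), is.character(protected))
  structure(
    list(
      stopwords = unique(tolower(stopwords)),
      protected = unique(tolower(protected)),
      removal = setdiff(unique(tolower(stopwords)), tolower(protected))
    ),
    class = "notephen_policy"
  )
}

# Decide, per slash character, whether it is clinical shorthand (s/p, w/o:
# short alphanumeric runs on both sides -> standardized to "-") or a word
# separator (and/or -> split).
resolve_slashes <- function(x) {
  pos <- gregexpr("/", x, fixed = TRUE)[[1]]
  if (pos[1] == -1L) return(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  is_alnum <- grepl("[A-Za-z0-9]", chars)
  for (p in pos) {
    l <- 0L
    while (p - l - 1L >= 1L && is_alnum[p - l - 1L]) l <- l + 1L
    r <- 0L
    while (p + r + 1L <= length(chars) && is_alnum[p + r + 1L]) r <- r + 1L
    chars[p] <- if (l >= 1L && l <= 2L && r >= 1L && r <= 2L) "-" else " "
  }
  paste(chars, collapse = "")
}

#' Normalize free text into tokens with character spans
#'
#' Applies the package's text standardization: non-ASCII punctuation mapped
#' to ASCII, lower-casing, whitespace tokenization with leading/trailing
#' punctuation stripped, internal hyphens/periods kept (so shorthand like
#' `x-ray` and `1.5` survive), slashes treated as separators except inside
#' short shorthand (`s/p` becomes `s-p`). Each surviving token carries a
#' 0-based half-open character span into the raw text. Stop-word filtering
#' (minus protected words) is recorded as a logical mask rather than by
#' deletion, so downstream code can use either the filtered stream (for
#' searching) or the full normalized stream (for cue-phrase context).
#'
#' @param text A single character string (may be empty or `NA`).
#' @param policy A [stopword_policy()].
#' @return A list with `tokens` (full normalized stream), `spans`
#'   (integer matrix, columns `start`/`end`, 0-based half-open), and `keep`
#'   (logical; `FALSE` marks removed stop words). The filtered stream is
#'   `tokens[keep]`.
#' @export
#' @examples
#' pp <- preprocess_text("The patient has Pneumonia.")
#' pp$tokens[pp$keep]
preprocess_text <- function(text, policy = stopword_policy()) {
  empty <- list(
    tokens = character(0),
    spans = matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))),
    keep = logical(0)
  )
  if (length(text) != 1L || is.na(text) || !nzchar(text)) return(empty)
  x <- resolve_slashes(std_chars(text))
  runs <- gregexpr("\\S+", x, perl = TRUE)[[1]]
  if (runs[1] == -1L) return(empty)
  starts <- as.integer(runs)
  lens <- attr(runs, "match.length")
  raw_runs <- substring(x, starts, starts + lens - 1L)
  # trim each run to its alphanumeric core (keeps internal punctuation)
  core <- regexpr("[A-Za-z0-9](.*[A-Za-z0-9])?", raw_runs, perl = TRUE)
  ok <- core != -1L
  if (!any(ok)) return(empty)
  cs <- starts[ok] + as.integer(core[ok]) - 1L
  cl <- attr(core, "match.length")[ok]
  tok <- normalize_token(substring(x, cs, cs + cl - 1L))
  nz <- nzchar(tok)
  tok <- tok[nz]
  cs <- cs[nz]
  cl <- cl[nz]
  spans <- cbind(start = cs - 1L, end = cs + cl - 1L)
  list(tokens = tok, spans = spans, keep = !(tok %in% policy$removal))
}

# default mapping from file column names to corpus fields
default_col_map <- function() {
  list(
    patient_id = "patient_id", note_id = "note_id",
    note_type = "note_type", chart_time = "chart_time", text = "text"
  )
}

NOTE_TYPES <- c("history_physical", "progress", "discharge_summary", "other")

#' Read a note corpus from a delimited text file
#'
#' Reads one row per clinical note (patient key, note id, optional note
#' type and timestamp, free text) and applies [preprocess_text()] to every
#' note, so downstream modules operate on normalized tokens. The format is
#' RFC-4180 CSV by default; note text may contain embedded newlines inside
#' quotes.
#'
#' @param path Path to the delimited file. Must have a header row.
#' @param col_map Named list mapping corpus fields (`patient_id`,
#'   `note_id`, `note_type`, `chart_time`, `text`) to file column names.
#'   `note_type` and `chart_time` are optional in the file.
#' @param delim Field delimiter (default `","`).
#' @param policy A [stopword_policy()].
#' @return A tibble of class `notephen_corpus` with columns `patient_id`,
#'   `note_id`, `note_type`, `chart_time`, `raw_text` and list-columns
#'   `tokens`, `spans`, `keep` (see [preprocess_text()]).
#' @export
read_notes <- function(path, col_map = default_col_map(), delim = ",",
                       policy = stopword_policy()) {
  if (!file.exists(path)) {
    abort(paste0("note file not found: ", path), class = "notephen_io_error")
  }
  df <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  cm <- utils::modifyList(default_col_map(), as.list(col_map))
  for (field in c("patient_id", "note_id", "text")) {
    if (!cm[[field]] %in% names(df)) {
      abort(
        paste0("required column '", cm[[field]], "' (", field, ") missing from ", path),
        class = "notephen_config_error"
      )
    }
  }
  out <- tibble::tibble(
    patient_id = df[[cm$patient_id]],
    note_id = df[[cm$note_id]],
    note_type = if (cm$note_type %in% names(df)) df[[cm$note_type]] else "other",
    chart_time = if (cm$chart_time %in% names(df)) df[[cm$chart_time]] else NA_character_,
    raw_text = dplyr::coalesce(df[[cm$text]], "")
  )
  as_note_corpus(out, policy = policy)
}

#' Build a note corpus from an in-memory data frame
#'
#' Validates corpus invariants (non-empty keys, unique note ids) and
#' attaches the normalized token streams. Used by [read_notes()] and by
#' the synthetic corpus generator.
#'
#' @param df Data frame with columns `patient_id`, `note_id`, `raw_text`
#'   (or `text`) and optionally `note_type`, `chart_time`.
#' @param policy A [stopword_policy()].
#' @return A `notephen_corpus` tibble.
#' @export
as_note_corpus <- function(df, policy = stopword_policy()) {
  df <- tibble::as_tibble(df)
  if ("text" %in% names(df) && !"raw_text" %in% names(df)) {
    df <- dplyr::rename(df, raw_text = "text")
  }
  if (!"note_type" %in% names(df)) df$note_type <- "other"
  if (!"chart_time" %in% names(df)) df$chart_time <- NA_character_
  df$note_type <- ifelse(df$note_type %in% NOTE_TYPES, df$note_type, "other")
  df$raw_text <- dplyr::coalesce(as.character(df$raw_text), "")
  bad <- which(!nzchar(dplyr::coalesce(df$patient_id, "")) |
                 !nzchar(dplyr::coalesce(df$note_id, "")))
  if (length(bad) > 0) {
    abort(
      paste0("empty patient_id or note_id at data row ", bad[1]),
      class = "notephen_corpus_error"
    )
  }
  dup <- df$note_id[duplicated(df$note_id)]
  if (length(dup) > 0) {
    abort(
      paste0("duplicate note_id in corpus: ", paste(unique(dup), collapse = ", ")),
      class = "notephen_corpus_error"
    )
  }
  pp <- lapply(df$raw_text, preprocess_text, policy = policy)
  df$tokens <- lapply(pp, `[[`, "tokens")
  df$spans <- lapply(pp, `[[`, "spans")
  df$keep <- lapply(pp, `[[`, "keep")
  df <- df[, c(
    "patient_id", "note_id", "note_type", "chart_time",
    "raw_text", "tokens", "spans", "keep"
  )]
  class(df) <- c("notephen_corpus", class(df))
  df
}

#' Write a note corpus back to a delimited file
#'
#' Writes the raw note fields (not the token streams) so that
#' `read_notes(write_notes(x))` round-trips the corpus, raw text preserved
#' byte-for-byte inside CSV quoting.
#'
#' @param corpus A `notephen_corpus`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_notes <- function(corpus, path, delim = ",") {
  out <- tibble::tibble(
    patient_id = corpus$patient_id,
    note_id = corpus$note_id,
    note_type = corpus$note_type,
    chart_time = corpus$chart_time,
    text = corpus$raw_text
  )
  readr::write_delim(out, path, delim = delim, na = "", eol = "\n")
  invisible(path)
}

# content hash identifying a corpus (used to detect stale intermediate DBs)
corpus_fingerprint <- function(corpus) {
  rlang::hash(list(corpus$patient_id, corpus$note_id, corpus$raw_text))
}
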