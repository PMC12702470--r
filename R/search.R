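# search: locate pattern instances and build the intermediate database -----

#' Locate all instances of a search pattern in a corpus
#'
#' Scans the stop-word-filtered token stream of every note, left to right,
#' recording one instance per non-overlapping match (longest match wins; a
#' match of length L resumes scanning L tokens later). Each instance
#' stores its surrounding context from the *full* normalized stream — stop
#' words included — because cue phrases such as "no evidence of" contain
#' stop words. Contexts are truncated at note boundaries.
#'
#' @param corpus A `notephen_corpus` (see [read_notes()]).
#' @param pattern A `notephen_pattern` (see [compile_pattern()]).
#' @param window Maximum context tokens stored per side (default 12).
#' @return An object of class `notephen_idb`: the intermediate database,
#'   with elements `instances` (tibble, one row per mention, sorted by
#'   patient, note, position, all categories `UNCATEGORIZED`), `pattern`,
#'   `corpus_fingerprint`, `relevant_note_ids`, and `window`.
#' @export
find_instances <- function(corpus, pattern, window = 12L) {
  stopifnot(inherits(pattern, "notephen_pattern"), window >= 1L)
  rows <- vector("list", nrow(corpus))
  for (r in seq_len(nrow(corpus))) {
    toks <- corpus$tokens[[r]]
    keep <- corpus$keep[[r]]
    if (length(toks) == 0L) next
    fidx <- which(keep)
    if (length(fidx) == 0L) next
    ftoks <- toks[fidx]
    cand <- candidate_positions(pattern, ftoks)
    if (length(cand) == 0L) next
    spans <- corpus$spans[[r]]
    raw <- corpus$raw_text[r]
    hits <- list()
    resume <- 1L
    for (j in cand) {
      if (j < resume) next
      len <- pattern_match(pattern, ftoks, j)
      if (len == 0L) next
      fs <- fidx[j]
      fe <- fidx[j + len - 1L]
      left <- if (fs > 1L) toks[max(1L, fs - window):(fs - 1L)] else character(0)
      right <- if (fe < length(toks)) {
        toks[(fe + 1L):min(length(toks), fe + window)]
      } else {
        character(0)
      }
      hits[[length(hits) + 1L]] <- tibble::tibble(
        instance_id = paste0(corpus$note_id[r], "#", fs - 1L),
        patient_id = corpus$patient_id[r],
        note_id = corpus$note_id[r],
        note_type = corpus$note_type[r],
        condition = pattern$condition_name,
        match_token_start = fs - 1L,
        match_token_len = fe - fs + 1L,
        surface = substr(raw, spans[fs, "start"] + 1L, spans[fe, "end"]),
        left_context = list(left),
        right_context = list(right),
        category = "UNCATEGORIZED",
        rule_id = NA_character_
      )
      resume <- j + len
    }
    if (length(hits) > 0) rows[[r]] <- dplyr::bind_rows(hits)
  }
  instances <- dplyr::bind_rows(rows)
  if (nrow(instances) == 0L) {
    instances <- empty_instances()
  }
  instances <- dplyr::arrange(
    instances, .data$patient_id, .data$note_id, .data$match_token_start
  )
  structure(
    list(
      instances = instances,
      pattern = pattern,
      corpus_fingerprint = corpus_fingerprint(corpus),
      relevant_note_ids = sort(unique(instances$note_id)),
      window = as.integer(window)
    ),
    class = "notephen_idb"
  )
}

# token positions worth testing (vectorized prefilter; the per-position
# check is pattern_match itself)
candidate_positions <- function(pattern, ftoks) {
  hit <- ftoks %in% pattern$literals
  for (s in pattern$stems) hit <- hit | startsWith(ftoks, s)
  for (mw in pattern$multiword) hit <- hit | ftoks == mw[1]
  which(hit)
}

empty_instances <- function() {
  tibble::tibble(
    instance_id = character(0), patient_id = character(0),
    note_id = character(0), note_type = character(0),
    condition = character(0), match_token_start = integer(0),
    match_token_len = integer(0), surface = character(0),
    left_context = list(), right_context = list(),
    category = character(0), rule_id = character(0)
  )
}

#' @export
print.notephen_idb <- function(x, ...) {
  cat(
    "<intermediate db> condition:", x$pattern$condition_name,
    "| instances:", nrow(x$instances),
    "| relevant notes:", length(x$relevant_note_ids), "\n"
  )
  invisible(x)
}

#' Restrict a corpus to the notes relevant to an intermediate database
#'
#' Re-searching only the cached subset of relevant notes must reproduce
#' the full-corpus result; this helper extracts that subset.
#'
#' @param corpus A `notephen_corpus`.
#' @param db A `notephen_idb`.
#' @return The sub-corpus containing only notes with at least one match.
#' @export
relevant_subset <- function(corpus, db) {
  out <- corpus[corpus$note_id %in% db$relevant_note_ids, ]
  class(out) <- class(corpus)
  out
}

#' Save an intermediate database as searchable plain text
#'
#' One tab-separated row per instance with a small metadata header
#' (`#%` lines carrying the corpus fingerprint, the compiled pattern as
#' JSON, and the context window). Context token sequences are
#' space-joined; tokens never contain spaces, so the round trip is
#' lossless. Identical inputs produce byte-identical files.
#'
#' @param db A `notephen_idb`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_intermediate <- function(db, path) {
  ins <- db$instances
  pat <- db$pattern
  meta <- c(
    paste0("#% fingerprint=", db$corpus_fingerprint),
    paste0("#% window=", db$window),
    paste0("#% pattern=", jsonlite::toJSON(unclass(pat), auto_unbox = TRUE))
  )
  header <- paste(
    c(
      "instance_id", "patient_id", "note_id", "note_type", "condition",
      "start", "len", "surface", "left_context", "right_context",
      "category", "rule_id"
    ),
    collapse = "\t"
  )
  body <- paste(
    ins$instance_id, ins$patient_id, ins$note_id, ins$note_type,
    ins$condition, ins$match_token_start, ins$match_token_len, ins$surface,
    vapply(ins$left_context, paste, "", collapse = " "),
    vapply(ins$right_context, paste, "", collapse = " "),
    ins$category,
    ifelse(is.na(ins$rule_id), "", ins$rule_id),
    sep = "\t"
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(meta, header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Load an intermediate database from its plain-text form
#'
#' @param path Path written by [save_intermediate()].
#' @param corpus Optional `notephen_corpus` to re-attach; if its content
#'   fingerprint differs from the one recorded in the file, a staleness
#'   warning (class `notephen_stale_warning`) is emitted — re-run
#'   [find_instances()] if the corpus has changed.
#' @return A `notephen_idb`.
#' @export
load_intermediate <- function(path, corpus = NULL) {
  lines <- readLines(path, warn = FALSE)
  meta_idx <- grep("^#% ", lines)
  meta <- lines[meta_idx]
  get_meta <- function(key) {
    m <- grep(paste0("^#% ", key, "="), meta, value = TRUE)
    if (length(m) != 1L) {
      abort(
        paste0("malformed intermediate file (missing ", key, "): ", path),
        class = "notephen_format_error"
      )
    }
    sub(paste0("^#% ", key, "="), "", m)
  }
  fp <- get_meta("fingerprint")
  window <- as.integer(get_meta("window"))
  pat_raw <- jsonlite::fromJSON(get_meta("pattern"), simplifyDataFrame = FALSE)
  pattern <- structure(
    list(
      condition_name = pat_raw$condition_name,
      stems = as.character(unlist(pat_raw$stems)),
      literals = as.character(unlist(pat_raw$literals)),
      multiword = lapply(pat_raw$multiword, as.character)
    ),
    class = "notephen_pattern"
  )
  body <- lines[-meta_idx]
  if (length(body) < 1L) {
    abort(paste0("malformed intermediate file (no header): ", path),
          class = "notephen_format_error")
  }
  expected <- "instance_id\tpatient_id\tnote_id"
  if (!startsWith(body[1], expected)) {
    abort(paste0("malformed intermediate file (bad header): ", path),
          class = "notephen_format_error")
  }
  body <- body[-1]
  if (length(body) == 0L) {
    instances <- empty_instances()
  } else {
    # sentinel guards against strsplit dropping trailing empty fields
    parts <- strsplit(paste0(body, "\t."), "\t", fixed = TRUE)
    parts <- lapply(parts, function(p) p[-length(p)])
    if (any(lengths(parts) != 12L)) {
      abort(paste0("malformed intermediate file (bad row): ", path),
            class = "notephen_format_error")
    }
    col <- function(i) vapply(parts, `[[`, "", i)
    split_ctx <- function(x) {
      lapply(x, function(s) if (nzchar(s)) strsplit(s, " ", fixed = TRUE)[[1]] else character(0))
    }
    instances <- tibble::tibble(
      instance_id = col(1), patient_id = col(2), note_id = col(3),
      note_type = col(4), condition = col(5),
      match_token_start = as.integer(col(6)),
      match_token_len = as.integer(col(7)),
      surface = col(8),
      left_context = split_ctx(col(9)),
      right_context = split_ctx(col(10)),
      category = col(11),
      rule_id = ifelse(nzchar(col(12)), col(12), NA_character_)
    )
  }
  if (!is.null(corpus) && corpus_fingerprint(corpus) != fp) {
    warn(
      "corpus content differs from the fingerprint recorded in the intermediate database; results may be stale — re-run find_instances()",
      class = "notephen_stale_warning"
    )
  }
  structure(
    list(
      instances = instances,
      pattern = pattern,
      corpus_fingerprint = fp,
      relevant_note_ids = sort(unique(instances$note_id)),
      window = window
    ),
    class = "notephen_idb"
  )
}
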