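# textnorm: stemming and search-pattern compilation ------------------------

# Ordered suffix list for the lightweight medical stemmer. Longest suffix
# whose removal leaves a stem of >= 4 characters wins; one pass only.
# Includes Latinate clinical suffixes (-itis, -itus, -ium, -ious, -ia) so
# that inflection families like delirium/delirious and decubitus collapse
# onto their shared roots.
STEM_SUFFIXES <- c(
  "ization", "ational", "fulness", "ousness", "iveness",
  "ations", "iously", "ation", "ingly", "itis", "itus", "ious",
  "ness", "ment", "ence", "ance", "able", "ible", "ally",
  "ium", "ies", "ial", "ful", "ous", "ive", "ing", "ism",
  "al", "ia", "ic", "ly", "ed", "es", "s"
)
MIN_STEM_LEN <- 4L

#' Stem a normalized token
#'
#' Deterministic lightweight suffix stripping tuned for clinical
#' vocabulary: the longest suffix in a fixed ordered list is removed,
#' provided at least four characters remain. The result is always a prefix
#' of the input, so stem-based search patterns use simple prefix
#' semantics. Short tokens and abbreviations (e.g. `pna`) pass through
#' unchanged.
#'
#' @param token Character vector of normalized tokens.
#' @return Character vector of stems, same length as `token`.
#' @export
#' @examples
#' stem_token(c("delirium", "delirious", "decubitus", "pna"))
stem_token <- function(token) {
  out <- token
  done <- rep(FALSE, length(token))
  nc <- nchar(token)
  for (suf in STEM_SUFFIXES) {
    ns <- nchar(suf)
    hit <- !done & nc - ns >= MIN_STEM_LEN & endsWith(token, suf)
    if (any(hit)) {
      out[hit] <- substr(token[hit], 1L, nc[hit] - ns)
      done <- done | hit
    }
  }
  out
}

# normalize a raw term (full stream, no stop-word removal applied)
normalize_term <- function(term) {
  pp <- preprocess_text(term)
  pp$tokens
}

#' Compile a condition search pattern
#'
#' Turns a condition name plus a raw term list into a matchable pattern.
#' Terms are routed by shape: single-word terms ending in `*` declare an
#' explicit root with prefix semantics (e.g. `"delir*"` matches delirium
#' and delirious); terms containing whitespace become multiword literals
#' (e.g. `"central cord syndrome"`); all other terms are exact-token
#' literals (e.g. the abbreviation `"pna"` alongside `"pneumonia"`). All
#' entries are normalized with the corpus rules.
#'
#' @param condition_name Condition label; becomes the dataset column name,
#'   so it must match `^[A-Za-z][A-Za-z0-9_.]*$`.
#' @param terms Character vector of raw terms (at least one).
#' @return An object of class `notephen_pattern` with elements
#'   `condition_name`, `stems`, `literals`, `multiword` (list of token
#'   vectors).
#' @export
#' @examples
#' compile_pattern("pneumonia", c("pneumonia", "pna"))
#' compile_pattern("delirium", "delir*")
compile_pattern <- function(condition_name, terms) {
  if (!is.character(condition_name) || length(condition_name) != 1L ||
      !grepl("^[A-Za-z][A-Za-z0-9_.]*$", condition_name)) {
    abort(
      "condition_name must be a legal dataset column name ([A-Za-z][A-Za-z0-9_.]*)",
      class = "notephen_spec_error"
    )
  }
  terms <- terms[!is.na(terms)]
  if (length(terms) == 0L) {
    abort(
      paste0("empty term list for condition '", condition_name, "'"),
      class = "notephen_spec_error"
    )
  }
  stems <- character(0)
  literals <- character(0)
  multiword <- list()
  for (term in terms) {
    starred <- grepl("\\*\\s*$", term)
    base <- sub("\\*\\s*$", "", term)
    toks <- normalize_term(base)
    if (length(toks) == 0L) {
      abort(
        paste0("term '", term, "' normalizes to nothing"),
        class = "notephen_spec_error"
      )
    }
    if (length(toks) > 1L) {
      multiword <- c(multiword, list(toks))
    } else if (starred) {
      stems <- c(stems, toks)
    } else {
      literals <- c(literals, toks)
    }
  }
  # longest multiword first so longest-match-wins needs no search
  if (length(multiword) > 0) {
    multiword <- unique(multiword)
    multiword <- multiword[order(-lengths(multiword))]
  }
  structure(
    list(
      condition_name = condition_name,
      stems = sort(unique(stems)),
      literals = sort(unique(literals)),
      multiword = multiword
    ),
    class = "notephen_pattern"
  )
}

#' @export
print.notephen_pattern <- function(x, ...) {
  cat("<search pattern> condition:", x$condition_name, "\n")
  if (length(x$stems)) cat("  stems:    ", paste0(x$stems, "*", collapse = ", "), "\n")
  if (length(x$literals)) cat("  literals: ", paste(x$literals, collapse = ", "), "\n")
  if (length(x$multiword)) {
    cat("  multiword:", paste(vapply(x$multiword, paste, "", collapse = " "),
                              collapse = "; "), "\n")
  }
  invisible(x)
}

#' Test a search pattern at one token position
#'
#' Returns the length (in tokens) of the longest pattern match starting at
#' position `i` of `tokens`, or 0 if nothing matches. Multiword literals
#' beat single-token matches; a stem matches when the token starts with
#' the stem.
#'
#' @param pattern A `notephen_pattern`.
#' @param tokens Character vector of normalized tokens.
#' @param i 1-based token index into `tokens`.
#' @return Integer match length (0 = no match).
#' @export
pattern_match <- function(pattern, tokens, i) {
  n <- length(tokens)
  if (i < 1L || i > n) {
    abort("token index out of range", class = "notephen_contract_error")
  }
  for (mw in pattern$multiword) {
    k <- length(mw)
    if (i + k - 1L <= n && all(tokens[i:(i + k - 1L)] == mw)) return(k)
  }
  tok <- tokens[i]
  if (tok %in% pattern$literals) return(1L)
  if (length(pattern$stems) && any(startsWith(tok, pattern$stems))) return(1L)
  0L
}

#' Load condition search patterns from a spec file
#'
#' One condition per line in JSON-lines form:
#' `{"condition": "pneumonia", "terms": ["pneumonia", "pna"]}`.
#' Every record is validated through [compile_pattern()].
#'
#' @param path Path to a JSON-lines pattern spec file.
#' @return A named list of `notephen_pattern` objects.
#' @export
load_patterns <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pats <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    compile_pattern(rec$condition, unlist(rec$terms))
  })
  names(pats) <- vapply(pats, `[[`, "", "condition_name")
  if (anyDuplicated(names(pats))) {
    abort("duplicate condition name in pattern spec", class = "notephen_spec_error")
  }
  pats
}
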