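# context_library: cue phrases mapped to meaning categories ----------------

RULE_COLS <- c("rule_id", "cue", "side", "max_gap", "category", "source", "created_from")

# conservative category ordering used as a precedence tie-break: prefer
# "absent" readings over "present" ones
CATEGORY_PRECEDENCE <- c(
  DIFFERENT_MEANING = 1L, NEGATED = 2L, UNDER_EVALUATION = 3L,
  HISTORICAL_CHRONIC = 4L, ACUTE_PRESENT = 5L
)

#' Create a cue-phrase rule
#'
#' A rule maps a normalized cue phrase, found within `max_gap` tokens of a
#' condition mention on the permitted `side`, to one of the five meaning
#' categories. A cue may contain the placeholder `<term>`, which stands
#' for the matched term itself and turns the rule into a collocation rule
#' (e.g. `"<term> xray"` marks `decubitus xray` as a different sense of
#' decubitus).
#'
#' @param rule_id Unique rule identifier.
#' @param cue Cue phrase: space-separated normalized tokens, optionally
#'   one `<term>` placeholder.
#' @param category One of the five assignable categories
#'   (see [category_levels()]).
#' @param side Where the cue may appear relative to the match: `"before"`,
#'   `"after"`, or `"either"`. Ignored for placeholder rules, whose cue
#'   fixes the geometry itself.
#' @param max_gap Maximum tokens between cue and match (default 5).
#' @param source `"general"` (reusable) or `"project"` (project-specific).
#' @param created_from Optional condition name the rule was learned from.
#' @return A one-row tibble with the rule fields.
#' @export
#' @examples
#' phrase_rule("neg-01", "no evidence of", "NEGATED")
phrase_rule <- function(rule_id, cue, category,
                        side = c("before", "after", "either"),
                        max_gap = 5L, source = c("general", "project"),
                        created_from = NA_character_) {
  side <- match.arg(side)
  source <- match.arg(source)
  cue <- trimws(cue)
  if (!nzchar(cue)) abort("cue must be non-empty", class = "notephen_rule_error")
  toks <- strsplit(cue, " +")[[1]]
  if (sum(toks == TERM_PLACEHOLDER) > 1L) {
    abort("at most one <term> placeholder per cue", class = "notephen_rule_error")
  }
  if (!category %in% category_levels(assignable = TRUE)) {
    abort(
      paste0("unknown category '", category, "'"),
      class = "notephen_rule_error"
    )
  }
  if (is.na(max_gap) || max_gap < 0) {
    abort("max_gap must be >= 0", class = "notephen_rule_error")
  }
  tibble::tibble(
    rule_id = as.character(rule_id), cue = paste(toks, collapse = " "),
    side = side, max_gap = as.integer(max_gap), category = category,
    source = source, created_from = created_from
  )
}

#' Create a cue-phrase rule library
#'
#' The library is the persistent, supervised knowledge base of the
#' pipeline: it grows with every review session and is what makes
#' categorization automatic on the next project. An append-only
#' provenance log records every addition (including duplicate no-ops).
#'
#' @param rules A tibble of rules (rows as produced by [phrase_rule()]),
#'   or `NULL` for an empty library.
#' @param version Library version string.
#' @return An object of class `notephen_library`.
#' @export
rule_library <- function(rules = NULL, version = "1") {
  if (is.null(rules)) {
    rules <- tibble::tibble(
      rule_id = character(0), cue = character(0), side = character(0),
      max_gap = integer(0), category = character(0), source = character(0),
      created_from = character(0)
    )
  }
  validate_rules(rules)
  structure(
    list(
      rules = rules[, RULE_COLS],
      version = version,
      provenance = tibble::tibble(
        rule_id = character(0), action = character(0), project = character(0)
      )
    ),
    class = "notephen_library"
  )
}

validate_rules <- function(rules, where = "library") {
  stopifnot(all(RULE_COLS %in% names(rules)))
  bad_cat <- which(!rules$category %in% category_levels(assignable = TRUE))
  if (length(bad_cat) > 0) {
    abort(
      paste0(
        "unknown category '", rules$category[bad_cat[1]], "' in ", where,
        " at rule ", bad_cat[1]
      ),
      class = "notephen_format_error"
    )
  }
  dup <- rules$rule_id[duplicated(rules$rule_id)]
  if (length(dup) > 0) {
    abort(
      paste0("duplicate rule_id in ", where, ": ", paste(unique(dup), collapse = ", ")),
      class = "notephen_format_error"
    )
  }
  invisible(rules)
}

#' Add a rule to a library
#'
#' A rule whose `(cue, side, max_gap, category)` already exists is a
#' no-op, recorded in the provenance log; the library never accumulates
#' exact duplicates.
#'
#' @param lib A `notephen_library`.
#' @param rule A one-row rule tibble from [phrase_rule()].
#' @param project Optional project tag for the provenance log.
#' @return The updated library.
#' @export
add_rule <- function(lib, rule, project = NA_character_) {
  stopifnot(inherits(lib, "notephen_library"), nrow(rule) == 1L)
  dup <- any(
    lib$rules$cue == rule$cue & lib$rules$side == rule$side &
      lib$rules$max_gap == rule$max_gap & lib$rules$category == rule$category
  )
  action <- if (dup) "duplicate_noop" else "add"
  if (!dup) {
    if (rule$rule_id %in% lib$rules$rule_id) {
      abort(
        paste0("rule_id '", rule$rule_id, "' already exists with different content"),
        class = "notephen_rule_error"
      )
    }
    lib$rules <- dplyr::bind_rows(lib$rules, rule)
  }
  lib$provenance <- dplyr::bind_rows(
    lib$provenance,
    tibble::tibble(rule_id = rule$rule_id, action = action, project = project)
  )
  lib
}

#' @export
print.notephen_library <- function(x, ...) {
  cat(
    "<rule library> rules:", nrow(x$rules),
    "| version:", x$version, "\n"
  )
  if (nrow(x$rules) > 0) print(table(x$rules$category))
  invisible(x)
}

# the starter cue inventory: standard clinical phrases for each category,
# plus collocation rules for classic different-sense traps
starter_rule_table <- function() {
  if (is.null(the$starter_rules)) {
    path <- system.file("extdata", "starter_rules.csv", package = "notephen")
    the$starter_rules <- readr::read_csv(
      path,
      col_types = readr::cols(
        rule_id = "c", cue = "c", side = "c", max_gap = "i",
        category = "c", source = "c", created_from = "c"
      ),
      progress = FALSE
    )
  }
  the$starter_rules
}

#' The starter rule library
#'
#' Loads the general-purpose cue-phrase library shipped with the package:
#' standard clinical phrases for each of the five meaning categories
#' ("currently with", "history of", "no evidence of", "suspected", ...)
#' plus collocation rules for classic different-sense traps (`<term>
#' xray`, `joint <term>`, `<term> anticoagulant`).
#'
#' @return A `notephen_library`.
#' @export
#' @examples
#' default_rule_library()
default_rule_library <- function() {
  rule_library(starter_rule_table(), version = "starter-1")
}

#' Save / load a rule library
#'
#' Libraries persist as plain CSV, one rule per row, columns
#' `rule_id, cue, side, max_gap, category, source, created_from`. The
#' loader validates every rule (closed category vocabulary, unique ids).
#'
#' @param lib A `notephen_library`.
#' @param path File path.
#' @return `save_library` returns `path` invisibly; `load_library`
#'   returns a `notephen_library`.
#' @export
save_library <- function(lib, path) {
  readr::write_csv(lib$rules, path, na = "", eol = "\n", progress = FALSE)
  invisible(path)
}

#' @rdname save_library
#' @param version Version string to attach on load.
#' @export
load_library <- function(path, version = "1") {
  rules <- readr::read_csv(
    path,
    col_types = readr::cols(
      rule_id = "c", cue = "c", side = "c", max_gap = "i",
      category = "c", source = "c", created_from = "c"
    ),
    progress = FALSE
  )
  if (nrow(rules) > 0 && any(!rules$side %in% c("before", "after", "either"))) {
    abort(paste0("invalid side value in ", path), class = "notephen_format_error")
  }
  rule_library(validate_rules(rules, where = path), version = version)
}

# find 1-based start positions of a contiguous token subsequence
seq_find <- function(hay, needle) {
  n <- length(hay)
  k <- length(needle)
  if (k == 0L || k > n) return(integer(0))
  idx <- which(hay == needle[1])
  idx <- idx[idx + k - 1L <= n]
  if (k == 1L || length(idx) == 0L) return(idx)
  idx[vapply(idx, function(s) all(hay[s:(s + k - 1L)] == needle), logical(1))]
}

# Evaluate one rule against an instance's contexts. Returns NULL (no
# fire) or a list(distance, cue_len, placeholder).
fire_rule <- function(cue, side, max_gap, left, right) {
  toks <- strsplit(cue, " ", fixed = TRUE)[[1]]
  ph <- which(toks == TERM_PLACEHOLDER)
  nl <- length(left)
  if (length(ph) == 1L) {
    before_part <- if (ph > 1L) toks[seq_len(ph - 1L)] else character(0)
    after_part <- if (ph < length(toks)) toks[(ph + 1L):length(toks)] else character(0)
    gb <- 0L
    if (length(before_part) > 0) {
      occ <- seq_find(left, before_part)
      if (length(occ) == 0L) return(NULL)
      gaps <- nl - (occ + length(before_part) - 1L)
      gaps <- gaps[gaps <= max_gap]
      if (length(gaps) == 0L) return(NULL)
      gb <- min(gaps)
    }
    ga <- 0L
    if (length(after_part) > 0) {
      occ <- seq_find(right, after_part)
      if (length(occ) == 0L) return(NULL)
      gaps <- occ - 1L
      gaps <- gaps[gaps <= max_gap]
      if (length(gaps) == 0L) return(NULL)
      ga <- min(gaps)
    }
    return(list(distance = gb + ga, cue_len = length(toks), placeholder = TRUE))
  }
  best <- Inf
  if (side %in% c("before", "either")) {
    occ <- seq_find(left, toks)
    if (length(occ) > 0) {
      gaps <- nl - (occ + length(toks) - 1L)
      gaps <- gaps[gaps <= max_gap]
      if (length(gaps) > 0) best <- min(best, min(gaps))
    }
  }
  if (side %in% c("after", "either")) {
    occ <- seq_find(right, toks)
    if (length(occ) > 0) {
      gaps <- occ - 1L
      gaps <- gaps[gaps <= max_gap]
      if (length(gaps) > 0) best <- min(best, min(gaps))
    }
  }
  if (!is.finite(best)) return(NULL)
  list(distance = as.integer(best), cue_len = length(toks), placeholder = FALSE)
}

#' Match library rules against one instance
#'
#' Scans the instance's left/right contexts for every cue in the library
#' and returns the winning rule under the documented precedence:
#' (1) `DIFFERENT_MEANING` placeholder rules win outright (they redefine
#' the entity itself); then (2) smallest token distance between cue and
#' match; (3) longest cue; (4) conservative category order
#' `DIFFERENT_MEANING` > `NEGATED` > `UNDER_EVALUATION` >
#' `HISTORICAL_CHRONIC` > `ACUTE_PRESENT`; (5) lexicographically smallest
#' `rule_id`. Sentence boundaries are not enforced; `max_gap` is the sole
#' scope limiter.
#'
#' @param instance A one-row slice of an intermediate database's
#'   `instances` tibble (contexts populated).
#' @param lib A `notephen_library`.
#' @return `NULL` if no rule fires, else a list with `rule` (one-row
#'   tibble) and `category`.
#' @export
match_rules <- function(instance, lib) {
  left <- instance$left_context[[1]]
  right <- instance$right_context[[1]]
  rules <- lib$rules
  if (nrow(rules) == 0L) return(NULL)
  fires <- vector("list", nrow(rules))
  for (i in seq_len(nrow(rules))) {
    fires[[i]] <- fire_rule(
      rules$cue[i], rules$side[i], rules$max_gap[i], left, right
    )
  }
  hit <- which(!vapply(fires, is.null, logical(1)))
  if (length(hit) == 0L) return(NULL)
  cand <- tibble::tibble(
    idx = hit,
    dm_placeholder = vapply(
      hit,
      function(i) fires[[i]]$placeholder && rules$category[i] == "DIFFERENT_MEANING",
      logical(1)
    ),
    distance = vapply(hit, function(i) fires[[i]]$distance, integer(1)),
    cue_len = vapply(hit, function(i) fires[[i]]$cue_len, integer(1)),
    cat_rank = unname(CATEGORY_PRECEDENCE[rules$category[hit]]),
    rule_id = rules$rule_id[hit]
  )
  cand <- cand[order(
    !cand$dm_placeholder, cand$distance, -cand$cue_len, cand$cat_rank, cand$rule_id
  ), ]
  win <- cand$idx[1]
  list(rule = rules[win, ], category = rules$category[win])
}
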