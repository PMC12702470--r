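# annotate: library-driven categorization and the review workflow ----------

#' Auto-categorize every instance from the rule library
#'
#' Applies [match_rules()] to each instance of the intermediate database.
#' Instances with a winning rule receive its category and `rule_id`;
#' the rest are `UNCATEGORIZED`. Categories are recomputed from scratch,
#' so the operation is idempotent.
#'
#' @param db A `notephen_idb`.
#' @param lib A `notephen_library`.
#' @param only_uncategorized If `TRUE`, leave existing five-category
#'   labels (e.g. manual review decisions) untouched and classify only
#'   the `UNCATEGORIZED` remainder.
#' @return A list with `db` (categorized) and `uncategorized_ids`
#'   (character vector of instance ids the library could not classify).
#' @export
categorize_corpus <- function(db, lib, only_uncategorized = FALSE) {
  ins <- db$instances
  todo <- if (only_uncategorized) {
    which(ins$category == "UNCATEGORIZED")
  } else {
    seq_len(nrow(ins))
  }
  for (i in todo) {
    res <- match_rules(ins[i, ], lib)
    if (is.null(res)) {
      ins$category[i] <- "UNCATEGORIZED"
      ins$rule_id[i] <- NA_character_
    } else {
      ins$category[i] <- res$category
      ins$rule_id[i] <- res$rule$rule_id
    }
  }
  db$instances <- ins
  list(db = db, uncategorized_ids = ins$instance_id[ins$category == "UNCATEGORIZED"])
}

# keyword-in-context key: k tokens before, the placeholder, k tokens after
context_key <- function(left, right, k) {
  paste(c(tail(left, k), TERM_PLACEHOLDER, head(right, k)), collapse = " ")
}

#' Group uncategorized instances by shared context window
#'
#' The review workflow shows uncategorized mentions keyword-in-context at
#' half-width `k`; mentions with byte-identical windows are collapsed into
#' one group so a single decision covers all of them. Groups are sorted by
#' descending member count (biggest savings first), ties by key.
#'
#' @param db A `notephen_idb` (after [categorize_corpus()]).
#' @param k Window half-width in tokens (>= 1).
#' @return A tibble with `context_key`, `k`, `n_members`, and
#'   `instance_ids` (list-column).
#' @export
review_groups <- function(db, k) {
  stopifnot(k >= 1L)
  ins <- db$instances
  unc <- ins[ins$category == "UNCATEGORIZED", ]
  if (nrow(unc) == 0L) {
    return(tibble::tibble(
      context_key = character(0), k = integer(0),
      n_members = integer(0), instance_ids = list()
    ))
  }
  keys <- vapply(
    seq_len(nrow(unc)),
    function(i) context_key(unc$left_context[[i]], unc$right_context[[i]], k),
    ""
  )
  split_ids <- split(unc$instance_id, keys)
  out <- tibble::tibble(
    context_key = names(split_ids),
    k = as.integer(k),
    n_members = unname(lengths(split_ids)),
    instance_ids = unname(split_ids)
  )
  out[order(-out$n_members, out$context_key), ]
}

# Derive the minimal distinguishing cue for a reviewed context window:
# the shortest token run adjacent to the term (preferring the before
# side) that appears in no other group's window; falls back to the full
# window as a placeholder collocation rule.
derive_rule_cue <- function(key, other_keys, k) {
  toks <- strsplit(key, " ", fixed = TRUE)[[1]]
  ph <- which(toks == TERM_PLACEHOLDER)
  left <- if (ph > 1L) toks[seq_len(ph - 1L)] else character(0)
  right <- if (ph < length(toks)) toks[(ph + 1L):length(toks)] else character(0)
  other_tok <- lapply(other_keys, function(x) strsplit(x, " ", fixed = TRUE)[[1]])
  occurs_elsewhere <- function(cue) {
    any(vapply(other_tok, function(h) length(seq_find(h, cue)) > 0, logical(1)))
  }
  for (l in seq_len(max(length(left), length(right)))) {
    if (l <= length(left)) {
      cue <- tail(left, l)
      if (!occurs_elsewhere(cue)) {
        return(list(cue = paste(cue, collapse = " "), side = "before"))
      }
    }
    if (l <= length(right)) {
      cue <- head(right, l)
      if (!occurs_elsewhere(cue)) {
        return(list(cue = paste(cue, collapse = " "), side = "after"))
      }
    }
  }
  list(cue = key, side = "either")   # full window, contains <term>
}

#' Apply a review decision to a group
#'
#' Labels every member of the group with the chosen category, derives a
#' cue-phrase rule from the group's context window (the minimal
#' distinguishing cue against the other open groups, or the full window
#' if no shorter cue is unique), and appends it to the library under the
#' chosen scope. Re-applying the same decision is a logged no-op on the
#' library side.
#'
#' @param db A `notephen_idb`.
#' @param group One row of [review_groups()] output.
#' @param category One of the five assignable categories.
#' @param scope `"general"` or `"project"` — where the learned rule goes.
#' @param lib A `notephen_library`.
#' @param groups The full group table the decision was made against
#'   (used for minimal-cue derivation); defaults to the group alone.
#' @param project Optional project tag for provenance.
#' @return A list with `db`, `lib`, and `rule` (the derived rule row).
#' @export
apply_assignment <- function(db, group, category, scope = c("general", "project"),
                             lib, groups = NULL, project = NA_character_) {
  scope <- match.arg(scope)
  if (!category %in% category_levels(assignable = TRUE)) {
    abort(
      paste0("cannot assign category '", category, "'"),
      class = "notephen_contract_error"
    )
  }
  other_keys <- if (!is.null(groups)) {
    setdiff(groups$context_key, group$context_key)
  } else {
    character(0)
  }
  d <- derive_rule_cue(group$context_key, other_keys, group$k)
  rid <- paste0("lrn-", substr(rlang::hash(list(d$cue, d$side, category)), 1, 10))
  rule <- phrase_rule(
    rid, d$cue, category,
    side = d$side, max_gap = group$k, source = scope,
    created_from = db$pattern$condition_name
  )
  lib <- add_rule(lib, rule, project = project)
  idx <- db$instances$instance_id %in% group$instance_ids[[1]]
  db$instances$category[idx] <- category
  db$instances$rule_id[idx] <- rid
  list(db = db, lib = lib, rule = rule)
}

#' Turn a decision transcript into a decision source
#'
#' A transcript is a data frame with columns `context_key`, `category`,
#' `scope`; the returned function answers review queries by exact key
#' lookup and abstains (returns `NULL`) on unknown keys. Replaying a
#' transcript recorded by [review_session()] reproduces the session
#' exactly.
#'
#' @param transcript Data frame with `context_key`, `category`, `scope`.
#' @return A function `(group, k) -> NULL | list(category, scope)`.
#' @export
transcript_decider <- function(transcript) {
  force(transcript)
  function(group, k) {
    hit <- which(transcript$context_key == group$context_key)
    if (length(hit) == 0L) return(NULL)
    list(
      category = transcript$category[hit[1]],
      scope = transcript$scope[hit[1]]
    )
  }
}

#' Run an expanding-context review session
#'
#' Implements the review loop: group the uncategorized instances at the
#' narrowest window half-width, ask the decision source about each group
#' (largest first), apply every answer (labeling all members and growing
#' the library), re-categorize the remainder with the grown library, and
#' widen the window for whatever is left. The uncategorized count never
#' increases; with a decision source that answers everything the session
#' ends at zero. If the source abstains on groups even at the widest
#' window, those instances are returned as an unresolved report rather
#' than an error.
#'
#' @param db A `notephen_idb` (already passed through
#'   [categorize_corpus()], or not — the session categorizes first).
#' @param lib A `notephen_library`.
#' @param decisions A decision source: a function `(group, k)` returning
#'   `NULL` or `list(category, scope)`, or a transcript data frame
#'   (see [transcript_decider()]).
#' @param k_schedule Strictly increasing window half-widths
#'   (default `c(3, 5, 8, 12)`; capped by the stored context window).
#' @param project Optional project tag for library provenance.
#' @return A list with `db`, `lib`, `transcript` (tibble of applied
#'   decisions: `k`, `context_key`, `category`, `scope`), and
#'   `unresolved` (tibble of still-uncategorized instances).
#' @export
review_session <- function(db, lib, decisions, k_schedule = c(3L, 5L, 8L, 12L),
                           project = NA_character_) {
  if (any(diff(k_schedule) <= 0) || any(k_schedule < 1)) {
    abort("k_schedule must be strictly increasing and >= 1",
          class = "notephen_contract_error")
  }
  if (is.data.frame(decisions)) decisions <- transcript_decider(decisions)
  k_schedule <- pmin(as.integer(k_schedule), db$window)
  k_schedule <- unique(k_schedule)
  res <- categorize_corpus(db, lib, only_uncategorized = TRUE)
  db <- res$db
  transcript <- tibble::tibble(
    k = integer(0), context_key = character(0),
    category = character(0), scope = character(0)
  )
  for (k in k_schedule) {
    groups <- review_groups(db, k)
    if (nrow(groups) == 0L) break
    for (g in seq_len(nrow(groups))) {
      ans <- decisions(groups[g, ], k)
      if (is.null(ans)) next
      applied <- apply_assignment(
        db, groups[g, ], ans$category,
        scope = ans$scope, lib = lib, groups = groups, project = project
      )
      db <- applied$db
      lib <- applied$lib
      transcript <- dplyr::bind_rows(transcript, tibble::tibble(
        k = as.integer(k), context_key = groups$context_key[g],
        category = ans$category, scope = ans$scope
      ))
    }
    # learned rules may cover other open instances
    res <- categorize_corpus(db, lib, only_uncategorized = TRUE)
    db <- res$db
  }
  unresolved <- db$instances[db$instances$category == "UNCATEGORIZED", ]
  list(db = db, lib = lib, transcript = transcript, unresolved = unresolved)
}

#' Save / read a review transcript
#'
#' Transcripts persist as JSON-lines, one decision per line; they double
#' as the audit trail making every review replayable.
#'
#' @param transcript Tibble with `k`, `context_key`, `category`, `scope`.
#' @param path File path.
#' @export
write_transcript <- function(transcript, path) {
  lines <- vapply(
    seq_len(nrow(transcript)),
    function(i) {
      jsonlite::toJSON(as.list(transcript[i, ]), auto_unbox = TRUE)
    },
    ""
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_transcript
#' @export
read_transcript <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  dplyr::bind_rows(lapply(lines, function(l) {
    tibble::as_tibble(jsonlite::fromJSON(l))
  }))
}
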