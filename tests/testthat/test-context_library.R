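make_instance <- function(left, right) {
  tibble::tibble(
    instance_id = "i1", patient_id = "p", note_id = "n", note_type = "other",
    condition = "c", match_token_start = length(left), match_token_len = 1L,
    surface = "term",
    left_context = list(left), right_context = list(right),
    category = "UNCATEGORIZED", rule_id = NA_character_
  )
}

test_that("the starter library carries the standard cue inventory", {
  lib <- default_rule_library()
  expect_gte(nrow(lib$rules), 13L)
  expect_setequal(unique(lib$rules$category), category_levels(assignable = TRUE))
  expect_true("no evidence of" %in% lib$rules$cue)
})

test_that("library files round-trip and are validated on load", {
  lib <- default_rule_library()
  f <- withr::local_tempfile(fileext = ".csv")
  save_library(lib, f)
  back <- load_library(f)
  expect_equal(back$rules, lib$rules)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "rule_id,cue,side,max_gap,category,source,created_from",
    "r1,some cue,before,5,maybe,general,"
  ), bad)
  expect_error(load_library(bad), "maybe", class = "notephen_format_error")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "rule_id,cue,side,max_gap,category,source,created_from",
    "r1,cue one,before,5,NEGATED,general,",
    "r1,cue two,before,5,NEGATED,general,"
  ), dup)
  expect_error(load_library(dup), "duplicate rule_id", class = "notephen_format_error")
})

test_that("phrase_rule validates its invariants", {
  expect_error(phrase_rule("r", "", "NEGATED"), class = "notephen_rule_error")
  expect_error(phrase_rule("r", "<term> x <term>", "NEGATED"),
               class = "notephen_rule_error")
  expect_error(phrase_rule("r", "cue", "UNCATEGORIZED"),
               class = "notephen_rule_error")
  expect_error(phrase_rule("r", "cue", "NEGATED", max_gap = -1),
               class = "notephen_rule_error")
})

test_that("duplicate rule insertion is a logged no-op", {
  lib <- rule_library()
  r <- phrase_rule("r1", "no sign of", "NEGATED")
  lib <- add_rule(lib, r)
  lib <- add_rule(lib, phrase_rule("r2", "no sign of", "NEGATED"))
  expect_equal(nrow(lib$rules), 1L)
  expect_equal(lib$provenance$action, c("add", "duplicate_noop"))
})

test_that("match_rules classifies the canonical cue examples", {
  lib <- default_rule_library()
  neg <- match_rules(make_instance(c("exam", "no", "evidence", "of"), c("today")), lib)
  expect_equal(neg$category, "NEGATED")

  hist <- match_rules(make_instance(c("history", "of"), c("noted")), lib)
  expect_equal(hist$category, "HISTORICAL_CHRONIC")

  # collocation rule: decubitus xray is a different sense of decubitus
  dm <- match_rules(make_instance(c("portable"), c("xray", "obtained")), lib)
  expect_equal(dm$category, "DIFFERENT_MEANING")

  expect_null(match_rules(make_instance(c("routine"), c("followup")), lib))
  expect_null(match_rules(make_instance(c("no", "evidence", "of"), c("x")),
                          rule_library()))  # empty library
})

test_that("cues outside max_gap do not fire; nearest cue wins", {
  lib <- rule_library()
  lib <- add_rule(lib, phrase_rule("neg", "no evidence of", "NEGATED", max_gap = 2))
  lib <- add_rule(lib, phrase_rule("acu", "admitted with", "ACUTE_PRESENT", max_gap = 5))

  far <- make_instance(c("no", "evidence", "of", "a", "b", "c"), character(0))
  expect_null(match_rules(far, lib))  # gap 3 > max_gap 2

  both <- make_instance(c("admitted", "with", "no", "evidence", "of"), character(0))
  expect_equal(match_rules(both, lib)$category, "NEGATED")  # distance 0 beats 3
})

test_that("match_rules agrees with exhaustive (rule, position) enumeration", {
  lib <- default_rule_library()
  vocab <- c(
    "no", "evidence", "of", "history", "currently", "with", "admitted",
    "negative", "for", "doubt", "without", "may", "have", "suspected",
    "assessment", "joint", "xray", "anticoagulant", "chief", "complaint",
    "stable", "exam", "plan", "labs", "as", "a", "child"
  )
  withr::with_seed(17, {
    for (rep in 1:60) {
      left <- sample(vocab, sample(0:10, 1), replace = TRUE)
      right <- sample(vocab, sample(0:10, 1), replace = TRUE)
      got <- match_rules(make_instance(left, right), lib)
      want <- oracle_match_rules(left, right, lib$rules)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(got$rule$rule_id, want)
      }
    }
  })
})

test_that("adding an irrelevant rule never changes unrelated outcomes", {
  lib <- default_rule_library()
  inst <- make_instance(c("history", "of"), c("noted"))
  before <- match_rules(inst, lib)
  lib2 <- add_rule(lib, phrase_rule("zz-distant", "completely unrelated phrase",
                                    "NEGATED"))
  after <- match_rules(inst, lib2)
  expect_equal(after$rule$rule_id, before$rule$rule_id)
})
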