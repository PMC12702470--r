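test_that("categorize_corpus: complete library -> zero uncategorized; empty -> all; idempotent", {
  sim <- simulate_corpus(sim_config(n_patients = 50, seed = 21))
  db <- find_instances(as_note_corpus(sim$notes), pneumonia_pattern())

  res <- categorize_corpus(db, sim$cue_library)
  expect_length(res$uncategorized_ids, 0)

  # labels equal the generator's intended categories
  truth <- sim$truth[sim$truth$condition == "pneumonia", ]
  got <- res$db$instances
  expect_equal(nrow(got), nrow(truth))
  truth_sorted <- truth[order(truth$note_id, truth$category), ]
  got_sorted <- got[order(got$note_id, got$category), ]
  expect_equal(
    table(got_sorted$category)[sort(unique(truth$category))],
    table(truth_sorted$category)[sort(unique(truth$category))]
  )

  res_empty <- categorize_corpus(db, rule_library())
  expect_equal(length(res_empty$uncategorized_ids), nrow(db$instances))

  res2 <- categorize_corpus(res$db, sim$cue_library)
  expect_equal(res2$db$instances, res$db$instances)  # idempotent
})

test_that("review_groups collapses identical windows, biggest group first", {
  mk <- function(id, left, right) {
    tibble::tibble(
      instance_id = id, patient_id = "p", note_id = id, note_type = "other",
      condition = "c", match_token_start = 0L, match_token_len = 1L,
      surface = "t", left_context = list(left), right_context = list(right),
      category = "UNCATEGORIZED", rule_id = NA_character_
    )
  }
  db <- structure(list(
    instances = dplyr::bind_rows(
      mk("a", c("spiking", "fevers"), c("on", "exam")),
      mk("b", c("spiking", "fevers"), c("on", "exam")),
      mk("c", c("spiking", "fevers"), c("on", "exam")),
      mk("d", c("other", "context"), c("entirely")),
      mk("e", c("third", "window"), c("here"))
    ),
    pattern = pneumonia_pattern(), corpus_fingerprint = "x",
    relevant_note_ids = letters[1:5], window = 12L
  ), class = "notephen_idb")

  g <- review_groups(db, k = 3)
  expect_equal(g$n_members[1], 3L)   # shared window listed first
  expect_equal(sum(g$n_members), 5L) # groups partition the uncategorized set
  expect_setequal(unlist(g$instance_ids), letters[1:5])

  # saturated k cannot merge distinct windows further
  g2 <- review_groups(db, k = 50)
  expect_equal(nrow(g2), 3L)

  empty_db <- db
  empty_db$instances$category <- "NEGATED"
  expect_equal(nrow(review_groups(empty_db, 3)), 0L)
})

test_that("apply_assignment labels the group, grows the library, shrinks the list", {
  sim <- simulate_corpus(sim_config(n_patients = 40, seed = 33))
  db <- find_instances(as_note_corpus(sim$notes), pneumonia_pattern())
  db <- categorize_corpus(db, rule_library())$db  # everything uncategorized
  n0 <- sum(db$instances$category == "UNCATEGORIZED")
  groups <- review_groups(db, 3)
  lib <- rule_library()

  applied <- apply_assignment(db, groups[1, ], "NEGATED", "general", lib,
                              groups = groups)
  n1 <- sum(applied$db$instances$category == "UNCATEGORIZED")
  expect_equal(n0 - n1, groups$n_members[1])
  expect_equal(nrow(applied$lib$rules), 1L)

  # same decision again: library no-op
  applied2 <- apply_assignment(applied$db, groups[1, ], "NEGATED", "general",
                               applied$lib, groups = groups)
  expect_equal(nrow(applied2$lib$rules), 1L)
  expect_true("duplicate_noop" %in% applied2$lib$provenance$action)

  expect_error(
    apply_assignment(db, groups[1, ], "UNCATEGORIZED", "general", lib),
    class = "notephen_contract_error"
  )
})

test_that("review_session reaches zero uncategorized with scripted decisions", {
  sim <- simulate_corpus(sim_config(n_patients = 50, seed = 21))
  db <- find_instances(as_note_corpus(sim$notes), pneumonia_pattern())

  # oracle decision source: answer every group from the generator's truth
  truth_by_note <- split(sim$truth$category[sim$truth$condition == "pneumonia"],
                         sim$truth$note_id[sim$truth$condition == "pneumonia"])
  decider <- function(group, k) {
    ids <- group$instance_ids[[1]]
    notes <- sub("#.*$", "", ids)
    list(category = truth_by_note[[notes[1]]][1], scope = "project")
  }
  res <- review_session(db, rule_library(), decider)
  expect_equal(nrow(res$unresolved), 0L)
  expect_gt(nrow(res$lib$rules), 0L)
})

test_that("uncategorized count never increases during a session (monotone shrinkage)", {
  sim <- simulate_corpus(sim_config(n_patients = 30, seed = 44))
  db <- find_instances(as_note_corpus(sim$notes), pneumonia_pattern())
  counts <- integer(0)
  spy <- function(group, k) {
    counts <<- c(counts, NA_integer_)  # marker: one query
    if (runif(1) < 0.5) list(category = "NEGATED", scope = "project") else NULL
  }
  withr::with_seed(3, {
    res <- review_session(db, rule_library(), spy)
  })
  # recompute trajectory by replaying the transcript step by step
  db2 <- categorize_corpus(db, rule_library())$db
  n_prev <- sum(db2$instances$category == "UNCATEGORIZED")
  lib2 <- rule_library()
  for (i in seq_len(nrow(res$transcript))) {
    g <- review_groups(db2, res$transcript$k[i])
    hit <- which(g$context_key == res$transcript$context_key[i])
    if (length(hit) == 0) next
    a <- apply_assignment(db2, g[hit, ], res$transcript$category[i],
                          res$transcript$scope[i], lib2, groups = g)
    db2 <- a$db; lib2 <- a$lib
    n_now <- sum(db2$instances$category == "UNCATEGORIZED")
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("a replayed transcript reproduces the session exactly", {
  sim <- simulate_corpus(sim_config(n_patients = 30, seed = 55))
  db <- find_instances(as_note_corpus(sim$notes), pneumonia_pattern())
  truth_by_note <- split(sim$truth$category[sim$truth$condition == "pneumonia"],
                         sim$truth$note_id[sim$truth$condition == "pneumonia"])
  decider <- function(group, k) {
    ids <- group$instance_ids[[1]]
    list(category = truth_by_note[[sub("#.*$", "", ids[1])]][1], scope = "general")
  }
  res1 <- review_session(db, rule_library(), decider)

  f <- withr::local_tempfile(fileext = ".jsonl")
  write_transcript(res1$transcript, f)
  res2 <- review_session(db, rule_library(), read_transcript(f))
  expect_equal(res2$db$instances, res1$db$instances)
  expect_equal(res2$lib$rules, res1$lib$rules)
  expect_equal(res2$transcript, res1$transcript)
})

test_that("an abstaining decision source yields an unresolved report, not an error", {
  sim <- simulate_corpus(sim_config(n_patients = 20, seed = 66))
  db <- find_instances(as_note_corpus(sim$notes), pneumonia_pattern())
  res <- review_session(db, rule_library(), function(group, k) NULL)
  expect_equal(nrow(res$unresolved), nrow(db$instances))
  expect_equal(nrow(res$transcript), 0L)
})

test_that("k_schedule must be strictly increasing", {
  sim <- simulate_corpus(sim_config(n_patients = 5, seed = 1))
  db <- find_instances(as_note_corpus(sim$notes), pneumonia_pattern())
  expect_error(
    review_session(db, rule_library(), function(g, k) NULL, k_schedule = c(5, 3)),
    class = "notephen_contract_error"
  )
})
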