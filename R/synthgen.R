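# synthgen: synthetic multi-note corpora with known ground truth -----------

# filler vocabulary for neutral sentence padding; deliberately disjoint
# from every starter cue word and from the default condition terms, so
# cue-phrase scope is controlled by construction
FILLER_WORDS <- c(
  "vitals", "stable", "overnight", "afebrile", "ambulating", "tolerating",
  "diet", "labs", "reviewed", "unremarkable", "plan", "continue",
  "monitoring", "exam", "benign", "improving", "oriented", "comfortable",
  "resting", "wound", "clean", "dressing", "changed", "family", "updated"
)

# cue inventory used by the generator: exactly the starter library
GEN_CUES <- list(
  ACUTE_PRESENT = c("currently with", "admitted with", "chief complaint"),
  HISTORICAL_CHRONIC = c("history of", "previous hospitalization for", "as a child"),
  NEGATED = c("no evidence of", "negative for", "doubt", "without"),
  UNDER_EVALUATION = c("may have", "suspected", "assessment for"),
  DIFFERENT_MEANING = c("<term> xray", "joint <term>", "<term> anticoagulant")
)

#' Define a simulated condition
#'
#' @param name Condition name (legal dataset column name).
#' @param terms Term list including abbreviations/synonyms; the same list
#'   is used to embed mentions and to compile the search pattern.
#' @param prevalence Probability a patient truly has the condition,
#'   in (0, 1).
#' @param chronic_fraction Fraction of true positives whose condition is
#'   chronic/historical rather than acute, in \[0, 1\].
#' @return A list describing the condition.
#' @export
sim_condition <- function(name, terms, prevalence = 0.10, chronic_fraction = 0.5) {
  if (prevalence <= 0 || prevalence >= 1) {
    abort("sim_condition: prevalence must be in (0, 1)",
          class = "notephen_config_error")
  }
  if (chronic_fraction < 0 || chronic_fraction > 1) {
    abort("sim_condition: chronic_fraction must be in [0, 1]",
          class = "notephen_config_error")
  }
  list(
    name = name, terms = terms,
    prevalence = prevalence, chronic_fraction = chronic_fraction
  )
}

#' Simulation configuration
#'
#' Describes a synthetic single-admission ICU-style cohort: multi-note
#' patients (one history & physical, one to five daily progress notes,
#' one discharge summary), configurable condition prevalence, mentions
#' drawn from all five context categories using the starter cue
#' inventory, abbreviation/synonym surface forms, note bloat via copied
#' sentences, and an ICD-style comparator labeling derived from the gold
#' labels by random flips (with an extra false-negative boost for chronic
#' conditions, emulating chronic-omission coding errors).
#'
#' @param n_patients Number of patients.
#' @param conditions List of [sim_condition()] specs.
#' @param category_mix Named probability vector over the five categories,
#'   used for extra mentions in truly positive patients; must sum to 1.
#' @param extra_mention_rate Poisson mean of extra mentions per positive
#'   patient-condition (beyond the guaranteed anchor mention).
#' @param distractor_rate Poisson mean of distractor mentions (negated /
#'   under-evaluation / different-meaning) per negative patient-condition.
#' @param bloat_factor Poisson mean of duplicated (copied) sentences per
#'   note; bloat changes note length, never the ground truth.
#' @param comparator_error List with `fn_rate`, `fp_rate`,
#'   `chronic_fn_boost`: gold positives flip to 0 with probability
#'   `fn_rate` (+ `chronic_fn_boost` when chronic), gold negatives flip
#'   to 1 with probability `fp_rate`.
#' @param seed Integer seed; output is fully determined by the config.
#' @return An object of class `notephen_sim_config`.
#' @export
sim_config <- function(n_patients = 500L,
                       conditions = list(
                         sim_condition("pneumonia", c("pneumonia", "pna")),
                         sim_condition("delirium", c("delirium", "delirious"))
                       ),
                       category_mix = c(
                         ACUTE_PRESENT = 0.45, HISTORICAL_CHRONIC = 0.20,
                         NEGATED = 0.20, UNDER_EVALUATION = 0.10,
                         DIFFERENT_MEANING = 0.05
                       ),
                       extra_mention_rate = 1,
                       distractor_rate = 0.3,
                       bloat_factor = 1,
                       comparator_error = list(
                         fn_rate = 0.25, fp_rate = 0.05, chronic_fn_boost = 0.15
                       ),
                       seed = 1L) {
  if (n_patients < 1) {
    abort("sim_config: n_patients must be >= 1", class = "notephen_config_error")
  }
  if (!setequal(names(category_mix), category_levels(assignable = TRUE))) {
    abort("sim_config: category_mix must name exactly the five categories",
          class = "notephen_config_error")
  }
  if (abs(sum(category_mix) - 1) > 1e-8) {
    abort("sim_config: category_mix must sum to 1", class = "notephen_config_error")
  }
  for (fld in c("fn_rate", "fp_rate", "chronic_fn_boost")) {
    v <- comparator_error[[fld]]
    if (is.null(v) || v < 0 || v > 1) {
      abort(paste0("sim_config: comparator_error$", fld, " must be in [0, 1]"),
            class = "notephen_config_error")
    }
  }
  if (distractor_rate < 0 || bloat_factor < 0 || extra_mention_rate < 0) {
    abort("sim_config: rates must be >= 0", class = "notephen_config_error")
  }
  nm <- vapply(conditions, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    abort("sim_config: duplicate condition names", class = "notephen_config_error")
  }
  structure(
    list(
      n_patients = as.integer(n_patients), conditions = conditions,
      category_mix = category_mix[category_levels(assignable = TRUE)],
      extra_mention_rate = extra_mention_rate,
      distractor_rate = distractor_rate, bloat_factor = bloat_factor,
      comparator_error = comparator_error, seed = as.integer(seed)
    ),
    class = "notephen_sim_config"
  )
}

filler_sentence <- function() {
  sample(FILLER_WORDS, sample(4:7, 1), replace = TRUE)
}

# build one mention sentence: neutral padding, the cue in its documented
# geometry (gap 0), the condition term
mention_sentence <- function(category, term_tokens, condition) {
  cue <- sample(GEN_CUES[[category]], 1)
  cue_toks <- strsplit(cue, " ", fixed = TRUE)[[1]]
  ph <- which(cue_toks == TERM_PLACEHOLDER)
  body <- if (length(ph) == 1L) {
    append(cue_toks[-ph], term_tokens, after = ph - 1L)
  } else {
    c(cue_toks, term_tokens)
  }
  list(
    tokens = c(sample(FILLER_WORDS, 3), body, sample(FILLER_WORDS, 3)),
    mention = list(condition = condition, category = category, cue = cue,
                   term = paste(term_tokens, collapse = " "))
  )
}

render_sentence <- function(tokens) {
  tokens[1] <- paste0(toupper(substr(tokens[1], 1, 1)), substr(tokens[1], 2, nchar(tokens[1])))
  paste0(paste(tokens, collapse = " "), ".")
}

#' Generate a synthetic corpus with known ground truth
#'
#' Produces, fully determined by `cfg$seed`: a note table in the corpus
#' format, per-patient gold labels (the "ever had the condition" truth),
#' per-patient-condition chronic-history flags, an ICD-style comparator
#' labeling derived from gold by the configured flip model, a truth log
#' of every embedded mention with its intended category and cue, and the
#' cue-phrase library covering the generator's entire cue inventory.
#' Every truly positive patient carries at least one `ACUTE_PRESENT`
#' (acute) or `HISTORICAL_CHRONIC` (chronic) anchor mention; truly
#' negative patients carry only distractor mentions or none.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `notephen_simulation` with elements `notes`,
#'   `gold`, `comparator`, `chronic`, `truth`, `cue_library`, `config`.
#' @export
simulate_corpus <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "notephen_sim_config"))
  withr::with_seed(cfg$seed, simulate_corpus_impl(cfg))
}

simulate_corpus_impl <- function(cfg) {
  n <- cfg$n_patients
  pids <- sprintf("P%05d", seq_len(n))
  conds <- cfg$conditions
  cond_names <- vapply(conds, `[[`, "", "name")

  gold <- matrix(0L, n, length(conds), dimnames = list(NULL, cond_names))
  chronic <- gold
  for (j in seq_along(conds)) {
    gold[, j] <- rbinom(n, 1L, conds[[j]]$prevalence)
    chronic[, j] <- gold[, j] * rbinom(n, 1L, conds[[j]]$chronic_fraction)
  }

  note_rows <- list()
  truth_rows <- list()
  distractor_cats <- c("NEGATED", "UNDER_EVALUATION", "DIFFERENT_MEANING")
  dmix <- cfg$category_mix[distractor_cats]
  dmix <- dmix / sum(dmix)

  for (i in seq_len(n)) {
    note_types <- c("history_physical", rep("progress", sample(1:5, 1)),
                    "discharge_summary")
    n_notes <- length(note_types)
    # each note starts with neutral padding sentences
    notes <- lapply(seq_len(n_notes), function(x) {
      lapply(seq_len(sample(2:4, 1)), function(y) {
        list(tokens = filler_sentence(), mention = NULL)
      })
    })
    for (j in seq_along(conds)) {
      surfaces <- sub("\\*\\s*$", "", conds[[j]]$terms)
      draw_term <- function() {
        strsplit(tolower(sample(surfaces, 1)), " +")[[1]]
      }
      cats <- character(0)
      if (gold[i, j] == 1L) {
        anchor <- if (chronic[i, j] == 1L) "HISTORICAL_CHRONIC" else "ACUTE_PRESENT"
        n_extra <- rpois(1, cfg$extra_mention_rate)
        cats <- c(anchor, sample(names(cfg$category_mix), n_extra,
                                 replace = TRUE, prob = cfg$category_mix))
      } else {
        n_d <- rpois(1, cfg$distractor_rate)
        if (n_d > 0) {
          cats <- sample(distractor_cats, n_d, replace = TRUE, prob = dmix)
        }
      }
      for (category in cats) {
        target <- sample.int(n_notes, 1)
        notes[[target]] <- c(
          notes[[target]],
          list(mention_sentence(category, draw_term(), cond_names[j]))
        )
      }
    }
    base_time <- as.POSIXct("2008-03-01 08:00:00", tz = "UTC")
    for (k in seq_len(n_notes)) {
      sents <- notes[[k]]
      # note bloat: copy existing sentences (truth is logged after bloat,
      # so duplicated mentions are duplicated truth too)
      n_dup <- rpois(1, cfg$bloat_factor)
      if (n_dup > 0) {
        sents <- c(sents, sents[sample.int(length(sents), n_dup, replace = TRUE)])
      }
      note_id <- sprintf("%s-N%02d", pids[i], k)
      text <- paste(
        vapply(sents, function(s) render_sentence(s$tokens), ""),
        collapse = " "
      )
      note_rows[[length(note_rows) + 1L]] <- c(
        pids[i], note_id, note_types[k],
        format(base_time + (k - 1) * 86400, "%Y-%m-%dT%H:%M:%SZ"), text
      )
      for (s in sents) {
        if (!is.null(s$mention)) {
          truth_rows[[length(truth_rows) + 1L]] <- c(
            pids[i], note_id, s$mention$condition, s$mention$category,
            s$mention$cue, s$mention$term
          )
        }
      }
    }
  }

  comparator <- gold
  ce <- cfg$comparator_error
  for (j in seq_along(conds)) {
    p_fn <- pmin(1, ce$fn_rate + ce$chronic_fn_boost * chronic[, j])
    flip_fn <- rbinom(n, 1L, p_fn)
    flip_fp <- rbinom(n, 1L, ce$fp_rate)
    comparator[, j] <- ifelse(
      gold[, j] == 1L, 1L - flip_fn, flip_fp
    )
  }

  wide <- function(mat) {
    tibble::as_tibble(cbind(
      tibble::tibble(patient_id = pids), tibble::as_tibble(mat)
    ))
  }
  from_rows <- function(rows, cols) {
    if (length(rows) == 0L) {
      return(tibble::as_tibble(setNames(
        replicate(length(cols), character(0), simplify = FALSE), cols
      )))
    }
    m <- do.call(rbind, rows)
    colnames(m) <- cols
    tibble::as_tibble(m)
  }
  structure(
    list(
      notes = from_rows(note_rows, c("patient_id", "note_id", "note_type",
                                     "chart_time", "text")),
      gold = wide(gold),
      comparator = wide(comparator),
      chronic = wide(chronic),
      truth = from_rows(truth_rows, c("patient_id", "note_id", "condition",
                                      "category", "cue", "term")),
      cue_library = default_rule_library(),
      config = cfg
    ),
    class = "notephen_simulation"
  )
}

#' @export
print.notephen_simulation <- function(x, ...) {
  cat(
    "<simulation>", x$config$n_patients, "patients |",
    nrow(x$notes), "notes |", nrow(x$truth), "embedded mentions\n"
  )
  invisible(x)
}

#' Write simulation outputs to a directory
#'
#' Writes `notes.csv` (corpus format), `gold.csv` / `comparator.csv` /
#' `chronic.csv` (dataset format), `truth.csv`, and `cue_library.csv`.
#'
#' @param sim A `notephen_simulation`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(sim$notes, file.path(dir, "notes.csv"), na = "", eol = "\n",
                   progress = FALSE)
  write_dataset(sim$gold, file.path(dir, "gold.csv"))
  write_dataset(sim$comparator, file.path(dir, "comparator.csv"))
  write_dataset(sim$chronic, file.path(dir, "chronic.csv"))
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"), na = "", eol = "\n",
                   progress = FALSE)
  save_library(sim$cue_library, file.path(dir, "cue_library.csv"))
  invisible(dir)
}
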