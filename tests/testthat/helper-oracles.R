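# Independent brute-force oracles, deliberately written in a different
# style from the package internals so equivalence tests are meaningful.

# sliding-window occurrence count with greedy non-overlap: try every term
# of the pattern at every position, longest wins
oracle_count_matches <- function(terms_exact, terms_stem, terms_multi, tokens) {
  n <- length(tokens)
  count <- 0L
  i <- 1L
  while (i <= n) {
    best <- 0L
    for (mw in terms_multi) {
      k <- length(mw)
      if (i + k - 1L <= n && identical(tokens[i:(i + k - 1L)], mw) && k > best) {
        best <- k
      }
    }
    if (best == 0L) {
      for (t in terms_exact) if (tokens[i] == t) best <- 1L
      for (s in terms_stem) {
        if (substr(tokens[i], 1, nchar(s)) == s) best <- 1L
      }
    }
    if (best > 0L) {
      count <- count + 1L
      i <- i + best
    } else {
      i <- i + 1L
    }
  }
  count
}

# exhaustive (rule, position) enumeration under the documented precedence
oracle_match_rules <- function(left, right, rules) {
  firings <- data.frame(
    idx = integer(0), dist = integer(0), cue_len = integer(0),
    dm_ph = logical(0)
  )
  for (r in seq_len(nrow(rules))) {
    toks <- strsplit(rules$cue[r], " ", fixed = TRUE)[[1]]
    ph <- which(toks == "<term>")
    gap_max <- rules$max_gap[r]
    if (length(ph) == 1L) {
      bef <- if (ph > 1) toks[1:(ph - 1)] else character(0)
      aft <- if (ph < length(toks)) toks[(ph + 1):length(toks)] else character(0)
      gb_ok <- NULL
      if (length(bef) == 0) gb_ok <- 0L else {
        for (s in seq_len(max(0L, length(left) - length(bef) + 1L))) {
          if (identical(left[s:(s + length(bef) - 1L)], bef)) {
            g <- length(left) - (s + length(bef) - 1L)
            if (g <= gap_max && (is.null(gb_ok) || g < gb_ok)) gb_ok <- g
          }
        }
      }
      ga_ok <- NULL
      if (length(aft) == 0) ga_ok <- 0L else {
        for (s in seq_len(max(0L, length(right) - length(aft) + 1L))) {
          if (identical(right[s:(s + length(aft) - 1L)], aft)) {
            g <- s - 1L
            if (g <= gap_max && (is.null(ga_ok) || g < ga_ok)) ga_ok <- g
          }
        }
      }
      if (!is.null(gb_ok) && !is.null(ga_ok)) {
        firings <- rbind(firings, data.frame(
          idx = r, dist = gb_ok + ga_ok, cue_len = length(toks),
          dm_ph = rules$category[r] == "DIFFERENT_MEANING"
        ))
      }
    } else {
      dists <- integer(0)
      if (rules$side[r] %in% c("before", "either")) {
        for (s in seq_len(max(0L, length(left) - length(toks) + 1L))) {
          if (identical(left[s:(s + length(toks) - 1L)], toks)) {
            g <- length(left) - (s + length(toks) - 1L)
            if (g <= gap_max) dists <- c(dists, g)
          }
        }
      }
      if (rules$side[r] %in% c("after", "either")) {
        for (s in seq_len(max(0L, length(right) - length(toks) + 1L))) {
          if (identical(right[s:(s + length(toks) - 1L)], toks)) {
            g <- s - 1L
            if (g <= gap_max) dists <- c(dists, g)
          }
        }
      }
      if (length(dists) > 0) {
        firings <- rbind(firings, data.frame(
          idx = r, dist = min(dists), cue_len = length(toks), dm_ph = FALSE
        ))
      }
    }
  }
  if (nrow(firings) == 0) return(NULL)
  cat_rank <- c(
    DIFFERENT_MEANING = 1, NEGATED = 2, UNDER_EVALUATION = 3,
    HISTORICAL_CHRONIC = 4, ACUTE_PRESENT = 5
  )
  firings$rank <- cat_rank[rules$category[firings$idx]]
  firings$rid <- rules$rule_id[firings$idx]
  ord <- order(!firings$dm_ph, firings$dist, -firings$cue_len,
               firings$rank, firings$rid)
  rules$rule_id[firings$idx[ord[1]]]
}

# hand 2x2 tally via table()
oracle_confusion <- function(pred, gold) {
  tab <- table(factor(pred, levels = c(0, 1)), factor(gold, levels = c(0, 1)))
  list(tp = tab["1", "1"], fp = tab["1", "0"], fn = tab["0", "1"], tn = tab["0", "0"])
}

# textbook pooled-variance two-sample t
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tt, p = 2 * pt(-abs(tt), df = na + nb - 2))
}

# tiny deterministic corpus used across tests
fixture_corpus <- function() {
  as_note_corpus(tibble::tibble(
    patient_id = c("p1", "p1", "p2"),
    note_id = c("n1", "n2", "n3"),
    note_type = c("history_physical", "progress", "discharge_summary"),
    text = c(
      "Chief complaint pneumonia. Vitals stable overnight.",
      "No evidence of pna today. Continue monitoring.",
      "History of pneumonia as noted. Plan unchanged."
    )
  ))
}

pneumonia_pattern <- function() compile_pattern("pneumonia", c("pneumonia", "pna"))

# search -> categorize on a simulation, returning phenotypes and db
run_pipeline <- function(sim, condition, lib = sim$cue_library,
                         ever = TRUE, uncategorized = "error") {
  corpus <- as_note_corpus(sim$notes)
  spec <- Filter(function(x) x$name == condition, sim$config$conditions)[[1]]
  db <- find_instances(corpus, compile_pattern(spec$name, spec$terms))
  res <- categorize_corpus(db, lib)
  cfg <- export_config(ever_present = ever, uncategorized = uncategorized)
  ph <- aggregate_patients(res$db, cfg, unique(sim$notes$patient_id))
  list(db = res$db, uncategorized_ids = res$uncategorized_ids, phenotypes = ph)
}
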