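# evaluate: accuracy of a phenotype labeling versus a gold standard --------

# coerce a flag input (named vector, or data frame patient_id+flag) to a
# named integer vector
as_flag_vector <- function(x, arg = "flags") {
  if (is.data.frame(x)) {
    cols <- setdiff(names(x), "patient_id")
    if (!"patient_id" %in% names(x) || length(cols) != 1L) {
      abort(
        paste0(arg, " data frame must have columns patient_id + one flag column"),
        class = "notephen_contract_error"
      )
    }
    out <- as.integer(x[[cols]])
    names(out) <- x$patient_id
    return(out)
  }
  if (is.null(names(x))) {
    abort(paste0(arg, " must be a named vector or a data frame"),
          class = "notephen_contract_error")
  }
  out <- as.integer(x)
  names(out) <- names(x)
  out
}

#' Confusion counts of a predicted labeling versus the gold standard
#'
#' @param pred,gold Named 0/1 vectors (names = patient keys), or data
#'   frames with `patient_id` and one flag column. Key sets must be
#'   identical; a mismatch is an error naming the offending keys.
#' @return An object of class `notephen_confusion`: list with `tp`, `fp`,
#'   `fn`, `tn`, `n`.
#' @export
#' @examples
#' confusion(c(a = 1, b = 0, c = 1), c(a = 1, b = 0, c = 0))
confusion <- function(pred, gold) {
  p <- as_flag_vector(pred, "pred")
  g <- as_flag_vector(gold, "gold")
  only_p <- setdiff(names(p), names(g))
  only_g <- setdiff(names(g), names(p))
  if (length(only_p) > 0 || length(only_g) > 0) {
    abort(
      paste0(
        "patient key sets differ; only in pred: ",
        paste(head(only_p, 5), collapse = ", "),
        " | only in gold: ", paste(head(only_g, 5), collapse = ", ")
      ),
      class = "notephen_key_error"
    )
  }
  g <- g[names(p)]
  structure(
    list(
      tp = sum(p == 1L & g == 1L), fp = sum(p == 1L & g == 0L),
      fn = sum(p == 0L & g == 1L), tn = sum(p == 0L & g == 0L),
      n = length(p)
    ),
    class = "notephen_confusion"
  )
}

#' @export
print.notephen_confusion <- function(x, ...) {
  cat("<confusion> tp:", x$tp, " fp:", x$fp, " fn:", x$fn, " tn:", x$tn, "\n")
  invisible(x)
}

#' Wilson score interval for a binomial proportion
#'
#' The default interval for sensitivity/specificity: well-behaved at
#' proportions near 0 and 1 (where accurate phenotyping lives), unlike
#' the normal/t approximation. At `k = m` the upper bound is exactly 1.
#'
#' @param k Successes.
#' @param m Trials (> 0).
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(low, high)`.
#' @export
#' @examples
#' wilson_interval(9, 10)
wilson_interval <- function(k, m, level = 0.95) {
  stopifnot(m > 0, k >= 0, k <= m)
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / m
  denom <- 1 + z^2 / m
  center <- (p + z^2 / (2 * m)) / denom
  half <- z * sqrt(p * (1 - p) / m + z^2 / (4 * m^2)) / denom
  c(low = max(0, center - half), high = min(1, center + half))
}

# t-quantile normal-approximation interval (p +/- t * sqrt(pq/m)),
# clipped to [0,1]; degenerate at p-hat 0 or 1
t_normal_interval <- function(k, m, level = 0.95) {
  stopifnot(m > 1, k >= 0, k <= m)
  p <- k / m
  tq <- qt(1 - (1 - level) / 2, df = m - 1)
  half <- tq * sqrt(p * (1 - p) / m)
  c(low = max(0, p - half), high = min(1, p + half))
}

proportion_ci <- function(k, m, level, method) {
  switch(method,
    wilson = wilson_interval(k, m, level),
    t_normal = t_normal_interval(k, m, level),
    exact = {
      ci <- stats::binom.test(k, m, conf.level = level)$conf.int
      c(low = ci[1], high = ci[2])
    },
    abort(paste0("unknown CI method '", method, "'"),
          class = "notephen_config_error")
  )
}

#' Sensitivity and specificity with confidence intervals
#'
#' Point estimates are `tp / (tp + fn)` and `tn / (tn + fp)`; the
#' interval method defaults to Wilson score, with `"t_normal"`
#' (t-quantile on the normal approximation) and `"exact"`
#' (Clopper-Pearson) selectable. A metric whose denominator is zero (no
#' gold positives, or no gold negatives) is undefined and raises an error
#' naming the metric.
#'
#' @param counts A `notephen_confusion`.
#' @param level Confidence level.
#' @param method `"wilson"`, `"t_normal"`, or `"exact"`.
#' @return A tibble with one row per metric: `metric`, `point`,
#'   `ci_low`, `ci_high`, `level`, `method`, `k`, `m`.
#' @export
sens_spec <- function(counts, level = 0.95, method = c("wilson", "t_normal", "exact")) {
  method <- match.arg(method)
  stopifnot(inherits(counts, "notephen_confusion"))
  if (counts$tp + counts$fn == 0) {
    abort("sensitivity undefined: no gold positives (tp + fn = 0)",
          class = "notephen_undefined_metric")
  }
  if (counts$fp + counts$tn == 0) {
    abort("specificity undefined: no gold negatives (fp + tn = 0)",
          class = "notephen_undefined_metric")
  }
  one <- function(metric, k, m) {
    ci <- proportion_ci(k, m, level, method)
    tibble::tibble(
      metric = metric, point = k / m,
      ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
      level = level, method = method, k = k, m = m
    )
  }
  dplyr::bind_rows(
    one("sensitivity", counts$tp, counts$tp + counts$fn),
    one("specificity", counts$tn, counts$tn + counts$fp)
  )
}

#' Mean of per-condition accuracy estimates
#'
#' Conditions are weighted equally (not pooled over patients): the mean
#' of the per-condition point estimates, with its standard error.
#'
#' @param estimates Numeric vector of per-condition point estimates.
#' @return List with `mean`, `sem`, `n`.
#' @export
#' @examples
#' mean_accuracy(c(0.9, 0.95, 1.0))
mean_accuracy <- function(estimates) {
  estimates <- as.numeric(estimates)
  if (length(estimates) < 1L || anyNA(estimates)) {
    abort("estimates must be a non-empty numeric vector without NA",
          class = "notephen_contract_error")
  }
  list(
    mean = mean(estimates),
    sem = if (length(estimates) > 1L) sd(estimates) / sqrt(length(estimates)) else 0,
    n = length(estimates)
  )
}

#' Two-sample t-test on per-condition accuracy columns
#'
#' Pooled-variance (equal-variance) two-sided t-test by default, the
#' textbook form for comparing two labelers' per-condition accuracy
#' columns; Welch's unequal-variance form is selectable.
#'
#' @param a,b Numeric vectors (length >= 2 each).
#' @param var_equal Pool variances (default `TRUE`).
#' @return List with `t`, `p` (two-sided), `df`.
#' @export
compare_means <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("each sample needs length >= 2", class = "notephen_contract_error")
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Discrepancy breakdown with chronic-omission tagging
#'
#' Compares a comparator labeling (e.g. ICD codes) and the note-derived
#' labeling against the gold standard, one record per patient-condition
#' where either disagrees with gold. Comparator false negatives
#' (comparator 0, gold 1) for a patient with chronic-history status are
#' tagged `chronic_omission` — the signature error of coders skipping
#' chronic conditions at the index admission; other discrepancies are
#' `other`, and comparator false negatives without chronic information
#' are `unreviewed`.
#'
#' @param comparator,note,gold Flag tibbles: `patient_id` + one 0/1
#'   column per condition (the [write_dataset()] shape). Key sets and
#'   condition columns must align.
#' @param chronic Optional tibble of the same shape: 1 marks a
#'   patient-condition with chronic-history status.
#' @return A list with `records` (tibble: `patient_id`, `condition`,
#'   `comparator_flag`, `note_flag`, `gold_flag`, `reason_tag`) and
#'   `chronic_omissions` (tibble of per-condition counts).
#' @export
discrepancy_breakdown <- function(comparator, note, gold, chronic = NULL) {
  melt <- function(df, value_name) {
    tidyr::pivot_longer(
      tibble::as_tibble(df), -"patient_id",
      names_to = "condition", values_to = value_name
    )
  }
  joined <- melt(comparator, "comparator_flag") |>
    dplyr::full_join(melt(note, "note_flag"), by = c("patient_id", "condition")) |>
    dplyr::full_join(melt(gold, "gold_flag"), by = c("patient_id", "condition"))
  if (anyNA(joined$comparator_flag) || anyNA(joined$note_flag) ||
      anyNA(joined$gold_flag)) {
    abort("comparator/note/gold keys or condition columns do not align",
          class = "notephen_key_error")
  }
  if (!is.null(chronic)) {
    joined <- dplyr::left_join(
      joined, melt(chronic, "chronic_flag"),
      by = c("patient_id", "condition")
    )
    joined$chronic_flag <- dplyr::coalesce(joined$chronic_flag, 0L)
  } else {
    joined$chronic_flag <- NA_integer_
  }
  rec <- joined[joined$comparator_flag != joined$gold_flag |
                  joined$note_flag != joined$gold_flag, ]
  comp_fn <- rec$comparator_flag == 0L & rec$gold_flag == 1L
  rec$reason_tag <- dplyr::case_when(
    comp_fn & is.na(rec$chronic_flag) ~ "unreviewed",
    comp_fn & rec$chronic_flag == 1L ~ "chronic_omission",
    TRUE ~ "other"
  )
  records <- rec[, c(
    "patient_id", "condition", "comparator_flag", "note_flag",
    "gold_flag", "reason_tag"
  )]
  counts <- records |>
    dplyr::filter(.data$reason_tag == "chronic_omission") |>
    dplyr::count(.data$condition, name = "chronic_omissions")
  all_conds <- sort(unique(joined$condition))
  counts <- dplyr::left_join(
    tibble::tibble(condition = all_conds), counts, by = "condition"
  )
  counts$chronic_omissions <- dplyr::coalesce(counts$chronic_omissions, 0L)
  list(records = records, chronic_omissions = counts)
}

#' Per-condition accuracy table versus the gold standard
#'
#' Mirrors the standard validation-report layout: one row per condition
#' with n, sensitivity, specificity and their confidence intervals.
#'
#' @param pred,gold Flag tibbles (`patient_id` + 0/1 condition columns)
#'   with aligned keys and columns.
#' @param level Confidence level.
#' @param method CI method (see [sens_spec()]).
#' @return A tibble: `condition`, `n`, `sensitivity`, `sens_low`,
#'   `sens_high`, `specificity`, `spec_low`, `spec_high`.
#' @export
accuracy_table <- function(pred, gold, level = 0.95, method = "wilson") {
  conds <- sort(intersect(setdiff(names(gold), "patient_id"),
                          setdiff(names(pred), "patient_id")))
  if (length(conds) == 0L) {
    abort("pred and gold share no condition columns",
          class = "notephen_key_error")
  }
  rows <- lapply(conds, function(cc) {
    cm <- confusion(pred[, c("patient_id", cc)], gold[, c("patient_id", cc)])
    est <- sens_spec(cm, level = level, method = method)
    tibble::tibble(
      condition = cc, n = cm$n,
      sensitivity = est$point[1], sens_low = est$ci_low[1], sens_high = est$ci_high[1],
      specificity = est$point[2], spec_low = est$ci_low[2], spec_high = est$ci_high[2]
    )
  })
  dplyr::bind_rows(rows)
}

#' Published per-condition validation benchmark table
#'
#' Per-condition sensitivity and specificity of ICD-9 coding and of
#' rule-based note extraction, each versus a chart-review gold standard,
#' for eleven ICU conditions (n per condition 73-497), from a published
#' validation of this style of pipeline. Useful as a benchmark input for
#' the aggregate statistics in this module: the equally-weighted column
#' means are 0.65/0.93 (ICD sensitivity/specificity) and 0.98/0.94
#' (note sensitivity/specificity).
#'
#' @return A tibble with columns `condition`, `n`, `icd_sensitivity`,
#'   `icd_specificity`, `note_sensitivity`, `note_specificity`.
#' @export
validation_benchmark <- function() {
  path <- system.file("extdata", "icd_note_benchmark.csv", package = "notephen")
  readr::read_csv(
    path,
    col_types = readr::cols(
      condition = "c", n = "i", icd_sensitivity = "d", icd_specificity = "d",
      note_sensitivity = "d", note_specificity = "d"
    ),
    progress = FALSE
  )
}

#' Published chronic-omission counts
#'
#' Per-condition counts of comparator (ICD-9) false negatives caused by
#' omission of a chronic condition, from the same published validation as
#' [validation_benchmark()].
#'
#' @return A tibble with `condition` and `chronic_omissions`.
#' @export
chronic_omission_benchmark <- function() {
  path <- system.file("extdata", "chronic_omissions.csv", package = "notephen")
  readr::read_csv(
    path,
    col_types = readr::cols(condition = "c", chronic_omissions = "i"),
    progress = FALSE
  )
}
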