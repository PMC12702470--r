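# reports_export: audit reports and the analysis-ready dataset -------------

#' Export configuration
#'
#' Controls how mention categories map to the per-patient binary flag and
#' how audit reports are sampled. By default only `ACUTE_PRESENT`
#' mentions count as "present" (an acute phenotype); `ever_present = TRUE`
#' switches to the "ever" phenotype `{ACUTE_PRESENT,
#' HISTORICAL_CHRONIC}`. Negated, different-meaning, under-evaluation and
#' (optionally) uncategorized mentions all map to absent.
#'
#' @param present_categories Categories that make a patient flag 1. May
#'   never contain `NEGATED`, `DIFFERENT_MEANING`, or `UNCATEGORIZED`.
#' @param ever_present Convenience switch: if `TRUE`, use
#'   `c("ACUTE_PRESENT", "HISTORICAL_CHRONIC")`.
#' @param include_patients `"all"` (every screened patient, flag 0 when no
#'   supporting mention — the denominator needed for specificity) or
#'   `"positive"` (pattern-positive patients only).
#' @param audit_sample_fraction Fraction of instances shown in a sampled
#'   audit report, in `[0, 1]`.
#' @param audit_seed Integer seed for audit sampling.
#' @param uncategorized `"error"` (refuse to export until review is
#'   finished) or `"absent"` (map uncategorized to absent, the
#'   "ambiguous means absent" convention).
#' @return An object of class `notephen_export_config`.
#' @export
export_config <- function(present_categories = "ACUTE_PRESENT",
                          ever_present = FALSE,
                          include_patients = c("all", "positive"),
                          audit_sample_fraction = 1,
                          audit_seed = 1L,
                          uncategorized = c("error", "absent")) {
  if (ever_present) present_categories <- c("ACUTE_PRESENT", "HISTORICAL_CHRONIC")
  include_patients <- match.arg(include_patients)
  uncategorized <- match.arg(uncategorized)
  forbidden <- intersect(
    present_categories, c("NEGATED", "DIFFERENT_MEANING", "UNCATEGORIZED")
  )
  if (length(forbidden) > 0) {
    abort(
      paste0(
        "present_categories may not contain: ", paste(forbidden, collapse = ", ")
      ),
      class = "notephen_config_error"
    )
  }
  if (!all(present_categories %in% category_levels(assignable = TRUE))) {
    abort("unknown category in present_categories", class = "notephen_config_error")
  }
  if (audit_sample_fraction < 0 || audit_sample_fraction > 1) {
    abort("audit_sample_fraction must be in [0, 1]", class = "notephen_config_error")
  }
  structure(
    list(
      present_categories = unique(present_categories),
      include_patients = include_patients,
      audit_sample_fraction = audit_sample_fraction,
      audit_seed = as.integer(audit_seed),
      uncategorized = uncategorized
    ),
    class = "notephen_export_config"
  )
}

#' Build an audit report of categorized instances
#'
#' One row per instance (patient, note, contexts, category, firing rule),
#' grouped by category, with `UNCATEGORIZED` instances listed first so
#' unfinished review is impossible to miss. With
#' `audit_sample_fraction < 1` a uniform, seeded, without-replacement
#' sample is drawn — the same seed always reproduces the same report.
#'
#' @param db A categorized `notephen_idb`.
#' @param cfg An [export_config()].
#' @return A tibble: the report rows.
#' @export
audit_report <- function(db, cfg = export_config()) {
  ins <- db$instances
  if (cfg$audit_sample_fraction < 1 && nrow(ins) > 0) {
    n_keep <- round(nrow(ins) * cfg$audit_sample_fraction)
    idx <- withr::with_seed(
      cfg$audit_seed,
      sort(sample.int(nrow(ins), n_keep))
    )
    ins <- ins[idx, ]
  }
  out <- tibble::tibble(
    category = ins$category,
    patient_id = ins$patient_id,
    note_id = ins$note_id,
    condition = ins$condition,
    surface = ins$surface,
    left_context = vapply(ins$left_context, paste, "", collapse = " "),
    right_context = vapply(ins$right_context, paste, "", collapse = " "),
    rule_id = ins$rule_id,
    instance_id = ins$instance_id
  )
  cat_order <- c("UNCATEGORIZED", category_levels(assignable = TRUE))
  out[order(match(out$category, cat_order), out$patient_id, out$instance_id), ]
}

#' Aggregate categorized instances into per-patient phenotype flags
#'
#' The patient flag is 1 iff at least one supporting instance carries a
#' category in `cfg$present_categories`; every screened patient appears
#' exactly once (patients with no instances get 0). Per-category support
#' counts are kept for auditability.
#'
#' @param db A categorized `notephen_idb`.
#' @param cfg An [export_config()].
#' @param screened_patient_ids Character vector of all screened patients
#'   (the study denominator). Every patient present in `db` must be in
#'   this set.
#' @return An object of class `notephen_phenotypes`: list with `flags`
#'   (tibble `patient_id` + one 0/1 column per condition), `support`
#'   (long tibble of per-patient per-category instance counts), and
#'   `config`.
#' @export
aggregate_patients <- function(db, cfg = export_config(), screened_patient_ids) {
  ins <- db$instances
  stray <- setdiff(unique(ins$patient_id), screened_patient_ids)
  if (length(stray) > 0) {
    abort(
      paste0(
        "instances reference patients outside the screened set: ",
        paste(head(stray, 5), collapse = ", ")
      ),
      class = "notephen_contract_error"
    )
  }
  n_unc <- sum(ins$category == "UNCATEGORIZED")
  if (n_unc > 0 && cfg$uncategorized == "error") {
    abort(
      paste0(
        n_unc, " instances are still UNCATEGORIZED; finish the review ",
        "session or set uncategorized = \"absent\" to map them to absent"
      ),
      class = "notephen_export_error"
    )
  }
  condition <- db$pattern$condition_name
  support <- ins |>
    dplyr::count(.data$patient_id, .data$condition, .data$category,
                  name = "n_instances")
  pos <- unique(ins$patient_id[ins$category %in% cfg$present_categories])
  ids <- if (cfg$include_patients == "all") {
    sort(unique(screened_patient_ids))
  } else {
    sort(unique(ins$patient_id))
  }
  flags <- tibble::tibble(patient_id = ids)
  flags[[condition]] <- as.integer(flags$patient_id %in% pos)
  structure(
    list(flags = flags, support = support, config = cfg),
    class = "notephen_phenotypes"
  )
}

#' @export
print.notephen_phenotypes <- function(x, ...) {
  conds <- setdiff(names(x$flags), "patient_id")
  cat("<patient phenotypes>", nrow(x$flags), "patients |",
      length(conds), "condition(s)\n")
  for (cc in conds) {
    cat(" ", cc, ": ", sum(x$flags[[cc]]), " positive\n", sep = "")
  }
  invisible(x)
}

#' Write a phenotype dataset to CSV
#'
#' Header is the patient key followed by one 0/1 column per condition in
#' lexicographic order; rows are sorted by patient key, so identical
#' inputs give byte-identical files.
#'
#' @param phenotypes A `notephen_phenotypes` object, or a plain data
#'   frame with `patient_id` plus 0/1 columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(phenotypes, path) {
  flags <- if (inherits(phenotypes, "notephen_phenotypes")) {
    phenotypes$flags
  } else {
    tibble::as_tibble(phenotypes)
  }
  conds <- sort(setdiff(names(flags), "patient_id"))
  flags <- flags[order(flags$patient_id), c("patient_id", conds)]
  readr::write_csv(flags, path, na = "", eol = "\n", progress = FALSE)
  invisible(path)
}

#' Read a phenotype dataset written by [write_dataset()]
#'
#' @param path CSV path (patient key + 0/1 condition columns).
#' @return A tibble with `patient_id` (character) and integer flags.
#' @export
read_dataset <- function(path) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      .default = readr::col_integer()
    ),
    progress = FALSE
  )
  tibble::as_tibble(df)
}

#' Merge phenotype datasets on the patient key
#'
#' Column union, full join on `patient_id`; a patient absent from one
#' dataset gets `NA` for that dataset's conditions. No row duplication.
#'
#' @param ... Two or more flag tibbles (as from [read_dataset()] or
#'   `aggregate_patients()$flags`).
#' @return The merged tibble, sorted by patient key.
#' @export
merge_datasets <- function(...) {
  parts <- list(...)
  out <- Reduce(function(a, b) dplyr::full_join(a, b, by = "patient_id"), parts)
  conds <- sort(setdiff(names(out), "patient_id"))
  out[order(out$patient_id), c("patient_id", conds)]
}
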