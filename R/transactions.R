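# Per-patient binary transaction database.
#
# A "transaction" is the complete set of three-character ICD-10 categories a
# patient was ever coded with across all hospitalizations; patients with a
# single hospitalization are excluded, because co-occurrence across repeat
# admissions is the signal being mined. Support denominators everywhere use
# the number of retained patients.

#' Normalise and filter raw diagnosis records
#'
#' Parses each record's ICD-10 code to its three-character category, then
#' removes codes excluded by the policy (excluded chapters, or descriptions
#' carrying the catch-all token). Malformed codes abort under
#' `strict = TRUE`, otherwise they are dropped and counted.
#'
#' @param records A data frame with columns `patient_id`, `admission_id`,
#'   `icd10_code` and `description` (missing `description` is treated as
#'   empty).
#' @param policy An [exclusion_policy()].
#' @param strict Passed to [icd10_parse()].
#'
#' @return A tibble of retained records with columns `patient_id`,
#'   `admission_id`, `category`, `chapter`, `description`, carrying an
#'   attribute `ingest_log` with counts of raw, malformed and excluded rows.
#' @export
prepare_records <- function(records, policy = exclusion_policy(), strict = FALSE) {
  records <- as_tibble(records)
  required <- c("patient_id", "admission_id", "icd10_code")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`records` is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!"description" %in% names(records)) records$description <- ""
  if (nrow(records) == 0) abort("`records` is empty.")
  if (any(is.na(records$patient_id) | records$patient_id == "" |
            is.na(records$admission_id) | records$admission_id == "")) {
    abort("`patient_id` and `admission_id` must be non-empty for every record.")
  }

  parsed <- icd10_parse(records$icd10_code, strict = strict)
  out <- records |>
    mutate(
      patient_id = as.character(.data$patient_id),
      admission_id = as.character(.data$admission_id),
      category = parsed$category,
      chapter = parsed$chapter
    ) |>
    select("patient_id", "admission_id", "category", "chapter", "description")

  n_raw <- nrow(out)
  malformed <- is.na(out$category)
  out <- out[!malformed, , drop = FALSE]
  excluded <- is_excluded(out$chapter, out$description, policy)
  out <- out[!excluded, , drop = FALSE]

  attr(out, "ingest_log") <- list(
    n_raw_rows = n_raw,
    n_malformed = sum(malformed),
    n_excluded_codes = sum(excluded),
    n_retained_codes = nrow(out)
  )
  out
}

#' Build the per-patient binary transaction database
#'
#' Implements the full patient-level selection: (1) codes are parsed and
#' truncated to categories; (2) excluded codes removed; (3) records grouped
#' by patient; (4) patients with fewer than two distinct admissions in the
#' *raw* input dropped (the single-hospitalization criterion counts
#' hospitalizations, not retainable codes, so it is assessed before code
#' exclusion); (5) each patient's categories deduplicated into one binary
#' transaction; (6) patients left with no retained category dropped, since
#' an all-false row would silently deflate every support.
#'
#' @inheritParams prepare_records
#' @return An object of class `transaction_db`: a list with elements
#'   * `long` — tibble `(patient_id, category)`, one row per TRUE cell;
#'   * `items` — lexicographically sorted item universe;
#'   * `patient_ids` — sorted retained patient identifiers;
#'   * `n_transactions` — number of retained patients;
#'   * `n_codes_ingested` — retained raw code rows after exclusion filtering
#'     (pre-deduplication);
#'   * `log` — ingest and selection counters.
#' @examples
#' recs <- tibble::tibble(
#'   patient_id = c("P1", "P1", "P2"),
#'   admission_id = c("H1", "H2", "H3"),
#'   icd10_code = c("I10", "E11.9", "I10"),
#'   description = ""
#' )
#' build_transactions(recs) # P2 dropped: single admission
#' @export
build_transactions <- function(records, policy = exclusion_policy(), strict = FALSE) {
  records <- as_tibble(records)
  if (nrow(records) == 0) abort("`records` is empty.")

  # Admission counting happens on raw input, before any code filtering.
  admissions <- records |>
    mutate(patient_id = as.character(.data$patient_id)) |>
    group_by(.data$patient_id) |>
    summarise(n_admissions = n_distinct(.data$admission_id), .groups = "drop")
  eligible <- admissions$patient_id[admissions$n_admissions >= 2L]
  n_single <- sum(admissions$n_admissions < 2L)

  retained <- prepare_records(records, policy = policy, strict = strict)
  ingest <- attr(retained, "ingest_log")

  long <- retained |>
    filter(.data$patient_id %in% eligible) |>
    distinct(.data$patient_id, .data$category) |>
    arrange(.data$patient_id, .data$category)

  # Eligible patients whose every code fell to the exclusion rules end up
  # with an all-false row, which would deflate every support; they are
  # dropped and counted here.
  n_empty <- length(eligible) - length(unique(long$patient_id))

  if (nrow(long) == 0) {
    abort("No eligible transactions: every patient was excluded by the selection rules.")
  }

  new_transaction_db(
    long = long,
    n_codes_ingested = sum(retained$patient_id %in% eligible),
    log = c(ingest, list(
      n_patients_raw = nrow(admissions),
      n_single_admission_patients = n_single,
      n_empty_after_exclusion = n_empty
    ))
  )
}

new_transaction_db <- function(long, n_codes_ingested, log = list()) {
  attr(long, "ingest_log") <- NULL
  items <- sort(unique(long$category), method = "radix")
  patient_ids <- sort(unique(long$patient_id))
  log$n_transactions <- length(patient_ids)
  structure(
    list(
      long = arrange(long, .data$patient_id, .data$category),
      items = items,
      patient_ids = patient_ids,
      n_transactions = length(patient_ids),
      n_codes_ingested = n_codes_ingested,
      log = log
    ),
    class = "transaction_db"
  )
}

#' @export
print.transaction_db <- function(x, ...) {
  cat("<transaction_db>\n")
  cat(sprintf("  %d transactions (patients), %d items (ICD-10 categories)\n",
              x$n_transactions, length(x$items)))
  cat(sprintf("  %d retained code rows ingested\n", x$n_codes_ingested))
  if (!is.null(x$log$n_single_admission_patients)) {
    cat(sprintf("  dropped: %d single-admission patients, %d codes excluded, %d malformed\n",
                x$log$n_single_admission_patients,
                x$log$n_excluded_codes %||% 0L,
                x$log$n_malformed %||% 0L))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a transaction database to a binary incidence matrix
#'
#' Rows are patients ordered by `patient_id`, columns the sorted item
#' universe; a cell is `TRUE` iff the patient's transaction contains the
#' category. Round-trips losslessly through [as_transaction_db()].
#'
#' @param db A `transaction_db`.
#' @return A logical matrix with patient row names and category column names.
#' @export
to_binary_matrix <- function(db) {
  stopifnot(inherits(db, "transaction_db"))
  m <- matrix(
    FALSE,
    nrow = db$n_transactions, ncol = length(db$items),
    dimnames = list(db$patient_ids, db$items)
  )
  m[cbind(
    match(db$long$patient_id, db$patient_ids),
    match(db$long$category, db$items)
  )] <- TRUE
  m
}

#' Build a transaction database from a binary incidence matrix
#'
#' Inverse of [to_binary_matrix()]: row names are patient identifiers,
#' column names ICD-10 categories. All-false rows are rejected (they cannot
#' arise from [build_transactions()], which drops empty patients).
#'
#' @param m Logical (or 0/1) matrix with row and column names.
#' @return A `transaction_db`.
#' @export
as_transaction_db <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("The incidence matrix needs patient row names and category column names.")
  }
  storage.mode(m) <- "logical"
  if (any(rowSums(m) == 0)) abort("All-false rows are not valid transactions.")
  idx <- which(m, arr.ind = TRUE)
  long <- tibble(
    patient_id = rownames(m)[idx[, 1L]],
    category = colnames(m)[idx[, 2L]]
  )
  new_transaction_db(long, n_codes_ingested = nrow(long))
}

#' Frequency distribution of retained diagnosis codes
#'
#' Counts every retained code occurrence (not deduplicated per patient),
#' grouped either by chapter letter or three-character category, with
#' fractions normalised by the total number of retained codes.
#'
#' @param x Either a character vector of three-character categories or a
#'   data frame with a `category` column (e.g. the output of
#'   [prepare_records()]).
#' @param level `"chapter"` or `"category"`.
#' @return A tibble with columns `key`, `count`, `fraction`, sorted by
#'   descending count (ties broken lexicographically), of class
#'   `icd_freq_table`.
#' @examples
#' frequency_table(c("I10", "I10", "E11", "C34"), level = "chapter")
#' @export
frequency_table <- function(x, level = c("chapter", "category")) {
  level <- match.arg(level)
  categories <- if (is.data.frame(x)) {
    if (!"category" %in% names(x)) abort("`x` has no `category` column.")
    x$category
  } else {
    as.character(x)
  }
  categories <- categories[!is.na(categories)]
  if (length(categories) == 0) abort("No retained codes to tabulate.")
  key <- if (level == "chapter") substr(categories, 1L, 1L) else categories
  out <- tibble(key = key) |>
    count(.data$key, name = "count") |>
    mutate(fraction = .data$count / sum(.data$count)) |>
    arrange(desc(.data$count), .data$key)
  attr(out, "level") <- level
  class(out) <- c("icd_freq_table", class(out))
  out
}

#' @method autoplot icd_freq_table
#' @export
autoplot.icd_freq_table <- function(object, top = 30, ...) {
  level <- attr(object, "level") %||% "category"
  df <- utils::head(object, top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$key, -.data$count),
    y = .data$fraction
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.1f%%", 100 * v)) +
    ggplot2::labs(
      x = sprintf("ICD-10 %s", level),
      y = "share of retained diagnosis codes",
      title = sprintf("Diagnosis code frequency by %s", level)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
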