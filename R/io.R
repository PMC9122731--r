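# Delimited-text I/O for diagnosis records and transaction databases.

#' Read diagnosis records from delimited text
#'
#' Expects a header row with columns `patient_id`, `admission_id`,
#' `icd10_code`, `description` (extra columns are kept but unused).
#'
#' @param path File path.
#' @param delim Field delimiter; default comma.
#' @return A tibble of diagnosis records.
#' @export
read_records <- function(path, delim = ",") {
  out <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  required <- c("patient_id", "admission_id", "icd10_code")
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols) > 0) {
    abort(paste0(path, " is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"description" %in% names(out)) out$description <- ""
  out$description[is.na(out$description)] <- ""
  out
}

#' Write diagnosis records to CSV
#'
#' @param records Tibble of diagnosis records.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Serialise a transaction database
#'
#' `write_transactions_long()` writes one row per TRUE cell
#' (`patient_id, category`); `write_transactions_matrix()` writes the dense
#' binary incidence matrix with a `patient_id` first column and one TRUE /
#' FALSE column per ICD-10 category.
#'
#' @param db A `transaction_db`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_transactions_long <- function(db, path) {
  stopifnot(inherits(db, "transaction_db"))
  readr::write_csv(db$long, path)
  invisible(path)
}

#' @rdname write_transactions_long
#' @export
write_transactions_matrix <- function(db, path) {
  m <- to_binary_matrix(db)
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(patient_id = rownames(m)), out)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a binary incidence matrix written by [write_transactions_matrix()]
#'
#' Also reads hand-entered incidence fixtures with a patient identifier
#' first column and logical category columns.
#'
#' @param path File path.
#' @return A `transaction_db`.
#' @export
read_transactions_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "logical"
  rownames(m) <- as.character(df[[1]])
  as_transaction_db(m)
}

#' Read a re-entered published-style rule table
#'
#' Reads CSVs shaped like the bundled example tables
#' (`example_rules_cross.csv`, `example_rules_within.csv` under
#' `inst/extdata`): columns `no`, `antecedent` (semicolon-joined),
#' `consequent`, `support_pct`, `confidence_pct`, `lift`. Percentages are
#' converted to fractions and antecedent/consequent sizes derived, so the
#' result is a `rule_set` compatible with [sort_rules()],
#' [partition_by_chapter()] and [lift_from_rule_pair()].
#'
#' @param path File path; see [icdmine_example()].
#' @return A `rule_set` tibble.
#' @export
read_rule_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  out <- tibble(
    antecedent = df$antecedent,
    consequent = df$consequent,
    antecedent_size = lengths(strsplit(df$antecedent, ";", fixed = TRUE)),
    consequent_size = lengths(strsplit(df$consequent, ";", fixed = TRUE)),
    support = df$support_pct / 100,
    confidence = df$confidence_pct / 100,
    lift = df$lift
  )
  class(out) <- c("rule_set", class(out))
  out
}

#' Path to a bundled example data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files. Bundled: a small worked binary
#'   incidence sample (`example_incidence.csv`) and two curated comorbidity
#'   rule tables from a large tertiary-hospital EMR analysis
#'   (`example_rules_cross.csv`, `example_rules_within.csv`).
#' @return A file path, or a character vector of file names.
#' @export
icdmine_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "icdmine")))
  }
  path <- system.file("extdata", file, package = "icdmine")
  if (path == "") abort(paste0("No bundled example file named ", file))
  path
}
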