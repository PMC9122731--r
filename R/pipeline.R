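# End-to-end orchestration: records -> transactions -> frequent itemsets ->
# scored, filtered, sorted, partitioned rules, with a run manifest recording
# every stage count.

#' Mine comorbidity association rules from diagnosis records
#'
#' Runs the full pipeline: [build_transactions()] (code normalisation,
#' exclusion rules, single-hospitalization filter, binary encoding), then
#' [find_frequent_itemsets()], [generate_rules()], [filter_rules()],
#' [sort_rules()] and [partition_by_chapter()].
#'
#' @param records Data frame of diagnosis records (`patient_id`,
#'   `admission_id`, `icd10_code`, `description`).
#' @param config A [mining_config()].
#' @param policy An [exclusion_policy()].
#' @param strict Abort on malformed codes instead of skipping them.
#' @param prune_redundant Apply the optional [prune_redundant_rules()]
#'   heuristic after filtering. Off by default; the core contract is
#'   threshold filtering only.
#' @return An object of class `comorbidity_mining` with elements
#'   `rules` (sorted, with `partition` column), `cross_chapter`,
#'   `within_chapter`, `frequent`, `db`, `config`, `manifest`.
#' @examples
#' cfg <- cohort_config(
#'   n_patients = 400,
#'   planted_rules = list(planted_rule("G45", "I61", 0.3, 0.8, 0.05)),
#'   seed = 7
#' )
#' fit <- mine_comorbidity_rules(generate_records(cfg),
#'                               config = mining_config(min_support = 0.05))
#' tidy(fit)
#' @export
mine_comorbidity_rules <- function(records,
                                   config = mining_config(),
                                   policy = exclusion_policy(),
                                   strict = FALSE,
                                   prune_redundant = FALSE) {
  stopifnot(inherits(config, "mining_config"))
  db <- build_transactions(records, policy = policy, strict = strict)
  frequent <- find_frequent_itemsets(db, min_support = config$min_support,
                                     max_len = config$max_len)
  all_rules <- generate_rules(frequent, db = db)
  kept <- filter_rules(all_rules, config)
  if (prune_redundant) kept <- prune_redundant_rules(kept)
  kept <- sort_rules(kept)
  parts <- partition_by_chapter(kept)
  kept$partition <- if (nrow(kept)) rule_chapters(kept$antecedent, kept$consequent) else character()

  manifest <- run_manifest(
    db = db, config = config, policy = policy,
    n_frequent = nrow(frequent),
    n_rules_generated = nrow(all_rules),
    n_rules_kept = nrow(kept)
  )
  structure(
    list(
      rules = kept,
      cross_chapter = parts$cross_chapter,
      within_chapter = parts$within_chapter,
      frequent = frequent,
      db = db,
      config = config,
      manifest = manifest
    ),
    class = "comorbidity_mining"
  )
}

run_manifest <- function(db, config, policy, n_frequent,
                         n_rules_generated, n_rules_kept) {
  m <- list(
    tool = "icdmine",
    version = as.character(utils::packageVersion("icdmine")),
    config = list(
      min_support = config$min_support,
      min_confidence = config$min_confidence,
      min_lift = config$min_lift,
      max_antecedent_size = config$max_antecedent_size,
      consequent_size = config$consequent_size,
      max_len = config$max_len,
      excluded_chapters = policy$excluded_chapters,
      description_token = policy$description_token
    ),
    counts = list(
      raw_rows = db$log$n_raw_rows,
      malformed_codes = db$log$n_malformed,
      excluded_codes = db$log$n_excluded_codes,
      patients_raw = db$log$n_patients_raw,
      single_admission_patients = db$log$n_single_admission_patients,
      empty_after_exclusion = db$log$n_empty_after_exclusion,
      n_transactions = db$n_transactions,
      codes_ingested = db$n_codes_ingested,
      items = length(db$items),
      frequent_itemsets = n_frequent,
      rules_generated = n_rules_generated,
      rules_kept = n_rules_kept
    )
  )
  validate_manifest(m)
  m
}

validate_manifest <- function(m) {
  cnt <- m$counts
  ok <- all(vapply(cnt, function(x) is.null(x) || (is.numeric(x) && x >= 0), logical(1))) &&
    cnt$rules_kept <= cnt$rules_generated &&
    cnt$n_transactions <= cnt$patients_raw &&
    cnt$single_admission_patients <= cnt$patients_raw &&
    cnt$codes_ingested <= cnt$raw_rows
  if (!ok) abort("Internal error: inconsistent run-manifest stage counts.")
  invisible(m)
}

#' @export
print.comorbidity_mining <- function(x, ...) {
  cnt <- x$manifest$counts
  cat("<comorbidity_mining>\n")
  cat(sprintf("  %d transactions over %d items -> %d frequent itemsets\n",
              cnt$n_transactions, cnt$items, cnt$frequent_itemsets))
  cat(sprintf("  %d rules generated, %d kept (%d cross-chapter, %d within-chapter)\n",
              cnt$rules_generated, cnt$rules_kept,
              nrow(x$cross_chapter), nrow(x$within_chapter)))
  if (nrow(x$rules) > 0) {
    cat("  top rules by confidence:\n")
    print(utils::head(format_rules(x$rules), 5))
  }
  invisible(x)
}

#' Tidy the mined rule table
#'
#' @param x A `comorbidity_mining` object.
#' @param ... Unused.
#' @return A tibble with one row per kept rule: `antecedent`, `consequent`,
#'   sizes, `support`, `confidence`, `lift`, `partition`, sorted by
#'   descending confidence.
#' @method tidy comorbidity_mining
#' @export
tidy.comorbidity_mining <- function(x, ...) {
  as_tibble(x$rules)
}

#' One-row summary of a mining run
#'
#' @param x A `comorbidity_mining` object.
#' @param ... Unused.
#' @return A one-row tibble of stage counts (raw rows, excluded codes,
#'   dropped patients, transactions, frequent itemsets, generated and kept
#'   rules).
#' @method glance comorbidity_mining
#' @export
glance.comorbidity_mining <- function(x, ...) {
  as_tibble(x$manifest$counts[!vapply(x$manifest$counts, is.null, logical(1))])
}

#' @method autoplot comorbidity_mining
#' @export
autoplot.comorbidity_mining <- function(object, ...) {
  autoplot(object$rules, ...)
}

#' Write mining outputs to a directory
#'
#' Writes `rules.csv` (all kept rules, with partition), `rules_cross.csv`,
#' `rules_within.csv`, `rules.json` (raw fractions) and `manifest.json`.
#'
#' @param x A `comorbidity_mining` object.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_mining_results <- function(x, dir) {
  stopifnot(inherits(x, "comorbidity_mining"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_rules(x$rules, file.path(dir, "rules.csv"))
  write_rules(x$cross_chapter, file.path(dir, "rules_cross.csv"))
  write_rules(x$within_chapter, file.path(dir, "rules_within.csv"))
  jsonlite::write_json(
    as_tibble(x$rules),
    file.path(dir, "rules.json"),
    digits = NA, auto_unbox = TRUE
  )
  jsonlite::write_json(
    x$manifest, file.path(dir, "manifest.json"),
    digits = NA, auto_unbox = TRUE
  )
  invisible(dir)
}
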