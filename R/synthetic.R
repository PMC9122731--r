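# Synthetic longitudinal EMR cohort with planted association structure.
#
# Each eligible patient draws a binary condition profile: planted rules
# contribute antecedent/consequent items with known probabilities (so the
# support, confidence and lift the miner should recover have closed forms),
# noise items are independent Bernoulli draws, and the profile is scattered
# across >= 2 hospital admissions. Decoy single-admission patients and
# injected excluded codes (V-Z chapters, "Other ..." descriptions) exercise
# the selection rules.

#' Define a planted association rule
#'
#' Per patient, the full antecedent (one or two categories) is present with
#' probability `p_antecedent`; given the antecedent the consequent appears
#' with probability `p_conditional`, otherwise with probability
#' `p_background`. Closed-form expectations over patients:
#' support `= p_antecedent * p_conditional`, confidence `= p_conditional`,
#' lift `= p_conditional / (p_antecedent * p_conditional +
#' (1 - p_antecedent) * p_background)`.
#'
#' @param antecedent One or two ICD-10 categories.
#' @param consequent A single ICD-10 category, disjoint from the antecedent.
#' @param p_antecedent,p_conditional,p_background Probabilities in `[0, 1]`.
#' @return An object of class `planted_rule`.
#' @examples
#' planted_rule("G45", "I63", 0.3, 0.8, 0.1)
#' @export
planted_rule <- function(antecedent, consequent,
                         p_antecedent, p_conditional, p_background) {
  antecedent <- toupper(as.character(antecedent))
  consequent <- toupper(as.character(consequent))
  if (!length(antecedent) %in% 1:2) abort("`antecedent` must have 1 or 2 categories.")
  if (length(consequent) != 1L) abort("`consequent` must be a single category.")
  if (any(consequent %in% antecedent)) {
    abort("Antecedent and consequent must be disjoint.")
  }
  icd10_parse(c(antecedent, consequent), strict = TRUE)
  for (p in list(p_antecedent, p_conditional, p_background)) {
    if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1) {
      abort("Planted-rule probabilities must be single values in [0, 1].")
    }
  }
  structure(
    list(
      antecedent = sort_c(antecedent), consequent = consequent,
      p_antecedent = p_antecedent, p_conditional = p_conditional,
      p_background = p_background
    ),
    class = "planted_rule"
  )
}

#' Closed-form expected metrics of a planted rule
#'
#' @param rule A [planted_rule()].
#' @return A one-row tibble with `support`, `confidence`, `lift`.
#' @examples
#' expected_metrics(planted_rule("G45", "I63", 0.3, 0.8, 0.1))
#' @export
expected_metrics <- function(rule) {
  stopifnot(inherits(rule, "planted_rule"))
  p_cons <- rule$p_antecedent * rule$p_conditional +
    (1 - rule$p_antecedent) * rule$p_background
  tibble(
    support = rule$p_antecedent * rule$p_conditional,
    confidence = rule$p_conditional,
    lift = if (p_cons > 0) rule$p_conditional / p_cons else NA_real_
  )
}

default_noise_items <- function() {
  # marginal prevalences loosely shaped like the head of a tertiary-care
  # diagnosis frequency distribution (circulatory codes dominating)
  c(
    I10 = 0.30, I63 = 0.20, E11 = 0.15, I25 = 0.10, C34 = 0.08,
    C50 = 0.07, J18 = 0.06, K29 = 0.05, I20 = 0.05, N18 = 0.04
  )
}

#' Configure a synthetic cohort
#'
#' @param n_patients Number of eligible (multi-admission) patients.
#' @param planted_rules List of [planted_rule()] objects. Planted categories
#'   must not overlap the noise categories.
#' @param noise_items Named numeric vector: ICD-10 category -> marginal
#'   prevalence, drawn independently per patient. The default emulates a
#'   hospital cohort dominated by circulatory-system codes.
#' @param admissions_lambda Eligible patients draw
#'   `2 + Poisson(admissions_lambda)` admissions; the default 1.85 gives a
#'   mean of about 3.85 hospitalizations per patient, typical of a
#'   multi-year tertiary-care cohort.
#' @param frac_single_admission Decoy patients with exactly one admission,
#'   as a fraction of `n_patients`; they must be removed by the
#'   single-hospitalization filter. Default 0.1.
#' @param frac_excluded_codes Per-admission probability of injecting one
#'   excluded code (a V/W/X/Y/Z-chapter code or an A-U code whose
#'   description contains the word "Other"). Default 0.05.
#' @param fallback_items Categories (disjoint from planted and noise items)
#'   from which one code is drawn for a patient whose stochastic draws
#'   produced no condition at all: every hospitalization carries at least
#'   one codable principal diagnosis, and keeping such patients in the
#'   cohort keeps the planted closed-form metrics exact.
#' @param seed Integer seed; a fixed seed makes [generate_records()] output
#'   byte-identical across runs.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          planted_rules = list(),
                          noise_items = default_noise_items(),
                          admissions_lambda = 1.85,
                          frac_single_admission = 0.1,
                          frac_excluded_codes = 0.05,
                          fallback_items = c("J06", "A09", "K52", "N39", "R50"),
                          seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 1L) abort("`n_patients` must be >= 1.")
  if (!is.list(planted_rules) ||
        !all(vapply(planted_rules, inherits, logical(1), "planted_rule"))) {
    abort("`planted_rules` must be a list of planted_rule objects.")
  }
  if (length(noise_items) > 0) {
    if (is.null(names(noise_items)) || any(names(noise_items) == "")) {
      abort("`noise_items` must be a named vector: category -> prevalence.")
    }
    icd10_parse(names(noise_items), strict = TRUE)
    if (any(noise_items < 0 | noise_items > 1)) {
      abort("Noise prevalences must lie in [0, 1].")
    }
  }
  planted_cats <- unique(unlist(lapply(
    planted_rules, function(r) c(r$antecedent, r$consequent)
  )))
  overlap <- intersect(planted_cats, names(noise_items))
  if (length(overlap) > 0) {
    abort(paste0("Planted and noise categories must be disjoint; overlap: ",
                 paste(overlap, collapse = ", ")))
  }
  icd10_parse(fallback_items, strict = TRUE)
  if (length(intersect(fallback_items, c(planted_cats, names(noise_items)))) > 0) {
    abort("`fallback_items` must be disjoint from planted and noise categories.")
  }
  # Rules sharing a category are OR-combined per patient, which perturbs
  # each other's closed forms; allowed, but flagged.
  if (length(planted_cats) <
        length(unlist(lapply(planted_rules, function(r) c(r$antecedent, r$consequent))))) {
    warn("Planted rules share categories; closed-form expected metrics may be approximate.")
  }
  stopifnot(
    admissions_lambda >= 0,
    frac_single_admission >= 0, frac_single_admission < 1,
    frac_excluded_codes >= 0, frac_excluded_codes <= 1
  )
  structure(
    list(
      n_patients = n_patients,
      planted_rules = planted_rules,
      noise_items = noise_items,
      admissions_lambda = admissions_lambda,
      frac_single_admission = frac_single_admission,
      frac_excluded_codes = frac_excluded_codes,
      fallback_items = as.character(fallback_items),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d eligible patients, seed %d\n", x$n_patients, x$seed))
  cat(sprintf("  %d planted rule(s), %d noise item(s)\n",
              length(x$planted_rules), length(x$noise_items)))
  cat(sprintf("  admissions ~ 2 + Poisson(%g); decoy fraction %g; excluded-code rate %g\n",
              x$admissions_lambda, x$frac_single_admission, x$frac_excluded_codes))
  invisible(x)
}

description_lookup <- c(
  I10 = "Essential (primary) hypertension",
  I63 = "Cerebral infarction",
  E11 = "Type 2 diabetes mellitus",
  I25 = "Chronic ischaemic heart disease",
  C34 = "Malignant neoplasm of bronchus and lung",
  C50 = "Malignant neoplasm of breast",
  J18 = "Pneumonia, organism unspecified",
  K29 = "Gastritis and duodenitis",
  I20 = "Angina pectoris",
  N18 = "Chronic kidney disease",
  G45 = "Transient cerebral ischaemic attacks and related syndromes",
  J06 = "Acute upper respiratory infections of multiple sites",
  A09 = "Infectious gastroenteritis and colitis",
  K52 = "Noninfective gastroenteritis and colitis",
  N39 = "Disorders of urinary system",
  R50 = "Fever of unknown origin"
)

describe_category <- function(category) {
  d <- unname(description_lookup[category])
  ifelse(is.na(d), paste("Condition", category), d)
}

#' Generate synthetic longitudinal diagnosis records
#'
#' Deterministic given `config$seed` (the global RNG state is restored
#' afterwards). Each emitted code carries a random fourth character
#' (`"I63.4"`) to exercise three-character truncation; every admission of
#' an eligible patient carries at least one code (chronic conditions are
#' re-coded on readmission, and duplicates collapse in the binary
#' encoding), so the single-hospitalization filter sees the patient's true
#' admission count.
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `patient_id`, `admission_id`, `icd10_code`,
#'   `description` — the same dialect [build_transactions()] and
#'   [read_records()] use.
#' @examples
#' cfg <- cohort_config(
#'   n_patients = 50,
#'   planted_rules = list(planted_rule("G45", "I61", 0.3, 0.8, 0.1)),
#'   seed = 42
#' )
#' head(generate_records(cfg))
#' @export
generate_records <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, generate_records_impl(config))
}

generate_records_impl <- function(config) {
  n <- config$n_patients
  planted_cats <- unique(unlist(lapply(
    config$planted_rules, function(r) c(r$antecedent, r$consequent)
  )))
  cats <- c(planted_cats, names(config$noise_items), config$fallback_items)
  profile <- matrix(FALSE, nrow = n, ncol = length(cats),
                    dimnames = list(NULL, cats))

  for (r in config$planted_rules) {
    ant_present <- runif(n) < r$p_antecedent
    p_cons <- ifelse(ant_present, r$p_conditional, r$p_background)
    cons_present <- runif(n) < p_cons
    for (a in r$antecedent) profile[, a] <- profile[, a] | ant_present
    profile[, r$consequent] <- profile[, r$consequent] | cons_present
  }
  for (item in names(config$noise_items)) {
    profile[, item] <- profile[, item] | (runif(n) < config$noise_items[[item]])
  }
  empty <- rowSums(profile) == 0
  if (any(empty)) {
    pick <- sample(config$fallback_items, sum(empty), replace = TRUE)
    profile[cbind(which(empty), match(pick, cats))] <- TRUE
  }

  n_adm <- 2L + rpois(n, config$admissions_lambda)

  idx <- which(profile, arr.ind = TRUE)
  items_long <- tibble(
    patient = idx[, 1L],
    category = cats[idx[, 2L]]
  ) |> arrange(.data$patient, .data$category)
  # uniform scatter of each condition into one of the patient's admissions
  items_long$adm <- 1L + as.integer(floor(runif(nrow(items_long)) *
                                            n_adm[items_long$patient]))

  # admissions that received no condition re-code one existing condition
  all_adm <- tibble(
    patient = rep.int(seq_len(n), n_adm),
    adm = sequence(n_adm)
  )
  filled <- unique(items_long[, c("patient", "adm")])
  missing <- dplyr::anti_join(all_adm, filled, by = c("patient", "adm"))
  if (nrow(missing) > 0) {
    cnt <- tabulate(items_long$patient, nbins = n)
    offset <- cumsum(cnt) - cnt
    pick_row <- offset[missing$patient] +
      1L + as.integer(floor(runif(nrow(missing)) * cnt[missing$patient]))
    missing$category <- items_long$category[pick_row]
    items_long <- bind_rows(items_long, missing)
  }

  pid <- sprintf("P%06d", seq_len(n))
  recs <- tibble(
    patient_id = pid[items_long$patient],
    admission_id = sprintf("%s-H%02d", pid[items_long$patient], items_long$adm),
    category = items_long$category
  )

  # decoy patients: exactly one admission, one or two conditions
  n_decoy <- as.integer(round(config$frac_single_admission * n))
  if (n_decoy > 0) {
    decoy_pool <- c(names(config$noise_items), config$fallback_items)
    decoy <- tibble(
      patient_id = sprintf("S%06d", seq_len(n_decoy)),
      admission_id = sprintf("S%06d-H01", seq_len(n_decoy)),
      category = sample(decoy_pool, n_decoy, replace = TRUE)
    )
    recs <- bind_rows(recs, decoy)
  }

  recs$icd10_code <- sprintf("%s.%d", recs$category,
                             as.integer(floor(runif(nrow(recs)) * 10)))
  recs$description <- describe_category(recs$category)

  # inject excluded codes at the configured per-admission rate
  adm_tbl <- unique(recs[, c("patient_id", "admission_id")])
  inject <- runif(nrow(adm_tbl)) < config$frac_excluded_codes
  if (any(inject)) {
    hit <- adm_tbl[inject, , drop = FALSE]
    m <- nrow(hit)
    as_chapter <- runif(m) < 0.5
    chap <- sample(c("V", "W", "X", "Y", "Z"), m, replace = TRUE)
    num <- sprintf("%02d", as.integer(floor(runif(m) * 100)))
    hit$icd10_code <- ifelse(
      as_chapter,
      paste0(chap, num),
      paste0(sample(c("L", "M", "T"), m, replace = TRUE), num)
    )
    hit$category <- substr(hit$icd10_code, 1L, 3L)
    hit$description <- ifelse(
      as_chapter,
      "Contact with health services or external cause",
      "Other specified disorders"
    )
    recs <- bind_rows(recs, hit)
  }

  recs |>
    select("patient_id", "admission_id", "icd10_code", "description") |>
    arrange(.data$patient_id, .data$admission_id, .data$icd10_code)
}

#' Read / write a cohort configuration as YAML
#'
#' @param path File path.
#' @return `read_cohort_config()` returns a [cohort_config()];
#'   `write_cohort_config()` returns `path` invisibly.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  rules <- lapply(y$planted_rules %||% list(), function(r) {
    planted_rule(
      antecedent = unlist(r$antecedent), consequent = r$consequent,
      p_antecedent = r$p_antecedent, p_conditional = r$p_conditional,
      p_background = r$p_background
    )
  })
  noise <- unlist(y$noise_items %||% list())
  cohort_config(
    n_patients = y$n_patients,
    planted_rules = rules,
    noise_items = if (length(noise)) noise else default_noise_items(),
    admissions_lambda = y$admissions_lambda %||% 1.85,
    frac_single_admission = y$frac_single_admission %||% 0.1,
    frac_excluded_codes = y$frac_excluded_codes %||% 0.05,
    fallback_items = unlist(y$fallback_items %||% c("J06", "A09", "K52", "N39", "R50")),
    seed = y$seed %||% 1L
  )
}

#' @rdname read_cohort_config
#' @param config A [cohort_config()].
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  y <- list(
    n_patients = config$n_patients,
    planted_rules = lapply(config$planted_rules, function(r) {
      list(
        antecedent = as.list(r$antecedent), consequent = r$consequent,
        p_antecedent = r$p_antecedent, p_conditional = r$p_conditional,
        p_background = r$p_background
      )
    }),
    noise_items = as.list(config$noise_items),
    admissions_lambda = config$admissions_lambda,
    frac_single_admission = config$frac_single_admission,
    frac_excluded_codes = config$frac_excluded_codes,
    fallback_items = as.list(config$fallback_items),
    seed = config$seed
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
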