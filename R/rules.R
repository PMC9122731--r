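# Association rule generation, scoring, filtering, sorting, and the
# cross-chapter / within-chapter partition.
#
# For a rule A -> B over patient transactions:
#   support    = P(A and B)         joint prevalence of the two itemsets
#   confidence = P(A and B) / P(A)  comorbidity of B with A
#   lift       = P(A and B) / (P(A) P(B))  symmetric dependence; > 1 means
#                positive association.

#' Mining thresholds and rule-shape limits
#'
#' Defaults follow the common EMR mining convention: very low support floor
#' (0.001) so rare but strong patterns survive, confidence at least 60%
#' (inclusive), lift strictly greater than 1, antecedents of at most two
#' ICD-10 categories and single-category consequents.
#'
#' @param min_support Minimum rule support, inclusive. Default 0.001.
#' @param min_confidence Minimum confidence, inclusive. Default 0.60.
#' @param min_lift Lift threshold, strict (`lift > min_lift`). Default 1.
#' @param max_antecedent_size Largest allowed antecedent. Default 2.
#' @param consequent_size Required consequent size. Default 1.
#' @param max_len Largest itemset mined; defaults to
#'   `max_antecedent_size + consequent_size`.
#' @return An object of class `mining_config`.
#' @export
mining_config <- function(min_support = 0.001,
                          min_confidence = 0.60,
                          min_lift = 1,
                          max_antecedent_size = 2L,
                          consequent_size = 1L,
                          max_len = max_antecedent_size + consequent_size) {
  stopifnot(
    min_support > 0, min_support <= 1,
    min_confidence >= 0, min_confidence <= 1,
    min_lift >= 0,
    max_antecedent_size >= 1, consequent_size >= 1,
    max_len >= 2
  )
  structure(
    list(
      min_support = min_support,
      min_confidence = min_confidence,
      min_lift = min_lift,
      max_antecedent_size = as.integer(max_antecedent_size),
      consequent_size = as.integer(consequent_size),
      max_len = as.integer(max_len)
    ),
    class = "mining_config"
  )
}

#' @export
print.mining_config <- function(x, ...) {
  cat("<mining_config>\n")
  cat(sprintf("  support >= %g, confidence >= %g, lift > %g\n",
              x$min_support, x$min_confidence, x$min_lift))
  cat(sprintf("  antecedent size <= %d, consequent size == %d, itemsets up to %d\n",
              x$max_antecedent_size, x$consequent_size, x$max_len))
  invisible(x)
}

#' Generate all association rules from frequent itemsets
#'
#' For every frequent itemset of size two or more, emits every ordered
#' partition into a non-empty antecedent and consequent, scored with exact
#' supports. Sub-itemset supports are looked up in the mined table (they are
#' guaranteed present by downward closure); if a needed support is missing
#' it is recomputed exactly from `db` when supplied, otherwise the
#' inconsistency is an error.
#'
#' @param frequent A [find_frequent_itemsets()] result.
#' @param db The source `transaction_db` (optional but recommended; used to
#'   recompute any missing sub-itemset support exactly).
#' @return A tibble of class `rule_set` with columns `antecedent`,
#'   `consequent` (semicolon-joined categories), `antecedent_size`,
#'   `consequent_size`, `support`, `confidence`, `lift`.
#' @export
generate_rules <- function(frequent, db = NULL) {
  stopifnot(inherits(frequent, "frequent_itemsets"))
  sup <- setNames(frequent$support, frequent$itemset)
  lookup <- function(key) {
    if (!is.na(sup[key])) return(unname(sup[key]))
    if (!is.null(db)) return(itemset_support(db, split_key(key)))
    abort(paste0(
      "Inconsistent input: support of sub-itemset {", key,
      "} is unavailable and no `db` was supplied to recompute it."
    ))
  }

  big <- frequent[frequent$size >= 2L, , drop = FALSE]
  rows <- purrr::map(seq_len(nrow(big)), function(i) {
    items <- big$items[[i]]
    s_full <- big$support[i]
    k <- length(items)
    # every non-empty proper subset as antecedent
    purrr::map(seq_len(k - 1L), function(a_size) {
      ants <- utils::combn(items, a_size, simplify = FALSE)
      purrr::map(ants, function(ant) {
        cons <- setdiff(items, ant)
        s_ant <- lookup(itemset_key(ant))
        s_con <- lookup(itemset_key(cons))
        tibble(
          antecedent = itemset_key(ant),
          consequent = itemset_key(cons),
          antecedent_size = length(ant),
          consequent_size = length(cons),
          support = s_full,
          confidence = s_full / s_ant,
          lift = s_full / (s_ant * s_con)
        )
      })
    })
  })
  out <- bind_rows(purrr::flatten(purrr::flatten(rows)))
  if (nrow(out) == 0) {
    out <- tibble(
      antecedent = character(), consequent = character(),
      antecedent_size = integer(), consequent_size = integer(),
      support = double(), confidence = double(), lift = double()
    )
  }
  out <- arrange(out, .data$antecedent_size + .data$consequent_size,
                 .data$antecedent, .data$consequent)
  class(out) <- c("rule_set", class(out))
  out
}

#' Filter rules by thresholds and shape
#'
#' Keeps rules with `support >= min_support`, `confidence >= min_confidence`
#' (both inclusive), `lift > min_lift` (strict), antecedent of at most
#' `max_antecedent_size` items and consequent of exactly `consequent_size`
#' items.
#'
#' @param rules A `rule_set` tibble.
#' @param config A [mining_config()].
#' @return The filtered `rule_set`.
#' @export
filter_rules <- function(rules, config = mining_config()) {
  stopifnot(inherits(config, "mining_config"))
  out <- filter(
    rules,
    .data$support >= config$min_support,
    .data$confidence >= config$min_confidence,
    .data$lift > config$min_lift,
    .data$antecedent_size <= config$max_antecedent_size,
    .data$consequent_size == config$consequent_size
  )
  class(out) <- unique(c("rule_set", class(out)))
  out
}

#' Sort rules by descending confidence
#'
#' The rules with the highest confidence are the most interesting, so the
#' primary key is confidence descending; ties break by lift descending,
#' then support descending, then lexicographic (antecedent, consequent).
#' Stable and deterministic.
#'
#' @param rules A `rule_set` tibble.
#' @return The sorted `rule_set`.
#' @export
sort_rules <- function(rules) {
  out <- arrange(
    rules,
    desc(.data$confidence), desc(.data$lift), desc(.data$support),
    .data$antecedent, .data$consequent
  )
  class(out) <- unique(c("rule_set", class(out)))
  out
}

rule_chapters <- function(antecedent, consequent) {
  purrr::map2_chr(antecedent, consequent, function(a, b) {
    ch <- unique(substr(c(split_key(a), split_key(b)), 1L, 1L))
    if (length(ch) == 1L) "within" else "cross"
  })
}

#' Partition rules into cross-chapter and within-chapter sets
#'
#' A rule is *within-chapter* iff every antecedent and consequent category
#' shares one ICD-10 chapter letter (same body system); otherwise it is
#' *cross-chapter*. The two sets partition the input.
#'
#' @param rules A `rule_set` tibble.
#' @return A list with elements `cross_chapter` and `within_chapter`, each a
#'   `rule_set` with an added `partition` column.
#' @export
partition_by_chapter <- function(rules) {
  part <- if (nrow(rules) == 0) character() else
    rule_chapters(rules$antecedent, rules$consequent)
  rules$partition <- part
  res <- list(
    cross_chapter = rules[part == "cross", , drop = FALSE],
    within_chapter = rules[part == "within", , drop = FALSE]
  )
  lapply(res, function(x) {
    class(x) <- unique(c("rule_set", class(x)))
    x
  })
}

#' Lift implied by a symmetric rule pair
#'
#' For a pair of rules A -> B and B -> A over the same two itemsets, the
#' definitions give P(A) = support / conf_forward and
#' P(B) = support / conf_backward, so the (shared, symmetric) lift is
#' `conf_forward * conf_backward / support`. This analytic identity lets
#' published rule tables be validated from their printed support and the
#' two printed confidences alone.
#'
#' @param support Joint support of the pair (fraction, > 0).
#' @param conf_forward Confidence of A -> B.
#' @param conf_backward Confidence of B -> A.
#' @return The implied lift (vectorised).
#' @examples
#' lift_from_rule_pair(0.4868, 0.7386, 0.6792) # ~1.03
#' @export
lift_from_rule_pair <- function(support, conf_forward, conf_backward) {
  if (any(support <= 0)) abort("`support` must be strictly positive.")
  if (any(conf_forward < support - 1e-12) || any(conf_backward < support - 1e-12) ||
        any(conf_forward > 1) || any(conf_backward > 1)) {
    abort("Confidences must lie in [support, 1].")
  }
  conf_forward * conf_backward / support
}

#' Render a rule table the way published comorbidity tables print it
#'
#' Support and confidence become percentages with two decimals and a
#' trailing percent sign; lift is printed with two decimals. Formatting is
#' for display/export only; all computation keeps full precision.
#'
#' @param rules A `rule_set` tibble.
#' @return A tibble with columns `no`, `antecedent`, `consequent`,
#'   `support`, `confidence`, `lift` (character-formatted metrics), plus
#'   `partition` when present.
#' @export
format_rules <- function(rules) {
  out <- tibble(
    no = seq_len(nrow(rules)),
    antecedent = rules$antecedent,
    consequent = rules$consequent,
    support = sprintf("%.2f%%", 100 * rules$support),
    confidence = sprintf("%.2f%%", 100 * rules$confidence),
    lift = sprintf("%.2f", rules$lift)
  )
  if ("partition" %in% names(rules)) out$partition <- rules$partition
  out
}

#' Serialise a rule table to CSV
#'
#' Raw fractions at full precision, one row per rule, with a `partition`
#' column when present.
#'
#' @param rules A `rule_set` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  cols <- intersect(
    c("antecedent", "consequent", "support", "confidence", "lift", "partition"),
    names(rules)
  )
  out <- mutate(select(as_tibble(rules), dplyr::all_of(cols)),
                no = row_number(), .before = 1)
  readr::write_csv(out, path)
  invisible(path)
}

#' Optional redundancy pruning (off by default in the pipeline)
#'
#' Drops a rule when a proper sub-antecedent rule with the same consequent
#' achieves confidence at least as high: the larger antecedent then adds no
#' predictive value. This is a labelled heuristic stand-in for manual expert
#' de-duplication, not part of the core mining contract.
#'
#' @param rules A `rule_set` tibble.
#' @return The pruned `rule_set`.
#' @export
prune_redundant_rules <- function(rules) {
  if (nrow(rules) < 2) return(rules)
  keep <- vapply(seq_len(nrow(rules)), function(i) {
    ant_i <- split_key(rules$antecedent[i])
    if (length(ant_i) == 1L) return(TRUE)
    same_con <- rules$consequent == rules$consequent[i]
    for (j in which(same_con)) {
      if (j == i) next
      ant_j <- split_key(rules$antecedent[j])
      if (length(ant_j) < length(ant_i) && all(ant_j %in% ant_i) &&
            rules$confidence[j] >= rules$confidence[i]) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  out <- rules[keep, , drop = FALSE]
  class(out) <- unique(c("rule_set", class(out)))
  out
}

#' @method autoplot rule_set
#' @export
autoplot.rule_set <- function(object, ...) {
  df <- as_tibble(object)
  if (!"partition" %in% names(df)) {
    df$partition <- rule_chapters(df$antecedent, df$consequent)
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$support, y = .data$confidence,
    size = .data$lift, colour = .data$partition
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10(labels = function(v) sprintf("%.2g%%", 100 * v)) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(
      x = "support (joint prevalence, log scale)",
      y = "confidence", size = "lift", colour = NULL,
      title = "Mined comorbidity rules"
    ) +
    ggplot2::theme_minimal()
}
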