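# Level-wise Apriori frequent-itemset mining.
#
# Support counting is exact: each item carries the sorted set of transaction
# ids containing it, and candidate supports come from intersecting those
# tid-sets, so counts are integers and runs are deterministic. Candidate
# generation is the classic (k-2)-prefix join with downward-closure pruning.

itemset_key <- function(items) paste(sort_c(items), collapse = ";")

split_key <- function(key) strsplit(key, ";", fixed = TRUE)[[1]]

sort_c <- function(x) sort(x, method = "radix")

item_tidlists <- function(db) {
  tid <- match(db$long$patient_id, db$patient_ids)
  lapply(split(tid, db$long$category), sort.int)
}

#' Exact support of one itemset
#'
#' Fraction of transactions containing every member of the itemset. The
#' empty itemset has support 1 (every transaction contains it).
#'
#' @param db A [build_transactions()] `transaction_db`.
#' @param itemset Character vector of ICD-10 categories (order irrelevant).
#' @return A single fraction in `[0, 1]`.
#' @examples
#' m <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("A00", "I10")))
#' itemset_support(as_transaction_db(m), "I10")
#' @export
itemset_support <- function(db, itemset) {
  stopifnot(inherits(db, "transaction_db"))
  itemset <- unique(as.character(itemset))
  if (length(itemset) == 0) return(1)
  unknown <- setdiff(itemset, db$items)
  if (length(unknown) > 0) {
    abort(paste0("Item(s) not in the transaction universe: ",
                 paste(unknown, collapse = ", ")))
  }
  tl <- item_tidlists(db)
  tids <- Reduce(intersect, tl[itemset])
  length(tids) / db$n_transactions
}

#' Mine all frequent itemsets with level-wise Apriori
#'
#' Finds exactly the itemsets of size `<= max_len` whose support is at least
#' `min_support` (inclusive, matching the support threshold convention
#' `support >= 0.001`). Level 1 comes from a single scan; candidates of size
#' k are generated by joining frequent (k-1)-itemsets that share a (k-2)
#' -prefix, and any candidate with an infrequent (k-1)-subset is pruned
#' before counting (downward closure). Support counts are exact integers
#' from tid-set intersection.
#'
#' @param db A `transaction_db`.
#' @param min_support Minimum support fraction in `(0, 1]`.
#' @param max_len Largest itemset size to mine. The default 3 covers rules
#'   with up to a two-item antecedent and a one-item consequent.
#' @return A tibble of class `frequent_itemsets` with columns `itemset`
#'   (semicolon-joined sorted categories), `items` (list column), `size`,
#'   `support_count`, `support`, sorted by size, then support descending,
#'   then itemset. Carries `n_transactions` as an attribute.
#' @examples
#' m <- matrix(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE), 2, 3,
#'             dimnames = list(c("P1", "P2"), c("A00", "B01", "I10")))
#' find_frequent_itemsets(as_transaction_db(m), min_support = 0.5)
#' @export
find_frequent_itemsets <- function(db, min_support, max_len = 3L) {
  stopifnot(inherits(db, "transaction_db"))
  if (!is.numeric(min_support) || length(min_support) != 1L ||
        min_support <= 0 || min_support > 1) {
    abort("`min_support` must be a single fraction in (0, 1].")
  }
  max_len <- as.integer(max_len)
  if (is.na(max_len) || max_len < 1L) abort("`max_len` must be >= 1.")

  n <- db$n_transactions
  tl <- item_tidlists(db)

  # Level 1: one scan over the item universe.
  f1_items <- sort_c(names(tl)[vapply(tl, length, 1L) / n >= min_support])
  levels <- list()
  current <- lapply(f1_items, function(it) list(items = it, tids = tl[[it]]))
  names(current) <- f1_items
  if (length(current) > 0) levels[[1L]] <- current

  k <- 2L
  while (k <= max_len && length(current) >= 2L) {
    prev_keys <- names(current)
    nxt <- list()
    # prefix join: keys are sorted, so joinable pairs share the first k-2
    # items and differ in the last.
    prefixes <- vapply(current, function(e) {
      paste(e$items[-length(e$items)], collapse = ";")
    }, character(1))
    for (grp in split(seq_along(current), prefixes)) {
      if (length(grp) < 2L) next
      for (a in seq_len(length(grp) - 1L)) {
        for (b in seq((a + 1L), length(grp))) {
          ia <- current[[grp[a]]]; ib <- current[[grp[b]]]
          cand <- sort_c(union(ia$items, ib$items))
          # downward closure: every (k-1)-subset must be frequent.
          subs <- vapply(seq_along(cand), function(drop_i) {
            paste(cand[-drop_i], collapse = ";")
          }, character(1))
          if (!all(subs %in% prev_keys)) next
          tids <- intersect(ia$tids, ib$tids)
          if (length(tids) / n >= min_support) {
            nxt[[paste(cand, collapse = ";")]] <-
              list(items = cand, tids = sort.int(tids))
          }
        }
      }
    }
    if (length(nxt) == 0) break
    nxt <- nxt[sort_c(names(nxt))]
    levels[[k]] <- nxt
    current <- nxt
    k <- k + 1L
  }

  all_sets <- unlist(levels, recursive = FALSE, use.names = TRUE)
  if (length(all_sets) == 0) {
    out <- tibble(
      itemset = character(), items = list(), size = integer(),
      support_count = integer(), support = double()
    )
  } else {
    all_sets <- unname(all_sets)
    out <- tibble(
      itemset = vapply(all_sets, function(e) paste(e$items, collapse = ";"), character(1)),
      items = lapply(all_sets, `[[`, "items"),
      size = vapply(all_sets, function(e) length(e$items), integer(1)),
      support_count = vapply(all_sets, function(e) length(e$tids), integer(1))
    ) |>
      mutate(support = .data$support_count / n) |>
      arrange(.data$size, desc(.data$support), .data$itemset)
  }
  attr(out, "n_transactions") <- n
  attr(out, "min_support") <- min_support
  class(out) <- c("frequent_itemsets", class(out))
  out
}

#' Serialise frequent itemsets to CSV
#'
#' Writes columns `itemset` (semicolon-joined), `size`, `support_count`,
#' `support`.
#'
#' @param x A `frequent_itemsets` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frequent_itemsets <- function(x, path) {
  readr::write_csv(select(x, "itemset", "size", "support_count", "support"), path)
  invisible(path)
}
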