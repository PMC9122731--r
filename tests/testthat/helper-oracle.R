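# Independent brute-force oracle and random-database generator.
#
# The oracle works directly on the dense binary matrix by exhaustive subset
# enumeration; it shares no code path with the tid-set Apriori miner it
# checks against.

code_universe <- function() {
  sprintf("%s%02d", rep(LETTERS[1:20], each = 5), rep(10 * (0:4) + 1, times = 20))
}

random_transaction_db <- function(n_items, n_trans, density = 0.35) {
  items <- sort(sample(code_universe(), n_items))
  m <- matrix(runif(n_trans * n_items) < density, nrow = n_trans,
              dimnames = list(sprintf("T%03d", seq_len(n_trans)), items))
  empty <- rowSums(m) == 0
  m[cbind(which(empty), sample.int(n_items, sum(empty), replace = TRUE))] <- TRUE
  as_transaction_db(m)
}

brute_support <- function(m, items) {
  mean(rowSums(m[, items, drop = FALSE]) == length(items))
}

brute_frequent <- function(db, min_support, max_len = 3L) {
  m <- to_binary_matrix(db)
  items <- colnames(m)
  res <- list()
  for (k in seq_len(min(max_len, length(items)))) {
    for (set in utils::combn(items, k, simplify = FALSE)) {
      cnt <- sum(rowSums(m[, set, drop = FALSE]) == k)
      if (cnt / nrow(m) >= min_support) {
        res[[paste(set, collapse = ";")]] <- list(
          itemset = paste(set, collapse = ";"),
          size = k, support_count = cnt, support = cnt / nrow(m)
        )
      }
    }
  }
  if (length(res) == 0) {
    return(tibble::tibble(itemset = character(), size = integer(),
                          support_count = integer(), support = double()))
  }
  dplyr::bind_rows(res)
}

brute_rules <- function(db, min_support, max_len = 3L) {
  m <- to_binary_matrix(db)
  freq <- brute_frequent(db, min_support, max_len)
  if (nrow(freq) == 0 || !any(freq$size >= 2)) {
    return(tibble::tibble(antecedent = character(), consequent = character(),
                          support = double(), confidence = double(), lift = double()))
  }
  rows <- list()
  for (key in freq$itemset[freq$size >= 2]) {
    items <- strsplit(key, ";", fixed = TRUE)[[1]]
    for (a_size in seq_len(length(items) - 1L)) {
      for (ant in utils::combn(items, a_size, simplify = FALSE)) {
        cons <- setdiff(items, ant)
        s <- brute_support(m, items)
        sa <- brute_support(m, ant)
        sc <- brute_support(m, cons)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          antecedent = paste(sort(ant), collapse = ";"),
          consequent = paste(sort(cons), collapse = ";"),
          support = s, confidence = s / sa, lift = s / (sa * sc)
        )
      }
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), antecedent, consequent)
}

example_db <- function() {
  read_transactions_matrix(icdmine_example("example_incidence.csv"))
}
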