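test_that("rule metrics on the worked sample match hand counts", {
  db <- example_db()
  fr <- find_frequent_itemsets(db, min_support = 2 / 11, max_len = 2)
  rules <- generate_rules(fr, db)
  r <- dplyr::filter(rules, antecedent == "B01", consequent == "C03")
  expect_equal(nrow(r), 1)
  expect_equal(r$support, 2 / 11)
  expect_equal(r$confidence, 1.0)
  expect_equal(r$lift, 11 / 4)
})

test_that("lift is one when the consequent is universal", {
  m <- matrix(c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE), 3, 2,
              dimnames = list(c("P1", "P2", "P3"), c("A00", "B01")))
  db <- as_transaction_db(m)
  fr <- find_frequent_itemsets(db, min_support = 0.5, max_len = 2)
  rules <- generate_rules(fr, db)
  r <- dplyr::filter(rules, antecedent == "A00", consequent == "B01")
  expect_equal(r$lift, 1)
})

test_that("all generated metrics match a brute-force recomputation", {
  set.seed(505)
  for (i in 1:10) {
    db <- random_transaction_db(n_items = sample(5:10, 1), n_trans = sample(30:150, 1))
    ms <- runif(1, 0.03, 0.2)
    fr <- find_frequent_itemsets(db, min_support = ms, max_len = 3)
    got <- dplyr::arrange(generate_rules(fr, db), antecedent, consequent)
    want <- brute_rules(db, min_support = ms, max_len = 3)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$antecedent, want$antecedent)
    expect_equal(got$consequent, want$consequent)
    expect_equal(got$support, want$support, tolerance = 1e-9)
    expect_equal(got$confidence, want$confidence, tolerance = 1e-9)
    expect_equal(got$lift, want$lift, tolerance = 1e-9)
  }
})

test_that("metric identities hold on every generated rule", {
  set.seed(606)
  db <- random_transaction_db(n_items = 9, n_trans = 120)
  fr <- find_frequent_itemsets(db, min_support = 0.05, max_len = 3)
  rules <- generate_rules(fr, db)
  sup <- stats::setNames(fr$support, fr$itemset)
  for (i in seq_len(nrow(rules))) {
    a <- rules$antecedent[i]; b <- rules$consequent[i]
    # symmetric twin exists with equal support and lift
    j <- which(rules$antecedent == b & rules$consequent == a)
    expect_length(j, 1)
    expect_equal(rules$support[i], rules$support[j], tolerance = 1e-12)
    expect_equal(rules$lift[i], rules$lift[j], tolerance = 1e-12)
    # confidence * P(antecedent) recovers the joint support
    expect_equal(rules$confidence[i] * sup[[a]], rules$support[i],
                 tolerance = 1e-12)
    expect_gte(rules$confidence[i] + 1e-12, rules$support[i])
  }
})

test_that("a larger antecedent never raises the joint support", {
  set.seed(707)
  db <- random_transaction_db(n_items = 8, n_trans = 100, density = 0.45)
  fr <- find_frequent_itemsets(db, min_support = 0.02, max_len = 3)
  rules <- generate_rules(fr, db)
  two <- dplyr::filter(rules, antecedent_size == 2, consequent_size == 1)
  for (i in seq_len(nrow(two))) {
    parts <- strsplit(two$antecedent[i], ";", fixed = TRUE)[[1]]
    for (p in parts) {
      sub <- dplyr::filter(rules, antecedent == p,
                           consequent == two$consequent[i])
      if (nrow(sub) == 1) expect_lte(two$support[i], sub$support + 1e-12)
    }
  }
})

test_that("filtering uses inclusive support/confidence and strict lift", {
  fake <- tibble::tibble(
    antecedent = c("A01", "A01", "A01", "A01;B01;C01", "A01"),
    consequent = c("B01", "B01", "B01", "D01", "B01;C01"),
    antecedent_size = c(1L, 1L, 1L, 3L, 1L),
    consequent_size = c(1L, 1L, 1L, 1L, 2L),
    support = c(0.001, 0.01, 0.0009, 0.01, 0.01),
    confidence = c(0.60, 0.59, 0.9, 0.9, 0.9),
    lift = c(1.5, 1.5, 1.5, 1.5, 1.5)
  )
  class(fake) <- c("rule_set", class(fake))
  kept <- filter_rules(fake, mining_config())
  # row 1: all boundaries pass (support and confidence inclusive)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$support, 0.001)
  expect_equal(kept$confidence, 0.60)
  # lift exactly at the threshold is dropped (strict >)
  fake$lift <- 1.0
  expect_equal(nrow(filter_rules(fake, mining_config())), 0)
})

test_that("sorting is by confidence desc with documented tie-breaks", {
  r <- tibble::tibble(
    antecedent = c("A01", "B01", "C01", "D01"),
    consequent = "Z99",
    antecedent_size = 1L, consequent_size = 1L,
    support = c(0.1, 0.2, 0.1, 0.1),
    confidence = c(0.7, 0.9, 0.8, 0.8),
    lift = c(1.1, 1.1, 1.5, 2.0)
  )
  class(r) <- c("rule_set", class(r))
  s <- sort_rules(r)
  expect_equal(s$confidence, c(0.9, 0.8, 0.8, 0.7))
  expect_equal(s$antecedent[2:3], c("D01", "C01")) # lift 2.0 before 1.5
})

test_that("the re-entered cross-chapter table is a fixed point of sort_rules", {
  tab <- read_rule_table(icdmine_example("example_rules_cross.csv"))
  sorted <- sort_rules(tab)
  expect_equal(as.data.frame(sorted), as.data.frame(tab))
  expect_true(all(diff(tab$confidence) <= 0))
  expect_equal(tab$confidence[1], 0.8361)
  expect_equal(tab$confidence[nrow(tab)], 0.6079)
})

test_that("chapter partition splits rules by shared chapter letter", {
  tab <- tibble::tibble(
    antecedent = c("E11;N18", "I66", "E11;G45"),
    consequent = c("I10", "I63", "I63"),
    antecedent_size = c(2L, 1L, 2L), consequent_size = 1L,
    support = 0.01, confidence = 0.7, lift = 1.5
  )
  class(tab) <- c("rule_set", class(tab))
  parts <- partition_by_chapter(tab)
  expect_equal(parts$within_chapter$antecedent, "I66")
  expect_setequal(parts$cross_chapter$antecedent, c("E11;N18", "E11;G45"))
  expect_equal(nrow(parts$cross_chapter) + nrow(parts$within_chapter), nrow(tab))
})

test_that("the re-entered published tables partition as labelled", {
  cross <- read_rule_table(icdmine_example("example_rules_cross.csv"))
  within <- read_rule_table(icdmine_example("example_rules_within.csv"))
  expect_equal(nrow(partition_by_chapter(cross)$cross_chapter), nrow(cross))
  expect_equal(nrow(partition_by_chapter(within)$within_chapter), nrow(within))
})

test_that("symmetric-pair lift identity evaluates its closed forms", {
  expect_equal(round(lift_from_rule_pair(0.4868, 0.7386, 0.6792), 2), 1.03)
  expect_equal(round(lift_from_rule_pair(0.1215, 0.9091, 0.7718), 2), 5.77)
  s <- c(0.1, 0.25, 0.5)
  expect_equal(lift_from_rule_pair(s, 1, 1), 1 / s)
  expect_error(lift_from_rule_pair(0, 0.5, 0.5), "positive")
  expect_error(lift_from_rule_pair(0.5, 0.4, 0.9), "Confidences")
})

test_that("lift identity reproduces stored lift on generated symmetric pairs", {
  set.seed(808)
  db <- random_transaction_db(n_items = 8, n_trans = 120)
  fr <- find_frequent_itemsets(db, min_support = 0.05, max_len = 2)
  rules <- generate_rules(fr, db)
  for (i in seq_len(nrow(rules))) {
    j <- which(rules$antecedent == rules$consequent[i] &
                 rules$consequent == rules$antecedent[i])
    expect_equal(
      lift_from_rule_pair(rules$support[i], rules$confidence[i], rules$confidence[j]),
      rules$lift[i],
      tolerance = 1e-12
    )
  }
})

test_that("redundancy pruning drops dominated two-item antecedents only", {
  r <- tibble::tibble(
    antecedent = c("A01", "A01;B01", "A01;C01"),
    consequent = "Z99",
    antecedent_size = c(1L, 2L, 2L), consequent_size = 1L,
    support = c(0.2, 0.1, 0.1),
    confidence = c(0.8, 0.75, 0.9),
    lift = 1.5
  )
  class(r) <- c("rule_set", class(r))
  pruned <- prune_redundant_rules(r)
  expect_setequal(pruned$antecedent, c("A01", "A01;C01"))
})

test_that("formatted tables render two-decimal percentages", {
  tab <- read_rule_table(icdmine_example("example_rules_cross.csv"))
  f <- format_rules(sort_rules(tab))
  expect_equal(f$confidence[1], "83.61%")
  expect_equal(f$support[1], "1.08%")
  expect_equal(f$lift[1], "1.98")
})
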