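test_that("Apriori equals exhaustive enumeration on a toy matrix", {
  withr::local_seed(101)
  tr <- random_transactions(n_rows = 40, n_attr_items = 6)  # 8 items total
  for (ms in c(0, 0.1, 0.3, 0.6)) {
    mined <- mine_frequent_itemsets(tr, min_support = ms, max_len = 8L)
    oracle <- oracle_frequent(tr$incidence, ms, 8L)
    key <- function(items) paste(sort(items), collapse = "|")
    got <- setNames(mined$support_count,
                    vapply(mined$items, key, ""))
    want <- setNames(
      vapply(oracle, `[[`, 0, "count"),
      vapply(oracle, function(o) key(colnames(tr$incidence)[o$set]), ""))
    expect_identical(sort(names(got)), sort(names(want)))
    expect_equal(got[names(want)], want)
  }
})

test_that("Apriori edge contracts hold", {
  withr::local_seed(102)
  tr <- random_transactions(30, 5)
  # min_support = 0, max_len = 1: one singleton per catalog item
  s <- mine_frequent_itemsets(tr, min_support = 0, max_len = 1L)
  expect_equal(nrow(s), ncol(tr$incidence))
  expect_setequal(unlist(s$items), colnames(tr$incidence))
  # monotonicity in the threshold
  hi <- mine_frequent_itemsets(tr, 0.3, 3L)
  lo <- mine_frequent_itemsets(tr, 0.2, 3L)
  key <- vapply(hi$items, function(x) paste(sort(x), collapse = "|"), "")
  keylo <- vapply(lo$items, function(x) paste(sort(x), collapse = "|"), "")
  expect_true(all(key %in% keylo))
  # Apriori property: every subset of a frequent itemset is frequent
  for (i in which(hi$size > 1)) {
    items <- hi$items[[i]]
    for (j in seq_along(items)) {
      expect_true(paste(sort(items[-j]), collapse = "|") %in% key)
    }
  }
  # empty matrix errors
  tr0 <- tr; tr0$incidence <- tr$incidence[0, , drop = FALSE]; tr0$n <- 0L
  expect_error(mine_frequent_itemsets(tr0), "empty")
})

test_that("contingency tables come from exact row scans", {
  # 10-row toy with |A| = 4, |B| = 5, co-occurrence 3
  inc <- cbind(A = c(1,1,1,1,0,0,0,0,0,0) == 1,
               B = c(1,1,1,0,1,1,0,0,0,0) == 1,
               C = rep(FALSE, 10))
  tr <- structure(list(incidence = inc, n = 10L,
                       items = data.frame(label = colnames(inc))),
                  class = "survrule_transactions")
  ct <- contingency(tr, "A", "B")
  expect_equal(ct[c("n11", "n10", "n01", "n00")],
               list(n11 = 3L, n10 = 1L, n01 = 2L, n00 = 4L))
  expect_equal(ct$n_a, 4L); expect_equal(ct$n_b, 5L)
  expect_equal(with(ct, n11 + n10 + n01 + n00), 10L)
  # disjoint pair
  expect_equal(contingency(tr, "A", "C")$n11, 0L)
  # self-pair
  ct2 <- contingency(tr, "A", "A")
  expect_equal(ct2$n10, 0L); expect_equal(ct2$n01, 0L)
  expect_error(contingency(tr, "A", "Z"), "unknown")
})

test_that("metric suite matches the hand-derived 2x2 arithmetic", {
  m <- compute_metrics(contingency_from_counts(3, 1, 2, 4))
  expect_equal(m$support, 0.300)
  expect_equal(m$confidence, 0.750)
  expect_equal(m$lift, 1.500)
  expect_equal(m$cosine, 0.6708204, tolerance = 1e-6)
  expect_equal(m$correlation, 0.4082483, tolerance = 1e-6)
  expect_equal(m$chi_square, 1.6666667, tolerance = 1e-6)
  expect_equal(m$odds_ratio, 6.0)
  # Woolf interval straddles the point estimate
  expect_lt(m$or_ci_low, 6); expect_gt(m$or_ci_high, 6)

  # perfect association: A = B exactly
  mp <- compute_metrics(contingency_from_counts(5, 0, 0, 5))
  expect_equal(mp$confidence, 1)
  expect_equal(mp$cosine, 1)
  expect_equal(mp$correlation, 1)
  expect_equal(mp$chi_square, 10)

  # exact independence
  mi <- compute_metrics(contingency_from_counts(2, 2, 3, 3))
  expect_equal(mi$lift, 1)
  expect_equal(mi$correlation, 0)
  expect_equal(mi$chi_square, 0)

  # degenerate margin: phi flagged NA, not an error
  md <- compute_metrics(contingency_from_counts(3, 0, 7, 0))
  expect_true(is.na(md$correlation))
  expect_true(is.na(md$chi_square))
  # zero antecedent support is an error
  expect_error(compute_metrics(contingency_from_counts(0, 0, 4, 6)),
               "confidence undefined")
  # n11 = 0 reports lift 0 and a finite Haldane-Anscombe odds ratio
  m0 <- compute_metrics(contingency_from_counts(0, 4, 3, 3))
  expect_equal(m0$lift, 0)
  expect_equal(m0$cosine, 0)
  expect_true(is.finite(m0$odds_ratio) && m0$odds_ratio > 0)
})

test_that("metric identities hold on 1000 random 2x2 tables", {
  withr::local_seed(103)
  for (i in seq_len(1000)) {
    ct <- random_contingency()
    f <- compute_metrics(do.call(contingency_from_counts, ct))
    # chi-square = N * phi^2
    n <- with(ct, n11 + n10 + n01 + n00)
    expect_equal(f$chi_square, n * f$correlation^2,
                 tolerance = 1e-9)
    # cosine = sqrt(conf(A->B) * conf(B->A))
    swapped <- compute_metrics(
      contingency_from_counts(ct$n11, ct$n01, ct$n10, ct$n00))
    expect_equal(f$cosine, sqrt(f$confidence * swapped$confidence),
                 tolerance = 1e-9)
    # symmetry of support and lift; asymmetry of confidence unless |A|=|B|
    expect_equal(f$support, swapped$support)
    expect_equal(f$lift, swapped$lift, tolerance = 1e-12)
    if (ct$n10 != ct$n01 && ct$n11 > 0) {
      expect_false(f$confidence == swapped$confidence)
    }
    # bounds chain: support <= min(|A|,|B|)/N; lift = confidence / (|B|/N)
    expect_lte(f$support,
               min(ct$n11 + ct$n10, ct$n11 + ct$n01) / n + 1e-12)
    expect_equal(f$lift, f$confidence / ((ct$n11 + ct$n01) / n),
                 tolerance = 1e-12)
  }
})

test_that("metrics agree with the independent vector-based oracle", {
  withr::local_seed(104)
  for (i in seq_len(50)) {
    n <- sample(10:60, 1)
    a <- runif(n) < runif(1, 0.2, 0.8)
    b <- runif(n) < runif(1, 0.2, 0.8)
    if (sum(a) == 0) a[1] <- TRUE
    ct <- contingency_from_counts(sum(a & b), sum(a & !b),
                                  sum(!a & b), sum(!a & !b))
    f <- compute_metrics(ct)
    o <- oracle_metrics(a, b)
    for (nm in c("support", "confidence", "lift", "cosine")) {
      expect_equal(f[[nm]], o[[nm]], tolerance = 1e-12)
    }
    if (!is.na(o$correlation) && !is.na(f$correlation)) {
      expect_equal(f$correlation, o$correlation, tolerance = 1e-9)
      expect_equal(f$chi_square, o$chi_square, tolerance = 1e-9)
    }
  }
})

test_that("rule generation pairs frequent antecedents with outcomes only", {
  withr::local_seed(105)
  tr <- random_transactions(50, 6)
  its <- mine_frequent_itemsets(tr, min_support = 0, max_len = 2L)
  rules <- generate_rules(its, tr, min_confidence = 0)
  # no antecedent contains an outcome item
  expect_false(any(vapply(rules$antecedent,
                          function(a) any(a %in% outcome_items()), TRUE)))
  # rule count = (frequent non-outcome antecedents with support > 0) x 2
  n_ante <- sum(vapply(its$items,
                       function(s) !any(s %in% outcome_items()), TRUE) &
                its$support_count > 0)
  expect_equal(nrow(rules), 2L * n_ante)
  # exhaustive cross-check of every rule's confidence
  for (i in seq_len(nrow(rules))) {
    a <- rowSums(tr$incidence[, rules$antecedent[[i]], drop = FALSE]) ==
      length(rules$antecedent[[i]])
    b <- tr$incidence[, rules$consequent[i]]
    expect_equal(rules$confidence[i], sum(a & b) / sum(a))
  }
  # threshold semantics
  high <- generate_rules(its, tr, min_confidence = 0.99)
  expect_true(all(high$confidence >= 0.99))
  expect_error(generate_rules(its, tr, consequents = character()), "empty")
  expect_error(generate_rules(its, tr, consequents = "attr1: yes"),
               "outcome")
})

test_that("mine+score matches the exhaustive oracle end to end", {
  withr::local_seed(106)
  for (rep in seq_len(3)) {
    tr <- random_transactions(n_rows = sample(20:64, 1),
                              n_attr_items = 10)   # 12 items total
    ms <- runif(1, 0.05, 0.3)
    mined <- mine_frequent_itemsets(tr, ms, max_len = 12L)
    oracle <- oracle_frequent(tr$incidence, ms, 12L)
    expect_equal(nrow(mined), length(oracle))
    rules <- generate_rules(mined, tr, min_confidence = 0)
    for (i in seq_len(nrow(rules))) {
      a <- rowSums(tr$incidence[, rules$antecedent[[i]], drop = FALSE]) ==
        length(rules$antecedent[[i]])
      o <- oracle_metrics(a, tr$incidence[, rules$consequent[i]])
      expect_equal(rules$support[i], o$support, tolerance = 1e-12)
      expect_equal(rules$confidence[i], o$confidence, tolerance = 1e-12)
      expect_equal(rules$lift[i], o$lift, tolerance = 1e-12)
      expect_equal(rules$cosine[i], o$cosine, tolerance = 1e-12)
    }
  }
})

test_that("rules export as JSON lines", {
  withr::local_seed(107)
  tr <- random_transactions(30, 4)
  rules <- generate_rules(mine_frequent_itemsets(tr, 0.1, 1L), tr,
                          min_confidence = 0)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_rules_jsonl(rules, path)
  lines <- readLines(path)
  expect_length(lines, nrow(rules))
  rec <- jsonlite::fromJSON(lines[1])
  expect_identical(rec$consequent, rules$consequent[1])
  expect_equal(rec$confidence, rules$confidence[1])
})
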