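# Redundancy filtering, chi-square significance, confidence ranking and the
# publication-style report table.

#' Filter redundant rules
#'
#' A rule is redundant when a shorter rule already explains it at least as
#' well: rule R' is removed iff some retained rule R shares its consequent,
#' has an antecedent that is a strict subset of R''s, and has confidence
#' >= confidence(R'). A longer rule that strictly improves confidence is
#' kept. The filter is idempotent. Set `enabled = FALSE` to pass rules
#' through untouched.
#'
#' @param rules A `survrule_rules` data.frame (one transaction base).
#' @param enabled Apply the filter? Default `TRUE`.
#' @return The retained rules, original order preserved.
#' @export
filter_redundant <- function(rules, enabled = TRUE) {
  stopifnot(is.data.frame(rules))
  if (!enabled || nrow(rules) < 2L) return(rules)
  n <- nrow(rules)
  drop <- logical(n)
  for (i in seq_len(n)) {
    ai <- rules$antecedent[[i]]
    for (j in seq_len(n)) {
      if (i == j || rules$consequent[j] != rules$consequent[i]) next
      aj <- rules$antecedent[[j]]
      # j strictly subsumes i without losing confidence => i redundant;
      # confidence dominance is transitive along subset chains, so checking
      # against all rules equals checking against retained ones
      if (length(aj) < length(ai) && all(aj %in% ai) &&
          rules$confidence[j] >= rules$confidence[i]) {
        drop[i] <- TRUE
        break
      }
    }
  }
  rules[!drop, , drop = FALSE]
}

#' Chi-square significance of rules
#'
#' Upper-tail p-value of the rule's (uncorrected) Pearson chi-square
#' statistic against the chi-square distribution with one degree of
#' freedom; a rule is flagged significant when p < alpha. P-values are
#' per-rule and uncorrected; an optional Benjamini-Hochberg column can be
#' added for multiplicity-aware reading.
#'
#' @param rules A `survrule_rules` data.frame, or a numeric vector of
#'   chi-square statistics.
#' @param alpha Significance level. Default 0.05.
#' @param bh Also add a Benjamini-Hochberg adjusted p-value column
#'   (`p_adjusted`)? Default `FALSE`.
#' @return For a data.frame input, the rules with added `p_value` and
#'   `significant` columns; for a numeric input, a list with `p_value` and
#'   `significant`.
#' @export
significance_flag <- function(rules, alpha = 0.05, bh = FALSE) {
  if (is.numeric(rules)) {
    p <- stats::pchisq(rules, df = 1, lower.tail = FALSE)
    return(list(p_value = p, significant = !is.na(p) & p < alpha))
  }
  stopifnot(is.data.frame(rules), "chi_square" %in% names(rules))
  p <- stats::pchisq(rules$chi_square, df = 1, lower.tail = FALSE)
  rules$p_value <- p
  rules$significant <- !is.na(p) & p < alpha
  if (bh) rules$p_adjusted <- stats::p.adjust(p, method = "BH")
  rules
}

#' Rank rules by confidence within each consequent
#'
#' Groups rules by consequent and sorts each group by confidence
#' (descending), breaking ties by support (descending) and then by the
#' canonical antecedent string (ascending), for fully reproducible reports.
#' Each group is truncated to its top `k` and numbered from 1.
#'
#' @param rules A `survrule_rules` data.frame.
#' @param k Rows kept per consequent. Default 10.
#' @return A `survrule_ranked` data.frame with a leading `rank` column;
#'   groups appear in [outcome_items()] order (death first).
#' @export
rank_rules <- function(rules, k = 10L) {
  stopifnot(is.data.frame(rules))
  if (k < 1L) stop("'k' must be >= 1")
  groups <- unique(rules$consequent)
  # stable report order: death consequent first, then survival
  groups <- c(intersect(unname(outcome_items()), groups),
              setdiff(groups, unname(outcome_items())))
  out <- lapply(groups, function(g) {
    r <- rules[rules$consequent == g, , drop = FALSE]
    o <- order(-r$confidence, -r$support, r$antecedent_str,
               method = "radix")
    r <- r[o, , drop = FALSE][seq_len(min(k, nrow(r))), , drop = FALSE]
    r <- cbind(rank = seq_len(nrow(r)), r)
    r
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("survrule_ranked", "data.frame")
  res
}

fmt_num <- function(x, digits = 3) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "f"))
}

#' Format the ranked-rule report table
#'
#' One row per ranked rule with the publication-style columns: `Rule`,
#' `Antecedent (LHS)`, `Consequent (RHS)`, `Support`, `Confidence`, `Lift`,
#' `Cosine`, `Correlation coefficient`, `Chi-square` and `OR (95% CI)`.
#'
#' @param ranked A `survrule_ranked` data.frame from [rank_rules()].
#' @param digits Decimal places for the metric columns. Default 3.
#' @return A plain data.frame of formatted strings/numbers.
#' @export
format_rule_report <- function(ranked, digits = 3) {
  stopifnot(is.data.frame(ranked))
  data.frame(
    `Rule` = ranked$rank,
    `Antecedent (LHS)` = ranked$antecedent_str,
    `Consequent (RHS)` = ranked$consequent,
    `Support` = fmt_num(ranked$support, digits),
    `Confidence` = fmt_num(ranked$confidence, digits),
    `Lift` = fmt_num(ranked$lift, digits),
    `Cosine` = fmt_num(ranked$cosine, digits),
    `Correlation coefficient` = fmt_num(ranked$correlation, digits),
    `Chi-square` = fmt_num(ranked$chi_square, digits),
    `OR (95% CI)` = paste0(fmt_num(ranked$odds_ratio, digits), " (",
                           fmt_num(ranked$or_ci_low, digits), "-",
                           fmt_num(ranked$or_ci_high, digits), ")"),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

#' Write the ranked-rule report CSV
#'
#' @param ranked A `survrule_ranked` data.frame.
#' @param path Output CSV path.
#' @param digits Decimal places. Default 3.
#' @return `path`, invisibly.
#' @export
write_rule_report <- function(ranked, path, digits = 3) {
  utils::write.csv(format_rule_report(ranked, digits), path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full mining pipeline on a cohort
#'
#' Convenience wrapper: encode transactions, mine frequent itemsets,
#' generate and score rules against both survivability consequents, filter
#' redundant rules, attach significance, and rank per consequent.
#'
#' @param cohort A `survrule_cohort`.
#' @param schema A `survrule_schema`. Default [default_schema()].
#' @param min_support,min_confidence Mining thresholds. Defaults 0.05 and
#'   0.10 — permissive enough to admit low-support single-item rules of the
#'   kind clinical reports list.
#' @param max_len Maximum antecedent size. Default 1.
#' @param k Report rows per consequent. Default 10.
#' @param alpha Significance level. Default 0.05.
#' @param filter Apply redundancy filtering. Default `TRUE`.
#' @return A list with `transactions`, `itemsets`, `rules` (filtered, with
#'   significance columns) and `ranked`.
#' @export
mine_survivability_rules <- function(cohort, schema = default_schema(),
                                     min_support = 0.05,
                                     min_confidence = 0.10,
                                     max_len = 1L, k = 10L, alpha = 0.05,
                                     filter = TRUE) {
  transactions <- encode_transactions(cohort, schema)
  itemsets <- mine_frequent_itemsets(transactions, min_support, max_len)
  rules <- generate_rules(itemsets, transactions,
                          min_confidence = min_confidence)
  rules <- filter_redundant(rules, enabled = filter)
  rules <- significance_flag(rules, alpha = alpha)
  list(transactions = transactions, itemsets = itemsets, rules = rules,
       ranked = rank_rules(rules, k = k))
}
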