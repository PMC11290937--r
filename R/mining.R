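# Frequent-itemset mining (level-wise Apriori) and association-rule scoring
# from 2x2 contingency tables: support, confidence, lift, cosine, the phi
# correlation coefficient, the Pearson chi-square statistic, and the odds
# ratio with a Woolf confidence interval.

#' Mine frequent itemsets with Apriori
#'
#' Level-wise candidate generation with the anti-monotone support bound:
#' every subset of a frequent itemset is itself frequent, so size-k
#' candidates are joins of size-(k-1) frequent itemsets and are pruned when
#' any (k-1)-subset is infrequent. Returns exactly the itemsets of size
#' `<= max_len` whose relative support reaches `min_support`.
#'
#' @param transactions A `survrule_transactions`.
#' @param min_support Minimum relative support in `[0, 1]`. Default 0.05.
#' @param max_len Maximum itemset size. Default 1 (single-item antecedents,
#'   the reporting convention for clinical rule tables); raise for
#'   multi-item antecedents.
#' @return data.frame with list-column `items` (canonical item strings,
#'   catalog order), `size`, `support_count` and `support`; ordered by size,
#'   then catalog order.
#' @export
mine_frequent_itemsets <- function(transactions, min_support = 0.05,
                                   max_len = 1L) {
  stopifnot(inherits(transactions, "survrule_transactions"))
  if (min_support < 0 || min_support > 1) {
    stop("'min_support' must be in [0, 1]")
  }
  if (max_len < 1L) stop("'max_len' must be >= 1")
  inc <- transactions$incidence
  n <- transactions$n
  if (n == 0L) stop("empty transaction matrix")
  labels <- colnames(inc)
  m <- ncol(inc)

  qualifies <- function(count) count / n >= min_support
  # itemsets as sorted integer column-index vectors
  counts1 <- colSums(inc)
  frequent <- list()
  level <- lapply(which(qualifies(counts1)), identity)
  level_counts <- counts1[qualifies(counts1)]
  k <- 1L
  while (length(level) > 0L) {
    frequent[[k]] <- list(sets = level, counts = as.numeric(level_counts))
    if (k >= max_len) break
    # join step: pairs sharing the first k-1 items
    keys <- vapply(level, function(s) paste(s[-k], collapse = ","), "")
    cand <- list()
    for (key in unique(keys)) {
      grp <- level[keys == key]
      lasts <- sort(unique(vapply(grp, function(s) s[k], 0L)))
      if (length(lasts) < 2L) next
      prefix <- grp[[1L]][-k]
      pairs <- utils::combn(lasts, 2L)
      for (j in seq_len(ncol(pairs))) {
        cand[[length(cand) + 1L]] <- c(prefix, pairs[1L, j], pairs[2L, j])
      }
    }
    if (!length(cand)) break
    # prune step: all k-subsets must be frequent
    have <- new.env(hash = TRUE)
    for (s in level) assign(paste(s, collapse = ","), TRUE, envir = have)
    keep <- vapply(cand, function(s) {
      all(vapply(seq_along(s), function(i) {
        exists(paste(s[-i], collapse = ","), envir = have, inherits = FALSE)
      }, TRUE))
    }, TRUE)
    cand <- cand[keep]
    if (!length(cand)) break
    cnt <- vapply(cand, function(s) {
      sum(rowSums(inc[, s, drop = FALSE]) == length(s))
    }, 0)
    ok <- qualifies(cnt)
    level <- cand[ok]
    level_counts <- cnt[ok]
    k <- k + 1L
  }
  sets <- unlist(lapply(frequent, `[[`, "sets"), recursive = FALSE)
  cnts <- unlist(lapply(frequent, `[[`, "counts"))
  if (is.null(sets)) sets <- list()
  data.frame(
    items = I(lapply(sets, function(s) labels[s])),
    size = vapply(sets, length, 0L),
    support_count = as.integer(cnts %||% integer()),
    support = as.numeric(cnts %||% numeric()) / n,
    stringsAsFactors = FALSE
  )
}

#' 2x2 contingency table of an antecedent/consequent pair
#'
#' Exact row scan of the transaction matrix: `n11` patients with both the
#' full antecedent itemset A and item B, `n10` with A only, `n01` with B
#' only, `n00` with neither. Marginals |A|, |B| and the co-occurrence count
#' follow by construction.
#'
#' @param transactions A `survrule_transactions`.
#' @param antecedent Character vector of canonical item strings (itemset A).
#' @param consequent Single canonical item string (item B).
#' @return A `survrule_contingency` list: `n11`, `n10`, `n01`, `n00`, `n`,
#'   `n_a` (|A|), `n_b` (|B|).
#' @export
contingency <- function(transactions, antecedent, consequent) {
  stopifnot(inherits(transactions, "survrule_transactions"),
            length(consequent) == 1L, length(antecedent) >= 1L)
  inc <- transactions$incidence
  unknown <- setdiff(c(antecedent, consequent), colnames(inc))
  if (length(unknown)) {
    stop("unknown item(s): ", paste(unknown, collapse = ", "))
  }
  a <- rowSums(inc[, antecedent, drop = FALSE]) == length(antecedent)
  b <- inc[, consequent]
  n11 <- sum(a & b); n10 <- sum(a & !b); n01 <- sum(!a & b)
  structure(list(n11 = n11, n10 = n10, n01 = n01,
                 n00 = transactions$n - n11 - n10 - n01,
                 n = transactions$n, n_a = n11 + n10, n_b = n11 + n01),
            class = "survrule_contingency")
}

#' Build a contingency table from raw cell counts
#'
#' @param n11,n10,n01,n00 Nonnegative cell counts: both, antecedent only,
#'   consequent only, neither.
#' @return A `survrule_contingency`.
#' @export
contingency_from_counts <- function(n11, n10, n01, n00) {
  cells <- c(n11, n10, n01, n00)
  if (any(cells < 0) || anyNA(cells)) stop("cell counts must be nonnegative")
  n <- sum(cells)
  if (n < 1) stop("empty contingency table")
  structure(list(n11 = n11, n10 = n10, n01 = n01, n00 = n00, n = n,
                 n_a = n11 + n10, n_b = n11 + n01),
            class = "survrule_contingency")
}

#' Score a rule from its 2x2 contingency table
#'
#' Computes the rule-interestingness suite:
#' \describe{
#'   \item{support}{n11 / N — joint frequency of antecedent and consequent.}
#'   \item{confidence}{n11 / |A| — conditional frequency of the consequent
#'     given the antecedent (requires |A| >= 1).}
#'   \item{lift}{N * n11 / (|A| * |B|) — observed over expected support
#'     under independence; 1 means independent. Reported as 0 when
#'     n11 = 0.}
#'   \item{cosine}{n11 / sqrt(|A| * |B|) — null-invariant geometric-mean
#'     normalisation, equal to sqrt(conf(A->B) * conf(B->A)).}
#'   \item{correlation}{the phi coefficient
#'     (N*n11 - |A|*|B|) / sqrt(|A|*|B|*(N-|A|)*(N-|B|)); `NA` when either
#'     margin is degenerate (|A| or |B| equal to 0 or N).}
#'   \item{chi_square}{Pearson statistic of the 2x2 table, no continuity
#'     correction, so the identity chi_square = N * correlation^2 holds.}
#'   \item{odds_ratio}{(n11*n00) / (n10*n01), with the Haldane-Anscombe
#'     +0.5 added to all four cells when any cell is zero; 95% CI by Woolf's
#'     log method, exp(log OR +/- 1.96 * sqrt(sum of reciprocal cells)).}
#' }
#'
#' @param ct A `survrule_contingency`.
#' @return Named list of class `survrule_metrics`.
#' @export
compute_metrics <- function(ct) {
  stopifnot(inherits(ct, "survrule_contingency"))
  n11 <- ct$n11; n10 <- ct$n10; n01 <- ct$n01; n00 <- ct$n00
  n <- ct$n; na <- ct$n_a; nb <- ct$n_b
  if (n < 1) stop("empty contingency table")
  if (na < 1) stop("antecedent support is zero: confidence undefined")
  support <- n11 / n
  confidence <- n11 / na
  lift <- if (n11 == 0) 0 else n * n11 / (na * nb)
  cosine <- if (n11 == 0) 0 else n11 / sqrt(na * nb)
  denom <- as.numeric(na) * nb * (n - na) * (n - nb)
  if (denom > 0) {
    correlation <- (n * n11 - as.numeric(na) * nb) / sqrt(denom)
    chi_square <- n * correlation^2
  } else {
    correlation <- NA_real_   # degenerate margin: phi undefined, flagged
    chi_square <- NA_real_
  }
  cells <- c(n11, n10, n01, n00)
  if (any(cells == 0)) cells <- cells + 0.5
  odds_ratio <- (cells[1L] * cells[4L]) / (cells[2L] * cells[3L])
  se <- sqrt(sum(1 / cells))
  structure(list(
    support = support, confidence = confidence, lift = lift,
    cosine = cosine, correlation = correlation, chi_square = chi_square,
    odds_ratio = odds_ratio,
    or_ci_low = exp(log(odds_ratio) - 1.96 * se),
    or_ci_high = exp(log(odds_ratio) + 1.96 * se)
  ), class = "survrule_metrics")
}

#' Generate scored survivability rules from frequent itemsets
#'
#' Pairs every frequent itemset free of outcome items (the antecedent) with
#' each requested outcome consequent, scores the pair from its contingency
#' table, and keeps rules whose confidence reaches `min_confidence`.
#'
#' @param itemsets Output of [mine_frequent_itemsets()].
#' @param transactions The `survrule_transactions` the itemsets were mined
#'   from.
#' @param consequents Character vector of outcome item strings; must be a
#'   non-empty subset of [outcome_items()]. Default both outcomes.
#' @param min_confidence Minimum confidence in `[0, 1]`. Default 0.10.
#' @return A `survrule_rules` data.frame: `antecedent` (list-column),
#'   `antecedent_str` (items joined by `" & "`), `consequent`, and the
#'   metric columns of [compute_metrics()].
#' @export
generate_rules <- function(itemsets, transactions,
                           consequents = outcome_items(),
                           min_confidence = 0.10) {
  stopifnot(inherits(transactions, "survrule_transactions"))
  consequents <- unname(consequents)
  if (length(consequents) == 0L) stop("empty consequent set")
  if (!all(consequents %in% outcome_items())) {
    stop("consequents must be outcome items")
  }
  if (min_confidence < 0 || min_confidence > 1) {
    stop("'min_confidence' must be in [0, 1]")
  }
  out_set <- outcome_items()
  ante <- itemsets[vapply(itemsets$items,
                          function(s) !any(s %in% out_set), TRUE), ,
                   drop = FALSE]
  ante_items <- list(); cons <- character(); mets <- list()
  for (i in seq_len(nrow(ante))) {
    a <- ante$items[[i]]
    if (ante$support_count[i] == 0L) next  # confidence undefined
    for (b in consequents) {
      m <- compute_metrics(contingency(transactions, a, b))
      if (m$confidence >= min_confidence) {
        k <- length(cons) + 1L
        ante_items[[k]] <- a
        cons[k] <- b
        mets[[k]] <- unlist(unclass(m))
      }
    }
  }
  if (!length(cons)) return(empty_rules())
  df <- data.frame(
    antecedent_str = vapply(ante_items, paste, "", collapse = " & "),
    consequent = cons, stringsAsFactors = FALSE)
  met <- do.call(rbind, mets)
  for (nm in metric_columns()) df[[nm]] <- unname(met[, nm])
  df$antecedent <- I(ante_items)
  df <- df[, c("antecedent", "antecedent_str", "consequent",
               metric_columns())]
  rownames(df) <- NULL
  class(df) <- c("survrule_rules", "data.frame")
  df
}

metric_columns <- function() {
  c("support", "confidence", "lift", "cosine", "correlation",
    "chi_square", "odds_ratio", "or_ci_low", "or_ci_high")
}

empty_rules <- function() {
  df <- data.frame(antecedent_str = character(), consequent = character(),
                   stringsAsFactors = FALSE)
  for (nm in metric_columns()) df[[nm]] <- numeric()
  df$antecedent <- I(list())
  df <- df[, c("antecedent", "antecedent_str", "consequent",
               metric_columns())]
  class(df) <- c("survrule_rules", "data.frame")
  df
}

#' Write rules as JSON lines
#'
#' One JSON object per line: antecedent items, consequent and the full
#' metric vector.
#'
#' @param rules A `survrule_rules` data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rules_jsonl <- function(rules, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(rules))) {
    rec <- c(list(antecedent = rules$antecedent[[i]],
                  consequent = rules$consequent[i]),
             as.list(rules[i, metric_columns()]))
    writeLines(as.character(
      jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null")),
      con)
  }
  invisible(path)
}
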