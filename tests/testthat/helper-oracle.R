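# Independent oracles, deliberately built on different primitives than the
# package: exhaustive subset enumeration for frequent itemsets, and base-R
# stats (chisq.test, cor, inner products on raw 0/1 vectors) for the rule
# measures.

# All itemsets (as column-index vectors) of size <= max_len whose relative
# support reaches min_support, by enumerating every subset.
oracle_frequent <- function(inc, min_support, max_len) {
  m <- ncol(inc)
  n <- nrow(inc)
  out <- list()
  for (k in seq_len(min(max_len, m))) {
    subsets <- utils::combn(m, k, simplify = FALSE)
    for (s in subsets) {
      cnt <- sum(rowSums(inc[, s, drop = FALSE]) == k)
      if (cnt / n >= min_support) {
        out[[length(out) + 1L]] <- list(set = s, count = cnt)
      }
    }
  }
  out
}

# Rule measures computed from the raw indicator vectors.
oracle_metrics <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a)
  tab <- table(factor(a, levels = c(1, 0)), factor(b, levels = c(1, 0)))
  phi <- suppressWarnings(stats::cor(a, b))
  chi <- tryCatch(
    unname(suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$statistic)),
    error = function(e) NA_real_)
  list(
    support = mean(a * b),
    confidence = sum(a * b) / sum(a),
    lift = if (sum(a * b) == 0) 0 else mean(a * b) / (mean(a) * mean(b)),
    cosine = if (sum(a * b) == 0) 0 else
      sum(a * b) / (sqrt(sum(a)) * sqrt(sum(b))),
    correlation = phi,
    chi_square = chi
  )
}

# Random 2x2 table with all-positive margins (so every measure is defined).
random_contingency <- function() {
  repeat {
    cells <- stats::rmultinom(1, size = sample(20:400, 1),
                              prob = stats::runif(4, 0.05, 1))[, 1]
    ct <- list(n11 = cells[1], n10 = cells[2], n01 = cells[3],
               n00 = cells[4])
    na <- ct$n11 + ct$n10; nb <- ct$n11 + ct$n01; n <- sum(cells)
    if (na > 0 && nb > 0 && na < n && nb < n) return(ct)
  }
}

# Random small transaction matrix wrapped as survrule_transactions, with the
# two outcome items in the last two (mutually exclusive) columns.
random_transactions <- function(n_rows, n_attr_items) {
  inc <- matrix(stats::runif(n_rows * n_attr_items) < 0.4,
                nrow = n_rows)
  death <- stats::runif(n_rows) < 0.6
  inc <- cbind(inc, death, !death)
  labs <- c(paste0("attr", seq_len(n_attr_items), ": yes"),
            unname(survrule::outcome_items()))
  colnames(inc) <- labs
  structure(list(
    incidence = inc,
    items = data.frame(attribute = c(paste0("attr",
                                            seq_len(n_attr_items)),
                                     "outcome", "outcome"),
                       category = c(rep("yes", n_attr_items),
                                    "Death within 5 years",
                                    "Survive more than 5 years"),
                       label = labs,
                       outcome = c(rep(FALSE, n_attr_items), TRUE, TRUE),
                       stringsAsFactors = FALSE),
    n = n_rows), class = "survrule_transactions")
}
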