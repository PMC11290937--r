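# Patient records: CSV I/O, validation, numeric binning, outcome
# derivation and transaction encoding.

#' Assemble and validate a cohort
#'
#' A cohort is a data.frame with one character column per schema attribute,
#' an integer `survival_months` column (>= 1) and a logical
#' `dead_within_followup` column. If `dead_within_followup` is absent it is
#' derived from `survival_months <= outcome_cutoff_months` (complete
#' follow-up, the reference cohort's situation).
#'
#' @param df A data.frame of raw records.
#' @param schema A `survrule_schema`.
#' @return The validated cohort with class `survrule_cohort`.
#' @export
as_cohort <- function(df, schema) {
  stopifnot(inherits(schema, "survrule_schema"), is.data.frame(df))
  df <- bin_numeric_attributes(df, schema)
  need <- schema_attribute_names(schema)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing attribute column(s): ", paste(miss, collapse = ", "))
  }
  if (!"survival_months" %in% names(df)) {
    stop("missing 'survival_months' column")
  }
  if (nrow(df) > 0L) {
    sm <- suppressWarnings(as.integer(df$survival_months))
    bad <- which(is.na(sm) | sm < 1L)
    if (length(bad)) {
      stop("row ", bad[1L], ": survival_months must be a positive integer, ",
           "got '", df$survival_months[bad[1L]], "'")
    }
    df$survival_months <- sm
    for (nm in need) {
      v <- as.character(df[[nm]])
      ok <- v %in% schema$attributes[[nm]]$categories
      if (!all(ok)) {
        i <- which(!ok)[1L]
        stop("row ", i, ", attribute '", nm, "': unknown category '",
             v[i], "' (allowed: ",
             paste(schema$attributes[[nm]]$categories, collapse = ", "), ")")
      }
      df[[nm]] <- v
    }
    if ("dead_within_followup" %in% names(df)) {
      d <- df$dead_within_followup
      if (is.character(d)) d <- toupper(d) %in% c("TRUE", "T", "1", "YES")
      df$dead_within_followup <- as.logical(d)
    } else {
      df$dead_within_followup <- df$survival_months <= schema$outcome_cutoff_months
    }
  } else {
    df$survival_months <- integer()
    df$dead_within_followup <- logical()
  }
  df <- df[, c(need, "survival_months", "dead_within_followup"), drop = FALSE]
  class(df) <- c("survrule_cohort", "data.frame")
  attr(df, "schema") <- schema
  df
}

bin_numeric_attributes <- function(df, schema) {
  for (nm in names(schema$numeric_bins)) {
    b <- schema$numeric_bins[[nm]]
    if (nm %in% names(df)) next           # already categorical
    if (!b$source %in% names(df)) next    # neither form present: caught later
    x <- suppressWarnings(as.numeric(df[[b$source]]))
    if (nrow(df) > 0L && anyNA(x)) {
      stop("non-numeric value in column '", b$source, "' (row ",
           which(is.na(x))[1L], ")")
    }
    lab <- cut(x, breaks = b$edges, labels = b$labels, right = FALSE)
    if (nrow(df) > 0L && anyNA(lab)) {
      stop("value in '", b$source, "' falls outside the bin edges (row ",
           which(is.na(lab))[1L], ")")
    }
    df[[nm]] <- as.character(lab)
    df[[b$source]] <- NULL
  }
  df
}

#' Load a cohort CSV
#'
#' Reads a comma-separated UTF-8 table with a header row, one patient per
#' row, discretises any numeric source columns declared in the schema's
#' `numeric_bins` and validates every value against the schema. A header-only
#' file yields an empty cohort, not an error.
#'
#' @param path CSV file path.
#' @param schema A `survrule_schema`.
#' @return A `survrule_cohort` data.frame.
#' @export
load_cohort <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  as_cohort(df, schema)
}

#' Write a cohort CSV
#'
#' @param cohort A `survrule_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Derive the survivability consequent
#'
#' Maps survival length to one of the two outcome items: survival strictly
#' beyond the cutoff (default 60 months) is long-term survival; anything at
#' or below it — the 49-60-month bin included — is death within five years.
#'
#' @param cohort A `survrule_cohort`, or an integer vector of survival
#'   months.
#' @param schema A `survrule_schema` (supplies the cutoff).
#' @return Character vector of canonical outcome item strings, one per
#'   record.
#' @export
derive_outcome <- function(cohort, schema) {
  months <- if (is.data.frame(cohort)) cohort$survival_months else cohort
  months <- as.integer(months)
  if (anyNA(months) || any(months < 1L)) {
    stop("survival months must be positive integers")
  }
  oi <- outcome_items()
  unname(ifelse(months > schema$outcome_cutoff_months,
                oi[["survive"]], oi[["death"]]))
}

#' Encode a cohort as a binary transaction matrix
#'
#' Every patient becomes one transaction holding exactly one item per schema
#' attribute (the `N/A` category is an ordinary item) plus exactly one
#' outcome item, over the deterministic catalog of [item_catalog()].
#'
#' @param cohort A validated `survrule_cohort`.
#' @param schema A `survrule_schema`.
#' @return A `survrule_transactions` object: list with `incidence` (logical
#'   N x M matrix, columns named by canonical item strings), `items` (the
#'   catalog data.frame) and `n` (number of patients).
#' @export
encode_transactions <- function(cohort, schema) {
  stopifnot(inherits(schema, "survrule_schema"))
  if (!inherits(cohort, "survrule_cohort")) cohort <- as_cohort(cohort, schema)
  catalog <- item_catalog(schema)
  n <- nrow(cohort)
  inc <- matrix(FALSE, nrow = n, ncol = nrow(catalog),
                dimnames = list(NULL, catalog$label))
  for (nm in schema_attribute_names(schema)) {
    lab <- paste0(schema_label(schema, nm), ": ", cohort[[nm]])
    inc[cbind(seq_len(n), match(lab, catalog$label))] <- TRUE
  }
  if (n > 0L) {
    out <- derive_outcome(cohort, schema)
    inc[cbind(seq_len(n), match(out, catalog$label))] <- TRUE
  }
  structure(list(incidence = inc, items = catalog, n = n),
            class = "survrule_transactions")
}

#' @export
print.survrule_transactions <- function(x, ...) {
  cat("survrule transactions:", x$n, "patients x", nrow(x$items), "items\n")
  invisible(x)
}

#' Item support counts of a transaction matrix
#'
#' @param transactions A `survrule_transactions`.
#' @return Named integer vector of per-item support counts.
#' @export
item_supports <- function(transactions) {
  colSums(transactions$incidence)
}

#' Write transactions as canonical item lines
#'
#' One line per patient, canonical item strings joined by `"; "` — the
#' interchange format generic itemset miners can ingest.
#'
#' @param transactions A `survrule_transactions`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transactions <- function(transactions, path) {
  lines <- apply(transactions$incidence, 1L, function(r) {
    paste(transactions$items$label[r], collapse = "; ")
  })
  writeLines(as.character(lines), path, useBytes = TRUE)
  invisible(path)
}
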