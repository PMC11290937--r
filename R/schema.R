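# Attribute schema: the contract between raw patient records and the
# categorical items that association-rule mining consumes.

#' Construct an attribute schema
#'
#' The schema declares, in order, every categorical attribute a patient
#' record must carry, the category labels each attribute allows, which
#' attributes may take the non-available (`N/A`) label, how numeric source
#' columns are discretised into categories, and the follow-up cutoff (in
#' months) that dichotomises five-year survivability.
#'
#' @param attributes Named list. Each element describes one attribute and is
#'   itself a list with elements `label` (display name used in canonical item
#'   strings, e.g. `"Surgical margin"`) and `categories` (character vector of
#'   allowed labels, in reporting order).
#' @param na_label Single string used for non-available pathology data.
#'   Default `"N/A"`.
#' @param na_attributes Character vector of attribute names for which
#'   `na_label` is a legal category. `na_label` must appear in the category
#'   list of exactly these attributes.
#' @param numeric_bins Named list keyed by attribute name. Each element is a
#'   list with `source` (name of the numeric input column), `edges` (strictly
#'   increasing numeric cut points, outer edges may be infinite) and `labels`
#'   (one label per bin, `length(edges) - 1` of them; these must equal the
#'   attribute's categories).
#' @param outcome_cutoff_months Integer cutoff dividing death within the
#'   follow-up window from long-term survival. Default 60 (five years).
#'
#' @return An object of class `survrule_schema`.
#' @seealso [default_schema()] for the shipped oral-cancer schema,
#'   [read_schema()]/[write_schema()] for JSON (de)serialisation.
#' @export
attribute_schema <- function(attributes, na_label = "N/A",
                             na_attributes = character(),
                             numeric_bins = list(),
                             outcome_cutoff_months = 60L) {
  if (!is.list(attributes) || length(attributes) == 0L ||
      is.null(names(attributes)) || anyNA(names(attributes)) ||
      any(names(attributes) == "")) {
    stop("'attributes' must be a non-empty named list")
  }
  if (anyDuplicated(names(attributes))) {
    stop("attribute names must be unique across the schema")
  }
  for (nm in names(attributes)) {
    a <- attributes[[nm]]
    if (is.null(a$label) || !is.character(a$label) || length(a$label) != 1L) {
      stop("attribute '", nm, "' must have a single character 'label'")
    }
    if (is.null(a$categories) || !is.character(a$categories) ||
        length(a$categories) == 0L) {
      stop("attribute '", nm, "' must declare at least one category")
    }
    if (anyDuplicated(a$categories)) {
      stop("duplicate category labels in attribute '", nm, "'")
    }
  }
  labels <- vapply(attributes, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("attribute display labels must be unique")
  if (!is.character(na_label) || length(na_label) != 1L || !nzchar(na_label)) {
    stop("'na_label' must be a single non-empty string")
  }
  bad <- setdiff(na_attributes, names(attributes))
  if (length(bad)) stop("unknown na_attributes: ", paste(bad, collapse = ", "))
  # na_label legal for exactly the attributes that declare it
  for (nm in names(attributes)) {
    has_na <- na_label %in% attributes[[nm]]$categories
    if (has_na && !(nm %in% na_attributes)) {
      stop("attribute '", nm, "' lists '", na_label,
           "' but is not in na_attributes")
    }
    if (!has_na && nm %in% na_attributes) {
      stop("attribute '", nm, "' is in na_attributes but lacks category '",
           na_label, "'")
    }
  }
  for (nm in names(numeric_bins)) {
    b <- numeric_bins[[nm]]
    if (!nm %in% names(attributes)) {
      stop("numeric_bins entry '", nm, "' is not a schema attribute")
    }
    if (is.null(b$source) || is.null(b$edges) || is.null(b$labels)) {
      stop("numeric_bins entry '", nm,
           "' needs 'source', 'edges' and 'labels'")
    }
    if (length(b$edges) < 2L || any(diff(b$edges) <= 0)) {
      stop("bin edges for '", nm, "' must be strictly increasing (>= 1 bin)")
    }
    if (length(b$labels) != length(b$edges) - 1L) {
      stop("'", nm, "': need one label per bin")
    }
    if (!identical(as.character(b$labels), attributes[[nm]]$categories)) {
      stop("'", nm, "': bin labels must equal the attribute's categories")
    }
  }
  outcome_cutoff_months <- as.integer(outcome_cutoff_months)
  if (is.na(outcome_cutoff_months) || outcome_cutoff_months < 1L) {
    stop("'outcome_cutoff_months' must be a positive integer")
  }
  structure(
    list(attributes = attributes, na_label = na_label,
         na_attributes = na_attributes, numeric_bins = numeric_bins,
         outcome_cutoff_months = outcome_cutoff_months),
    class = "survrule_schema"
  )
}

#' @export
print.survrule_schema <- function(x, ...) {
  cat("survrule schema:", length(x$attributes), "attributes,",
      "outcome cutoff", x$outcome_cutoff_months, "months\n")
  for (nm in names(x$attributes)) {
    a <- x$attributes[[nm]]
    cat("  ", a$label, " [", nm, "]: ",
        paste(a$categories, collapse = " | "), "\n", sep = "")
  }
  invisible(x)
}

schema_attribute_names <- function(schema) names(schema$attributes)

schema_label <- function(schema, name) schema$attributes[[name]]$label

#' Canonical item string
#'
#' Items are attribute--value pairs written `"<attribute label>: <category>"`,
#' e.g. `"Extranodal extension: positive"`. The canonical form round-trips
#' through [parse_item()].
#'
#' @param attribute Attribute name (schema key).
#' @param category Category label.
#' @param schema A `survrule_schema`.
#' @return Single canonical item string.
#' @export
item_string <- function(attribute, category, schema) {
  if (!attribute %in% names(schema$attributes)) {
    stop("unknown attribute: ", attribute)
  }
  if (!category %in% schema$attributes[[attribute]]$categories) {
    stop("'", category, "' is not a category of attribute '", attribute, "'")
  }
  paste0(schema_label(schema, attribute), ": ", category)
}

#' Parse a canonical item string
#'
#' @param x Canonical item string (`"label: category"`).
#' @param schema A `survrule_schema`.
#' @return A list with elements `attribute` (schema key) and `category`.
#'   Outcome items parse with `attribute = "outcome"`.
#' @export
parse_item <- function(x, schema) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- regexpr(": ", x, fixed = TRUE)
  if (m < 0L) stop("not a canonical item string: ", x)
  lab <- substr(x, 1L, m - 1L)
  cat <- substr(x, m + 2L, nchar(x))
  if (lab == outcome_attribute_label()) {
    if (!cat %in% outcome_categories()) stop("unknown outcome category: ", cat)
    return(list(attribute = "outcome", category = cat))
  }
  labels <- vapply(schema$attributes, `[[`, character(1), "label")
  nm <- names(labels)[match(lab, labels)]
  if (is.na(nm)) stop("unknown attribute label: ", lab)
  if (!cat %in% schema$attributes[[nm]]$categories) {
    stop("'", cat, "' is not a category of attribute '", nm, "'")
  }
  list(attribute = nm, category = cat)
}

# -- outcome items ----------------------------------------------------------

outcome_attribute_label <- function() "5-year survivability"

outcome_categories <- function() {
  c(death = "Death within 5 years", survive = "Survive more than 5 years")
}

#' Outcome item strings
#'
#' The two consequents of every mined rule: death within the follow-up
#' cutoff, and survival beyond it.
#'
#' @return Named character vector with elements `death` and `survive`.
#' @export
outcome_items <- function() {
  stats::setNames(
    paste0(outcome_attribute_label(), ": ", outcome_categories()),
    names(outcome_categories())
  )
}

#' Item catalog of a schema
#'
#' Every legal item in deterministic order: schema attribute order, then the
#' attribute's category order, then the two outcome items.
#'
#' @param schema A `survrule_schema`.
#' @return A data.frame with columns `attribute`, `category`, `label`
#'   (canonical string) and `outcome` (logical).
#' @export
item_catalog <- function(schema) {
  rows <- lapply(names(schema$attributes), function(nm) {
    a <- schema$attributes[[nm]]
    data.frame(attribute = nm, category = a$categories,
               label = paste0(a$label, ": ", a$categories),
               outcome = FALSE, stringsAsFactors = FALSE)
  })
  out <- data.frame(attribute = "outcome",
                    category = unname(outcome_categories()),
                    label = unname(outcome_items()),
                    outcome = TRUE, stringsAsFactors = FALSE)
  res <- do.call(rbind, c(rows, list(out)))
  rownames(res) <- NULL
  res
}

# -- JSON (de)serialisation -------------------------------------------------

#' Write a schema to a JSON config file
#'
#' @param schema A `survrule_schema`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  jsonlite::write_json(unclass(schema), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a schema from a JSON config file
#'
#' @param path Path to a JSON file written by [write_schema()] (or
#'   hand-authored with the same shape).
#' @return A validated `survrule_schema`.
#' @export
read_schema <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  attrs <- lapply(x$attributes, function(a) {
    list(label = a$label, categories = as.character(a$categories))
  })
  bins <- lapply(x$numeric_bins, function(b) {
    list(source = b$source, edges = as.numeric(b$edges),
         labels = as.character(b$labels))
  })
  attribute_schema(attrs, na_label = x$na_label,
                   na_attributes = as.character(x$na_attributes %||% character()),
                   numeric_bins = bins,
                   outcome_cutoff_months = x$outcome_cutoff_months)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
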