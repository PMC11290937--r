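# Seedable synthetic cohorts: independent categorical attributes drawn from
# stated marginals, plantable antecedent->death associations of known
# confidence, and exponential survival-time generation for the
# Kaplan-Meier path.

#' Per-attribute marginal distributions
#'
#' @param schema A `survrule_schema`.
#' @param probs Named list keyed by attribute name; each element a numeric
#'   probability vector over that attribute's categories (named vectors are
#'   checked against the category labels), summing to 1 within 1e-9.
#' @return A `survrule_marginals` object.
#' @export
marginal_spec <- function(schema, probs) {
  stopifnot(inherits(schema, "survrule_schema"), is.list(probs))
  need <- schema_attribute_names(schema)
  miss <- setdiff(need, names(probs))
  if (length(miss)) {
    stop("marginals missing for attribute(s): ", paste(miss, collapse = ", "))
  }
  out <- list()
  for (nm in need) {
    p <- probs[[nm]]
    cats <- schema$attributes[[nm]]$categories
    if (!is.numeric(p) || length(p) != length(cats)) {
      stop("marginal for '", nm, "' must have ", length(cats),
           " probabilities")
    }
    if (!is.null(names(p)) && !identical(names(p), cats)) {
      stop("marginal names for '", nm,
           "' do not match the schema's categories")
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("marginal for '", nm, "' must be nonnegative and sum to 1")
    }
    out[[nm]] <- stats::setNames(as.numeric(p), cats)
  }
  structure(out, class = "survrule_marginals")
}

#' Declare a planted antecedent-to-death association
#'
#' A planted rule forces the probability of death within the follow-up
#' cutoff to `confidence` for every patient carrying the antecedent item, so
#' downstream mining should recover a rule of approximately that confidence.
#'
#' @param attribute Attribute name (schema key) of the antecedent item.
#' @param category Category label of the antecedent item.
#' @param confidence Target probability in `[0, 1]` of death within the
#'   cutoff given the antecedent.
#' @return A `survrule_planted` object.
#' @export
planted_rule <- function(attribute, category, confidence) {
  stopifnot(is.character(attribute), length(attribute) == 1L,
            is.character(category), length(category) == 1L)
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      confidence < 0 || confidence > 1) {
    stop("'confidence' must be a probability in [0, 1]")
  }
  structure(list(attribute = attribute, category = category,
                 confidence = confidence),
            class = "survrule_planted")
}

# Runs expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Generate a synthetic cohort
#'
#' Attributes are drawn independently from `marginals`. Each patient's
#' probability of dying within the outcome cutoff is the confidence of the
#' first planted rule whose antecedent the patient carries, otherwise
#' `baseline_death_prob`. Survival months are drawn uniformly over
#' 1..cutoff for deaths and cutoff+1..2*cutoff for survivors, so that death
#' and the grouped outcome dichotomy coincide by construction. Identical
#' arguments and seed give identical cohorts.
#'
#' @param schema A `survrule_schema`. Default [default_schema()].
#' @param marginals A `survrule_marginals`. Default [default_marginals()].
#' @param planted List of [planted_rule()] objects referencing distinct
#'   attributes. Default none.
#' @param baseline_death_prob Death probability for patients matching no
#'   planted rule. Default [reference_death_rate()] (582/897).
#' @param n Number of patients (>= 1).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `survrule_cohort` with a `config` attribute recording every
#'   generator parameter (seed included) for provenance.
#' @export
generate_cohort <- function(schema = default_schema(),
                            marginals = default_marginals(schema),
                            planted = list(),
                            baseline_death_prob = reference_death_rate(),
                            n, seed = NULL) {
  stopifnot(inherits(schema, "survrule_schema"))
  if (!inherits(marginals, "survrule_marginals")) {
    marginals <- marginal_spec(schema, marginals)
  }
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("'n' must be >= 1")
  }
  n <- as.integer(n)
  if (baseline_death_prob < 0 || baseline_death_prob > 1) {
    stop("'baseline_death_prob' must be a probability")
  }
  if (inherits(planted, "survrule_planted")) planted <- list(planted)
  for (p in planted) {
    if (!inherits(p, "survrule_planted")) stop("'planted' must hold planted_rule objects")
    item_string(p$attribute, p$category, schema)  # validates the antecedent
  }
  p_attrs <- vapply(planted, `[[`, character(1), "attribute")
  if (anyDuplicated(p_attrs)) {
    stop("planted antecedents must reference distinct attributes")
  }
  cutoff <- schema$outcome_cutoff_months
  df <- with_seed(seed, {
    cols <- lapply(schema_attribute_names(schema), function(nm) {
      p <- marginals[[nm]]
      sample(names(p), n, replace = TRUE, prob = p)
    })
    names(cols) <- schema_attribute_names(schema)
    df <- as.data.frame(cols, stringsAsFactors = FALSE,
                        check.names = FALSE)
    death_p <- rep(baseline_death_prob, n)
    for (p in rev(planted)) {    # earlier rules take priority: applied last
      hit <- df[[p$attribute]] == p$category
      death_p[hit] <- p$confidence
    }
    dead <- stats::runif(n) < death_p
    df$survival_months <- ifelse(
      dead,
      sample(seq_len(cutoff), n, replace = TRUE),
      sample(seq.int(cutoff + 1L, 2L * cutoff), n, replace = TRUE))
    df$dead_within_followup <- dead
    df
  })
  cohort <- as_cohort(df, schema)
  attr(cohort, "config") <- list(
    n = n, seed = seed, baseline_death_prob = baseline_death_prob,
    planted = lapply(planted, unclass),
    marginals = lapply(marginals, as.list),
    outcome_cutoff_months = cutoff)
  cohort
}

#' Write the generator provenance sidecar
#'
#' Serialises the `config` attribute a [generate_cohort()] call attaches —
#' sample size, seed, baseline death probability, planted rules and
#' marginals — as JSON next to the cohort it documents.
#'
#' @param cohort A cohort produced by [generate_cohort()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cohort_config <- function(cohort, path) {
  cfg <- attr(cohort, "config")
  if (is.null(cfg)) stop("cohort carries no generator config")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Generate censored exponential survival times
#'
#' Event times are exponential with the given monthly hazard; observations
#' still event-free at `censor_at_months` are right-censored there. With a
#' `group` vector, `hazard_per_month` must be a named vector of per-group
#' hazards. A zero hazard yields no events (all censored).
#'
#' @param n Number of subjects (ignored when `group` is given).
#' @param hazard_per_month Nonnegative rate, or named per-group rates.
#' @param censor_at_months Administrative censoring time. Default 60.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param group Optional vector assigning each subject to a hazard group.
#' @return data.frame with `time` (months, positive) and `event` (logical;
#'   `FALSE` means censored), plus the `group` column when given.
#' @export
generate_survival_times <- function(n, hazard_per_month,
                                    censor_at_months = 60,
                                    seed = NULL, group = NULL) {
  if (any(hazard_per_month < 0)) stop("hazard must be nonnegative")
  if (censor_at_months <= 0) stop("'censor_at_months' must be positive")
  if (!is.null(group)) {
    n <- length(group)
    if (is.null(names(hazard_per_month)) ||
        !all(unique(group) %in% names(hazard_per_month))) {
      stop("with 'group', 'hazard_per_month' must be named by group")
    }
    rate <- unname(hazard_per_month[as.character(group)])
  } else {
    stopifnot(length(hazard_per_month) == 1L)
    rate <- rep(hazard_per_month, n)
  }
  with_seed(seed, {
    t_event <- ifelse(rate > 0, stats::rexp(n, rate = pmax(rate, 1e-300)), Inf)
    event <- t_event <= censor_at_months
    out <- data.frame(time = pmin(t_event, censor_at_months), event = event)
    if (!is.null(group)) out$group <- group
    out
  })
}
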