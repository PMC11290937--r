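# Shipped defaults: a 16-attribute oral-cancer schema and the published
# marginal frequencies of the 897-patient reference cohort they summarise.

.default_attribute_counts <- function() {
  list(
    gender = list(
      label = "Gender",
      counts = c("Male" = 460, "Female" = 437)),
    age_range = list(
      label = "Age range",
      counts = NULL),  # filled from the normal age model below
    comorbidities = list(
      label = "Comorbidities",
      counts = c("None" = 565, "Diabetes mellitus" = 48,
                 "Hypertension" = 90, "Dyslipidemia" = 4,
                 "Heart disease" = 7, "Neurological disease" = 5,
                 "Kidney disease" = 9, "Multiple diseases" = 60,
                 "Others" = 2)),
    tumor_location = list(
      label = "Tumor location",
      counts = c("Oral tongue" = 405, "Floor of mouth" = 112,
                 "Buccal mucosa" = 108, "Alveolar ridge" = 120,
                 "Hard palate" = 37, "Lip" = 78,
                 "Retromolar trigone" = 33, "Uncertain site" = 4)),
    t_stage = list(
      label = "T stage",
      counts = c("T1" = 125, "T2" = 240, "T3" = 128, "T4a" = 370,
                 "T4b" = 34)),
    n_stage = list(
      label = "N stage",
      counts = c("N0" = 407, "N1" = 150, "N2a" = 70, "N2b" = 167,
                 "N2c" = 83, "N3" = 20)),
    tnm_stage = list(
      label = "TNM stage",
      counts = c("Stage I" = 91, "Stage II" = 135, "Stage III" = 135,
                 "Stage IVa" = 481, "Stage IVb" = 48, "Stage IVc" = 7)),
    tumor_types = list(
      label = "Tumor types",
      counts = c("SCC, WD" = 522, "SCC, MD" = 234, "SCC, PD" = 41,
                 "Undifferentiated CA" = 18, "Nonkeratinizing CA" = 9,
                 "Adenoid cystic CA" = 29, "Mucoepidermoid CA" = 18,
                 "Others" = 26)),
    lymph_node_metastasis = list(
      label = "Lymph node metastasis",
      counts = c("Negative" = 407, "Positive" = 490)),
    surgical_margin = list(
      label = "Surgical margin",
      counts = c("Negative" = 397, "Positive" = 133, "N/A" = 367)),
    extranodal_extension = list(
      label = "Extranodal extension",
      counts = c("Negative" = 473, "Positive" = 46, "N/A" = 378)),
    lymphovascular_invasion = list(
      label = "Lymphovascular invasion",
      counts = c("Negative" = 473, "Positive" = 93, "N/A" = 367)),
    perineural_invasion = list(
      label = "Perineural invasion",
      counts = c("Negative" = 437, "Positive" = 93, "N/A" = 367)),
    recurrence = list(
      label = "Recurrence",
      counts = c("No" = 705, "Local recurrence" = 81,
                 "Regional recurrence" = 49,
                 "Locoregional recurrence" = 62)),
    distant_metastasis = list(
      label = "Distant metastasis",
      counts = c("No" = 832, "Lung metastasis" = 49,
                 "Bone metastasis" = 11, "Brain metastasis" = 1,
                 "Other area metastasis" = 4)),
    treatment = list(
      label = "Treatment modalities",
      counts = c("Surgery only" = 149, "Surgery and radiotherapy" = 252,
                 "Surgery and concurrent chemoradiotherapy" = 129,
                 "Induction chemotherapy" = 57,
                 "Concurrent chemoradiotherapy" = 216,
                 "Palliative treatment" = 94))
  )
}

.default_age_bins <- function() {
  list(source = "age",
       edges = c(-Inf, 40, 50, 60, 70, 80, Inf),
       labels = c("<40", "40-49", "50-59", "60-69", "70-79", ">=80"))
}

# Bin masses of the reference cohort's age model (mean 64, SD 8.88 years)
# over the decade bins; used as the default age_range marginal.
.default_age_probs <- function(mean = 64, sd = 8.88) {
  b <- .default_age_bins()
  p <- diff(stats::pnorm(b$edges, mean = mean, sd = sd))
  stats::setNames(p / sum(p), b$labels)
}

#' Default oral-cancer attribute schema
#'
#' Sixteen categorical clinicopathologic and treatment attributes with the
#' category lists of the reference oral-cancer cohort: gender, age range
#' (decade bins over a numeric `age` column), comorbidities, tumor location,
#' clinical T stage, cervical N stage, TNM stage, tumor types, lymph node
#' metastasis, surgical margin, extranodal extension, lymphovascular
#' invasion, perineural invasion, recurrence, distant metastasis and
#' treatment modality. The four post-surgical pathology attributes (surgical
#' margin, extranodal extension, lymphovascular and perineural invasion)
#' admit the `N/A` category carried by non-surgical patients; `N/A` is a
#' first-class item, never imputed.
#'
#' @return A `survrule_schema`.
#' @export
default_schema <- function() {
  defs <- .default_attribute_counts()
  attrs <- lapply(defs, function(d) list(label = d$label))
  for (nm in names(defs)) {
    attrs[[nm]]$categories <- if (nm == "age_range") {
      .default_age_bins()$labels
    } else {
      names(defs[[nm]]$counts)
    }
  }
  attribute_schema(
    attrs,
    na_label = "N/A",
    na_attributes = c("surgical_margin", "extranodal_extension",
                      "lymphovascular_invasion", "perineural_invasion"),
    numeric_bins = list(age_range = .default_age_bins()),
    outcome_cutoff_months = 60L
  )
}

#' Default marginal distribution
#'
#' Per-attribute category probabilities matching the reference cohort's
#' published marginal counts (n = 897), normalised to sum to one. The age
#' marginal comes from a normal age model (mean 64, SD 8.88) integrated over
#' the decade bins. One published pathology row does not sum to the cohort
#' size; the counts are kept and normalised as printed.
#'
#' @param schema A `survrule_schema`; only [default_schema()] is supported.
#' @return A `survrule_marginals` object (see [marginal_spec()]).
#' @export
default_marginals <- function(schema = default_schema()) {
  defs <- .default_attribute_counts()
  probs <- lapply(names(defs), function(nm) {
    if (nm == "age_range") return(.default_age_probs())
    cnt <- defs[[nm]]$counts
    cnt / sum(cnt)
  })
  names(probs) <- names(defs)
  marginal_spec(schema, probs)
}

#' Published survival-length distribution of the reference cohort
#'
#' Six-bin grouped survival lengths (months): 1-12, 13-24, 25-36, 37-48,
#' 49-60 and beyond 60, with counts 367, 133, 46, 26, 10 and 315
#' (n = 897). The final bin holds the five-year survivors.
#'
#' @return A `survrule_grouped` object (see [grouped_lengths()]).
#' @export
reference_survival_lengths <- function() {
  grouped_lengths(c(367, 133, 46, 26, 10, 315))
}

#' Overall death proportion of the reference cohort
#'
#' Deaths within five years over cohort size (582/897), the baseline death
#' probability used by [generate_cohort()] when none is supplied.
#'
#' @return A single proportion.
#' @export
reference_death_rate <- function() {
  g <- reference_survival_lengths()
  1 - grouped_survival_rate(g)
}
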