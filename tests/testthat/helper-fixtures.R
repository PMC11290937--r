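# Small fixtures built in code.

# Three-attribute schema with one N/A-bearing attribute and decade age bins.
tiny_schema <- function() {
  attribute_schema(
    attributes = list(
      gender = list(label = "Gender", categories = c("Male", "Female")),
      margin = list(label = "Surgical margin",
                    categories = c("Negative", "Positive", "N/A")),
      age_range = list(label = "Age range",
                       categories = c("<60", ">=60"))
    ),
    na_label = "N/A",
    na_attributes = "margin",
    numeric_bins = list(age_range = list(source = "age",
                                         edges = c(-Inf, 60, Inf),
                                         labels = c("<60", ">=60"))),
    outcome_cutoff_months = 60L
  )
}

tiny_cohort <- function(schema = tiny_schema()) {
  as_cohort(data.frame(
    gender = c("Male", "Female", "Male"),
    margin = c("Negative", "N/A", "Positive"),
    age_range = c("<60", ">=60", ">=60"),
    survival_months = c(12L, 72L, 60L),
    dead_within_followup = c(TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE), schema)
}
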