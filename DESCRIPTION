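Package: survrule
Title: Association-Rule Mining of Five-Year Cancer Survivability
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mines and ranks clinicopathologic antecedents of five-year
    survivability in categorical patient cohorts. Provides transaction
    encoding of patient records, Apriori frequent-itemset mining,
    association rules scored with support, confidence, lift, cosine,
    the phi correlation coefficient, the Pearson chi-square statistic
    and the odds ratio with a Woolf confidence interval, redundancy
    filtering and confidence ranking of rules, grouped and
    Kaplan-Meier survival estimation, and a seedable synthetic-cohort
    generator with plantable antecedent-to-outcome associations for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
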