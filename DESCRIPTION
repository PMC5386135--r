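Package: triomr
Title: Mendelian Randomization for Intrauterine Effects Using Parent-Offspring Trios
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for testing causal intrauterine effects of maternal pregnancy
    exposures on offspring outcomes with maternal genetic instrumental variables.
    Provides a parent-offspring trio simulator with a variance-component
    parameterization (Mendelian transmission, optional assortative mating and
    horizontal pleiotropy), two-stage least squares estimation under four
    adjustment strategies (unadjusted, offspring-genotype adjusted,
    offspring-plus-paternal adjusted, and maternal non-transmitted haplotype
    instruments), transmitted/non-transmitted allele resolution from unphased
    trio dosages, one-sample summary-statistic sensitivity estimators (IVW,
    MR-Egger, weighted median, and the minus-0.5 same-trait correction), and a
    scenario-grid runner that aggregates replicate estimates into bias, power
    and coverage summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
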