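Package: voleherit
Title: Heritability of Social Behaviour and Vasopressin Receptor Density in
    Laboratory Prairie Voles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pedigree-based quantitative genetics for laboratory prairie-vole
    colonies. Builds numerator relationship matrices from parentage records,
    fits a Bayesian animal model with direct (focal male) and indirect
    (partner and stranger female) additive genetic effects by Gibbs sampling,
    and reports posterior heritability estimates with convergence
    diagnostics, alongside a parent-offspring regression cross-check. A
    synthetic-colony simulator emulates the study's full-sib crossing scheme
    so that variance-component recovery can be scored against known truth.
    Also provides the supporting behavioural statistics: paired
    before/after-mating comparisons with Bonferroni control, Spearman screens
    of behaviour against regional vasopressin-1a-receptor density, and
    partner-preference summaries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
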