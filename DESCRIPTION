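Package: masldnlp
Title: Rule-Based Extraction of MASLD Histology from Liver Biopsy Pathology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based clinical natural language processing pipeline that
    converts free-text liver-biopsy pathology reports into structured
    histology labels for metabolic dysfunction-associated steatotic liver
    disease (MASLD): the four core features (steatosis, lobular inflammation,
    hepatocyte ballooning, steatohepatitis), cirrhosis assertion, and MASH CRN
    fibrosis stage F0-F4. Includes boilerplate stripping and parenchymal-biopsy
    screening, lexicon-driven concept matching with trigger-based negation
    scoping, fibrosis stage resolution from explicit stage notation or
    component descriptions, report-level MASLD categorisation with borderline
    policies, a validation-metric harness (sensitivity, specificity, PPV, NPV,
    F1, support), a synthetic labelled pathology-report generator for
    benchmarking, and person-years incidence-rate arithmetic with exact
    Poisson confidence intervals and cumulative incidence curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    stringi,
    survival,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
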