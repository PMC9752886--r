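Package: drugfunnel
Title: Genomic-Driven Drug Repurposing by Multi-Channel Gene Scoring and
    Connectivity Mapping
Version: 0.1.0
Authors@R:
    person("drugfunnel", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A reusable, tested implementation of a genomic-driven drug
    repurposing funnel for cancer gene lists: five functional-annotation
    channels (pathway, biological process, knockout-mouse phenotype,
    literature disease association, and tumor-vs-normal expression) are
    combined into a 0-5 gene score; risk genes (score >= 2) are intersected
    with a drug-target table; candidate drugs are ranked by a Connectivity
    Map style weighted Kolmogorov-Smirnov signature score normalized to a
    tau scale of -100..100 against a touchstone background; surviving
    candidates are triaged by clinical-trial / preclinical / no-evidence
    status. A synthetic-data module generates every pipeline input with
    planted structure, and a bundled pancreatic-cancer case study provides
    a deterministic worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
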