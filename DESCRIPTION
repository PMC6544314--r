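Package: socialinteractome
Title: Co-Expression Modules and Social Gene Regulatory Networks from
    Nurse-Larva Transcriptomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse social gene regulation between caregiving
    ant nurse workers and the larvae they feed. Implements short
    time-series co-expression module mining over a five-stage larval
    developmental series (81 predefined log2 fold-change profiles,
    Pearson assignment, permutation nulls, one-sided binomial enrichment
    with Bonferroni correction, parallel/anti-parallel shared-module
    detection and drop-1 jackknife confidence intervals), stage-association
    differential expression with a random-nurse control filter,
    random-forest inference of directed regulatory networks over combined
    nurse+larva meta-samples with within-tissue/social connectivity and a
    per-gene sociality index, downstream statistics relating network
    position to selective constraint, evolutionary age and secretion
    status, and a synthetic-data generator that plants recoverable
    co-expression modules, cross-tissue regulatory edges and
    evolution-annotation correlations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
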