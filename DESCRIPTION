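Package: tubertrace
Title: Vertical Transfer and Heritability of Tuber Microbiota Across Host Generations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for tracing bacterial amplicon sequence variants (ASVs) across
    ordered host generations and tuber compartments. Classifies taxa as vertically
    transferred (present in the founder seed community) or horizontally acquired,
    computes per-generation percentages and stage-wise retention flows, models
    transfer probability with binomial regression (Wald chi-square tests, optional
    cluster-robust errors, Firth-type bias reduction), estimates per-taxon
    broad-sense heritability of transformed abundance by one-way restricted maximum
    likelihood with a permutation null, and provides cumulative sum scaling
    normalization, alpha diversity, Bray-Curtis dissimilarity and PERMANOVA.
    Includes a synthetic multi-generation community generator with a known
    ground-truth ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    vegan,
    emmeans,
    sandwich,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    yaml,
    withr
Config/testthat/edition: 3
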