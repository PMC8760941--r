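Package: convloss
Title: Convergent Chemoreceptor Gene Loss Across Independent Parasite-Host Lineage Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers convergent gene-family loss across independently evolved
    parasite-host species pairs from gene trees. Provides reference-outgroup
    ortholog clustering with support-based polytomy collapsing, per-lineage
    gain/loss calling from paralog counts, an exact binomial convergence test
    against the product of per-species marginal loss probabilities (with
    Clopper-Pearson intervals and exact or simulated power), ancestral-subfamily
    enrichment, post-processing of selection-intensity (RELAX-style k) results,
    and a birth-death gene-family simulator along a species tree for
    calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    ape,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
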